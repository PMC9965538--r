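---
title: "Methods: genome-based phage taxonomy and feature analyses in phagetax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-based phage taxonomy and feature analyses in phagetax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phagetax` re-implements, at desk scale, the computational pipeline used
to place a newly isolated *Kuravirus*-like podovirus among its relatives
and to characterize its genome features.  This vignette explains the
models and conventions behind each stage, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical choices that make the pipeline deterministic.

## The alignment substrate

Every genome-scale statistic in the package is built from local
alignments produced by an in-package seed-and-extend engine
(`find_hsps_nt`), because whole-genome pairs of 70–80 kb are far too
large for full dynamic programming.  The engine follows the classic
BLAST architecture:

* exact word seeds of length `word_size` (default 11, a
  megablast-like choice that retains sensitivity at the ≥ 70%
  identities relevant to genus demarcation) on both strands;
* ungapped extension with x-drop termination (`x_drop`, default 20
  under match +1 / mismatch −2): extension stops when the running score
  falls `x_drop` below its maximum, and the segment is reported at the
  maximum;
* banded gapped x-drop extension with affine gaps (a gap of length
  *L* costs `gap_open + gap_extend·L`, defaults 5 + 2·L).  The live
  band of the dynamic program is pruned adaptively by the same x-drop
  rule, so the work per extension is proportional to the extension
  length times a narrow band width.

HSPs below `min_hsp_score` (default 30) are discarded; ties are ordered
by score (descending), then query start, then subject start, which makes
all downstream computations order-deterministic.  `N` is treated as a
mismatch everywhere, including against another `N`.  In tests the engine
is checked against a full Smith–Waterman oracle on pairs up to 300 bp:
scores agree exactly whenever the optimal alignment contains an exact
word seed and the x-drop never prunes the optimal path; we state a
tolerance of 25 score units for the remaining cases.

Protein alignment (`align_proteins`) is an exact Smith–Waterman with
affine gaps (11 + 1·L) under BLOSUM62 with the `X` row and column forced
to zero.  It is validated against an independent dynamic-programming
implementation on hundreds of random pairs; agreement is exact.

### Merging overlapping HSPs

Whole-genome statistics need each genome position counted once.
`merge_hsps` resolves overlaps greedily by descending score: a
lower-scoring HSP is trimmed to the positions not yet covered, and its
identity count is apportioned proportionally to the retained fraction of
its span, rounded half-up.  The proportional apportionment (rather than
re-aligning trimmed windows) is deterministic, cheap, and wrong by at
most about one nucleotide per trimmed HSP.

## Intergenomic similarity and threshold taxonomy

The similarity between genomes A and B is

```
sim(A,B) = 100 · (id_A + id_B) / (L_A + L_B)
```

with `id_X` the merged identical positions projected on genome X and
`L_X` its length.  This identity-over-total-length dialect is pinned
here explicitly; it makes `sim(A,A) = 100` exactly and is symmetric by
construction.  Matrix entries are kept at full precision internally and
rounded to one decimal only on output.

Species and genus partitions are connected components of the graphs with
edges at `sim ≥ 95` and `sim ≥ 70` respectively (single linkage).  We
chose single linkage because the demarcation criterion is phrased as an
edge rule ("≥ 70% similarity to cluster into a genus") and because it is
deterministic and permutation-invariant; whether the reference
implementation of the similarity heatmap uses single or complete linkage
near the threshold is not documented, and cluster counts close to the
threshold can be sensitive to that choice.  Because every species edge
is also a genus edge, the genus partition is a coarsening of the species
partition for any matrix.

## The protein-sharing network

Proteins from all genomes are clustered into protein clusters (PCs):
edges require local-alignment identity ≥ 0.35 covering ≥ 0.5 of the
shorter protein, followed by Markov clustering (MCL) at inflation 2.0.
These two thresholds are pinned in the package; the upstream tool runs
with undocumented defaults.  Candidate protein pairs are prefiltered by
shared 4-mers (at least two distinct shared words, skipping words that
occur in more than 100 proteins); at the ≥ 35% identity needed for an
edge this misses essentially nothing in practice while reducing the
all-vs-all alignment cost by two orders of magnitude.

A genome pair sharing `k` PCs, with `n_A` and `n_B` PCs out of a
universe of `U`, gets the edge weight

```
w = −log10 P(X ≥ k),   X ~ Hypergeometric(U, n_A, n_B)
```

computed in log space (`phyper(..., log.p = TRUE)`) and capped at 300 to
guard underflow; edges below weight 1 are dropped.  Note that with few
genomes the universe is small and large overlaps can be *forced*
(`k ≥ n_A + n_B − U`), making them insignificant — significance of
shared content is only meaningful against a reasonably large PC
universe, which is why the network stage is most informative when run
across many genomes.

Viral clusters (VCs) come from MCL on the weighted genome graph
(self-loops set to each node's maximum incident weight, inflation 2.0);
sub-VCs from a second MCL pass within each VC at inflation 4.0, so the
sub-VC partition refines the VC partition by construction.  This
two-pass MCL replaces the reference tool's ClusterONE-plus-splitting
machinery: it reproduces the VC/sub-VC semantics deterministically
without reimplementing ClusterONE.  Our MCL iterates expansion
(squaring) and inflation on a column-normalized sparse matrix until the
change falls below 1e-6 (at most 100 iterations), pruning entries below
1e-8; clusters are the connected components of the limit matrix's
support.  The procedure involves no randomness.

## GBDP distances, trees and OPTSIL clustering

From the merged per-genome coverages `H_A, H_B` and identities
`I_A, I_B`:

```
d0 = 1 − (H_A + H_B)/(L_A + L_B)
d4 = 1 − (I_A + I_B)/(H_A + H_B)    (1 when there are no HSPs)
d6 = 1 − (I_A + I_B)/(L_A + L_B)
```

all clamped to [0, 1].  The algebraic identity
`(1 − d6) = (1 − d4)(1 − d0)` follows directly and is asserted to 1e-12
in the tests.  `d0`, the coverage-based formula optimised for
nucleotide data, is the default.

Trees are built by neighbor joining (`ape::nj`) with negative branch
lengths clamped to zero.  The reference pipeline infers
minimum-evolution trees with SPR post-processing; we use NJ because it
is deterministic, fast, and recovers the same topology on additive
matrices (a property the tests verify on random 4–6-taxon additive
trees).  Exact tree topology on real data is therefore not a claim this
package makes.

Branch supports use a pseudo-bootstrap in which the resampling unit is
the merged HSP: for every genome pair, the trimmed HSP contributions are
resampled with replacement (same count), distances recomputed, and a
replicate NJ tree built; the support of an internal bipartition of the
point-estimate tree is the percentage of replicates containing it.  The
replicate count (default 100) follows standard practice; the resampling
unit is the GBDP convention, since only the replicate count — not the
unit — is typically reported.

OPTSIL-style clustering takes a distance threshold and a fraction *F* of
links (distances at or below the threshold) required for cluster
fusion: repeatedly merge the cluster pair with the maximal qualifying
link fraction (ties: smaller mean inter-cluster distance, then
lexicographic by smallest member id), until no pair qualifies.  *F* = 1
yields partitions satisfying the complete-linkage fixpoint (all
intra-cluster distances below threshold, no fully-linked cluster pair
remaining); *F* → 0 yields single-linkage components.  Distance
thresholds for species/genus/family boundaries are taken as explicit
parameters because no calibrated values are available at desk scale
(default 0.3 in the pipeline configuration, a placeholder threshold, and
*F* = 0.5).

## Genome features

**Adapter screening.**  The first and last 150 nt of a read are scanned
for the two library Y-adapter sequences (and reverse complements) at
≥ 75% identity; a matched prefix/suffix is removed, extrapolating the
full adapter footprint beyond the aligned match so that terminal
mismatches leave no residual adapter bases.  Trimming never touches the
read interior and is idempotent; on short reads the two windows are
processed sequentially so they cannot trim the same match twice.

**DTR detection from reads.**  Reads are trimmed, filtered to at least
the assembly length (generalizing a fixed read-length cutoff so the
operation works for any genome: only reads spanning a whole genome unit
can show the repeat at both ends), and oriented against the assembly.  A
repeat is called on a read when a ≥ 50-bp start window re-occurs at
≥ 90% identity at the molecule's end in the same orientation.  The
per-read repeat length is measured as the aligned span on the
*assembly* axis (averaging the evidence from both read ends): because
the assembly is error-free, this measurement is immune to indel
sequencing errors inside the read's own repeat copies, which would
otherwise jitter the per-read lengths by ±1–2 bp and blur the modal
length.  The reported DTR length is the mode of the per-read lengths
(ties broken by total alignment score) and the DTR sequence a per-column
majority consensus over the reads at the modal length.

**DTR in an assembly.**  The longest prefix (15–1000 bp) matching the
suffix at ≥ 95% Hamming identity.  On random sequence the expected
false-positive length is far below the 15-bp floor.

**ORF calling.**  A deterministic maximal-ORF caller (both strands, all
frames, start codons ATG/GTG/TTG, first start after the previous
in-frame stop, ≥ 30 aa) replaces trained gene finders.  This removes a
model dependency at the cost of approximate gene counts on real data;
the simulator plants an in-frame stop immediately upstream of every gene
so that planted genes are recovered exactly, which is what the recovery
tests measure.

**Slippery sites and the −1 frameshift.**  Slippery heptamers match
`N1N1N1N2N2N2N3` (positions 1–3 identical, 4–6 identical) — the minimal
pattern consistent with the canonical `GGGAAAG` — within a 30-nt window
upstream of the stop.  The slippage convention is pinned by arithmetic:
the ribosome translates zero-frame codons through the codon ending at
the heptamer's last base (which must lie on a codon boundary), then
resumes one nucleotide back — re-reading that base — in the −1 frame
until the next stop.  For a CDS starting at 7253 with the heptamer at
8293–8299 and a −1-frame stop ending at 9930 this yields 353 aa
(natural) and 892 aa (extended), the unique convention consistent with
both isoform lengths; the span-plus-one-re-read-base is always divisible
by 3.  Extensions of ≤ 20 aa are flagged `premature_stop`,
operationalizing "indistinguishable in size" for degenerate cases where
a −1-frame stop sits just downstream of the heptamer.

**Codon usage and bias.**  Codon usage is reported as synonymous shares
(each amino-acid family summing to 1, stop codons excluded, terminal
stops discarded), because tRNA-compensation arguments are about a
codon's share *within its family*, not its global frequency.  Fold
change is the phage/host share ratio; when either raw count of a codon
is zero, a pseudocount of 0.5 is added to the whole family's counts in
both tables and the entry is flagged unstable.  All six Arg codons are
always reported — zero-count codons are never suppressed.  Entries at
≥ 2-fold (either direction) are returned.

## The pangenome

Ortholog groups use the same protein graph as the network stage but at
the reduced identity threshold of 0.30 with MCL inflation 1.5; the
coverage requirement (≥ 0.5 of the shorter protein) is an addition that
prevents domain-level chaining between multi-domain proteins.  Direct
all-vs-all clustering replaces CD-HIT pre-clustering, paralog splitting
and synteny refinement, which matter at scales far beyond a few dozen
phage genomes; the core-proteome size depends mainly on the identity
threshold.  Core groups have at least one member in every genome;
per-genome accessory percentages are
`100·(1 − core members / proteome size)`.  Marker ranking uses the mean
pairwise identity over member pairs from distinct genomes; "similarity"
is the BLOSUM62 positive-score column fraction of the same alignments.

## The simulator: what it emulates, and what it does not

`synthesize_phage_genome` builds genomes with the structure the analyses
assume: identical terminal repeats (default 193 bp), a three-block
(late/middle/early) forward-strand gene layout, one gene carrying an
in-frame `GGGAAAG` whose −1-frame extension exceeds the natural product
by ≥ 200 aa, and genes sampled codon-by-codon from an explicit
codon-usage profile.  The default profile solves, by one-dimensional
root finding, for the within-family GC weighting that hits the target
coding GC (default 0.421) under uniform amino-acid usage, then pins the
Arg-AGA share to 0.202; the host-like profile uses GC 0.508 and AGA
share 0.036.  Intergenic base composition is solved after gene synthesis
so the realized genome GC matches the target within ±0.01 even at high
coding density.  Amino-acid usage is uniform across the 20 residues — a
simplification that leaves the synonymous-share signal intact, which is
what the codon analyses consume.

`evolve_genome` applies binomial per-site substitutions at the requested
divergence plus indel events at `divergence × indel_rate` per site with
geometric lengths (mean 3 bp); divergences above 0.6 are rejected
because the seed-and-extend engine's signal assumption breaks down.
`simulate_clustered_genomes` plants a two-level structure (root →
cluster ancestors at `inter_divergence` = 0.45 → members at
`intra_divergence` = 0.10): members of one cluster end up near 77–79%
intergenomic similarity (above the genus threshold, below the species
threshold), members of different clusters effectively at 0.  The
defaults were chosen once to straddle the 70%/95% thresholds; real
intra-genus divergences are not being matched.

`simulate_reads` emulates packaging from DNA concatemers: a full-length
read is one genome unit including both terminal repeat copies, other
reads are uniform sub-windows; about half the reads are
reverse-complemented, Y-adapters are appended at both ends, and errors
are iid per base (defaults: substitutions 0.005, insertions 0.002,
deletions 0.002).  The error model deliberately ignores homopolymer
effects, quality correlation and chimeras; passing the planted-recovery
tests therefore shows the detectors tolerate iid noise at nanopore-like
rates, not that they are robust to every real-world artifact.
Quality strings are synthetic (Gaussian around Q20).

## Problem sizes and determinism

All generators are pure functions of their seeds (the package saves and
restores the caller's RNG state).  The test suite exercises the
threshold-clustering recovery on twenty seeded replicates of a
12-genome, 40-kb, 4-cluster simulation; termini recovery on ten seeded
replicates of 20 full-length reads from a 20-kb genome with a planted
193-bp repeat; and the oracle suites (hypergeometric enumeration to
universe 12, Smith–Waterman oracle on 200 protein pairs, NJ recovery on
random additive trees, the d-formula identity, and the OPTSIL linkage
limits).  These sizes keep a full run comfortably in the minutes range
on a single core while leaving the statistical margins wide: simulated
within-cluster similarities sit ~7 points above the genus threshold, and
between-cluster similarities are essentially zero.

## Known limitations

* Gene calling is rule-based; CDS counts on real genomes will deviate
  from curated annotations, so annotation-dependent quantities (exact
  CDS counts, real-data core-proteome sizes) are approximate.
* The similarity statistic's dialect and the protein-edge thresholds
  are pinned choices; near-threshold cluster counts on real data may be
  sensitive to them.
* The network stage reports both VC/sub-VC and similarity-based genus
  partitions without arbitrating between them when they disagree, as
  they genuinely can.
* E-value statistics, translated searches, tRNA detection and
  database-dependent functional annotation are out of scope.
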