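# phagetax

Genome-based taxonomy and genome-feature characterization for
*Kuravirus*-like *Escherichia* phages — and, more generally, for any small
set of closely to moderately related phage genome assemblies.

Modern phage taxonomy is genome-based: the ICTV demarcates species at
≥ 95% and genera at ≥ 70% whole-genome intergenomic similarity, while
complementary evidence comes from shared protein content (reticulate
gene-sharing networks) and whole-genome distance phylogenies.
`phagetax` implements that entire computational pipeline at desk scale,
together with the genome-feature analyses that characterize members of
this podovirus group: short direct terminal repeats (DTRs) detected from
long reads, programmed −1 ribosomal frameshift isoforms of the major
capsid protein, codon-usage bias against the host, and the core
proteome.  A synthetic genome/read simulator with planted ground truth
makes every stage testable without downloading anything.

## What it computes

* **Local alignment engine** (`find_hsps_nt`, `align_proteins`) — a
  seed-and-extend HSP search (exact word seeds, ungapped x-drop
  extension, banded gapped x-drop extension; match/mismatch +1/−2, gaps
  5/2, word size 11) replacing BLASTn, and an exact Smith–Waterman with
  affine gaps under BLOSUM62 replacing BLASTp.
* **Intergenomic similarity** (`intergenomic_similarity`,
  `similarity_matrix`, `assign_taxa`) — the VIRIDIC-style statistic

  `sim(A,B) = 100 · (id_A + id_B) / (L_A + L_B)`

  where `id_X` counts identical aligned positions of the merged
  (overlap-trimmed) HSPs projected on genome X, followed by
  single-linkage threshold clustering at 95% (species) and 70% (genus).
* **Protein-sharing network** (`build_protein_clusters`,
  `build_genome_network`, `cluster_viral`) — protein clusters by Markov
  clustering (MCL), genome-pair edges weighted by the upper-tail
  hypergeometric probability `−log10 P(X ≥ k)` of sharing `k` protein
  clusters, and two-pass MCL into viral clusters (VCs) and sub-VCs.
* **GBDP phylogeny** (`gbdp_distance`, `nj_tree`, `bootstrap_supports`,
  `optsil_cluster`) — Genome-BLAST Distance Phylogeny formulas
  `d0 = 1 − (H_A+H_B)/(L_A+L_B)`, `d4 = 1 − (I_A+I_B)/(H_A+H_B)`,
  `d6 = 1 − (I_A+I_B)/(L_A+L_B)` (coverage `H`, identities `I`),
  neighbor-joining trees, pseudo-bootstrap supports by per-pair HSP
  resampling, and OPTSIL-style fraction-of-links clustering.
* **Genome features** (`detect_termini_from_reads`,
  `detect_dtr_in_assembly`, `find_orfs`, `find_slippery_sites`,
  `predict_extended_isoform`, `codon_usage`, `codon_bias`,
  `trim_adapters`) — DTR detection from full-length nanopore-like reads
  and assemblies, a deterministic ORF caller, slippery-heptamer
  (`N1N1N1N2N2N2N3`) scanning, −1 frameshift isoform prediction, and
  synonymous codon-usage shares with phage/host fold changes.
* **Pangenome** (`cluster_orthologs`, `core_proteome`, `rank_markers`) —
  ortholog groups at a reduced 30% identity threshold, core-proteome
  extraction and conservation-ranked marker genes.
* **Simulator** (`synthesize_phage_genome`, `evolve_genome`,
  `simulate_clustered_genomes`, `simulate_reads`) — ~78 kb / 42.1% GC
  genomes with 193-bp DTRs, a modular gene layout, one planted
  frameshift gene, codon-usage signal, planted cluster structure
  straddling the 70%/95% thresholds, and nanopore-like reads with
  Y-adapters.

## Worked example

```r
library(phagetax)

## 1. the -1 programmed frameshift of the major capsid protein gene:
##    a CDS at 7253-8314 with the slippery heptamer GGGAAAG at 8293-8299
fc <- make_frameshift_construct(seed = 1)
sites <- find_slippery_sites(fc$genome, fc$cds)
sites[, c("position", "heptamer", "cds_label", "offset_to_stop")]
#>   position heptamer cds_label offset_to_stop
#> 1     8293  GGGAAAG       mcp             21
predict_extended_isoform(fc$genome, fc$cds, sites[1, ])
#> <slippage_report> natural 353 aa, extended 892 aa (-1 stop ends at 9930)

## 2. genus demarcation on a simulated two-cluster genome set
gs <- genome_spec(length = 20000, n_genes = 20, seed = 1)
genomes <- simulate_clustered_genomes(
  cluster_spec(n_clusters = 2, genomes_per_cluster = 3, seed = 42), gs)
m <- similarity_matrix(genomes)
print(m)
#>         c01_g01 c01_g02 c01_g03 c02_g01 c02_g02 c02_g03
#> c01_g01   100.0    78.2    76.5     0.0     0.0     0.0
#> c01_g02    78.2   100.0    77.9     0.0     0.0     0.0
#> c01_g03    76.5    77.9   100.0     0.0     0.0     0.0
#> c02_g01     0.0     0.0     0.0   100.0    78.8    76.4
#> c02_g02     0.0     0.0     0.0    78.8   100.0    77.6
#> c02_g03     0.0     0.0     0.0    76.4    77.6   100.0
assign_taxa(m)$genera$membership
#> c01_g01 c01_g02 c01_g03 c02_g01 c02_g02 c02_g03
#>       1       1       1       2       2       2

## 3. codon-usage bias: Arg-AGA synonymous shares of 20.2% (phage)
##    vs 3.6% (host)
phage <- codon_usage_table(c(AGA = 202, AGG = 160, CGA = 160,
                             CGC = 159, CGG = 160, CGT = 159))
host  <- codon_usage_table(c(AGA = 36, AGG = 193, CGA = 193,
                             CGC = 192, CGG = 193, CGT = 193))
codon_bias(phage, host)
#>   codon aa phage_share host_share fold_change direction unstable
#> 1   AGA  R       0.202      0.036    5.611111        up    FALSE
```

The frameshift report reads: the natural gene product is 353 aa; when
the ribosome slips −1 at the heptamer (re-reading one nucleotide) it
continues to a stop ending at 9930, giving a 892-aa extended isoform.
Within a simulated cluster, genomes sit near 77–79% similarity (above
the 70% genus threshold but below the 95% species threshold); between
clusters similarity collapses, so threshold clustering recovers two
genera.  The AGA fold change of ≈ 5.6 is the phage-over-host ratio of
synonymous shares.

The whole pipeline (ORFs → network → similarity/taxa → GBDP/OPTSIL →
pangenome) runs as one call:

```r
res <- run_classify(genomes, pipeline_config(seed = 1), out_dir = "out")
```

writing the similarity matrix, cluster assignments, network edge list,
newick tree, presence/absence matrix and a manifest (seed + config
hash) under `out/`.

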