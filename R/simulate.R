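# Synthetic phage genomes, evolved genome clusters and nanopore-like reads.
#
# The generator plants every signal the downstream analyses look for:
# short direct terminal repeats, a modular late/middle/early gene layout,
# one gene carrying a slippery heptamer that drives a -1 frameshift
# extension, codon usage drawn from an explicit profile, and a planted
# cluster (genus/species) divergence structure.

Y_ADAPTER_TOP <- "GGCGTCTGCTTGGGTGTTTAACCTTTTTTTTTTAATGTACTTCGTTCAGTTACGTATTGCT"
Y_ADAPTER_BOTTOM <- "GCAATACGTAACTGAACGAAGT"

#' Nanopore Y-adapter sequences used as simulator/trimming defaults
#' @return Named character vector with elements `top` and `bottom`.
#' @export
y_adapters <- function() c(top = Y_ADAPTER_TOP, bottom = Y_ADAPTER_BOTTOM)

#' Specification of a synthetic phage genome
#'
#' Defaults emulate a ~78 kb, 42.1% GC podovirus genome with 193-bp
#' direct terminal repeats (DTRs), 120 genes in three transcriptional
#' blocks and one gene carrying a slippery heptamer.
#'
#' @param length Genome length in bp (including both DTR copies).
#' @param gc Target GC fraction.
#' @param dtr_len Direct terminal repeat length in bp (0 = none); must be
#'   below `length/10`.
#' @param n_genes Number of forward-strand CDSs.
#' @param slippage_gene Plant one -1 programmed frameshift gene?
#' @param trna_codon Codon whose usage the genome's (conceptual) own tRNA
#'   compensates; recorded in the truth metadata.
#' @param codon_bias_profile Optional [codon_usage_table()] used to sample
#'   gene codons; defaults to [synthetic_phage_codon_profile()] solved at
#'   `gc`.
#' @param seed Integer seed; the generator is a pure function of it.
#' @param id Genome id.
#' @return A list of class `genome_spec`.
#' @export
genome_spec <- function(length = 78000L, gc = 0.421, dtr_len = 193L,
                        n_genes = 120L, slippage_gene = TRUE,
                        trna_codon = "AGA", codon_bias_profile = NULL,
                        seed = 1L, id = "synthetic_phage") {
  stopifnot(length > 0, gc > 0, gc < 1, dtr_len >= 0, n_genes >= 1)
  if (dtr_len >= length / 10) stop("dtr_len must be below length/10")
  structure(list(length = as.integer(length), gc = gc,
                 dtr_len = as.integer(dtr_len), n_genes = as.integer(n_genes),
                 slippage_gene = isTRUE(slippage_gene),
                 trna_codon = trna_codon,
                 codon_bias_profile = codon_bias_profile,
                 seed = as.integer(seed), id = id),
            class = "genome_spec")
}

#' Specification of a planted cluster structure
#'
#' Each cluster descends from its own ancestor; ancestors descend from a
#' common root.  Defaults straddle the 70%/95% intergenomic-similarity
#' demarcation thresholds: members of one cluster stay above the genus
#' threshold, members of different clusters fall far below it.
#'
#' @param n_clusters Number of clusters.
#' @param genomes_per_cluster Integer vector (recycled to `n_clusters`).
#' @param intra_divergence Substitution fraction member vs cluster ancestor.
#' @param inter_divergence Substitution fraction ancestor vs root.
#' @param indel_rate Fraction of mutation events that are indels.
#' @param seed Integer seed.
#' @return A list of class `cluster_spec`.
#' @export
cluster_spec <- function(n_clusters = 4L, genomes_per_cluster = 3L,
                         intra_divergence = 0.10, inter_divergence = 0.45,
                         indel_rate = 0.05, seed = 1L) {
  stopifnot(n_clusters >= 1, all(genomes_per_cluster >= 1),
            intra_divergence < inter_divergence,
            intra_divergence >= 0, inter_divergence <= 0.6)
  genomes_per_cluster <- rep_len(as.integer(genomes_per_cluster), n_clusters)
  structure(list(n_clusters = as.integer(n_clusters),
                 genomes_per_cluster = genomes_per_cluster,
                 intra_divergence = intra_divergence,
                 inter_divergence = inter_divergence,
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "cluster_spec")
}

#' Read-simulation parameters
#'
#' The error model is iid per base (substitutions/insertions/deletions),
#' a deliberate simplification of nanopore behaviour.  Adapters default
#' to the Y-adapter top/bottom sequences used for library preparation.
#'
#' @param n_reads Number of reads.
#' @param sub_rate,ins_rate,del_rate Per-base error fractions in `[0, 0.2]`.
#' @param frac_full_length Fraction of reads spanning a whole genome unit
#'   (including both terminal repeat copies).
#' @param add_adapters Prepend/append adapter sequences?
#' @param adapter_top,adapter_bottom Adapter sequences.
#' @param seed Integer seed.
#' @return A list of class `read_sim_params`.
#' @export
read_sim_params <- function(n_reads = 20L, sub_rate = 0.005, ins_rate = 0.002,
                            del_rate = 0.002, frac_full_length = 0.3,
                            add_adapters = TRUE,
                            adapter_top = Y_ADAPTER_TOP,
                            adapter_bottom = Y_ADAPTER_BOTTOM, seed = 1L) {
  stopifnot(n_reads >= 0, sub_rate >= 0, sub_rate <= 0.2,
            ins_rate >= 0, ins_rate <= 0.2, del_rate >= 0, del_rate <= 0.2,
            frac_full_length >= 0, frac_full_length <= 1)
  structure(list(n_reads = as.integer(n_reads), sub_rate = sub_rate,
                 ins_rate = ins_rate, del_rate = del_rate,
                 frac_full_length = frac_full_length,
                 add_adapters = isTRUE(add_adapters),
                 adapter_top = adapter_top, adapter_bottom = adapter_bottom,
                 seed = as.integer(seed)),
            class = "read_sim_params")
}

BASES <- c("A", "C", "G", "T")

# iid background with P(G)=P(C)=gc/2
random_dna <- function(n, gc) {
  if (n <= 0) return(character(0))
  sample(BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

stop_codons <- c("TAA", "TAG", "TGA")

genetic_code_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(names(gc), unname(gc))
}

#' Synthetic codon-usage profile at a target GC
#'
#' Within each amino-acid family, synonymous codons are weighted by
#' `p^g (1-p)^(3-g)` where `g` is the codon's G+C count; `p` is solved so
#' that the expected coding GC (under uniform amino-acid usage) matches
#' `gc`.  The Arg family is then overridden to pin the AGA synonymous
#' share, emulating the elevated AGA usage of a phage carrying its own
#' Arg-AGA tRNA (or, for a host-like profile, a low AGA share).
#'
#' @param gc Target coding GC fraction.
#' @param aga_share Synonymous share of AGA within the Arg family
#'   (`NULL` = leave unpinned).
#' @return A [codon_usage_table()].
#' @export
synthetic_phage_codon_profile <- function(gc = 0.421, aga_share = 0.202) {
  fam <- genetic_code_families()
  gcc <- function(codon) vapply(strsplit(codon, ""), function(v)
    sum(v %in% c("G", "C")), numeric(1))
  shares_at <- function(p) {
    lapply(fam, function(cods) {
      w <- p^gcc(cods) * (1 - p)^(3 - gcc(cods))
      stats::setNames(w / sum(w), cods)
    })
  }
  exp_gc <- function(p) {
    sh <- shares_at(p)
    mean(vapply(sh, function(s) sum(s * gcc(names(s))) / 3, numeric(1)))
  }
  p <- stats::uniroot(function(p) exp_gc(p) - gc, c(0.02, 0.98))$root
  sh <- shares_at(p)
  if (!is.null(aga_share)) {
    r <- sh[["R"]]
    other <- setdiff(names(r), "AGA")
    r[other] <- r[other] / sum(r[other]) * (1 - aga_share)
    r["AGA"] <- aga_share
    sh[["R"]] <- r
  }
  counts <- unlist(unname(sh)) * 10000
  names(counts) <- unlist(lapply(sh, names))
  codon_usage_table(counts)
}

#' Synthetic host-like codon-usage profile
#'
#' A higher-GC coding profile with a low Arg-AGA synonymous share,
#' emulating an enterobacterial host against which phage codon bias is
#' measured.
#'
#' @param gc Target coding GC fraction.
#' @param aga_share Synonymous share of AGA within the Arg family.
#' @return A [codon_usage_table()].
#' @export
synthetic_host_codon_profile <- function(gc = 0.508, aga_share = 0.036) {
  synthetic_phage_codon_profile(gc = gc, aga_share = aga_share)
}

# sample n codons (aa uniform over the 20 families, codon by family share)
sample_codons <- function(n, profile) {
  if (n <= 0) return(character(0))
  fam_share <- split(stats::setNames(profile$share, profile$codon), profile$aa)
  aas <- sample(names(fam_share), n, replace = TRUE)
  vapply(aas, function(a) {
    s <- fam_share[[a]]
    if (length(s) == 1L) names(s) else sample(names(s), 1L, prob = s)
  }, character(1), USE.NAMES = FALSE)
}

# expected GC fraction of codons sampled from a profile (aa uniform)
profile_gc <- function(profile) {
  g <- vapply(strsplit(profile$codon, ""), function(v)
    sum(v %in% c("G", "C")), numeric(1))
  fam <- split(seq_len(nrow(profile)), profile$aa)
  mean(vapply(fam, function(i)
    sum(profile$share[i] * g[i]) / 3, numeric(1)))
}

# tail of the slippage gene: ... GGG GGA AAG GCT GCT GCT GCT TAA so that
# GGGAAAG sits in frame with its last base on a codon boundary, 15 nt
# before the stop end, and the -1 frame is stop-free through the CDS end
slippage_tail_codons <- c("GGG", "GGA", "AAG", "GCT", "GCT", "GCT", "GCT")

# -1-frame extension: completes the -1 codon straddling the natural stop,
# then n_ext stop-free -1 codons, then a -1-frame stop
slippage_extension <- function(n_ext, profile) {
  cods <- sample_codons(n_ext, profile)
  cods[cods %in% stop_codons] <- "CAG"
  paste0("CA", paste(cods, collapse = ""), "TAA")
}

#' Synthesize a phage genome with planted features
#'
#' The genome begins and ends with an identical `dtr_len`-bp repeat,
#' carries `n_genes` non-overlapping forward-strand CDSs laid out in
#' three blocks (late / middle / early), and (optionally) one CDS with an
#' in-frame slippery heptamer `GGGAAAG` near its stop whose -1-frame
#' extension exceeds the natural product by >= 200 aa.  Each CDS is
#' preceded by an in-frame stop so that a deterministic ORF caller
#' recovers the planted genes exactly.  Intergenic base composition is
#' adjusted so the realized genome GC matches the spec within ~0.01.
#'
#' @param spec A [genome_spec()].
#' @return A list with `genome` (a [genome_record()] carrying the
#'   features), `features` (the CDS table) and `slippage` (truth for the
#'   planted frameshift site, or `NULL`).
#' @export
synthesize_phage_genome <- function(spec = genome_spec()) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    L <- spec$length; dtr <- spec$dtr_len; n <- spec$n_genes
    Lc <- L - dtr
    profile <- spec$codon_bias_profile
    if (is.null(profile)) profile <- synthetic_phage_codon_profile(spec$gc)
    profile <- codon_usage_table(profile)

    lead <- dtr + 40L; tail_margin <- 60L
    block_gap <- 120L; min_spacer <- 24L
    slip_extra <- if (spec$slippage_gene) 740L else 0L
    budget <- Lc - lead - tail_margin - 2L * block_gap - slip_extra
    mean_cod <- floor((budget / n - min_spacer) / 3) - 2L
    if (mean_cod < 16L)
      stop("infeasible packing: too many genes for genome length")
    aa_len <- pmax(14L, round(stats::runif(n, 0.6, 1.4) * mean_cod))
    # shrink uniformly if the draw overshoots the budget
    need <- function(al) sum(3L * (al + 1L) + min_spacer)
    while (need(aa_len) > budget) aa_len <- pmax(14L, aa_len - 2L)

    slip_idx <- if (spec$slippage_gene) min(8L, n) else 0L
    block_of <- rep(c("late", "middle", "early"),
                    c(ceiling(n / 3), ceiling(n / 3),
                      n - 2L * ceiling(n / 3)))[seq_len(n)]

    pieces <- list(); pos <- 1L
    feats <- vector("list", n); slip_truth <- NULL
    fixed_gc <- 0  # G+C count over all non-random (gene/extension/marker) bases

    emit <- function(s) {
      pieces[[length(pieces) + 1L]] <<- s
      pos <<- pos + nchar(s)
      fixed_gc <<- fixed_gc + sum(strsplit(s, "")[[1]] %in% c("G", "C"))
    }
    # placeholder intergenic stretches are generated in a second pass so
    # their composition can compensate the coding GC; here we record gaps
    gaps <- list()
    emit_gap <- function(len, suffix = "") {
      gaps[[length(gaps) + 1L]] <<- list(at = length(pieces) + 1L,
                                         len = len, suffix = suffix)
      pieces[[length(pieces) + 1L]] <<- NA_character_
      pos <<- pos + len + nchar(suffix)
    }

    emit_gap(lead - 3L, "TAA")
    for (g in seq_len(n)) {
      if (g > 1L && block_of[g] != block_of[g - 1L])
        emit_gap(block_gap - 3L, "TAA")
      A <- aa_len[g]
      gene_start <- pos
      if (g == slip_idx) {
        body <- sample_codons(A - 1L - length(slippage_tail_codons), profile)
        cods <- c("ATG", body, slippage_tail_codons, "TAA")
      } else {
        cods <- c("ATG", sample_codons(A - 1L, profile), "TAA")
      }
      gene_seq <- paste(cods, collapse = "")
      emit(gene_seq)
      feats[[g]] <- data.frame(
        genome_id = spec$id, start = gene_start, end = pos - 1L,
        strand = "+", label = sprintf("gp%03d", g),
        product = paste0(block_of[g], " module protein"),
        stringsAsFactors = FALSE)
      if (g == slip_idx) {
        A_ <- A
        he <- gene_start + 3L * (A_ - 4L) - 1L   # heptamer end (codon boundary)
        stop_end <- pos - 1L
        ext <- slippage_extension(240L, profile)
        emit(ext)
        slip_truth <- list(
          cds_label = sprintf("gp%03d", g), heptamer = "GGGAAAG",
          heptamer_start = he - 6L, heptamer_end = he,
          natural_aa = A_, extended_aa = A_ + 242L,
          extended_end = he + 740L, trna_codon = spec$trna_codon)
        stopifnot(substr(gene_seq, he - 6L - gene_start + 1L,
                         he - gene_start + 1L) == "GGGAAAG")
      }
      emit_gap(min_spacer - 3L, "TAA")
    }
    if (pos > Lc + 1L) stop("infeasible packing: genes exceed genome core")
    final_fill <- Lc - pos + 1L
    gaps[[length(gaps) + 1L]] <- list(at = length(pieces) + 1L,
                                      len = final_fill, suffix = "")
    pieces[[length(pieces) + 1L]] <- NA_character_

    # intergenic composition compensating the realized fixed-sequence GC
    inter_nt <- sum(vapply(gaps, function(x) x$len, numeric(1)))
    p_int <- (spec$gc * Lc - fixed_gc) / inter_nt
    p_int <- min(max(p_int, 0.02), 0.98)
    for (x in gaps)
      pieces[[x$at]] <- paste0(paste(random_dna(x$len, p_int), collapse = ""),
                               x$suffix)

    core <- paste(unlist(pieces), collapse = "")
    stopifnot(nchar(core) == Lc)
    seqs <- paste0(core, substr(core, 1L, dtr))
    features <- cds_features(do.call(rbind, feats), genome_length = L)
    genome <- genome_record(spec$id, seqs, features)
    list(genome = genome, features = features, slippage = slip_truth)
  })
}

# apply substitutions / deletions / insertions to a character vector.
# sub_idx: positions substituted (new base differs from old);
# del_idx: positions removed; ins: list(pos=..., str=list of char vectors)
# with each insertion placed after its (original-coordinate) position.
edit_sequence <- function(v, sub_idx, del_idx, ins_pos, ins_strs) {
  if (length(sub_idx)) {
    old <- v[sub_idx]
    new <- sample(BASES, length(sub_idx), replace = TRUE)
    clash <- new == old
    while (any(clash)) {
      new[clash] <- sample(BASES, sum(clash), replace = TRUE)
      clash <- new == old
    }
    v[sub_idx] <- new
  }
  keep <- rep(TRUE, length(v))
  if (length(del_idx)) keep[del_idx] <- FALSE
  if (length(ins_pos)) {
    o <- order(ins_pos)
    ins_pos <- ins_pos[o]; ins_strs <- ins_strs[o]
    kept_before <- cumsum(keep)
    at <- kept_before[ins_pos]     # insert after this many kept bases
    w <- v[keep]
    segs <- vector("list", 2L * length(at) + 1L)
    prev <- 0L
    for (k in seq_along(at)) {
      segs[[2L * k - 1L]] <- if (at[k] > prev) w[(prev + 1L):at[k]] else character(0)
      segs[[2L * k]] <- ins_strs[[k]]
      prev <- at[k]
    }
    segs[[2L * length(at) + 1L]] <-
      if (prev < length(w)) w[(prev + 1L):length(w)] else character(0)
    unlist(segs)
  } else v[keep]
}

#' Evolve a genome by random substitutions and indels
#'
#' Substitutions arrive per site with probability `divergence`
#' (binomially); indel events arrive with probability
#' `divergence * indel_rate` per site, with geometric lengths of mean
#' 3 bp, half insertions and half deletions.  Deterministic given `seed`.
#'
#' @param ancestor A [genome_record()].
#' @param divergence Substitution fraction in `[0, 0.6]`; beyond 0.6 the
#'   alignment signal assumption breaks and an error is thrown.
#' @param indel_rate Fraction of events that are indels.
#' @param seed Integer seed.
#' @param id Id for the evolved genome.
#' @return A [genome_record()] (features are dropped: coordinates shift).
#' @export
evolve_genome <- function(ancestor, divergence, indel_rate = 0.05, seed = 1L,
                          id = NULL) {
  if (divergence < 0 || divergence > 0.6)
    stop("divergence must be in [0, 0.6]")
  if (is.null(id)) id <- paste0(ancestor$id, "_evolved")
  if (divergence == 0)
    return(genome_record(id, ancestor$seq))
  with_seed(seed, {
    v <- strsplit(ancestor$seq, "")[[1]]
    L <- length(v)
    n_sub <- stats::rbinom(1L, L, divergence)
    sub_idx <- sample.int(L, n_sub)
    n_ind <- stats::rbinom(1L, L, divergence * indel_rate)
    del_idx <- integer(0); ins_pos <- integer(0); ins_strs <- list()
    if (n_ind > 0) {
      at <- sample.int(L, n_ind)
      sz <- stats::rgeom(n_ind, 1 / 3) + 1L
      is_ins <- stats::runif(n_ind) < 0.5
      for (k in seq_len(n_ind)) {
        if (is_ins[k]) {
          ins_pos <- c(ins_pos, at[k])
          ins_strs <- c(ins_strs, list(random_dna(sz[k], ancestor$gc)))
        } else {
          del_idx <- c(del_idx, at[k]:min(at[k] + sz[k] - 1L, L))
        }
      }
      del_idx <- unique(del_idx)
      ins_keep <- !(ins_pos %in% del_idx)
      ins_pos <- ins_pos[ins_keep]; ins_strs <- ins_strs[ins_keep]
    }
    genome_record(id, paste(edit_sequence(v, sub_idx, del_idx, ins_pos,
                                          ins_strs), collapse = ""))
  })
}

#' Simulate a planted cluster of genomes
#'
#' A root genome is synthesized from `genome_spec`; each cluster's
#' ancestor evolves from the root at `inter_divergence`, and members
#' evolve from their ancestor at `intra_divergence`.
#'
#' @param spec A [cluster_spec()].
#' @param genome_spec A [genome_spec()] for the root genome.
#' @return A named list of [genome_record()]s; each carries a `cluster`
#'   attribute, and the list carries a `truth` data frame (`id`,
#'   `cluster`).
#' @export
simulate_clustered_genomes <- function(spec = cluster_spec(),
                                       genome_spec = phagetax::genome_spec()) {
  stopifnot(inherits(spec, "cluster_spec"))
  root <- synthesize_phage_genome(genome_spec)$genome
  seeds <- with_seed(spec$seed,
                     sample.int(.Machine$integer.max - 1L,
                                spec$n_clusters * (1L + max(spec$genomes_per_cluster))))
  sm <- matrix(seeds, nrow = spec$n_clusters)
  out <- list(); truth <- NULL
  for (k in seq_len(spec$n_clusters)) {
    anc <- evolve_genome(root, spec$inter_divergence, spec$indel_rate,
                         seed = sm[k, 1L], id = sprintf("anc%02d", k))
    for (i in seq_len(spec$genomes_per_cluster[k])) {
      gid <- sprintf("c%02d_g%02d", k, i)
      g <- evolve_genome(anc, spec$intra_divergence, spec$indel_rate,
                         seed = sm[k, 1L + i], id = gid)
      attr(g, "cluster") <- k
      out[[gid]] <- g
      truth <- rbind(truth, data.frame(id = gid, cluster = k,
                                       stringsAsFactors = FALSE))
    }
  }
  attr(out, "truth") <- truth
  out
}

# iid per-base errors for read simulation
inject_read_errors <- function(seq, sub_rate, ins_rate, del_rate, gc) {
  v <- strsplit(seq, "")[[1]]
  L <- length(v)
  sub_idx <- which(stats::runif(L) < sub_rate)
  del_idx <- which(stats::runif(L) < del_rate)
  sub_idx <- setdiff(sub_idx, del_idx)
  ins_at <- which(stats::runif(L) < ins_rate)
  ins_strs <- lapply(seq_along(ins_at), function(k) random_dna(1L, gc))
  paste(edit_sequence(v, sub_idx, del_idx, ins_at, ins_strs), collapse = "")
}

#' Simulate nanopore-like reads from a genome
#'
#' Full-length reads carry the whole genome unit including both terminal
#' repeat copies (emulating packaging of one unit plus an extra repeat
#' from a DNA concatemer); other reads are uniform sub-windows.  About
#' half the reads are reverse-complemented; adapters are added at both
#' ends when requested; errors are iid per base.
#'
#' @param genome A [genome_record()].
#' @param params A [read_sim_params()].
#' @return A named list of [read_record()]s (empty for `n_reads = 0`).
#' @export
simulate_reads <- function(genome, params = read_sim_params()) {
  stopifnot(inherits(params, "read_sim_params"))
  if (params$n_reads == 0L) return(list())
  with_seed(params$seed, {
    L <- genome$length
    reads <- vector("list", params$n_reads)
    for (i in seq_len(params$n_reads)) {
      full <- stats::runif(1) < params$frac_full_length
      if (full) {
        s <- genome$seq
      } else {
        len <- max(200L, floor(stats::runif(1, 0.2, 0.95) * L))
        st <- sample.int(L - len + 1L, 1L)
        s <- substr(genome$seq, st, st + len - 1L)
      }
      if (params$sub_rate > 0 || params$ins_rate > 0 || params$del_rate > 0)
        s <- inject_read_errors(s, params$sub_rate, params$ins_rate,
                                params$del_rate, genome$gc)
      if (stats::runif(1) < 0.5) s <- revcomp(s)
      if (params$add_adapters)
        s <- paste0(params$adapter_top, s, revcomp(params$adapter_bottom))
      q <- pmin(pmax(round(stats::rnorm(nchar(s), 20, 4)), 3L), 40L)
      rid <- sprintf("read_%04d", i)
      reads[[i]] <- read_record(rid, s, q)
    }
    names(reads) <- vapply(reads, function(r) r$id, character(1))
    reads
  })
}

#' Build a minimal -1 frameshift test construct
#'
#' Generates a nucleotide sequence carrying one forward CDS with a
#' pattern-conforming slippery heptamer (`GGGAAAG`) whose last base falls
#' on a codon boundary, and a -1-frame stop at a chosen position, so the
#' frameshift isoform predictor can be exercised against known
#' coordinates.
#'
#' @param cds_start,cds_end CDS coordinates (1-based inclusive; span
#'   divisible by 3).
#' @param heptamer_end Genomic coordinate of the heptamer's last base;
#'   `(heptamer_end - cds_start + 1)` must be divisible by 3.
#' @param ext_stop_end Genomic coordinate of the last base of the
#'   -1-frame stop; since -1-frame codons start at `heptamer_end`,
#'   `(ext_stop_end - heptamer_end) %% 3` must equal 2.
#' @param total_length Total sequence length.
#' @param seed Integer seed for the random background.
#' @return A list with `genome` ([genome_record()]), `cds` (a one-row
#'   [cds_features()] table) and `heptamer_start`.
#' @export
make_frameshift_construct <- function(cds_start = 7253L, cds_end = 8314L,
                                      heptamer_end = 8299L,
                                      ext_stop_end = 9930L,
                                      total_length = 10500L, seed = 1L) {
  stopifnot((cds_end - cds_start + 1L) %% 3L == 0L,
            (heptamer_end - cds_start + 1L) %% 3L == 0L,
            (ext_stop_end - heptamer_end) %% 3L == 2L,
            heptamer_end - 6L >= cds_start, heptamer_end <= cds_end,
            ext_stop_end > cds_end, ext_stop_end <= total_length - 2L)
  with_seed(seed, {
    v <- random_dna(total_length, 0.42)
    nonstop_fill <- function(from, to, frame_anchor) {
      # overwrite codons [from..to] (aligned to frame_anchor) avoiding stops
      p <- from
      while (p + 2L <= to) {
        repeat {
          cod <- random_dna(3L, 0.42)
          if (!paste(cod, collapse = "") %in% stop_codons) break
        }
        v[p:(p + 2L)] <<- cod
        p <- p + 3L
      }
    }
    # CDS: ATG ... TAA with no internal stops
    v[cds_start:(cds_start + 2L)] <- c("A", "T", "G")
    nonstop_fill(cds_start + 3L, cds_end - 3L, cds_start)
    v[(cds_end - 2L):cds_end] <- c("T", "A", "A")
    # heptamer, last base on a codon boundary
    v[(heptamer_end - 6L):heptamer_end] <- strsplit("GGGAAAG", "")[[1]]
    # repair the codon split by the heptamer's first base: make it end in G
    # (already does), and keep the two heptamer codons GGA / AAG non-stop
    # (they are).  Re-assert the natural stop in case the heptamer overlapped.
    v[(cds_end - 2L):cds_end] <- c("T", "A", "A")
    # -1 frame: stop-free from heptamer_end to the planted stop, then stop
    m1 <- seq(heptamer_end, ext_stop_end - 3L, by = 3L)
    for (p in m1) {
      cod <- paste(v[p:(p + 2L)], collapse = "")
      if (cod %in% stop_codons) v[p + 2L] <- "C"
      # keep the 0-frame CDS stop intact if the patched base falls inside it
      if (p + 2L >= cds_end - 2L && p <= cds_end)
        v[(cds_end - 2L):cds_end] <- c("T", "A", "A")
    }
    v[(ext_stop_end - 2L):ext_stop_end] <- c("T", "A", "A")
    genome <- genome_record("frameshift_construct",
                            paste(v, collapse = ""))
    cds <- cds_features(data.frame(
      genome_id = genome$id, start = cds_start, end = cds_end, strand = "+",
      label = "mcp", product = "major capsid protein",
      stringsAsFactors = FALSE), genome_length = total_length)
    list(genome = genome, cds = cds, heptamer_start = heptamer_end - 6L)
  })
}
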