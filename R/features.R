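# Genome-feature analyses: adapter screening, direct-terminal-repeat
# detection from long reads and from assemblies, ORF calling, slippery-site
# scanning, -1 frameshift isoform prediction, and codon-usage bias.

#' Trim sequencing-adapter remnants from a read
#'
#' The first and last `window` nucleotides are scanned for local matches
#' to any adapter (and, by default, their reverse complements) at >= 75%
#' identity; a matched prefix/suffix is truncated.  The read interior is
#' never modified, and trimming is idempotent.
#'
#' @param read A [read_record()] (or nucleotide string).
#' @param adapters Character vector of adapter sequences; defaults to the
#'   Y-adapter top/bottom pair plus reverse complements.
#' @param window Terminal window scanned (nt).
#' @param min_identity Minimum adapter identity for a match.
#' @return The trimmed [read_record()].
#' @export
trim_adapters <- function(read, adapters = NULL, window = 150L,
                          min_identity = 0.75) {
  if (is.character(read)) read <- read_record("read", read)
  if (is.null(adapters)) {
    ad <- y_adapters()
    adapters <- c(ad, vapply(ad, revcomp, character(1)))
  }
  L <- nchar(read$seq)
  if (L < 10L) return(read)
  p <- align_params(word_size = 6L, x_drop = 12L, min_hsp_score = 8L)
  # first pass: the leading window.  The adapter footprint is
  # extrapolated beyond the aligned match so that terminal mismatches do
  # not leave residual adapter bases behind.
  w <- min(window, L)
  pre_end <- 0L
  prefix <- substr(read$seq, 1L, w)
  for (a in adapters) {
    h <- find_hsps_nt(a, prefix, p)
    h <- h[h$identities / nchar(a) >= min_identity, , drop = FALSE]
    if (nrow(h))
      pre_end <- max(pre_end, min(w, max(h$s_end + (nchar(a) - h$q_end))))
  }
  from <- pre_end + 1L
  # second pass: the trailing window of what remains, so overlapping
  # windows on short reads cannot trim the same match twice
  Lr <- L - pre_end
  suf_start <- Lr + 1L
  if (Lr >= 10L) {
    w2 <- min(window, Lr)
    suffix <- substr(read$seq, L - w2 + 1L, L)
    for (a in adapters) {
      h <- find_hsps_nt(a, suffix, p)
      h <- h[h$identities / nchar(a) >= min_identity, , drop = FALSE]
      if (nrow(h))
        suf_start <- min(suf_start,
                         max(1L, (Lr - w2) +
                               min(h$s_start - (h$q_start - 1L))))
    }
  }
  if (pre_end == 0L && suf_start == Lr + 1L) return(read)
  to <- pre_end + suf_start - 1L
  if (from > to) return(read_record(read$id, "", integer(0)))
  read_record(read$id, substr(read$seq, from, to),
              if (is.null(read$quals)) NULL else read$quals[from:to])
}

new_termini_report <- function(dtr_length, dtr_sequence = "",
                               n_supporting_reads = 0L,
                               per_read_lengths = integer(0)) {
  structure(list(dtr_length = as.integer(dtr_length),
                 dtr_sequence = dtr_sequence,
                 n_supporting_reads = as.integer(n_supporting_reads),
                 per_read_lengths = as.integer(per_read_lengths)),
            class = "termini_report")
}

#' @export
print.termini_report <- function(x, ...) {
  if (x$dtr_length == 0L) {
    cat("<termini_report> no direct terminal repeat detected\n")
  } else {
    cat(sprintf("<termini_report> DTR %d bp, %d supporting read(s)\n",
                x$dtr_length, x$n_supporting_reads))
  }
  invisible(x)
}

#' Detect direct terminal repeats from long reads
#'
#' Reads are adapter-trimmed, filtered to `min_read_len` (default: the
#' assembly length, so only reads spanning a whole genome unit qualify)
#' and oriented against the assembly.  A terminal direct repeat is called
#' on a read when a >= `min_repeat`-bp window at the read start re-occurs
#' at >= 90% identity at the read end in the same orientation; the
#' per-read repeat length is the maximal such repeat.  The reported DTR
#' length is the mode of the per-read lengths and the DTR sequence a
#' per-column majority consensus over the supporting reads.
#'
#' @param reads List of [read_record()]s.
#' @param assembly [genome_record()] of the assembled genome.
#' @param min_read_len Length filter after trimming (default = assembly
#'   length).
#' @param adapters Adapters passed to [trim_adapters()].
#' @param min_repeat Minimum repeat length (bp).
#' @param min_identity Minimum start/end window identity.
#' @param params [align_params()].
#' @return A `termini_report` (with `dtr_length = 0` and a warning when
#'   no qualifying read supports a repeat).
#' @export
detect_termini_from_reads <- function(reads, assembly, min_read_len = NULL,
                                      adapters = NULL, min_repeat = 50L,
                                      min_identity = 0.90,
                                      params = align_params()) {
  if (is.null(min_read_len)) min_read_len <- assembly$length
  trimmed <- lapply(reads, trim_adapters, adapters = adapters)
  trimmed <- Filter(function(r) nchar(r$seq) >= min_read_len, trimmed)
  if (!length(trimmed)) {
    warning("no reads pass the length filter; no termini called")
    return(new_termini_report(0L))
  }
  La <- assembly$length
  per_len <- integer(0); per_score <- numeric(0); starts <- character(0)
  for (r in trimmed) {
    L <- nchar(r$seq)
    # orient against the assembly using the best-scoring HSP
    oh <- find_hsps_nt(r$seq, assembly, params)
    s <- r$seq
    if (nrow(oh) && oh$strand[1] == "-") s <- revcomp(s)
    w <- min(2000L, floor(L / 3), floor(La / 3))
    if (w < min_repeat) next
    # the read-start window must re-occur at the (assembly) end and the
    # read-end window at the (assembly) start; measuring repeat spans on
    # the error-free assembly axis is immune to read indels
    h1 <- find_hsps_nt(substr(s, 1L, w),
                       substr(assembly$seq, La - w + 1L, La), params)
    h1 <- h1[h1$strand == "+" & h1$q_start <= 25L & h1$s_end >= w - 25L &
               h1$length >= min_repeat &
               h1$identities / h1$length >= min_identity, , drop = FALSE]
    h2 <- find_hsps_nt(substr(s, L - w + 1L, L),
                       substr(assembly$seq, 1L, w), params)
    h2 <- h2[h2$strand == "+" & h2$q_end >= w - 25L & h2$s_start <= 25L &
               h2$length >= min_repeat &
               h2$identities / h2$length >= min_identity, , drop = FALSE]
    if (!nrow(h1) || !nrow(h2)) next
    l1 <- h1$s_end[1L] - h1$s_start[1L] + 1L  # span on assembly end copy
    l2 <- h2$s_end[1L] - h2$s_start[1L] + 1L  # span on assembly start copy
    per_len <- c(per_len, as.integer(floor((l1 + l2) / 2 + 0.5)))
    per_score <- c(per_score, h1$score[1L] + h2$score[1L])
    starts <- c(starts, s)
  }
  if (!length(per_len)) {
    warning("no qualifying read supports a terminal repeat")
    return(new_termini_report(0L))
  }
  tab <- tapply(per_score, per_len, sum)
  cnt <- table(per_len)
  best_cnt <- max(cnt)
  cand <- as.integer(names(cnt)[cnt == best_cnt])
  mode_len <- cand[which.max(tab[as.character(cand)])]
  support <- which(per_len == mode_len)
  # majority-vote consensus across reads whose repeat length is modal
  mat <- do.call(rbind, lapply(starts[support], function(s)
    strsplit(substr(s, 1L, mode_len), "")[[1]]))
  cons <- apply(mat, 2L, function(col) names(which.max(table(col))))
  new_termini_report(mode_len, paste(cons, collapse = ""),
                     length(per_len), per_len)
}

#' Detect a direct terminal repeat in a linear assembly
#'
#' Reports the longest prefix (up to `max_dtr` bp) that matches the
#' sequence's suffix at >= `min_identity` Hamming identity.
#'
#' @param assembly [genome_record()] or nucleotide string.
#' @param max_dtr Maximum repeat length tried.
#' @param min_dtr Minimum repeat length reported.
#' @param min_identity Identity threshold.
#' @return A `termini_report` (`dtr_length = 0` when nothing matches).
#' @export
detect_dtr_in_assembly <- function(assembly, max_dtr = 1000L, min_dtr = 15L,
                                   min_identity = 0.95) {
  s <- as_seq(assembly)
  L <- nchar(s)
  v <- strsplit(s, "")[[1]]
  for (t in seq(min(max_dtr, floor(L / 2)), min_dtr)) {
    if (mean(v[1:t] == v[(L - t + 1):L]) >= min_identity)
      return(new_termini_report(t, substr(s, 1L, t), 0L))
  }
  new_termini_report(0L)
}

#' Locate a known DTR sequence near the termini of another genome
#'
#' HSP search of the query repeat against the first and last
#' `terminal_window` bp; hits at or above `min_identity` identity
#' covering at least `min_coverage` of the query are reported in genome
#' coordinates.
#'
#' @param dtr_seq Query repeat (50-1000 bp).
#' @param genome [genome_record()].
#' @param terminal_window Window at each end searched (bp).
#' @param min_identity,min_coverage Reporting thresholds.
#' @param params [align_params()].
#' @return Data frame with columns `start`, `end`, `identity`.
#' @export
find_dtr_by_similarity <- function(dtr_seq, genome, terminal_window = 2000L,
                                   min_identity = 0.80, min_coverage = 0.80,
                                   params = align_params()) {
  qlen <- nchar(dtr_seq)
  if (qlen < 50L || qlen > 1000L) stop("query repeat must be 50-1000 bp")
  L <- genome$length
  w <- min(terminal_window, L)
  hits <- NULL
  for (off in unique(c(0L, L - w))) {
    win <- substr(genome$seq, off + 1L, off + w)
    h <- find_hsps_nt(dtr_seq, win, params)
    h <- h[h$identities / h$length >= min_identity &
             (h$q_end - h$q_start + 1L) / qlen >= min_coverage, , drop = FALSE]
    if (nrow(h))
      hits <- rbind(hits, data.frame(start = off + h$s_start,
                                     end = off + h$s_end,
                                     identity = h$identities / h$length))
  }
  if (is.null(hits))
    return(data.frame(start = integer(0), end = integer(0),
                      identity = numeric(0)))
  unique(hits[order(hits$start), , drop = FALSE])
}

#' Call open reading frames
#'
#' Deterministic maximal-ORF caller: on both strands and all frames, each
#' ORF runs from the first start codon after the previous in-frame stop
#' to the next stop (inclusive), keeping ORFs of >= `min_aa` residues.
#'
#' @param genome [genome_record()] or nucleotide string.
#' @param min_aa Minimum protein length (residues, including Met,
#'   excluding the stop).
#' @param starts Accepted start codons.
#' @return A [cds_features()] table sorted by `start` (empty for an empty
#'   genome).
#' @export
find_orfs <- function(genome, min_aa = 30L, starts = c("ATG", "GTG", "TTG")) {
  s <- as_seq(genome)
  gid <- seq_id(genome, "genome")
  L <- nchar(s)
  empty <- cds_features(data.frame(genome_id = character(0),
                                   start = integer(0), end = integer(0),
                                   strand = character(0), label = character(0),
                                   stringsAsFactors = FALSE))
  if (L < 3L * (min_aa + 1L)) return(empty)
  scan_strand <- function(sq, strand) {
    rows <- NULL
    for (f in 0:2) {
      p <- seq(1L + f, nchar(sq) - 2L, by = 3L)
      cod <- substring(sq, p, p + 2L)
      is_stop <- cod %in% stop_codons
      is_start <- cod %in% starts
      stop_i <- which(is_stop)
      if (!length(stop_i)) next
      start_i <- which(is_start)
      if (!length(start_i)) next
      # for each start codon, the index of the next stop at/after it
      nxt <- stop_i[findInterval(start_i, stop_i) + 1L]
      ok <- !is.na(nxt)
      start_i <- start_i[ok]; nxt <- nxt[ok]
      if (!length(start_i)) next
      first_start <- tapply(start_i, nxt, min)
      st_codon <- as.integer(first_start)
      en_codon <- as.integer(names(first_start))
      aa <- en_codon - st_codon  # sense codons (incl start) = aa length
      keep <- aa >= min_aa
      if (!any(keep)) next
      rows <- rbind(rows, data.frame(start = p[st_codon[keep]],
                                     end = p[en_codon[keep]] + 2L,
                                     strand = strand,
                                     stringsAsFactors = FALSE))
    }
    rows
  }
  fw <- scan_strand(s, "+")
  rvs <- scan_strand(revcomp(s), "-")
  if (!is.null(rvs)) {
    tmp <- rvs$start
    rvs$start <- L - rvs$end + 1L
    rvs$end <- L - tmp + 1L
  }
  orfs <- rbind(fw, rvs)
  if (is.null(orfs) || !nrow(orfs)) return(empty)
  orfs <- orfs[order(orfs$start, orfs$end), , drop = FALSE]
  orfs$genome_id <- gid
  orfs$label <- sprintf("orf_%04d", seq_len(nrow(orfs)))
  orfs$product <- NA_character_
  cds_features(orfs[, c("genome_id", "start", "end", "strand", "label",
                        "product")], genome_length = L)
}

# reading-direction sequence from the CDS start to the end of the molecule
transcript_from <- function(genome, cds) {
  if (cds$strand == "+") {
    substr(genome$seq, cds$start, genome$length)
  } else {
    revcomp(substr(genome$seq, 1L, cds$end))
  }
}

# map a transcript offset (1-based from CDS start) back to a genomic coord
transcript_to_genomic <- function(cds, offset) {
  if (cds$strand == "+") cds$start + offset - 1L else cds$end - offset + 1L
}

#' Scan a CDS for slippery heptamers near its stop codon
#'
#' Reports every heptamer matching `N1N1N1N2N2N2N3` (positions 1-3
#' identical and 4-6 identical) whose start lies within
#' `[stop_end - window - 6, stop_end]` of the CDS.
#'
#' @param genome [genome_record()].
#' @param cds One row of a [cds_features()] table.
#' @param window Search window upstream of the stop end (nt).
#' @return A data frame of class `slippery_sites` with columns
#'   `position` (genomic coordinate of the heptamer start, reading
#'   direction), `heptamer`, `cds_label`, `offset_to_stop`.
#' @export
find_slippery_sites <- function(genome, cds, window = 30L) {
  cds <- as.data.frame(cds)[1L, ]
  tseq <- transcript_from(genome, cds)
  cds_len <- cds$end - cds$start + 1L
  lo <- max(1L, cds_len - window - 6L)
  hi <- cds_len - 6L
  out <- NULL
  if (hi >= lo) {
    for (p in lo:hi) {
      h <- substr(tseq, p, p + 6L)
      v <- strsplit(h, "")[[1]]
      if (v[1] == v[2] && v[2] == v[3] && v[4] == v[5] && v[5] == v[6]) {
        out <- rbind(out, data.frame(
          position = transcript_to_genomic(cds, p), heptamer = h,
          cds_label = cds$label, offset_to_stop = cds_len - p,
          transcript_offset = p, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out))
    out <- data.frame(position = integer(0), heptamer = character(0),
                      cds_label = character(0), offset_to_stop = integer(0),
                      transcript_offset = integer(0),
                      stringsAsFactors = FALSE)
  class(out) <- c("slippery_sites", "data.frame")
  out
}

#' Predict the -1 programmed-frameshift extended isoform
#'
#' The ribosome translates zero-frame codons through the codon ending at
#' the heptamer's last base, then resumes one nucleotide back (re-reading
#' that base) in the -1 frame until the next stop.  The heptamer's last
#' base must fall on a zero-frame codon boundary.
#'
#' @param genome [genome_record()].
#' @param cds One row of a [cds_features()] table.
#' @param site One row of the [find_slippery_sites()] result (or a list
#'   with a `position` field).
#' @return A list of class `slippage_report` with `natural_length_aa`,
#'   `extended_length_aa`, `extended_end` (genomic coordinate of the
#'   -1-frame stop's last base) and `premature_stop` (`TRUE` when the
#'   extension is <= 20 aa).
#' @export
predict_extended_isoform <- function(genome, cds, site) {
  cds <- as.data.frame(cds)[1L, ]
  site <- as.data.frame(site)[1L, ]
  tseq <- transcript_from(genome, cds)
  cds_len <- cds$end - cds$start + 1L
  if (cds_len %% 3L != 0L) stop("CDS span not divisible by 3")
  hs_t <- if (!is.null(site$transcript_offset)) site$transcript_offset else {
    if (cds$strand == "+") site$position - cds$start + 1L
    else cds$end - site$position + 1L
  }
  he_t <- hs_t + 6L
  if (he_t %% 3L != 0L)
    stop("heptamer end does not coincide with a codon boundary of the CDS")
  if (hs_t < 1L || he_t > cds_len) stop("slippery site not within the CDS")
  natural_aa <- cds_len / 3L - 1L
  # -1 frame: codons starting at he_t (re-reading the heptamer's last base)
  n_avail <- nchar(tseq)
  p <- he_t
  ext_end_t <- NA_integer_
  while (p + 2L <= n_avail) {
    if (substr(tseq, p, p + 2L) %in% stop_codons) { ext_end_t <- p + 2L; break }
    p <- p + 3L
  }
  if (is.na(ext_end_t))
    stop("runaway frame: no -1-frame stop before the end of the molecule")
  extended_aa <- (ext_end_t + 1L) / 3L - 1L
  structure(list(
    natural_length_aa = as.integer(natural_aa),
    extended_length_aa = as.integer(extended_aa),
    extended_end = transcript_to_genomic(cds, ext_end_t),
    premature_stop = (extended_aa - natural_aa) <= 20L),
    class = "slippage_report")
}

#' @export
print.slippage_report <- function(x, ...) {
  cat(sprintf(paste0("<slippage_report> natural %d aa, extended %d aa",
                     " (-1 stop ends at %d)%s\n"),
              x$natural_length_aa, x$extended_length_aa, x$extended_end,
              if (x$premature_stop) " [premature stop]" else ""))
  invisible(x)
}

# ---- codon usage ----------------------------------------------------------

#' Build a codon-usage table
#'
#' @param counts Named numeric vector of codon counts (stop codons are
#'   dropped), or an existing `codon_usage_table` (returned unchanged).
#' @return A data frame of class `codon_usage_table` with columns
#'   `codon`, `aa`, `count` and `share` (synonymous share within the
#'   codon's amino-acid family; each family sums to 1), and attribute
#'   `total` (total codon count).
#' @export
codon_usage_table <- function(counts) {
  if (inherits(counts, "codon_usage_table")) return(counts)
  code <- Biostrings::GENETIC_CODE
  code <- code[code != "*"]
  full <- stats::setNames(numeric(length(code)), names(code))
  counts <- counts[names(counts) %in% names(code)]
  full[names(counts)] <- counts
  df <- data.frame(codon = names(code), aa = unname(code), count = unname(full),
                   stringsAsFactors = FALSE)
  fam_tot <- tapply(df$count, df$aa, sum)
  tot <- fam_tot[df$aa]
  df$share <- ifelse(tot > 0, df$count / tot, 0)
  df <- df[order(df$aa, df$codon), ]
  rownames(df) <- NULL
  attr(df, "total") <- sum(df$count)
  class(df) <- c("codon_usage_table", "data.frame")
  df
}

#' Codon usage of a set of coding sequences
#'
#' Counts codons over all CDSs, excluding each terminal stop codon, and
#' computes synonymous shares per amino-acid family.  CDS lengths must be
#' divisible by 3; internal stop codons are an error.
#'
#' @param cds_sequences Named character vector (or list) of in-frame CDS
#'   nucleotide sequences.
#' @return A [codon_usage_table()].
#' @export
codon_usage <- function(cds_sequences) {
  cds_sequences <- unlist(cds_sequences)
  if (is.null(names(cds_sequences)))
    names(cds_sequences) <- sprintf("cds_%04d", seq_along(cds_sequences))
  counts <- stats::setNames(numeric(64), names(Biostrings::GENETIC_CODE))
  for (i in seq_along(cds_sequences)) {
    s <- toupper(cds_sequences[[i]])
    if (nchar(s) %% 3L != 0L)
      stop(sprintf("CDS '%s': length not divisible by 3", names(cds_sequences)[i]))
    p <- seq(1L, nchar(s) - 2L, by = 3L)
    cod <- substring(s, p, p + 2L)
    if (cod[length(cod)] %in% stop_codons) cod <- cod[-length(cod)]
    if (any(cod %in% stop_codons))
      stop(sprintf("CDS '%s': internal stop codon", names(cds_sequences)[i]))
    tb <- table(cod)
    counts[names(tb)] <- counts[names(tb)] + as.numeric(tb)
  }
  codon_usage_table(counts)
}

#' Codon-usage bias of a phage relative to its host
#'
#' Fold change is the ratio of synonymous shares (phage over host).  When
#' either raw count of a codon is zero, `pseudocount` is added to every
#' count of that codon's family in both tables before shares are compared
#' (such entries are flagged `unstable`).  Entries whose fold change
#' reaches `min_fold` (either direction) are returned, sorted by
#' `|log2 fold|` descending.
#'
#' @param phage,host [codon_usage_table()]s.
#' @param min_fold Reporting threshold (default 2 = two-fold).
#' @param pseudocount Added to a family's counts when a zero is involved.
#' @return A data frame of class `codon_bias` with columns `codon`, `aa`,
#'   `phage_share`, `host_share`, `fold_change`, `direction`, `unstable`.
#' @export
codon_bias <- function(phage, host, min_fold = 2.0, pseudocount = 0.5) {
  phage <- codon_usage_table(phage); host <- codon_usage_table(host)
  stopifnot(identical(phage$codon, host$codon))
  p_share <- phage$share; h_share <- host$share
  unstable <- phage$count == 0 | host$count == 0
  if (any(unstable)) {
    fams <- unique(phage$aa[unstable])
    for (f in fams) {
      i <- phage$aa == f
      pc <- phage$count[i] + pseudocount
      hc <- host$count[i] + pseudocount
      p_share[i] <- pc / sum(pc)
      h_share[i] <- hc / sum(hc)
    }
  }
  fold <- p_share / h_share
  keep <- !is.na(fold) & is.finite(fold) & fold > 0 &
    (fold >= min_fold | fold <= 1 / min_fold)
  out <- data.frame(codon = phage$codon[keep], aa = phage$aa[keep],
                    phage_share = p_share[keep], host_share = h_share[keep],
                    fold_change = fold[keep],
                    direction = ifelse(fold[keep] >= 1, "up", "down"),
                    unstable = unstable[keep], stringsAsFactors = FALSE)
  out <- out[order(-abs(log2(out$fold_change))), ]
  rownames(out) <- NULL
  class(out) <- c("codon_bias", "data.frame")
  out
}
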