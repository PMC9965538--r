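# Sequence records and external formats (FASTA, FASTQ, GFF3, newick, TSV).
# Coordinates are 1-based inclusive everywhere, following GFF3.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")

#' Construct a genome record
#'
#' A genome record bundles a nucleotide sequence with its id, length, GC
#' fraction and (optionally) CDS features.  Sequences are uppercased, `U`
#' is mapped to `T`, and characters outside `A/C/G/T/N` are rejected.
#' `N` bases are excluded from both the numerator and denominator of the
#' GC fraction.
#'
#' @param id Non-empty record id (truncated at first whitespace on output).
#' @param seq Nucleotide sequence as a single string.
#' @param features Optional CDS feature table (see [cds_features()]).
#' @return An object of class `genome_record` with fields `id`, `seq`,
#'   `length`, `gc` and `features`.
#' @export
genome_record <- function(id, seq, features = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("genome id must be a non-empty string")
  seq <- unname(as.character(seq))
  seq <- chartr("u", "t", toupper(seq))
  seq <- chartr("U", "T", seq)
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), DNA_ALPHABET)
  if (length(bad))
    stop(sprintf("record '%s': illegal nucleotide character(s): %s",
                 id, paste(bad, collapse = ", ")))
  if (!is.null(features)) features <- cds_features(features)
  structure(
    list(id = id, seq = seq, length = nchar(seq), gc = gc_content(seq),
         features = features),
    class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp, GC %.1f%%, %d feature(s)\n",
              x$id, format(x$length, big.mark = ","), 100 * x$gc,
              if (is.null(x$features)) 0L else nrow(x$features)))
  invisible(x)
}

#' GC fraction of a nucleotide sequence
#'
#' `N` bases are excluded from numerator and denominator.
#'
#' @param seq A string, `genome_record`, or `Biostrings::DNAString`.
#' @return GC fraction in `[0, 1]` (NaN for an all-N or empty sequence).
#' @export
gc_content <- function(seq) {
  if (inherits(seq, "genome_record")) seq <- seq$seq
  f <- Biostrings::alphabetFrequency(Biostrings::DNAString(as.character(seq)))
  gc <- f[["G"]] + f[["C"]]
  at <- f[["A"]] + f[["T"]]
  gc / (gc + at)
}

#' Reverse complement of a nucleotide string
#' @param seq Nucleotide string.
#' @return The reverse complement as a string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Construct a read record
#'
#' @param id Read id.
#' @param seq Nucleotide string.
#' @param quals Optional integer Phred qualities, one per base.
#' @return An object of class `read_record`.
#' @export
read_record <- function(id, seq, quals = NULL) {
  seq <- unname(toupper(as.character(seq)))
  if (!is.null(quals)) {
    quals <- as.integer(quals)
    if (length(quals) != nchar(seq))
      stop(sprintf("read '%s': %d qualities for %d bases", id,
                   length(quals), nchar(seq)))
  }
  structure(list(id = id, seq = seq, quals = quals), class = "read_record")
}

#' @export
print.read_record <- function(x, ...) {
  cat(sprintf("<read_record> %s: %d bp%s\n", x$id, nchar(x$seq),
              if (is.null(x$quals)) "" else
                sprintf(", mean Q%.1f", mean(x$quals))))
  invisible(x)
}

#' Construct/validate a CDS feature table
#'
#' Features use 1-based inclusive coordinates on the forward strand of
#' their genome.  Plain (non-frameshifted) CDS spans must be divisible
#' by 3.
#'
#' @param x A data frame with columns `genome_id`, `start`, `end`,
#'   `strand` and `label` (plus optional `product`).
#' @param genome_length Optional genome length for bounds checking.
#' @return The validated data frame with class `cds_features`.
#' @export
cds_features <- function(x, genome_length = NULL) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("genome_id", "start", "end", "strand", "label")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "))
  if (!"product" %in% names(x)) x$product <- rep(NA_character_, nrow(x))
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  if (any(x$start < 1L)) stop("feature start below 1")
  if (any(x$end < x$start)) stop("feature end before start")
  if (!all(x$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!is.null(genome_length) && any(x$end > genome_length))
    stop("feature coordinate beyond genome length")
  class(x) <- c("cds_features", "data.frame")
  x
}

# ---- FASTA ----------------------------------------------------------------

#' Read a FASTA file
#'
#' @param path FASTA file (nucleotide or amino-acid).
#' @param alphabet `"dna"` returns a named list of [genome_record()]s
#'   (U mapped to T, only `A/C/G/T/N` accepted); `"aa"` returns a named
#'   character vector of protein sequences.
#' @return See `alphabet`.
#' @export
read_fasta <- function(path, alphabet = c("dna", "aa")) {
  alphabet <- match.arg(alphabet)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop(sprintf("cannot parse FASTA '%s': %s",
                                                  path, conditionMessage(e))))
  if (length(ss) == 0L) stop(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate record id(s) in '%s': %s", path,
                 paste(unique(dup), collapse = ", ")))
  seqs <- toupper(as.character(ss))
  if (alphabet == "dna") {
    recs <- lapply(seq_along(ids), function(i) genome_record(ids[i], seqs[i]))
    names(recs) <- ids
    recs
  } else {
    for (i in seq_along(ids)) {
      bad <- setdiff(unique(strsplit(seqs[i], "")[[1]]), AA_ALPHABET)
      if (length(bad))
        stop(sprintf("record '%s': illegal amino-acid character(s): %s",
                     ids[i], paste(bad, collapse = ", ")))
    }
    stats::setNames(seqs, ids)
  }
}

#' Write sequences to FASTA (70-column wrapping)
#'
#' @param x A `genome_record`, list of them, or named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "genome_record")) x <- list(x)
  if (is.list(x)) {
    seqs <- vapply(x, function(g) g$seq, character(1))
    names(seqs) <- vapply(x, function(g) g$id, character(1))
  } else seqs <- x
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# ---- FASTQ ----------------------------------------------------------------

#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ file.
#' @return A named list of [read_record()]s.
#' @export
read_fastq <- function(path) {
  # validate the 4-line record structure up front: the parser below
  # silently normalizes quality strings of the wrong length
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop(sprintf("truncated FASTQ record at end of '%s'", path))
  n <- length(lines) / 4L
  for (i in seq_len(n)) {
    sq <- lines[4L * i - 2L]; ql <- lines[4L * i]
    if (nchar(sq) != nchar(ql))
      stop(sprintf("FASTQ record %d: %d quality values for %d bases",
                   i, nchar(ql), nchar(sq)))
  }
  ss <- tryCatch(
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
    error = function(e) stop(sprintf("cannot parse FASTQ '%s': %s",
                                     path, conditionMessage(e))))
  ids <- sub("\\s.*$", "", names(ss))
  quals <- as(Biostrings::quality(ss), "IntegerList")
  recs <- lapply(seq_along(ss), function(i) {
    read_record(ids[i], as.character(ss[[i]]), as.integer(quals[[i]]))
  })
  names(recs) <- ids
  recs
}

#' Write read records to FASTQ (Phred+33)
#'
#' Reads without qualities are written at a constant Q20.
#'
#' @param reads A list of [read_record()]s.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (inherits(reads, "read_record")) reads <- list(reads)
  seqs <- vapply(reads, function(r) r$seq, character(1))
  ids <- vapply(reads, function(r) r$id, character(1))
  qs <- vapply(reads, function(r) {
    q <- if (is.null(r$quals)) rep(20L, nchar(r$seq)) else r$quals
    rawToChar(as.raw(pmin(pmax(q, 0L), 93L) + 33L))
  }, character(1))
  ss <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(seqs, ids)),
    Biostrings::PhredQuality(qs)))
  Biostrings::writeQualityScaledXStringSet(ss, path)
  invisible(path)
}

# ---- GFF3 -----------------------------------------------------------------

#' Read CDS features from a GFF3 file
#'
#' Only `CDS` rows are kept.  Coordinates are 1-based inclusive.
#'
#' @param path GFF3 file.
#' @param genome_length Optional named vector of genome lengths for bounds
#'   checking.
#' @return A [cds_features()] data frame.
#' @export
read_gff3 <- function(path, genome_length = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop(sprintf("cannot parse GFF3 '%s': %s",
                                                  path, conditionMessage(e))))
  gr <- gr[gr$type == "CDS"]
  df <- data.frame(
    genome_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    label = if (!is.null(gr$ID)) as.character(gr$ID) else
      sprintf("cds_%04d", seq_along(gr)),
    product = if (!is.null(gr$product)) as.character(gr$product) else
      NA_character_,
    stringsAsFactors = FALSE)
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  if (!is.null(genome_length)) {
    ok <- match(df$genome_id, names(genome_length))
    over <- !is.na(ok) & df$end > genome_length[ok]
    if (any(over))
      stop(sprintf("feature '%s' extends beyond its genome", df$label[which(over)[1]]))
  }
  cds_features(df)
}

#' Write CDS features to GFF3
#'
#' @param features A [cds_features()] table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  features <- cds_features(features)
  gr <- GenomicRanges::GRanges(
    seqnames = features$genome_id,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand)
  gr$type <- "CDS"
  gr$source <- "phagetax"
  gr$phase <- 0L
  gr$ID <- features$label
  if (any(!is.na(features$product))) gr$product <- features$product
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# ---- newick / TSV ---------------------------------------------------------

#' Write a phylogenetic tree to newick
#'
#' Branch supports are written as internal-node labels.
#'
#' @param tree An `ape::phylo` tree with labeled leaves.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)) ||
      anyNA(tree$tip.label))
    stop("all leaves must be labeled")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a labeled matrix to TSV with row and column headers
#'
#' @param m Matrix with identical row/column names when `symmetric`.
#' @param path Output file.
#' @param symmetric Check symmetry (within `tol`) before writing.
#' @param tol Symmetry tolerance.
#' @param header Optional comment line(s) written before the table.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, symmetric = FALSE, tol = 1e-9,
                             header = NULL) {
  m <- as.matrix(m)
  if (symmetric) {
    if (nrow(m) != ncol(m) || max(abs(m - t(m))) > tol)
      stop("matrix declared symmetric but is not (beyond tolerance)")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], format(m[i, ], trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}
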