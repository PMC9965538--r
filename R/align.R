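# Local alignment: nucleotide seed-and-extend HSP engine and protein
# Smith-Waterman (compiled backends in src/align.cpp).

#' Alignment parameters
#'
#' Defaults follow megablast-like settings for nucleotides (word size 11,
#' match +1 / mismatch -2, affine gaps 5/2, x-drop 20) and BLOSUM62 with
#' affine gaps 11/1 for proteins.  `X` scores 0 against everything.
#'
#' @param word_size Exact seed length for the nucleotide engine (4-13).
#' @param match,mismatch Nucleotide match reward / mismatch penalty
#'   (both positive integers).
#' @param gap_open,gap_extend Affine gap penalties; a gap of length L
#'   costs `gap_open + gap_extend * L`.
#' @param x_drop Extension is abandoned when the running score falls this
#'   far below the best score seen.
#' @param min_hsp_score HSPs scoring below this are discarded.
#' @param protein_matrix Substitution matrix name (only `"BLOSUM62"`).
#' @param protein_gap_open,protein_gap_extend Affine gap penalties for
#'   protein alignment.
#' @return A list of class `align_params`.
#' @export
align_params <- function(word_size = 11L, match = 1L, mismatch = 2L,
                         gap_open = 5L, gap_extend = 2L, x_drop = 20L,
                         min_hsp_score = 30L, protein_matrix = "BLOSUM62",
                         protein_gap_open = 11L, protein_gap_extend = 1L) {
  stopifnot(word_size >= 4, word_size <= 13, match > 0, mismatch > 0,
            gap_open > 0, gap_extend > 0, x_drop > 0, min_hsp_score > 0)
  if (!identical(protein_matrix, "BLOSUM62"))
    stop("only BLOSUM62 is supported as protein matrix")
  structure(list(word_size = as.integer(word_size), match = as.integer(match),
                 mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 x_drop = as.integer(x_drop),
                 min_hsp_score = as.integer(min_hsp_score),
                 protein_matrix = protein_matrix,
                 protein_gap_open = as.integer(protein_gap_open),
                 protein_gap_extend = as.integer(protein_gap_extend)),
            class = "align_params")
}

as_seq <- function(x) {
  if (inherits(x, "genome_record")) x$seq else as.character(x)
}
seq_id <- function(x, default) {
  if (inherits(x, "genome_record")) x$id else default
}

#' Find high-scoring segment pairs between two nucleotide sequences
#'
#' Exact `word_size`-mer seeds on both strands are extended ungapped with
#' x-drop termination and then gapped with a banded x-drop extension.
#' All coordinates are 1-based inclusive; for minus-strand HSPs the
#' subject coordinates refer to the forward strand (`s_start <= s_end`).
#'
#' @param query,subject [genome_record()]s or nucleotide strings.
#' @param params [align_params()].
#' @return A data frame of class `hsp_set` with columns `q_start`,
#'   `q_end`, `s_start`, `s_end`, `strand`, `length`, `identities`,
#'   `score`, sorted by score (desc), then `q_start`, then `s_start`.
#'   Attributes `q_len`, `s_len`, `q_id`, `s_id` record the inputs.
#' @export
find_hsps_nt <- function(query, subject, params = align_params()) {
  q <- as_seq(query); s <- as_seq(subject)
  if (!nzchar(q) || !nzchar(s)) stop("sequences must be non-empty")
  df <- cpp_find_hsps(q, s, params$word_size, params$match, params$mismatch,
                      params$gap_open, params$gap_extend, params$x_drop,
                      params$min_hsp_score)
  attr(df, "q_len") <- nchar(q)
  attr(df, "s_len") <- nchar(s)
  attr(df, "q_id") <- seq_id(query, "query")
  attr(df, "s_id") <- seq_id(subject, "subject")
  class(df) <- c("hsp_set", "data.frame")
  df
}

#' Merge overlapping HSPs on one genome axis
#'
#' Overlaps are resolved greedily by descending score: each HSP is
#' trimmed to the positions not yet covered, and its identity count is
#' apportioned proportionally to the retained fraction of its span,
#' rounded half-up.
#'
#' @param hsps An `hsp_set` (or compatible data frame).
#' @param axis `"query"` or `"subject"`: which genome the HSPs are
#'   projected onto.
#' @param seq_length Length of that genome.
#' @param detail If `TRUE`, also return the per-HSP trimmed coverage and
#'   identity contributions (used by the pseudo-bootstrap).
#' @return A named numeric vector `c(covered_positions, identical_positions)`,
#'   or a list with elements `totals`, `cov`, `ident` when `detail`.
#' @export
merge_hsps <- function(hsps, axis = c("query", "subject"), seq_length,
                       detail = FALSE) {
  axis <- match.arg(axis)
  a <- if (axis == "query") hsps$q_start else hsps$s_start
  b <- if (axis == "query") hsps$q_end else hsps$s_end
  n <- length(a)
  if (n && (any(a < 1L) || any(b > seq_length)))
    stop("HSP coordinate out of bounds [1, seq_length]")
  o <- order(-hsps$score, hsps$q_start, hsps$s_start)
  covered <- logical(seq_length)
  cov_i <- ident_i <- numeric(n)
  for (k in o) {
    span <- a[k]:b[k]
    new <- span[!covered[span]]
    c_new <- length(new)
    if (c_new) {
      covered[new] <- TRUE
      cov_i[k] <- c_new
      ident_i[k] <- floor(hsps$identities[k] * c_new / length(span) + 0.5)
    }
  }
  totals <- c(covered_positions = sum(cov_i),
              identical_positions = sum(ident_i))
  if (detail) list(totals = totals, cov = cov_i, ident = ident_i) else totals
}

#' Write an HSP set to a BLAST outfmt-6-like TSV
#'
#' @param hsps An `hsp_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hsps_tsv <- function(hsps, path) {
  df <- data.frame(qid = attr(hsps, "q_id"), sid = attr(hsps, "s_id"),
                   qstart = hsps$q_start, qend = hsps$q_end,
                   sstart = hsps$s_start, send = hsps$s_end,
                   strand = hsps$strand, length = hsps$length,
                   identities = hsps$identities, score = hsps$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# BLOSUM62 with the X row/column forced to zero, plus the residue coder
blosum62_x0 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      data("BLOSUM62", package = "Biostrings", envir = environment())
      m <- get("BLOSUM62", envir = environment())
      m["X", ] <- 0L; m[, "X"] <- 0L
      cache <<- m
    }
    cache
  }
})

encode_protein <- function(p, alphabet) {
  v <- strsplit(p, "")[[1]]
  idx <- match(v, alphabet)
  if (anyNA(idx))
    stop(sprintf("illegal amino-acid character(s): %s",
                 paste(unique(v[is.na(idx)]), collapse = ", ")))
  idx - 1L
}

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman with affine gaps under BLOSUM62 (with `X` scoring 0
#' against everything).  Coverage fractions are the aligned span of each
#' protein divided by its full length.
#'
#' @param a,b Protein sequences (standard 20 letters plus `X`).
#' @param params [align_params()].
#' @return A list with `score`, `length` (aligned columns), `identities`,
#'   `identity` (= identities/length), `positives` (fraction of aligned
#'   columns with positive substitution score), `a_cov`, `b_cov`, and the
#'   1-based aligned spans `a_start`/`a_end`/`b_start`/`b_end`.
#' @export
align_proteins <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence")
  m <- blosum62_x0()
  ab <- colnames(m)
  r <- cpp_sw_protein(encode_protein(toupper(a), ab),
                      encode_protein(toupper(b), ab),
                      m, params$protein_gap_open, params$protein_gap_extend)
  r$identity <- if (r$length > 0) r$identities / r$length else 0
  r$positives <- if (r$length > 0) r$positives / r$length else 0
  r$a_cov <- (r$a_end - r$a_start + 1) / nchar(a)
  r$b_cov <- (r$b_end - r$b_start + 1) / nchar(b)
  if (r$score == 0) { r$a_cov <- 0; r$b_cov <- 0 }
  r
}
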