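# Genome-BLAST Distance Phylogeny: d0/d4/d6 distances, neighbor-joining
# trees, HSP-resampling pseudo-bootstrap supports, and OPTSIL-style
# fraction-of-links clustering.

#' GBDP parameters
#'
#' @param formula Distance formula: `"d0"` (coverage-based, the
#'   nucleotide-optimised default), `"d4"` (identity over aligned
#'   positions) or `"d6"` (identity over total length).
#' @param replicates Pseudo-bootstrap replicate count.
#' @param F OPTSIL fraction of links required for cluster fusion.
#' @param seed Integer seed for the bootstrap resampling.
#' @return A list of class `gbdp_params`.
#' @export
gbdp_params <- function(formula = c("d0", "d4", "d6"), replicates = 100L,
                        F = 0.5, seed = 1L) {
  formula <- match.arg(formula)
  stopifnot(replicates >= 1, F > 0, F <= 1)
  structure(list(formula = formula, replicates = as.integer(replicates),
                 F = F, seed = as.integer(seed)), class = "gbdp_params")
}

# distances from merged coverage/identity totals
gbdp_from_totals <- function(HA, IA, HB, IB, LA, LB) {
  d0 <- 1 - (HA + HB) / (LA + LB)
  d4 <- if ((HA + HB) > 0) 1 - (IA + IB) / (HA + HB) else 1
  d6 <- 1 - (IA + IB) / (LA + LB)
  clamp <- function(x) min(1, max(0, x))
  c(d0 = clamp(d0), d4 = clamp(d4), d6 = clamp(d6))
}

#' GBDP distance between two genomes
#'
#' With `HX`/`IX` the merged HSP coverage and identical positions
#' projected on genome X and `LX` its length:
#' `d0 = 1 - (HA+HB)/(LA+LB)`, `d4 = 1 - (IA+IB)/(HA+HB)` (1 when there
#' are no HSPs), `d6 = 1 - (IA+IB)/(LA+LB)`; all clamped to `[0, 1]`.
#'
#' @param A,B [genome_record()]s.
#' @param hsps Optional precomputed `hsp_set` for the pair (A = query).
#' @param formula `"d0"`, `"d4"`, `"d6"`, or `"all"` for the named triple.
#' @param params [align_params()].
#' @return The selected distance (or named vector of all three).
#' @export
gbdp_distance <- function(A, B, hsps = NULL, formula = "d0",
                          params = align_params()) {
  if (is.null(hsps)) hsps <- find_hsps_nt(A, B, params)
  if (nrow(hsps)) {
    mA <- merge_hsps(hsps, "query", A$length)
    mB <- merge_hsps(hsps, "subject", B$length)
    d <- gbdp_from_totals(mA[["covered_positions"]], mA[["identical_positions"]],
                          mB[["covered_positions"]], mB[["identical_positions"]],
                          A$length, B$length)
  } else {
    d <- c(d0 = 1, d4 = 1, d6 = 1)
  }
  if (identical(formula, "all")) d else unname(d[[formula]])
}

#' All-pairs GBDP distance matrix
#'
#' @param genomes Named list of [genome_record()]s.
#' @param formula Distance formula (see [gbdp_distance()]).
#' @param params [align_params()].
#' @param keep_hsps Keep the per-pair trimmed HSP contributions for the
#'   pseudo-bootstrap (attribute `"pair_data"`).
#' @return A symmetric distance matrix with zero diagonal.
#' @export
gbdp_distance_matrix <- function(genomes, formula = "d0",
                                 params = align_params(), keep_hsps = FALSE) {
  ids <- vapply(genomes, function(g) g$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome ids")
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  pair_data <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      A <- genomes[[i]]; B <- genomes[[j]]
      h <- find_hsps_nt(A, B, params)
      if (nrow(h)) {
        mA <- merge_hsps(h, "query", A$length, detail = TRUE)
        mB <- merge_hsps(h, "subject", B$length, detail = TRUE)
        d <- gbdp_from_totals(sum(mA$cov), sum(mA$ident),
                              sum(mB$cov), sum(mB$ident),
                              A$length, B$length)[[formula]]
        if (keep_hsps)
          pair_data[[paste(ids[i], ids[j], sep = "\r")]] <-
            list(covA = mA$cov, idA = mA$ident, covB = mB$cov, idB = mB$ident,
                 LA = A$length, LB = B$length)
      } else {
        d <- 1
        if (keep_hsps)
          pair_data[[paste(ids[i], ids[j], sep = "\r")]] <-
            list(covA = numeric(0), idA = numeric(0), covB = numeric(0),
                 idB = numeric(0), LA = A$length, LB = B$length)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  if (keep_hsps) attr(D, "pair_data") <- pair_data
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via `ape::nj`) with negative branch lengths
#' clamped to zero.
#'
#' @param D Symmetric distance matrix (n >= 3) with dimnames.
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Neighbor-joining tree with pseudo-bootstrap supports
#'
#' The point-estimate tree is built from the full GBDP distance matrix.
#' Each replicate resamples every pair's merged HSP set with replacement
#' (same count), recomputes the pair distances and a replicate tree;
#' support of each internal bipartition of the point tree is the
#' percentage of replicates containing it (stored in `node.label`).
#'
#' @param genomes Named list of [genome_record()]s (n >= 3).
#' @param params A [gbdp_params()].
#' @param align [align_params()].
#' @return An `ape::phylo` tree with supports in `[0, 100]` as internal
#'   node labels (`NA` for the root).
#' @export
bootstrap_supports <- function(genomes, params = gbdp_params(),
                               align = align_params()) {
  D <- gbdp_distance_matrix(genomes, params$formula, align, keep_hsps = TRUE)
  pd <- attr(D, "pair_data")
  ids <- rownames(D)
  n <- length(ids)
  if (n < 3L) stop("need at least 3 genomes")
  point <- nj_tree(D)
  reps <- with_seed(params$seed, {
    lapply(seq_len(params$replicates), function(r) {
      Dr <- matrix(0, n, n, dimnames = dimnames(D))
      for (key in names(pd)) {
        p <- pd[[key]]
        idx <- strsplit(key, "\r", fixed = TRUE)[[1]]
        m <- length(p$covA)
        if (m == 0L) { d <- 1 } else {
          s <- sample.int(m, m, replace = TRUE)
          HA <- min(p$LA, sum(p$covA[s])); IA <- min(HA, sum(p$idA[s]))
          HB <- min(p$LB, sum(p$covB[s])); IB <- min(HB, sum(p$idB[s]))
          d <- gbdp_from_totals(HA, IA, HB, IB, p$LA, p$LB)[[params$formula]]
        }
        Dr[idx[1], idx[2]] <- Dr[idx[2], idx[1]] <- d
      }
      nj_tree(Dr)
    })
  })
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  point$node.label <- round(100 * counts / params$replicates, 1)
  point
}

#' OPTSIL-style fraction-of-links clustering
#'
#' Agglomerative merging: a "link" between two items is a distance at or
#' below `distance_threshold`.  Repeatedly merge the cluster pair whose
#' fraction of inter-cluster links is maximal and at least `F`; ties are
#' broken by smaller mean inter-cluster distance, then lexicographically
#' by the smallest member ids.  Stops when no pair qualifies.  `F = 1`
#' reproduces complete-linkage components; `F -> 0` single-linkage
#' components.
#'
#' @param D Symmetric distance matrix with dimnames.
#' @param distance_threshold Link threshold.
#' @param F Fraction of links required for fusion (0 < F <= 1).
#' @return A `partition`.
#' @export
optsil_cluster <- function(D, distance_threshold, F = 0.5) {
  stopifnot(F > 0, F <= 1)
  D <- as.matrix(D)
  ids <- rownames(D)
  n <- length(ids)
  clusters <- as.list(seq_len(n))
  repeat {
    best <- NULL
    for (a in seq_along(clusters)) {
      if (is.null(clusters[[a]])) next
      for (b in seq_along(clusters)) {
        if (b <= a || is.null(clusters[[b]])) next
        dd <- D[clusters[[a]], clusters[[b]], drop = FALSE]
        frac <- mean(dd <= distance_threshold)
        if (frac < F) next
        cand <- list(a = a, b = b, frac = frac, mean_d = mean(dd),
                     key = paste(min(ids[clusters[[a]]]),
                                 min(ids[clusters[[b]]])))
        if (is.null(best) ||
            cand$frac > best$frac ||
            (cand$frac == best$frac && cand$mean_d < best$mean_d) ||
            (cand$frac == best$frac && cand$mean_d == best$mean_d &&
             cand$key < best$key)) best <- cand
      }
    }
    if (is.null(best)) break
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[best$b] <- list(NULL)
  }
  memb <- integer(n)
  k <- 0L
  for (cl in clusters) {
    if (is.null(cl)) next
    k <- k + 1L
    memb[cl] <- k
  }
  relabel_first_seen(stats::setNames(memb, ids), ids)
}

#' Write a distance matrix as square PHYLIP-like TSV
#' @param D Distance matrix with dimnames.
#' @param path Output file.
#' @param header Optional comment line.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(D, path, header = NULL) {
  write_matrix_tsv(as.matrix(D), path, symmetric = TRUE, tol = 1e-6,
                   header = header)
}
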