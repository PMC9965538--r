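# Shared-protein-cluster viral network: protein clustering, hypergeometric
# genome-pair significance, and Markov clustering into viral clusters.

# Markov clustering on a (sparse) non-negative adjacency matrix.
# Deterministic: column-normalize, then iterate expansion (squaring) and
# inflation until the matrix stabilizes; clusters are the connected
# components of the non-zero structure of the limit matrix.
mcl_cluster <- function(adj, inflation = 2, loop = c("one", "max"),
                        max_iter = 100L, tol = 1e-6, prune = 1e-8) {
  loop <- match.arg(loop)
  n <- nrow(adj)
  ids <- rownames(adj)
  if (n == 1L) return(new_partition(stats::setNames(1L, ids)))
  M <- Matrix::Matrix(adj, sparse = TRUE)
  M <- (M + Matrix::t(M)) / 2
  lv <- if (loop == "max") {
    mx <- apply(abs(M), 1L, max)
    ifelse(mx > 0, mx, 1)
  } else rep(1, n)
  Matrix::diag(M) <- lv
  normalize <- function(X) {
    cs <- Matrix::colSums(X)
    cs[cs == 0] <- 1
    X %*% Matrix::Diagonal(x = 1 / cs)
  }
  M <- normalize(M)
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2@x <- M2@x^inflation
    M2 <- Matrix::drop0(M2, tol = prune)
    M2 <- normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  S <- (abs(M) > prune)
  g <- igraph::graph_from_adjacency_matrix(S | Matrix::t(S), mode = "max")
  comp <- igraph::components(g)$membership
  names(comp) <- ids
  relabel_first_seen(comp, ids)
}

# shared-kmer prefilter + Smith-Waterman edges between proteins.
# Returns a data frame (i, j, identity, coverage_short, positives, length)
# over candidate pairs passing identity/coverage thresholds.
protein_edges <- function(seqs, genome_of, min_identity, min_coverage,
                          params = align_params(), k = 4L, min_shared = 2L,
                          max_kmer_bucket = 100L) {
  n <- length(seqs)
  if (n < 2L) return(NULL)
  km <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(character(0))
    unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
  })
  idx <- split(rep(seq_len(n), lengths(km)), unlist(km))
  idx <- idx[lengths(idx) >= 2L & lengths(idx) <= max_kmer_bucket]
  if (!length(idx)) return(NULL)
  pairs <- do.call(rbind, lapply(idx, function(v) {
    cmb <- utils::combn(sort(v), 2L)
    cbind(cmb[1L, ], cmb[2L, ])
  }))
  key <- paste(pairs[, 1L], pairs[, 2L])
  cnt <- table(key)
  keep <- names(cnt)[cnt >= min_shared]
  if (!length(keep)) return(NULL)
  kp <- do.call(rbind, strsplit(keep, " "))
  out <- NULL
  for (r in seq_len(nrow(kp))) {
    i <- as.integer(kp[r, 1L]); j <- as.integer(kp[r, 2L])
    al <- align_proteins(seqs[[i]], seqs[[j]], params)
    shorter <- min(nchar(seqs[[i]]), nchar(seqs[[j]]))
    cov <- if (al$length > 0) {
      max(al$a_cov * (nchar(seqs[[i]]) / shorter),
          al$b_cov * (nchar(seqs[[j]]) / shorter))
    } else 0
    cov <- min(cov, 1)
    if (al$identity >= min_identity && cov >= min_coverage)
      out <- rbind(out, data.frame(i = i, j = j, identity = al$identity,
                                   coverage_short = cov,
                                   positives = al$positives,
                                   length = al$length))
  }
  out
}

check_proteomes <- function(proteomes) {
  if (length(proteomes) < 2L) stop("need proteomes for >= 2 genomes")
  for (g in names(proteomes)) {
    if (!length(proteomes[[g]]))
      stop(sprintf("empty proteome for genome '%s'", g))
  }
  seqs <- character(0); genome_of <- character(0)
  for (g in names(proteomes)) {
    p <- proteomes[[g]]
    if (is.null(names(p)))
      names(p) <- sprintf("%s|p%04d", g, seq_along(p))
    nm <- names(p)
    if (any(nm %in% names(seqs))) nm <- paste0(g, "|", nm)
    seqs <- c(seqs, stats::setNames(as.character(p), nm))
    genome_of <- c(genome_of, stats::setNames(rep(g, length(p)), nm))
  }
  list(seqs = seqs, genome_of = genome_of)
}

#' Cluster proteins into protein clusters (PCs)
#'
#' Builds a graph over all proteins with edges where local alignment
#' identity >= `min_identity` and coverage of the shorter protein >=
#' `min_coverage`, then applies Markov clustering.  Singletons are kept.
#'
#' @param proteomes Named list (by genome id) of named character vectors
#'   of protein sequences.
#' @param min_identity,min_coverage Edge thresholds.
#' @param inflation Markov-clustering inflation.
#' @param params [align_params()].
#' @return A list of class `protein_cluster_set`: `clusters` (list of
#'   protein-id vectors), `membership` (protein id -> cluster index),
#'   `genome_of` (protein id -> genome id), `universe_size` (number of
#'   clusters).
#' @export
build_protein_clusters <- function(proteomes, min_identity = 0.35,
                                   min_coverage = 0.5, inflation = 2,
                                   params = align_params()) {
  pp <- check_proteomes(proteomes)
  seqs <- pp$seqs
  n <- length(seqs)
  ed <- protein_edges(seqs, pp$genome_of, min_identity, min_coverage, params)
  adj <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (!is.null(ed)) {
    for (r in seq_len(nrow(ed))) {
      adj[ed$i[r], ed$j[r]] <- adj[ed$j[r], ed$i[r]] <- ed$identity[r]
    }
  }
  part <- mcl_cluster(adj, inflation = inflation, loop = "one")
  memb <- part$membership
  clusters <- split(names(memb), memb)
  names(clusters) <- NULL
  structure(list(clusters = clusters, membership = memb,
                 genome_of = pp$genome_of,
                 universe_size = length(clusters)),
            class = "protein_cluster_set")
}

#' @export
print.protein_cluster_set <- function(x, ...) {
  cat(sprintf("<protein_cluster_set> %d protein(s) in %d cluster(s)\n",
              length(x$membership), x$universe_size))
  invisible(x)
}

#' Hypergeometric significance of shared protein clusters
#'
#' Upper-tail probability `P(X >= k_shared)` for the number of protein
#' clusters shared by two genomes, where genome A carries `n_A` clusters,
#' genome B `n_B`, out of `universe` clusters in total.  Computed in log
#' space for stability.
#'
#' @param k_shared Shared cluster count.
#' @param n_A,n_B Cluster counts of the two genomes.
#' @param universe Total number of protein clusters.
#' @param log10 Return `-log10(p)` instead of `p`.
#' @return The p-value (or `-log10(p)` capped at 300).
#' @export
shared_pc_significance <- function(k_shared, n_A, n_B, universe,
                                   log10 = FALSE) {
  if (k_shared > min(n_A, n_B) || max(n_A, n_B) > universe || k_shared < 0)
    stop("need k_shared <= min(n_A, n_B) <= universe")
  lp <- stats::phyper(k_shared - 1, n_A, universe - n_A, n_B,
                      lower.tail = FALSE, log.p = TRUE)
  if (log10) min(300, -lp / log(10)) else exp(lp)
}

#' Build the genome-level shared-protein network
#'
#' One edge per genome pair with weight `-log10 P(X >= shared)` from
#' [shared_pc_significance()], kept when the weight reaches `min_weight`.
#'
#' @param pcs A [build_protein_clusters()] result.
#' @param min_weight Minimum edge weight.
#' @return A list of class `genome_network` with `nodes` and an `edges`
#'   data frame (`from`, `to`, `weight`).
#' @export
build_genome_network <- function(pcs, min_weight = 1.0) {
  genomes <- unique(unname(pcs$genome_of))
  pc_sets <- lapply(genomes, function(g)
    unique(pcs$membership[names(pcs$genome_of)[pcs$genome_of == g]]))
  names(pc_sets) <- genomes
  u <- pcs$universe_size
  edges <- NULL
  n <- length(genomes)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      k <- length(intersect(pc_sets[[i]], pc_sets[[j]]))
      w <- shared_pc_significance(k, length(pc_sets[[i]]),
                                  length(pc_sets[[j]]), u, log10 = TRUE)
      if (w >= min_weight)
        edges <- rbind(edges, data.frame(from = genomes[i], to = genomes[j],
                                         weight = w,
                                         stringsAsFactors = FALSE))
    }
  }
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0))
  structure(list(nodes = genomes, edges = edges), class = "genome_network")
}

#' @export
print.genome_network <- function(x, ...) {
  cat(sprintf("<genome_network> %d node(s), %d edge(s)\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

network_adjacency <- function(network) {
  n <- length(network$nodes)
  adj <- matrix(0, n, n, dimnames = list(network$nodes, network$nodes))
  e <- network$edges
  for (r in seq_len(nrow(e)))
    adj[e$from[r], e$to[r]] <- adj[e$to[r], e$from[r]] <- e$weight[r]
  adj
}

#' Cluster a genome network into viral clusters and sub-clusters
#'
#' Two-pass Markov clustering: a first pass at `inflation` (self-loops
#' set to each node's maximum incident weight) yields viral clusters
#' (VCs); a second pass at `sub_inflation` within each VC yields sub-VCs
#' nested inside the VCs.  Isolated nodes become singleton VCs.
#'
#' @param network A [build_genome_network()] result.
#' @param inflation,sub_inflation Markov-clustering inflations.
#' @return A list with `vcs` and `sub_vcs` partitions (sub-VCs refine VCs).
#' @export
cluster_viral <- function(network, inflation = 2, sub_inflation = 4) {
  adj <- network_adjacency(network)
  vcs <- mcl_cluster(adj, inflation = inflation, loop = "max")
  memb <- vcs$membership
  sub <- integer(0)
  next_id <- 0L
  for (v in sort(unique(memb))) {
    nodes <- names(memb)[memb == v]
    if (length(nodes) == 1L) {
      s <- stats::setNames(1L, nodes)
    } else {
      s <- mcl_cluster(adj[nodes, nodes, drop = FALSE],
                       inflation = sub_inflation, loop = "max")$membership
    }
    sub <- c(sub, s + next_id)
    next_id <- next_id + max(s)
  }
  sub_part <- relabel_first_seen(sub, names(memb))
  list(vcs = vcs, sub_vcs = sub_part)
}

#' Write network edges to TSV (source, target, weight)
#' @param network A `genome_network`.
#' @param path Output file.
#' @param header Optional comment line.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path, header = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  e <- network$edges
  names(e) <- c("source", "target", "weight")
  utils::write.table(e, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
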