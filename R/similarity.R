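# VIRIDIC-style intergenomic similarity and ICTV threshold clustering.

#' Species/genus demarcation thresholds
#'
#' ICTV-recommended intergenomic-similarity thresholds: >= 95% for
#' species, >= 70% for genus.
#'
#' @param species,genus Percentages with `species > genus`.
#' @return A list of class `taxon_thresholds`.
#' @export
taxon_thresholds <- function(species = 95, genus = 70) {
  stopifnot(species > genus, species <= 100, genus >= 0)
  structure(list(species = species, genus = genus), class = "taxon_thresholds")
}

#' Intergenomic similarity of two genomes (percentage)
#'
#' HSPs between the pair are merged (overlap-trimmed) on each genome, and
#' `sim = 100 * (idA + idB) / (LA + LB)` where `idX` is the number of
#' identical aligned positions projected on genome X and `LX` its length.
#' Identical genomes score exactly 100; a pair with no HSPs scores 0.
#'
#' @param A,B [genome_record()]s.
#' @param params [align_params()].
#' @return Similarity percentage in `[0, 100]`.
#' @export
intergenomic_similarity <- function(A, B, params = align_params()) {
  h <- find_hsps_nt(A, B, params)
  if (!nrow(h)) return(0)
  idA <- merge_hsps(h, "query", A$length)[["identical_positions"]]
  idB <- merge_hsps(h, "subject", B$length)[["identical_positions"]]
  100 * (idA + idB) / (A$length + B$length)
}

#' All-pairs intergenomic similarity matrix
#'
#' @param genomes Named list of [genome_record()]s (unique ids; a single
#'   genome yields a 1x1 matrix of 100).
#' @param params [align_params()].
#' @return A symmetric matrix of class `similarity_matrix` with 100 on
#'   the diagonal, ordered as the input.
#' @export
similarity_matrix <- function(genomes, params = align_params()) {
  ids <- vapply(genomes, function(g) g$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome ids")
  n <- length(ids)
  m <- diag(100, n)
  dimnames(m) <- list(ids, ids)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- intergenomic_similarity(genomes[[i]], genomes[[j]],
                                                    params)
    }
  }
  class(m) <- c("similarity_matrix", class(m))
  m
}

#' @export
print.similarity_matrix <- function(x, ...) {
  print(round(unclass(x), 1), ...)
  invisible(x)
}

new_partition <- function(membership) {
  structure(list(membership = membership,
                 n_clusters = length(unique(membership))),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d item(s) in %d cluster(s)\n",
              length(x$membership), x$n_clusters))
  invisible(x)
}

# relabel cluster indices by first appearance in the input order
relabel_first_seen <- function(memb, ids) {
  memb <- memb[ids]
  new <- match(memb, unique(memb))
  new_partition(stats::setNames(new, ids))
}

#' Cluster genomes by a similarity threshold (single linkage)
#'
#' Connected components of the graph with an edge wherever
#' `sim >= threshold`.  Cluster indices are ordered by first-seen genome.
#'
#' @param matrix A [similarity_matrix()] (or plain symmetric matrix with
#'   dimnames).
#' @param threshold Percentage edge threshold.
#' @return A `partition`: list with `membership` (named integer vector)
#'   and `n_clusters`.
#' @export
cluster_by_threshold <- function(matrix, threshold) {
  m <- unclass(matrix)
  ids <- rownames(m)
  adj <- (m >= threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
  comp <- igraph::components(g)$membership
  relabel_first_seen(comp, ids)
}

#' Assign species and genus partitions from a similarity matrix
#'
#' Both partitions use single-linkage threshold clustering; because every
#' species edge (>= species threshold) is also a genus edge, the genus
#' partition is a coarsening of the species partition by construction.
#'
#' @param matrix A [similarity_matrix()].
#' @param thresholds A [taxon_thresholds()].
#' @return A list with `species` and `genera` partitions.
#' @export
assign_taxa <- function(matrix, thresholds = taxon_thresholds()) {
  list(species = cluster_by_threshold(matrix, thresholds$species),
       genera = cluster_by_threshold(matrix, thresholds$genus))
}

#' Write cluster assignments to TSV
#'
#' @param taxa Result of [assign_taxa()].
#' @param path Output file.
#' @param header Optional comment line.
#' @return `path`, invisibly.
#' @export
write_taxa_tsv <- function(taxa, path, header = NULL) {
  df <- data.frame(id = names(taxa$species$membership),
                   species_cluster = unname(taxa$species$membership),
                   genus_cluster = unname(taxa$genera$membership))
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
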