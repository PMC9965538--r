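# Pangenome: ortholog-group clustering across a genome set and
# core-proteome extraction with per-group conservation statistics.

#' Cluster proteomes into ortholog groups
#'
#' All-vs-all protein graph with edges at >= `min_identity` local
#' identity and >= `min_coverage` coverage of the shorter protein,
#' clustered with Markov clustering at a mild inflation.  Paralogs (two
#' members from one genome) are permitted but flagged.
#'
#' @param proteomes Named list (by genome id) of named protein vectors.
#' @param min_identity Identity threshold (default 0.30, the reduced
#'   BLASTp-style threshold used for phage pangenomes).
#' @param min_coverage Coverage of the shorter protein.
#' @param inflation Markov-clustering inflation.
#' @param params [align_params()].
#' @return A list of `ortholog_group`s, each with `group_id`, `members`
#'   (data frame `genome`, `protein`, `sequence`), `n_genomes_present`,
#'   `has_paralogs`, `mean_pairwise_identity` and
#'   `mean_pairwise_similarity` (BLOSUM62 positive-score column fraction),
#'   means taken over all unordered member pairs from distinct genomes.
#' @export
cluster_orthologs <- function(proteomes, min_identity = 0.30,
                              min_coverage = 0.5, inflation = 1.5,
                              params = align_params()) {
  pp <- check_proteomes(proteomes)
  seqs <- pp$seqs
  n <- length(seqs)
  ed <- protein_edges(seqs, pp$genome_of, min_identity, min_coverage, params)
  adj <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (!is.null(ed)) {
    for (r in seq_len(nrow(ed)))
      adj[ed$i[r], ed$j[r]] <- adj[ed$j[r], ed$i[r]] <- ed$identity[r]
  }
  part <- mcl_cluster(adj, inflation = inflation, loop = "one")
  memb <- part$membership
  groups <- lapply(sort(unique(memb)), function(k) {
    prot <- names(memb)[memb == k]
    members <- data.frame(genome = unname(pp$genome_of[prot]), protein = prot,
                          sequence = unname(seqs[prot]),
                          stringsAsFactors = FALSE)
    stats_ <- group_conservation(members, params)
    structure(list(group_id = sprintf("og_%04d", k), members = members,
                   n_genomes_present = length(unique(members$genome)),
                   has_paralogs = anyDuplicated(members$genome) > 0,
                   mean_pairwise_identity = stats_$identity,
                   mean_pairwise_similarity = stats_$similarity),
              class = "ortholog_group")
  })
  groups
}

# mean pairwise identity / positive-score fraction over pairs from
# distinct genomes (NA for single-member or single-genome groups)
group_conservation <- function(members, params = align_params()) {
  n <- nrow(members)
  idents <- numeric(0); sims <- numeric(0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (members$genome[i] == members$genome[j]) next
      al <- align_proteins(members$sequence[i], members$sequence[j], params)
      idents <- c(idents, al$identity)
      sims <- c(sims, al$positives)
    }
  }
  list(identity = if (length(idents)) mean(idents) else NA_real_,
       similarity = if (length(sims)) mean(sims) else NA_real_)
}

#' @export
print.ortholog_group <- function(x, ...) {
  cat(sprintf("<ortholog_group> %s: %d member(s) in %d genome(s)%s\n",
              x$group_id, nrow(x$members), x$n_genomes_present,
              if (is.na(x$mean_pairwise_identity)) "" else
                sprintf(", mean identity %.3f", x$mean_pairwise_identity)))
  invisible(x)
}

#' Core-proteome report from ortholog groups
#'
#' Core groups have at least one member in every genome.  Per genome,
#' the accessory percentage is `100 * (1 - core members / proteome size)`.
#'
#' @param groups Result of [cluster_orthologs()].
#' @param genome_ids All genome ids in the set.
#' @return A list of class `core_proteome_report` with `core_count`,
#'   `core_groups` (the group objects), and `per_genome` (data frame
#'   `genome`, `proteome_size`, `core`, `accessory`, `accessory_pct`).
#' @export
core_proteome <- function(groups, genome_ids) {
  is_core <- vapply(groups, function(g)
    all(genome_ids %in% g$members$genome), logical(1))
  core_groups <- groups[is_core]
  all_members <- do.call(rbind, lapply(groups, function(g) g$members))
  core_members <- if (length(core_groups))
    do.call(rbind, lapply(core_groups, function(g) g$members)) else
      all_members[0, ]
  per_genome <- do.call(rbind, lapply(genome_ids, function(gid) {
    size <- sum(all_members$genome == gid)
    core <- sum(core_members$genome == gid)
    data.frame(genome = gid, proteome_size = size, core = core,
               accessory = size - core,
               accessory_pct = if (size > 0) 100 * (1 - core / size) else NA,
               stringsAsFactors = FALSE)
  }))
  structure(list(core_count = length(core_groups), core_groups = core_groups,
                 per_genome = per_genome),
            class = "core_proteome_report")
}

#' @export
print.core_proteome_report <- function(x, ...) {
  cat(sprintf("<core_proteome_report> %d core group(s) across %d genome(s)\n",
              x$core_count, nrow(x$per_genome)))
  invisible(x)
}

#' Rank core groups by sequence conservation
#'
#' @param core_groups Core groups (e.g. `$core_groups` of
#'   [core_proteome()]).
#' @param top_n How many to return (the full list if fewer exist).
#' @return A data frame (`group_id`, `n_genomes_present`,
#'   `mean_pairwise_identity`, `mean_pairwise_similarity`) sorted by mean
#'   identity descending.
#' @export
rank_markers <- function(core_groups, top_n = 5L) {
  if (!length(core_groups)) stop("empty core: no groups to rank")
  df <- do.call(rbind, lapply(core_groups, function(g)
    data.frame(group_id = g$group_id, n_genomes_present = g$n_genomes_present,
               mean_pairwise_identity = g$mean_pairwise_identity,
               mean_pairwise_similarity = g$mean_pairwise_similarity,
               stringsAsFactors = FALSE)))
  df <- df[order(-df$mean_pairwise_identity), ]
  rownames(df) <- NULL
  utils::head(df, top_n)
}

#' Gene presence/absence matrix (groups x genomes)
#'
#' @param groups Result of [cluster_orthologs()].
#' @param genome_ids All genome ids.
#' @return Integer matrix of member counts with groups as rows.
#' @export
presence_absence_matrix <- function(groups, genome_ids) {
  m <- t(vapply(groups, function(g)
    vapply(genome_ids, function(gid) sum(g$members$genome == gid),
           integer(1)),
    integer(length(genome_ids))))
  rownames(m) <- vapply(groups, function(g) g$group_id, character(1))
  colnames(m) <- genome_ids
  m
}
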