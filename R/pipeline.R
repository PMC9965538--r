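# End-to-end orchestration of the classification pipeline.

#' Pipeline configuration
#'
#' @param species_threshold,genus_threshold Intergenomic-similarity
#'   demarcation percentages.
#' @param pangenome_min_identity Ortholog-clustering identity threshold.
#' @param min_fold Codon-bias reporting fold threshold.
#' @param gbdp_formula GBDP distance formula.
#' @param replicates Pseudo-bootstrap replicates.
#' @param F OPTSIL fraction of links.
#' @param optsil_threshold OPTSIL distance (link) threshold.
#' @param min_orf_aa Minimum ORF length (residues).
#' @param seed Root seed for all randomness.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(species_threshold = 95, genus_threshold = 70,
                            pangenome_min_identity = 0.30, min_fold = 2.0,
                            gbdp_formula = "d0", replicates = 100L, F = 0.5,
                            optsil_threshold = 0.3, min_orf_aa = 30L,
                            seed = 1L) {
  stopifnot(species_threshold > genus_threshold,
            pangenome_min_identity > 0, pangenome_min_identity <= 1,
            min_fold >= 1, replicates >= 1, F > 0, F <= 1)
  structure(list(species_threshold = species_threshold,
                 genus_threshold = genus_threshold,
                 pangenome_min_identity = pangenome_min_identity,
                 min_fold = min_fold, gbdp_formula = gbdp_formula,
                 replicates = as.integer(replicates), F = F,
                 optsil_threshold = optsil_threshold,
                 min_orf_aa = as.integer(min_orf_aa),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(unclass(config)), collapse = ""), f)
  unname(tools::md5sum(f))
}

# translate forward-strand ORFs of one genome into a proteome
orfs_to_proteome <- function(genome, orfs) {
  seqs <- vapply(seq_len(nrow(orfs)), function(i) {
    nt <- if (orfs$strand[i] == "+")
      substr(genome$seq, orfs$start[i], orfs$end[i])
    else revcomp(substr(genome$seq, orfs$start[i], orfs$end[i]))
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(nt), if.fuzzy.codon = "X"))
    sub("\\*$", "", aa)
  }, character(1))
  stats::setNames(seqs, orfs$label)
}

#' Run the full classification pipeline
#'
#' ORF calling -> protein-sharing network (VC/sub-VC) -> intergenomic
#' similarity matrix + species/genus assignment -> GBDP tree with
#' pseudo-bootstrap supports + OPTSIL clustering -> pangenome/core
#' proteome.  All artifacts are written under `out_dir` together with a
#' run manifest recording the seed and a hash of the configuration.
#'
#' @param genomes Named list of [genome_record()]s (>= 2).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   file output.
#' @return A list of class `classification_result` with elements
#'   `orfs`, `proteomes`, `network`, `viral_clusters`, `similarity`,
#'   `taxa`, `tree`, `optsil`, `pangenome`, `manifest`.
#' @export
run_classify <- function(genomes, config = pipeline_config(), out_dir = NULL) {
  if (length(genomes) < 2L) stop("need >= 2 genomes")
  ids <- vapply(genomes, function(g) g$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome ids")
  hash <- config_hash(config)
  hdr <- sprintf("phagetax run: seed=%d config_md5=%s", config$seed, hash)

  orfs <- lapply(genomes, find_orfs, min_aa = config$min_orf_aa)
  proteomes <- lapply(seq_along(genomes), function(i)
    orfs_to_proteome(genomes[[i]], orfs[[i]]))
  names(proteomes) <- ids

  pcs <- build_protein_clusters(proteomes)
  network <- build_genome_network(pcs)
  vcs <- cluster_viral(network)

  sim <- similarity_matrix(genomes)
  taxa <- assign_taxa(sim, taxon_thresholds(config$species_threshold,
                                            config$genus_threshold))

  tree <- if (length(genomes) >= 3L) {
    bootstrap_supports(genomes, gbdp_params(config$gbdp_formula,
                                            config$replicates, config$F,
                                            config$seed))
  } else NULL
  D <- gbdp_distance_matrix(genomes, config$gbdp_formula)
  opts <- optsil_cluster(D, config$optsil_threshold, config$F)

  groups <- cluster_orthologs(proteomes,
                              min_identity = config$pangenome_min_identity)
  core <- core_proteome(groups, ids)

  manifest <- list(
    package = "phagetax",
    version = as.character(utils::packageVersion("phagetax")),
    seed = config$seed, config_md5 = hash, config = unclass(config),
    n_genomes = length(genomes), genome_ids = ids,
    n_protein_clusters = pcs$universe_size,
    n_vcs = vcs$vcs$n_clusters, n_sub_vcs = vcs$sub_vcs$n_clusters,
    n_species = taxa$species$n_clusters, n_genera = taxa$genera$n_clusters,
    n_optsil_clusters = opts$n_clusters,
    n_ortholog_groups = length(groups), core_count = core$core_count)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_matrix_tsv(round(unclass(sim), 1), file.path(out_dir, "similarity_matrix.tsv"),
                     symmetric = TRUE, tol = 0.06, header = hdr)
    write_taxa_tsv(taxa, file.path(out_dir, "clusters.tsv"), header = hdr)
    write_network_tsv(network, file.path(out_dir, "network_edges.tsv"),
                      header = hdr)
    vc_df <- data.frame(id = names(vcs$vcs$membership),
                        vc = unname(vcs$vcs$membership),
                        sub_vc = unname(vcs$sub_vcs$membership))
    con <- file(file.path(out_dir, "viral_clusters.tsv"), "w")
    writeLines(paste0("# ", hdr), con)
    utils::write.table(vc_df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    if (!is.null(tree)) write_newick(tree, file.path(out_dir, "gbdp_tree.nwk"))
    write_distance_tsv(D, file.path(out_dir, "gbdp_distances.tsv"),
                       header = hdr)
    pa <- presence_absence_matrix(groups, ids)
    write_matrix_tsv(pa, file.path(out_dir, "gene_presence_absence.tsv"),
                     header = hdr)
    jsonlite::write_json(
      c(manifest, list(core_per_genome = core$per_genome)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }

  structure(list(orfs = orfs, proteomes = proteomes, network = network,
                 viral_clusters = vcs, similarity = sim, taxa = taxa,
                 tree = tree, optsil = opts,
                 pangenome = list(groups = groups, core = core),
                 manifest = manifest),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("<classification_result> %d genome(s): %d species, ",
                     "%d genera (similarity); %d VC(s) / %d sub-VC(s); ",
                     "%d ortholog group(s), core %d\n"),
              m$n_genomes, m$n_species, m$n_genera, m$n_vcs, m$n_sub_vcs,
              m$n_ortholog_groups, m$core_count))
  invisible(x)
}
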