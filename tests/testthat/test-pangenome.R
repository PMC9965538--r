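make_family <- function(n_core, n_private, genome_ids, core_div = 0.1,
                        len = 160) {
  core <- vapply(seq_len(n_core), function(i) random_aa(len), "")
  out <- lapply(seq_along(genome_ids), function(gi) {
    m <- vapply(core, function(s) mutate_protein(s, core_div), "")
    priv <- vapply(seq_len(n_private[gi]), function(i) random_aa(len), "")
    stats::setNames(c(m, priv),
                    paste0(genome_ids[gi], "_", seq_len(n_core + n_private[gi])))
  })
  names(out) <- genome_ids
  out
}

test_that("identical proteomes form one group per gene, present in both genomes", {
  set.seed(81)
  prots <- stats::setNames(vapply(1:15, function(i) random_aa(150), ""),
                           paste0("p", 1:15))
  gr <- cluster_orthologs(list(gA = prots, gB = prots))
  expect_length(gr, 15L)
  expect_true(all(vapply(gr, function(g) g$n_genomes_present, integer(1)) == 2L))
  # unrelated proteomes collapse to singletons
  other <- stats::setNames(vapply(1:15, function(i) random_aa(150), ""),
                           paste0("q", 1:15))
  gr2 <- cluster_orthologs(list(gA = prots, gB = other))
  expect_length(gr2, 30L)
})

test_that("a planted core is extracted with correct per-genome accessory shares", {
  set.seed(82)
  prot <- make_family(8, c(3, 2, 4), c("gA", "gB", "gC"))
  gr <- cluster_orthologs(prot)
  core <- core_proteome(gr, names(prot))
  expect_equal(core$core_count, 8L)
  pg <- core$per_genome
  expect_equal(pg$accessory, c(3L, 2L, 4L))
  expect_equal(pg$accessory_pct, 100 * pg$accessory / pg$proteome_size)
  # all-identical genomes: zero accessory everywhere
  prots <- stats::setNames(vapply(1:6, function(i) random_aa(150), ""),
                           paste0("p", 1:6))
  gr3 <- cluster_orthologs(list(a = prots, b = prots, c = prots))
  core3 <- core_proteome(gr3, c("a", "b", "c"))
  expect_true(all(core3$per_genome$accessory_pct == 0))
  # one genome shares nothing: empty core
  gr4 <- cluster_orthologs(list(a = prots, b = prots,
                                z = stats::setNames(
                                  vapply(1:6, function(i) random_aa(150), ""),
                                  paste0("z", 1:6))))
  expect_equal(core_proteome(gr4, c("a", "b", "z"))$core_count, 0L)
})

test_that("adding a genome never increases the core; duplicating one never changes it", {
  set.seed(83)
  prot <- make_family(6, c(2, 2, 2), c("gA", "gB", "gC"))
  core3 <- core_proteome(cluster_orthologs(prot), names(prot))$core_count
  extra <- list(gD = stats::setNames(vapply(1:5, function(i) random_aa(160), ""),
                                     paste0("d", 1:5)))
  prot4 <- c(prot, extra)
  core4 <- core_proteome(cluster_orthologs(prot4), names(prot4))$core_count
  expect_lte(core4, core3)
  dup <- c(prot, list(gA2 = stats::setNames(unname(prot$gA),
                                            paste0("dup_", seq_along(prot$gA)))))
  coredup <- core_proteome(cluster_orthologs(dup), names(dup))$core_count
  expect_equal(coredup, core3)
})

test_that("group conservation means match a brute-force oracle and rank correctly", {
  set.seed(84)
  # two 3-genome groups at controlled divergence
  prot <- list(
    gA = c(hi = mutate_protein(b1 <- random_aa(120), 0),
           lo = mutate_protein(b2 <- random_aa(120), 0)),
    gB = c(hi = mutate_protein(b1, 0.05), lo = mutate_protein(b2, 0.20)),
    gC = c(hi = mutate_protein(b1, 0.05), lo = mutate_protein(b2, 0.20)))
  gr <- cluster_orthologs(prot)
  core <- core_proteome(gr, names(prot))
  expect_equal(core$core_count, 2L)
  rk <- rank_markers(core$core_groups, top_n = 10)
  expect_equal(nrow(rk), 2L)
  expect_true(rk$mean_pairwise_identity[1] > rk$mean_pairwise_identity[2])
  # brute-force check of the mean over distinct-genome pairs
  g1 <- core$core_groups[[which(vapply(core$core_groups, function(g)
    grepl("hi", g$members$protein[1]), logical(1)))[1]]]
  man <- c()
  m <- g1$members
  for (i in 1:(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    if (m$genome[i] == m$genome[j]) next
    man <- c(man, align_proteins(m$sequence[i], m$sequence[j])$identity)
  }
  expect_equal(g1$mean_pairwise_identity, mean(man), tolerance = 1e-12)
  expect_error(rank_markers(list()), "empty core")
})

test_that("presence/absence matrix shape and counts are consistent", {
  set.seed(85)
  prot <- make_family(4, c(1, 2), c("gA", "gB"))
  gr <- cluster_orthologs(prot)
  pa <- presence_absence_matrix(gr, names(prot))
  expect_equal(ncol(pa), 2L)
  expect_equal(sum(pa[, "gA"]), length(prot$gA))
  expect_equal(sum(pa[, "gB"]), length(prot$gB))
})
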