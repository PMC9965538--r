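test_that("GBDP distances follow their closed forms", {
  set.seed(51)
  s <- random_nt(5000)
  A <- genome_record("A", s); B <- genome_record("B", s)
  expect_equal(unname(gbdp_distance(A, B, formula = "all")),
               c(0, 0, 0), tolerance = 1e-12)
  # unrelated genomes: no HSPs, all distances 1 by convention
  U <- genome_record("U", random_nt(5000))
  expect_equal(unname(gbdp_distance(A, U, formula = "all")), c(1, 1, 1))
  # full-coverage alignment at ~90% identity, equal lengths:
  # d0 ~ 0, d4 ~ 0.1, d6 ~ 0.1
  C <- genome_record("C", substitute_frac(s, 0.10))
  d <- gbdp_distance(A, C, formula = "all")
  expect_lt(d[["d0"]], 0.01)
  expect_lt(abs(d[["d4"]] - 0.10), 0.015)
  expect_lt(abs(d[["d6"]] - 0.10), 0.015)
})

test_that("(1 - d6) = (1 - d4)(1 - d0) holds to numerical precision", {
  set.seed(52)
  s <- random_nt(4000)
  A <- genome_record("A", s)
  for (div in c(0.05, 0.15, 0.3)) {
    B <- genome_record("B", substitute_frac(s, div))
    d <- gbdp_distance(A, B, formula = "all")
    expect_lt(abs((1 - d[["d6"]]) - (1 - d[["d4"]]) * (1 - d[["d0"]])), 1e-12)
  }
})

test_that("neighbor joining recovers additive trees and rejects tiny inputs", {
  for (i in 1:10) {
    set.seed(i)
    tr <- ape::rtree(sample(4:6, 1))
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.3)
    D <- stats::cophenetic(tr)
    rec <- nj_tree(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                           ape::unroot(rec))), 0)
    # input order must not change the unrooted topology
    o <- sample(nrow(D))
    rec2 <- nj_tree(D[o, o])
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(rec),
                                           ape::unroot(rec2))), 0)
  }
  expect_error(nj_tree(matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "at least 3")
})

test_that("pseudo-bootstrap gives full support to well-separated planted clades", {
  gs <- genome_spec(length = 15000, n_genes = 12, seed = 2)
  sim <- simulate_clustered_genomes(
    cluster_spec(n_clusters = 2, genomes_per_cluster = 3,
                 intra_divergence = 0.05, inter_divergence = 0.4, seed = 3),
    gs)
  tr <- bootstrap_supports(sim, gbdp_params(replicates = 50, seed = 4))
  truth <- attr(sim, "truth")
  # locate the bipartition separating the two planted clades
  clade1 <- truth$id[truth$cluster == 1]
  mrca <- ape::getMRCA(ape::root(tr, outgroup = truth$id[truth$cluster == 2][1],
                                 resolve.root = TRUE), clade1)
  expect_true(any(as.numeric(tr$node.label) >= 95, na.rm = TRUE))
  # single replicate: supports are all 0 or 100
  tr1 <- bootstrap_supports(sim[1:4], gbdp_params(replicates = 1, seed = 5))
  expect_true(all(as.numeric(tr1$node.label) %in% c(0, 100)))
})

test_that("fraction-of-links clustering honours F limits and planted blocks", {
  ids <- letters[1:6]
  D <- matrix(0.9, 6, 6, dimnames = list(ids, ids)); diag(D) <- 0
  # threshold below all inter-item distances: everything stays singleton
  expect_equal(optsil_cluster(D, 0.1, F = 1)$n_clusters, 6L)
  # two tight blocks with no sub-threshold links between them
  D[1:3, 1:3] <- 0.05; D[4:6, 4:6] <- 0.05; diag(D) <- 0
  p <- optsil_cluster(D, 0.2, F = 0.5)
  expect_equal(p$n_clusters, 2L)
  expect_equal(length(unique(p$membership[c("a", "b", "c")])), 1L)
  # F -> 0 with one qualifying link anywhere chains everything
  D2 <- matrix(0.9, 4, 4, dimnames = list(ids[1:4], ids[1:4])); diag(D2) <- 0
  D2["a", "b"] <- D2["b", "a"] <- 0.1
  D2["b", "c"] <- D2["c", "b"] <- 0.1
  D2["c", "d"] <- D2["d", "c"] <- 0.1
  expect_equal(optsil_cluster(D2, 0.2, F = 1e-9)$n_clusters, 1L)
})

test_that("F limits reproduce single- and complete-linkage components", {
  for (i in 1:8) {
    set.seed(60 + i)
    n <- 7
    D <- matrix(stats::runif(n * n), n)
    D <- (D + t(D)) / 2; diag(D) <- 0
    dimnames(D) <- list(letters[1:n], letters[1:n])
    t0 <- 0.35
    # F -> 0: components of the link graph (single linkage)
    pS <- optsil_cluster(D, t0, F = 1e-9)
    sl <- stats::cutree(stats::hclust(stats::as.dist(D), "single"), h = t0)
    expect_true(partition_matches_truth(pS, sl))
    # F = 1: complete-linkage fixpoint (all intra links, no fully-linked
    # cluster pair left)
    pC <- optsil_cluster(D, t0, F = 1)
    groups <- split(names(pC$membership), pC$membership)
    for (g in groups) expect_true(all(D[g, g] <= t0))
    if (length(groups) > 1) {
      for (a in seq_len(length(groups) - 1)) {
        for (b in (a + 1):length(groups)) {
          expect_false(all(D[groups[[a]], groups[[b]]] <= t0))
        }
      }
    }
  }
})
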