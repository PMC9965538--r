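test_that("synthesized genomes carry identical terminal repeats and planted genes", {
  syn <- synthesize_phage_genome(genome_spec(length = 20000, n_genes = 20,
                                             seed = 1))
  g <- syn$genome
  expect_equal(g$length, 20000L)
  expect_identical(substr(g$seq, 1, 193), substr(g$seq, g$length - 192, g$length))
  expect_equal(nrow(syn$features), 20L)
  # genes are non-overlapping, forward strand, span divisible by 3
  f <- syn$features[order(syn$features$start), ]
  expect_true(all(f$start[-1] > f$end[-nrow(f)]))
  expect_true(all(f$strand == "+"))
  expect_true(all((f$end - f$start + 1) %% 3 == 0))
  # planted slippage gene: heptamer in frame, extension >= 200 aa
  tr <- syn$slippage
  expect_identical(substr(g$seq, tr$heptamer_start, tr$heptamer_end), "GGGAAAG")
  expect_gte(tr$extended_aa - tr$natural_aa, 200)
})

test_that("realized GC tracks the spec within 0.01 (including off-default targets)", {
  g1 <- synthesize_phage_genome(genome_spec(length = 20000, n_genes = 20,
                                            seed = 2))$genome
  expect_lt(abs(g1$gc - 0.421), 0.01)
  g2 <- synthesize_phage_genome(genome_spec(length = 10000, gc = 0.5,
                                            n_genes = 5, seed = 3))$genome
  expect_gte(g2$gc, 0.49); expect_lte(g2$gc, 0.51)
})

test_that("generators are pure functions of their seed", {
  a <- synthesize_phage_genome(genome_spec(length = 12000, n_genes = 10,
                                           seed = 9))$genome
  b <- synthesize_phage_genome(genome_spec(length = 12000, n_genes = 10,
                                           seed = 9))$genome
  expect_identical(a$seq, b$seq)
  r1 <- simulate_reads(a, read_sim_params(n_reads = 3, seed = 4))
  r2 <- simulate_reads(a, read_sim_params(n_reads = 3, seed = 4))
  expect_identical(lapply(r1, `[[`, "seq"), lapply(r2, `[[`, "seq"))
  e1 <- evolve_genome(a, 0.2, seed = 5)
  e2 <- evolve_genome(a, 0.2, seed = 5)
  e3 <- evolve_genome(a, 0.2, seed = 6)
  expect_identical(e1$seq, e2$seq)
  expect_false(identical(e1$seq, e3$seq))
})

test_that("evolution plants the requested substitution divergence", {
  g <- genome_record("anc", {set.seed(11); random_nt(10000)})
  expect_identical(evolve_genome(g, 0, seed = 1)$seq, g$seq)
  # without indels the pairwise alignment is the identity map, so the
  # mismatch fraction is directly measurable
  ev <- evolve_genome(g, 0.10, indel_rate = 0, seed = 2)
  va <- strsplit(g$seq, "")[[1]]; vb <- strsplit(ev$seq, "")[[1]]
  frac <- mean(va != vb)
  expect_gte(frac, 0.08); expect_lte(frac, 0.12)
  expect_error(evolve_genome(g, 0.7, seed = 1), "0.6")
})

test_that("clustered simulation labels genomes and honours degenerate settings", {
  gs <- genome_spec(length = 8000, n_genes = 6, seed = 4)
  sim0 <- simulate_clustered_genomes(
    cluster_spec(n_clusters = 1, genomes_per_cluster = 3,
                 intra_divergence = 0, inter_divergence = 0.3, seed = 1), gs)
  expect_length(sim0, 3L)
  seqs <- vapply(sim0, `[[`, "", "seq")
  expect_true(all(seqs == seqs[1]))
  truth <- attr(sim0, "truth")
  expect_equal(truth$cluster, rep(1L, 3))
})

test_that("read simulation honours error-free, adapter and orientation settings", {
  g <- synthesize_phage_genome(genome_spec(length = 8000, n_genes = 6,
                                           seed = 5))$genome
  clean <- simulate_reads(g, read_sim_params(
    n_reads = 6, sub_rate = 0, ins_rate = 0, del_rate = 0,
    frac_full_length = 1, add_adapters = FALSE, seed = 2))
  for (r in clean)
    expect_true(r$seq == g$seq || r$seq == revcomp(g$seq))
  withad <- simulate_reads(g, read_sim_params(
    n_reads = 6, sub_rate = 0, ins_rate = 0, del_rate = 0,
    frac_full_length = 1, seed = 2))
  ad <- y_adapters()
  for (r in withad) {
    expect_identical(substr(r$seq, 1, nchar(ad["top"])), unname(ad["top"]))
    expect_identical(substr(r$seq, nchar(r$seq) - nchar(ad["bottom"]) + 1,
                            nchar(r$seq)), revcomp(ad["bottom"]))
    expect_length(r$quals, nchar(r$seq))
  }
  expect_identical(simulate_reads(g, read_sim_params(n_reads = 0)), list())
})

test_that("infeasible gene packing is rejected", {
  expect_error(synthesize_phage_genome(genome_spec(length = 5000,
                                                   n_genes = 100, seed = 1)),
               "infeasible")
})
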