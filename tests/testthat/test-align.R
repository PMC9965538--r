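test_that("identical sequences give one full-coverage HSP; reverse complement flips strand", {
  set.seed(21)
  s <- random_nt(10000)
  h <- find_hsps_nt(s, s)
  expect_equal(nrow(h), 1L)
  expect_equal(unname(unlist(h[1, c("q_start", "q_end", "s_start", "s_end")])),
               c(1L, 10000L, 1L, 10000L))
  expect_equal(h$identities[1], h$length[1])
  h2 <- find_hsps_nt(s, revcomp(s))
  expect_equal(h2$strand[1], "-")
  expect_equal(h2$identities[1], 10000L)
  expect_equal(c(h2$s_start[1], h2$s_end[1]), c(1L, 10000L))
})

test_that("HSP scores match a full dynamic-programming oracle when seeds exist", {
  set.seed(22)
  n_eq <- 0; n_tot <- 0
  for (i in 1:40) {
    a <- random_nt(sample(80:300, 1))
    b <- random_nt(sample(80:300, 1))
    k <- sample(30:70, 1); p <- sample(nchar(a) - k, 1)
    seg <- substitute_frac(substr(a, p, p + k - 1), 0.08)
    q <- sample(nchar(b) - 1, 1)
    b <- paste0(substr(b, 1, q), seg, substr(b, q + 1, nchar(b)))
    h <- find_hsps_nt(a, b, align_params(min_hsp_score = 15))
    best <- if (nrow(h)) max(h$score) else 0
    orc <- sw_nt_oracle(a, b)
    # x-drop/seed-miss tolerance: never more than 25 below the optimum
    expect_gte(best, orc - 25)
    n_tot <- n_tot + 1; n_eq <- n_eq + (best == orc)
  }
  expect_gte(n_eq / n_tot, 0.85)
})

test_that("HSPs recover nearly all truly aligned positions of a 10%-divergent pair", {
  set.seed(23)
  a <- random_nt(1000)
  b <- substitute_frac(a, 0.10)  # identity map is the true alignment
  h <- find_hsps_nt(a, b, align_params(min_hsp_score = 20))
  cov <- logical(1000)
  for (r in seq_len(nrow(h))) cov[h$q_start[r]:h$q_end[r]] <- TRUE
  expect_gte(mean(cov), 0.95)
})

test_that("protein alignment equals the quadratic Smith-Waterman oracle", {
  set.seed(24)
  for (i in 1:40) {
    a <- random_aa(sample(30:300, 1))
    b <- random_aa(sample(30:300, 1))
    if (i %% 2 == 0) {  # plant a homologous segment half the time
      k <- sample(20:60, 1); p <- sample(nchar(a) - k, 1)
      b <- paste0(substr(b, 1, 10), substr(a, p, p + k), substr(b, 11, nchar(b)))
    }
    expect_equal(align_proteins(a, b)$score, sw_aa_oracle(a, b))
  }
})

test_that("protein alignment self and containment cases behave as specified", {
  set.seed(25)
  p <- random_aa(120)
  r <- align_proteins(p, p)
  expect_equal(r$identity, 1.0)
  expect_equal(r$a_cov, 1.0); expect_equal(r$b_cov, 1.0)
  long <- paste0("MKV", random_aa(50))
  r2 <- align_proteins("MKV", long)
  expect_equal(r2$a_cov, 1.0)
  expect_lt(r2$b_cov, 0.1)
  expect_error(align_proteins("", "MKV"), "empty")
})

test_that("merge_hsps trims overlaps greedily and apportions identities", {
  one <- data.frame(q_start = 1L, q_end = 1000L, s_start = 1L, s_end = 1000L,
                    strand = "+", length = 1000L, identities = 1000L,
                    score = 1000L)
  expect_equal(unname(merge_hsps(one, "query", 1000)), c(1000, 1000))
  two <- data.frame(q_start = c(1L, 201L), q_end = c(100L, 300L),
                    s_start = c(1L, 201L), s_end = c(100L, 300L),
                    strand = "+", length = 100L, identities = 100L,
                    score = c(100L, 100L))
  expect_equal(unname(merge_hsps(two, "query", 1000)), c(200, 200))
  # 50-bp overlap: the weaker HSP keeps round(90 * 50/100) = 45 identities
  ov <- data.frame(q_start = c(1L, 51L), q_end = c(100L, 150L),
                   s_start = c(1L, 51L), s_end = c(100L, 150L),
                   strand = "+", length = 100L, identities = c(100L, 90L),
                   score = c(100L, 80L))
  expect_equal(unname(merge_hsps(ov, "query", 1000)), c(150, 145))
  bad <- data.frame(q_start = 0L, q_end = 10L, s_start = 1L, s_end = 11L,
                    strand = "+", length = 11L, identities = 11L, score = 11L)
  expect_error(merge_hsps(bad, "query", 1000), "bounds")
})

test_that("self-comparison coverage is symmetric across query and subject", {
  set.seed(26)
  s <- random_nt(5000)
  h <- find_hsps_nt(s, s)
  mq <- merge_hsps(h, "query", 5000)
  ms <- merge_hsps(h, "subject", 5000)
  expect_equal(mq, ms)
})

test_that("summed identities fall as planted divergence rises", {
  set.seed(27)
  a <- random_nt(8000)
  tot <- vapply(c(0.02, 0.08, 0.15), function(d) {
    b <- substitute_frac(a, d)
    h <- find_hsps_nt(a, b)
    merge_hsps(h, "query", 8000)[["identical_positions"]]
  }, numeric(1))
  expect_true(all(diff(tot) < 0))
})
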