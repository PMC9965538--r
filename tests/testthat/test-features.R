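test_that("adapter trimming removes terminal matches only, idempotently", {
  ad <- y_adapters()
  r <- trim_adapters(read_record("r", paste0(ad["top"], "G")))
  expect_equal(r$seq, "G")
  # two substitutions inside the 61-nt top adapter: identity 59/61, still trimmed
  set.seed(71)
  core <- random_nt(600)
  mut <- strsplit(unname(ad["top"]), "")[[1]]
  mut[c(10, 30)] <- vapply(mut[c(10, 30)],
                           function(b) sample(setdiff(NT, b), 1), "")
  r2 <- trim_adapters(read_record("r2", paste0(paste(mut, collapse = ""), core)))
  expect_equal(r2$seq, core)
  # adapter in the read interior is untouched
  inner <- paste0(random_nt(400), ad["top"], random_nt(400))
  r3 <- trim_adapters(read_record("r3", inner))
  expect_equal(r3$seq, inner)
  # idempotence
  both <- read_record("r4", paste0(ad["top"], core, revcomp(ad["bottom"])))
  t1 <- trim_adapters(both)
  t2 <- trim_adapters(t1)
  expect_equal(t1$seq, core)
  expect_equal(t2$seq, t1$seq)
})

test_that("assembly DTR detection is exact, robust to substitutions, and quiet on random DNA", {
  set.seed(72)
  core <- random_nt(6000)
  g <- paste0(core, substr(core, 1, 193))
  expect_equal(detect_dtr_in_assembly(g)$dtr_length, 193L)
  r <- detect_dtr_in_assembly(random_nt(6000))
  expect_lt(r$dtr_length, 25L)
  # 5 substitutions in the terminal copy: identity 0.974 >= 0.95
  v <- strsplit(g, "")[[1]]
  L <- length(v)
  pos <- L - 193 + sort(sample(193, 5))
  v[pos] <- vapply(v[pos], function(b) sample(setdiff(NT, b), 1), "")
  expect_equal(detect_dtr_in_assembly(paste(v, collapse = ""))$dtr_length, 193L)
})

test_that("termini detection from reads is exact on error-free data for several repeat lengths", {
  for (L in c(50, 193, 400)) {
    g <- synthesize_phage_genome(genome_spec(length = 12000, n_genes = 8,
                                             dtr_len = L, seed = 2))$genome
    reads <- simulate_reads(g, read_sim_params(
      n_reads = 4, sub_rate = 0, ins_rate = 0, del_rate = 0,
      frac_full_length = 1, add_adapters = FALSE, seed = 3))
    rep <- suppressWarnings(detect_termini_from_reads(reads, g))
    expect_equal(rep$dtr_length, L)
    expect_equal(nchar(rep$dtr_sequence), L)
  }
  # circularly permuted (DTR-free) genome: negative control
  g0 <- synthesize_phage_genome(genome_spec(length = 12000, n_genes = 8,
                                            dtr_len = 0, seed = 2))$genome
  rot <- paste0(substr(g0$seq, 4001, g0$length), substr(g0$seq, 1, 4000))
  reads0 <- simulate_reads(genome_record(g0$id, rot), read_sim_params(
    n_reads = 4, frac_full_length = 1, seed = 4))
  rep0 <- suppressWarnings(detect_termini_from_reads(reads0,
                                                     genome_record(g0$id, rot)))
  expect_equal(rep0$dtr_length, 0L)
})

test_that("a known DTR is found near both termini by similarity search", {
  set.seed(73)
  core <- random_nt(8000)
  g <- genome_record("g", paste0(core, substr(core, 1, 193)))
  dtr <- substr(g$seq, 1, 193)
  hits <- find_dtr_by_similarity(dtr, g)
  expect_equal(nrow(hits), 2L)
  expect_true(all(hits$identity == 1))
  expect_equal(hits$start[1], 1L)
  expect_equal(hits$end[2], g$length)
  expect_equal(nrow(find_dtr_by_similarity(random_nt(193), g)), 0L)
  # 10% diverged query still found at ~0.9 identity
  hits2 <- find_dtr_by_similarity(substitute_frac(dtr, 0.10), g)
  expect_gte(nrow(hits2), 1L)
  expect_true(all(abs(hits2$identity - 0.9) < 0.06))
})

test_that("ORF calling finds constructed and planted genes", {
  set.seed(74)
  orf <- paste0("ATG", paste(rep("AAA", 30), collapse = ""), "TAA")
  g <- paste0("TTTAA", orf, random_nt(100))  # in-frame TAA precedes the ATG
  found <- find_orfs(g, min_aa = 30)
  fwd <- found[found$strand == "+", ]
  expect_true(any(fwd$end - fwd$start + 1 == nchar(orf)))
  expect_equal(nrow(find_orfs("", min_aa = 30)), 0L)
  # planted genes on a synthetic genome are recovered exactly
  syn <- synthesize_phage_genome(genome_spec(length = 20000, n_genes = 20,
                                             seed = 5))
  called <- find_orfs(syn$genome)
  key <- paste(called$start, called$end, called$strand)
  planted <- paste(syn$features$start, syn$features$end, syn$features$strand)
  expect_gte(mean(planted %in% key), 0.95)
})

test_that("slippery-site scanning applies the heptamer pattern near the stop", {
  fc <- make_frameshift_construct()
  sites <- find_slippery_sites(fc$genome, fc$cds)
  expect_true(8293 %in% sites$position)
  hit <- sites[sites$position == 8293, ]
  expect_equal(hit$heptamer, "GGGAAAG")
  # pattern counterexample and positive
  probe <- function(hept) {
    g <- fc$genome
    v <- strsplit(g$seq, "")[[1]]
    v[8293:8299] <- strsplit(hept, "")[[1]]
    find_slippery_sites(genome_record("p", paste(v, collapse = "")), fc$cds)
  }
  expect_false(8293 %in% probe("GAGAAAG")$position)
  expect_true(8293 %in% probe("CCCTTTA")$position)
})

test_that("the -1 isoform predictor reproduces the printed MCP coordinates", {
  fc <- make_frameshift_construct(cds_start = 7253, cds_end = 8314,
                                  heptamer_end = 8299, ext_stop_end = 9930)
  sites <- find_slippery_sites(fc$genome, fc$cds)
  rep <- predict_extended_isoform(fc$genome, fc$cds,
                                  sites[sites$position == 8293, ])
  expect_equal(rep$natural_length_aa, 353L)
  expect_equal(rep$extended_length_aa, 892L)
  expect_equal(rep$extended_end, 9930L)
  expect_false(rep$premature_stop)
  # slippage arithmetic: extended span plus the re-read base is a codon
  # multiple
  expect_equal((rep$extended_end - 7253 + 2) %% 3, 0)
})

test_that("an early -1-frame stop is reported as a premature (SU10-like) isoform", {
  fc <- make_frameshift_construct(ext_stop_end = 8299 + 41)
  sites <- find_slippery_sites(fc$genome, fc$cds)
  rep <- predict_extended_isoform(fc$genome, fc$cds,
                                  sites[sites$position == 8293, ])
  expect_true(rep$premature_stop)
  expect_lte(rep$extended_length_aa - rep$natural_length_aa, 10L)
  # heptamer off a codon boundary is rejected
  bad <- sites[sites$position == 8293, ]
  bad$transcript_offset <- bad$transcript_offset + 1L
  expect_error(predict_extended_isoform(fc$genome, fc$cds, bad),
               "codon boundary")
})

test_that("codon usage counts synonymous shares and rejects malformed CDSs", {
  cu <- codon_usage(c(one = "ATGAGAAGATAA"))
  expect_equal(cu$share[cu$codon == "AGA"], 1.0)
  expect_equal(cu$count[cu$codon == "AGA"], 2)
  cu2 <- codon_usage(c(a = "ATGAGACGTTAA", b = "ATGAGACGTTAA"))
  arg <- cu2[cu2$aa == "R", ]
  expect_equal(arg$share[arg$codon == "AGA"], 0.5)
  expect_equal(arg$share[arg$codon == "CGT"], 0.5)
  expect_error(codon_usage(c(bad = "ATGTAAAGATAA")), "bad.*internal stop")
  expect_error(codon_usage(c(off = "ATGAA")), "divisible")
  # input order and duplication do not change shares
  syn <- synthesize_phage_genome(genome_spec(length = 12000, n_genes = 10,
                                             seed = 6))
  cds <- vapply(seq_len(nrow(syn$features)), function(i)
    substr(syn$genome$seq, syn$features$start[i], syn$features$end[i]), "")
  s1 <- codon_usage(cds)$share
  s2 <- codon_usage(rev(cds))$share
  s3 <- codon_usage(c(cds, cds))$share
  expect_equal(s1, s2)
  expect_equal(s1, s3)
})

test_that("a genome synthesized from an AGA-rich profile recovers the planted share", {
  syn <- synthesize_phage_genome(genome_spec(seed = 1))  # 78 kb default
  cds <- vapply(seq_len(nrow(syn$features)), function(i)
    substr(syn$genome$seq, syn$features$start[i], syn$features$end[i]), "")
  cu <- codon_usage(cds)
  expect_lt(abs(cu$share[cu$codon == "AGA"] - 0.202), 0.02)
})

test_that("codon bias reports fold changes with pseudocount guarding", {
  phage <- codon_usage_table(c(AGA = 202, CGT = 300, CGC = 200, CGG = 100,
                               CGA = 150, AGG = 48, GCT = 500))
  host <- codon_usage_table(c(AGA = 36, CGT = 350, CGC = 250, CGG = 120,
                              CGA = 180, AGG = 64, GCT = 500))
  cb <- codon_bias(phage, host)
  aga <- cb[cb$codon == "AGA", ]
  expect_equal(round(aga$fold_change, 1), 5.6)
  expect_equal(aga$direction, "up")
  # identical tables produce nothing
  expect_equal(nrow(codon_bias(phage, phage)), 0L)
  # zero host count: finite fold via pseudocount, flagged unstable
  h0 <- codon_usage_table(c(AGA = 0, CGT = 350, GCT = 500))
  p0 <- codon_usage_table(c(AGA = 10, CGT = 350, GCT = 500))
  cb0 <- codon_bias(p0, h0)
  a0 <- cb0[cb0$codon == "AGA", ]
  expect_true(is.finite(a0$fold_change))
  expect_true(a0$unstable)
})
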