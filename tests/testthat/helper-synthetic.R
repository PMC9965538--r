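# shared fixture builders (everything is generated in code)

NT <- c("A", "C", "G", "T")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_nt <- function(n) paste(sample(NT, n, replace = TRUE), collapse = "")
random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# substitute a fraction of positions (no indels); returns the mutated string
substitute_frac <- function(seq, frac) {
  v <- strsplit(seq, "")[[1]]
  k <- round(length(v) * frac)
  if (k > 0) {
    pos <- sample(length(v), k)
    v[pos] <- vapply(v[pos], function(b) sample(setdiff(NT, b), 1), "")
  }
  paste(v, collapse = "")
}

# mutate a protein at a given fraction of residues
mutate_protein <- function(p, frac) {
  v <- strsplit(p, "")[[1]]
  k <- round(length(v) * frac)
  if (k > 0) {
    pos <- sample(length(v), k)
    v[pos] <- sample(AA20, k, replace = TRUE)
  }
  paste(v, collapse = "")
}

# upper-tail hypergeometric by exhaustive summation (independent oracle)
hyper_tail_enum <- function(k, nA, nB, U) {
  s <- 0
  for (x in k:min(nA, nB)) s <- s + choose(nA, x) * choose(U - nA, nB - x)
  s / choose(U, nB)
}

# Smith-Waterman score oracle via Biostrings (local, affine gaps with
# cost gapOpening + gapExtension * L)
sw_nt_oracle <- function(a, b, match = 1, mismatch = -2, gap_open = 5,
                         gap_ext = 2) {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                mismatch = mismatch,
                                                baseOnly = TRUE)
  Biostrings::pairwiseAlignment(a, b, type = "local", substitutionMatrix = m,
                                gapOpening = gap_open, gapExtension = gap_ext,
                                scoreOnly = TRUE)
}

sw_aa_oracle <- function(a, b, gap_open = 11, gap_ext = 1) {
  m <- phagetax:::blosum62_x0()
  Biostrings::pairwiseAlignment(a, b, type = "local", substitutionMatrix = m,
                                gapOpening = gap_open, gapExtension = gap_ext,
                                scoreOnly = TRUE)
}

# does every cluster in partition p contain items of a single truth label,
# with the same number of clusters as truth labels?
partition_matches_truth <- function(p, truth_labels) {
  lab <- truth_labels[names(p$membership)]
  pure <- all(tapply(lab, p$membership, function(x) length(unique(x)) == 1))
  pure && p$n_clusters == length(unique(lab))
}

# is partition p a refinement of partition q (same items)?
refines <- function(p, q) {
  all(tapply(q$membership[names(p$membership)], p$membership,
             function(x) length(unique(x)) == 1))
}
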