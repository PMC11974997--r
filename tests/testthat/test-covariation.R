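test_that("mutual information matches the closed form on perfect covariation", {
  ## 8 sequences, two columns in perfect Watson-Crick covariation:
  ## joint distribution is uniform over 4 complementary pairs, MI = 2 bits
  seqs <- c("AU", "AU", "GC", "GC", "CG", "CG", "UA", "UA")
  aln <- profile_alignment(seqs, weighting = "none")
  sc <- pair_scores(aln)
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$mi, 2.0, tolerance = 1e-12)
  ## APC of a single scored pair equals its own score
  expect_equal(sc$score, 0, tolerance = 1e-12)
})

test_that("constant and gap-dominated columns carry no signal", {
  aln <- profile_alignment(c("AAU", "AAU", "AAU", "AAU"), weighting = "none")
  sc <- pair_scores(aln)
  expect_true(all(sc$mi == 0))
  cls <- classify_pairs(aln, covariation_config(n_null_shuffles = 5, seed = 1))
  expect_true(all(cls$power == 0))
  expect_true(all(cls$label == "neutral"))
  ## a column with >= 50% gaps is never scored
  ag <- profile_alignment(c("A-U", "A-U", "AGU", "A-U"), weighting = "none")
  sg <- pair_scores(ag)
  expect_false(any(sg$i == 2L | sg$j == 2L))
  expect_error(pair_scores(profile_alignment("ACGU")), ">=2 sequences")
})

test_that("the empirical null is deterministic and pools all shuffles", {
  set.seed(42)
  seqs <- replicate(8, rand_seq(6))
  aln <- profile_alignment(seqs, weighting = "none")
  P <- nrow(pair_scores(aln))
  cfg <- covariation_config(n_null_shuffles = 2, seed = 9)
  ns <- null_scores(aln, cfg)
  expect_length(ns, 2L * P)
  expect_equal(ns, sort(ns, decreasing = TRUE))
  expect_identical(ns, null_scores(aln, cfg))
  ## identical sequences survive shuffling unchanged: all null scores zero
  ai <- profile_alignment(rep("ACGUAC", 6), weighting = "none")
  expect_true(all(null_scores(ai, cfg) == 0))
})

test_that("a planted perfectly covarying pair is classified positive", {
  set.seed(7)
  S <- 12L
  wc <- matrix(c("A","U","C","G","G","C","U","A"), ncol = 2, byrow = TRUE)
  draw <- wc[sample.int(4, S, replace = TRUE), , drop = FALSE]
  bg <- replicate(10, sample(c("A","C","G","U"), S, replace = TRUE))
  chars <- cbind(bg[, 1:5], draw[, 1L], bg[, 6:10], draw[, 2L])
  aln <- profile_alignment(apply(chars, 1, paste, collapse = ""),
                           weighting = "none")
  cls <- classify_pairs(aln, covariation_config(n_null_shuffles = 200, seed = 7))
  planted <- cls[cls$i == 6L & cls$j == 12L, ]
  expect_equal(planted$label, "positive")
  expect_lte(planted$evalue, 0.05)
  ## determinism of the full classification
  cls2 <- classify_pairs(aln, covariation_config(n_null_shuffles = 200, seed = 7))
  expect_identical(cls, cls2)
})

test_that("variable but independent columns are labelled negative", {
  set.seed(21)
  S <- 16L
  chars <- replicate(12, sample(c("A", "C", "G", "U"), S, replace = TRUE))
  aln <- profile_alignment(apply(chars, 1, paste, collapse = ""),
                           weighting = "none")
  cls <- classify_pairs(aln, covariation_config(n_null_shuffles = 100,
                                                seed = 21))
  ## high per-column variability gives high covariation power everywhere
  expect_true(all(cls$power >= 0.95))
  ## without covariation nothing reaches significance: all pairs negative
  expect_true(all(cls$label == "negative"))
  ## label semantics: positive iff significant
  expect_true(all((cls$evalue <= 0.05) == (cls$label == "positive")))
})

test_that("type-I error is controlled on covariation-free alignments", {
  ## zero-covariation replicates: the fraction of positive labels stays
  ## within twice the nominal per-alignment E-value threshold
  n_pos <- 0L; n_tot <- 0L
  for (r in 1:50) {
    set.seed(1000 + r)
    seqs <- replicate(10, rand_seq(10))
    aln <- profile_alignment(seqs, weighting = "none")
    cls <- classify_pairs(aln, covariation_config(n_null_shuffles = 40,
                                                  seed = 1000 + r))
    n_pos <- n_pos + sum(cls$label == "positive")
    n_tot <- n_tot + nrow(cls)
  }
  expect_lte(n_pos / n_tot, 2 * 0.05)
})

test_that("adding covarying sequences never decreases the planted pair score", {
  ## compensatory additions consistent with the planted covariation pattern
  base <- c("AU", "AU", "AU", "AU")
  additions <- c("GC", "CG", "UA", "GC", "CG", "UA")
  prev <- -Inf
  for (k in 0:6) {
    aln <- profile_alignment(c(base, additions[seq_len(k)]),
                             weighting = "none")
    mi <- pair_scores(aln)$mi
    expect_gte(mi + 1e-12, prev)
    prev <- mi
  }
})

test_that("external pair lists are validated and loaded verbatim", {
  f <- tmpfile(".txt")
  writeLines(c("# comment", "3 14 positive 0.001", "1 20 negative"), f)
  ext <- load_external_pairs(f, n_cols = 20L)
  expect_equal(ext$i, c(3L, 1L))
  expect_equal(ext$j, c(14L, 20L))
  expect_equal(ext$label, c("positive", "negative"))
  expect_equal(ext$evalue[1L], 0.001)
  f2 <- tmpfile(); writeLines("5 5 positive", f2)
  expect_error(load_external_pairs(f2, 20L), "i < j")
  f3 <- tmpfile(); writeLines("3 25 positive", f3)
  expect_error(load_external_pairs(f3, 20L), "out of range")
  f4 <- tmpfile(); writeLines("3 14 maybe", f4)
  expect_error(load_external_pairs(f4, 20L), "unknown label")
  f5 <- tmpfile(); writeLines(character(0), f5)
  expect_equal(nrow(load_external_pairs(f5, 20L)), 0L)
})

test_that("null helix expectation reproduces the E-value arithmetic", {
  expect_equal(expected_null_helices(14146, 0.05), 707.3)
})
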