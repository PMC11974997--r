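test_that("consensus emissions follow the off-consensus rule", {
  h <- build_segment_hmm("RNN")
  expect_equal(h$k, 3L)
  ## position 1: R = {A,G} share 1 - 2e-4, C and U get 1e-4 each
  expect_equal(unname(h$match_emis[, 1L]),
               c((1 - 2e-4) / 2, 1e-4, (1 - 2e-4) / 2, 1e-4), tolerance = 1e-15)
  ## N spreads evenly
  expect_equal(unname(h$match_emis[, 2L]), rep(0.25, 4))
  expect_equal(colSums(h$match_emis), rep(1, 3), tolerance = 1e-12)
  expect_error(build_segment_hmm("AXG"), "illegal IUPAC")
})

test_that("expected emitted length is k plus min(0.1 k, 1.5)", {
  expect_equal(expected_hmm_length(build_segment_hmm("ACGU")), 4.4,
               tolerance = 1e-9)
  expect_equal(expected_hmm_length(build_segment_hmm(strrep("A", 20))), 21.5,
               tolerance = 1e-9)
  ## empty segments keep a small insertion capacity
  expect_equal(expected_hmm_length(build_segment_hmm("")), 0.1,
               tolerance = 1e-9)
  for (k in c(1, 2, 5, 8, 14, 15, 16, 25)) {
    h <- build_segment_hmm(strrep("N", k))
    expect_equal(expected_hmm_length(h), k + min(0.1 * k, 1.5),
                 tolerance = 1e-9)
  }
})

test_that("forward probability matches single-path hand computations", {
  aln <- profile_alignment("G", weighting = "none")
  h <- build_segment_hmm("G", delta = 0)
  ## only path: no insert at junction 0, match G, no insert at junction 1
  t <- h$t_ins
  hand <- 2 * log(1 - t) + log(1 - 3e-4)
  expect_equal(hmm_forward(h, aln, 1L, 1L), hand, tolerance = 1e-12)
  ## expected insert count solves (k+1) t/(1-t) = 0.1 for k = 1, delta = 0
  expect_equal(2 * t / (1 - t), 0.1, tolerance = 1e-12)

  ## empty-consensus HMM on an empty span: geometric no-insert probability
  h0 <- build_segment_hmm("")
  expect_equal(hmm_forward(h0, aln, 1L, 0L), log(1 - h0$t_ins),
               tolerance = 1e-12)
  expect_equal(1 - h0$t_ins, 1 / 1.1, tolerance = 1e-12)

  ## a span shorter than the consensus is unreachable without deletions
  h2 <- build_segment_hmm("GG", delta = 0)
  expect_identical(hmm_forward(h2, aln, 1L, 1L), -Inf)
  ## ... but reachable with deletions
  h2d <- build_segment_hmm("GG", delta = 0.01)
  expect_true(is.finite(hmm_forward(h2d, aln, 1L, 1L)))
  expect_error(hmm_forward(h2, aln, 2L, 4L), "invalid span")
})

test_that("sampled lengths agree with the analytic expectation", {
  h <- build_segment_hmm("GNR")
  n <- 20000L
  set.seed(123)
  lens <- vapply(seq_len(n), function(i) nchar(sample_hmm(h)), 1)
  se <- stats::sd(lens) / sqrt(n)
  expect_lt(abs(mean(lens) - expected_hmm_length(h)), 3 * se)
})

test_that("the consensus outscores any single substitution", {
  h <- build_segment_hmm("GAUC")
  ref <- "GAUC"
  score <- function(s) {
    a <- profile_alignment(s, weighting = "none")
    hmm_forward(h, a, 1L, nchar(s))
  }
  s0 <- score(ref)
  for (pos in 1:4) for (b in c("A", "C", "G", "U")) {
    if (substr(ref, pos, pos) == b) next
    mut <- ref
    substr(mut, pos, pos) <- b
    expect_lt(score(mut), s0)
  }
})
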