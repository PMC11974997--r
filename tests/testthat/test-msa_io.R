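test_that("stockholm parsing builds column profiles and unifies gap dialects", {
  f <- tmpfile(".sto")
  writeLines(c("# STOCKHOLM 1.0", "s1 ACGt", "s2 a.GU", "//"), f)
  aln <- read_stockholm(f, weighting = "none")
  expect_equal(aln$n_seqs, 2L)
  expect_equal(aln$n_cols, 4L)
  expect_equal(unname(aln$col_freq[, 1L]), c(1, 0, 0, 0))    # both A
  expect_equal(unname(aln$col_freq[, 2L]), c(0, 0.5, 0, 0))  # C / gap
  expect_equal(aln$col_gapfrac, c(0, 0.5, 0, 0))
  expect_false(grepl("T", paste(aln$seqs, collapse = "")))

  ## identical sequences: degenerate profile
  a2 <- profile_alignment(c("ACGU", "ACGU"), weighting = "none")
  expect_equal(unname(a2$col_freq[, 1L]), c(1, 0, 0, 0))

  ## multi-block stockholm with SS_cons
  f2 <- tmpfile(".sto")
  writeLines(c("# STOCKHOLM 1.0", "s1 GGAA", "#=GC SS_cons <<..",
               "", "s1 UUCC", "#=GC SS_cons ..>>", "//"), f2)
  a3 <- read_stockholm(f2)
  expect_equal(a3$n_cols, 8L)
  ss <- attr(a3, "ss_cons")
  expect_equal(ss$pairs_by_layer[[1L]],
               matrix(c(1L, 2L, 8L, 7L), 2, 2, dimnames = NULL))
})

test_that("malformed alignments raise informative format errors", {
  expect_error(profile_alignment(c("ACGU", "ACGUA"), names = c("a", "bad")),
               "ragged.*bad")
  expect_error(profile_alignment("ACXG"), "non-IUPAC.*column 3")
  f <- tmpfile(".sto")
  writeLines(c("not stockholm"), f)
  expect_error(read_stockholm(f), "STOCKHOLM")
})

test_that("profile weighting schemes normalize correctly", {
  ## unweighted counting
  a <- profile_alignment(c("A", "A", "G", "G"), weighting = "none")
  expect_equal(unname(a$col_freq[, 1L]), c(0.5, 0, 0.5, 0))
  ## all-gap column
  ag <- profile_alignment(c("A-", "G-"), weighting = "none")
  expect_equal(ag$col_gapfrac[2L], 1)
  expect_equal(unname(ag$col_freq[, 2L]), rep(0, 4))
  ## position-based weights: 3 identical + 1 divergent sequence; hand
  ## computation gives 1/6 per column for the identical sequences and 1/2
  ## for the divergent one, normalizing to (2/3, 2/3, 2/3, 2)
  ah <- profile_alignment(c("ACGU", "ACGU", "ACGU", "GUAC"),
                          weighting = "henikoff")
  expect_equal(ah$weights, c(2/3, 2/3, 2/3, 2), tolerance = 1e-12)
  expect_gt(ah$weights[4L], 1)
  expect_equal(sum(ah$weights), 4)
  ## ambiguity codes distribute fractionally and keep columns normalized
  ar <- profile_alignment(c("RN", "AU"), weighting = "none")
  expect_equal(unname(ar$col_freq[, 1L]), c(0.75, 0, 0.25, 0))
  expect_equal(colSums(ar$col_freq) + ar$col_gapfrac, c(1, 1))
})

test_that("column profiles always satisfy freq + gapfrac = 1", {
  set.seed(5)
  for (rep in 1:10) {
    chars <- sample(c("A", "C", "G", "U", "-", "R", "N"), 40, replace = TRUE)
    seqs <- apply(matrix(chars, 4, 10), 1, paste, collapse = "")
    for (w in c("none", "henikoff")) {
      a <- profile_alignment(seqs, weighting = w)
      expect_equal(colSums(a$col_freq) + a$col_gapfrac, rep(1, a$n_cols),
                   tolerance = 1e-9)
      expect_equal(sum(a$weights), a$n_seqs, tolerance = 1e-9)
    }
  }
})

test_that("wuss strings and layered pair sets round-trip", {
  s <- wuss_to_structure("<<...(..)..>>")
  expect_equal(nrow(s$pairs_by_layer[[1L]]), 3L)
  ## pseudoknot letters form their own layers
  s2 <- wuss_to_structure("<<..AA..>>..aa")
  expect_equal(length(s2$pairs_by_layer), 2L)
  expect_equal(s2$pairs_by_layer[[2L]],
               matrix(c(5L, 6L, 14L, 13L), 2, 2, dimnames = NULL))
  ## render and re-parse
  w <- structure_to_wuss(list(matrix(c(1L, 2L, 9L, 8L), 2, 2),
                              matrix(c(4L, 12L), 1, 2)), 14L)
  expect_equal(substr(w$wuss, 1, 2), "<<")
  expect_match(w$wuss, "A")
  back <- wuss_to_structure(w$wuss)
  expect_equal(back$pairs_by_layer[[1L]][order(back$pairs_by_layer[[1L]][, 1]), ],
               w$pairs_by_layer[[1L]])
  expect_error(wuss_to_structure("<<.>"), "unbalanced")
})

test_that("stockholm write/read round-trips structures and motif lines", {
  aln <- profile_alignment(c("GGAAACC", "GGAAACC"), weighting = "none")
  fake <- list(structure = structure_to_wuss(
                 list(matrix(c(1L, 2L, 7L, 6L), 2, 2)), 7L),
               motifs = data.frame(motif = "GNRA", variant = 1L, class = "HL",
                                   segments = "3..5", span_start = 3L,
                                   span_end = 5L, logprob = -1.5,
                                   support = TRUE))
  f <- tmpfile(".sto")
  write_stockholm(aln, fake, f)
  txt <- readLines(f)
  expect_true(any(grepl("SS_cons", txt)))
  expect_true(any(grepl("R3D", txt)))
  back <- read_stockholm(f, weighting = "none")
  expect_equal(back$seqs, aln$seqs)
  expect_equal(attr(back, "ss_cons")$pairs_by_layer[[1L]],
               matrix(c(1L, 2L, 7L, 6L), 2, 2))
  ## read -> write -> read is idempotent on pairs and sequences
  f2 <- tmpfile(".sto")
  write_stockholm(back, fake, f2)
  back2 <- read_stockholm(f2, weighting = "none")
  expect_equal(back2$seqs, back$seqs)
  expect_error(write_stockholm(aln, list(structure = structure_to_wuss(list(), 5L),
                                         motifs = fake$motifs), tmpfile()),
               "column count")
})

test_that("fasta input becomes a profile alignment", {
  f <- tmpfile(".fa")
  writeLines(c(">one desc", "ACG", "U", ">two", "ACGU"), f)
  a <- read_fasta(f, weighting = "none")
  expect_equal(a$n_seqs, 2L)
  expect_equal(a$seqs, c("ACGU", "ACGU"))
  expect_equal(a$seq_names, c("one", "two"))
  f1 <- tmpfile(".fa")
  writeLines(c(">solo", "GGGAAACCC"), f1)
  expect_equal(read_fasta(f1)$n_seqs, 1L)
})
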