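test_that("column shuffling preserves per-column residue composition", {
  set.seed(3)
  seqs <- c("ACG-U", "AC--U", "GGGAU", "UCGAU")
  aln <- profile_alignment(seqs, weighting = "none")
  shuf <- column_shuffle(aln, seed = 11, weighting = "none")
  orig <- covfold:::aln_chars(aln)
  perm <- covfold:::aln_chars(shuf)
  for (c in seq_len(aln$n_cols))
    expect_equal(sort(perm[, c]), sort(orig[, c]))
  ## profiles are therefore identical
  expect_equal(shuf$col_freq, aln$col_freq)
  expect_equal(shuf$col_gapfrac, aln$col_gapfrac)
  ## determinism and the single-sequence identity
  expect_identical(column_shuffle(aln, seed = 11, weighting = "none")$seqs,
                   shuf$seqs)
  one <- profile_alignment("ACGU")
  expect_identical(column_shuffle(one, seed = 4)$seqs, one$seqs)
})

test_that("planted helices covary at rate 1 and freeze at rate 0", {
  gp <- make_gnra_plant(seed = 7)
  cls <- classify_pairs(gp$aln, covariation_config(n_null_shuffles = 100,
                                                   seed = 7))
  pos <- cls[cls$label == "positive", ]
  expect_true(all(paste(8:11, 19:16) %in% paste(pos$i, pos$j)))

  ## rate 0: helix columns are identical in every sequence, zero positives
  gp0 <- generate_plant(plant_spec(length = 30, n_seqs = 12,
    helices = list(list(pairs = cbind(8:11, 19:16), rate = 0)),
    background_rate = 0, seed = 5))
  chars <- covfold:::aln_chars(gp0$aln)
  for (col in c(8:11, 16:19))
    expect_length(unique(chars[, col]), 1L)
  cls0 <- classify_pairs(gp0$aln, covariation_config(n_null_shuffles = 50,
                                                     seed = 5))
  expect_equal(sum(cls0$label == "positive"), 0L)
})

test_that("planted motif columns match their consensus in most sequences", {
  gp <- make_gnra_plant(seed = 21, n_seqs = 40L)
  chars <- covfold:::aln_chars(gp$aln)
  codes <- c("G", "N", "R", "A")
  ok <- vapply(seq_len(40L), function(s) {
    all(vapply(1:4, function(k)
      chars[s, 11L + k] %in% covfold:::IUPAC_SETS[[codes[k]]], TRUE))
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("planted truth is recoverable by the full pipeline", {
  ## rate-1 helices, no background noise: every planted pair is forced by
  ## covariation and realized, and the motif is placed at the planted loop
  spec <- plant_spec(length = 30, n_seqs = 16,
    helices = list(list(pairs = cbind(8:11, 19:16), rate = 1.0)),
    motifs = list(list(name = "GNRA", spans = list(c(12, 15)),
                       consensus = "GNRA")),
    background_rate = 0, motif_mutation = 0, seed = 3)
  gp <- generate_plant(spec)
  res <- fold_rna(gp$aln, motifs = motif_subset("GNRA"),
                  config = fold_config(cov = covariation_config(
                    n_null_shuffles = 100, seed = 3)))
  key <- paste(res$structure$pairs_by_layer[[1L]][, 1],
               res$structure$pairs_by_layer[[1L]][, 2])
  expect_true(all(paste(gp$truth$pairs[, 1], gp$truth$pairs[, 2]) %in% key))
  ev <- evaluate_motif_predictions(res, gp$truth$motifs)
  expect_equal(ev$sensitivity, 1)
})

test_that("planted elements may not overlap", {
  expect_error(plant_spec(length = 20, n_seqs = 4,
    helices = list(list(pairs = rbind(c(2, 10)), rate = 1)),
    motifs = list(list(name = "x", spans = list(c(10, 12)),
                       consensus = "NNN"))),
    "overlap")
  expect_error(plant_spec(length = 8, n_seqs = 4,
    helices = list(list(pairs = rbind(c(2, 10)), rate = 1))),
    "outside")
})
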