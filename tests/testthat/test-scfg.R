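toy_grammar <- function(p_pair = 0.5, p_unp = 0.3, p_end = 0.2) {
  ## tiny nested-pair grammar for hand-checkable engine tests
  new_grammar("toy", "S",
              c("S"),
              list(scfg_rule("S", p_pair, list(a_nt("S"), a_nt("S")),
                             pair_table = "ep"),
                   scfg_rule("S", p_unp, list(a_emit("eu"), a_nt("S"))),
                   scfg_rule("S", p_end, list())),
              emis_single = list(eu = stats::setNames(rep(0.25, 4), c("A","C","G","U"))),
              emis_pair = list(ep = matrix(1/16, 4, 4,
                dimnames = list(c("A","C","G","U"), c("A","C","G","U")))))
}

test_that("grammar validation reports deficits and undefined symbols", {
  g <- toy_grammar()
  expect_true(validate_grammar(g)$ok)
  bad <- toy_grammar(p_end = 0.1)  # sums to 0.9
  rep <- validate_grammar(bad)
  expect_false(rep$ok)
  expect_equal(unname(rep$deficits["S"]), 0.1, tolerance = 1e-12)
  undef <- new_grammar("u", "S", "S",
                       list(scfg_rule("S", 1, list(a_nt("T")))),
                       emis_single = list(), emis_pair = list())
  expect_match(paste(validate_grammar(undef)$messages, collapse = " "),
               "undefined nonterminal")
  ## parsing with an unnormalized grammar is refused
  expect_error(cyk(bad, profile_alignment("AC", weighting = "none")),
               "invalid grammar")
})

test_that("cyk and inside agree with exhaustive enumeration on a toy grammar", {
  g <- toy_grammar()
  seq <- "GCAUCAG"
  ps <- enumerate_parses(g, seq)
  lps <- vapply(ps, `[[`, 0, "logprob")
  aln <- profile_alignment(seq, weighting = "none")
  expect_equal(cyk(g, aln)$logprob, max(lps), tolerance = 1e-9)
  expect_equal(inside(g, aln), lse(lps), tolerance = 1e-9)
  expect_gte(inside(g, aln), cyk(g, aln)$logprob)
})

test_that("the empty sequence scores the epsilon derivation", {
  g <- build_rbgj3j4()
  aln <- profile_alignment("", weighting = "none")
  expect_equal(cyk(g, aln)$logprob, log(rbg_default_params()$S[["end"]]),
               tolerance = 1e-12)
  ## S -> a S | epsilon toy: exactly one parse of "AA"
  lin <- new_grammar("lin", "S", "S",
                     list(scfg_rule("S", 0.5, list(a_emit("eu"), a_nt("S"))),
                          scfg_rule("S", 0.5, list())),
                     emis_single = list(eu = stats::setNames(rep(0.25, 4),
                                                             c("A","C","G","U"))))
  expect_length(enumerate_parses(lin, "AA"), 1L)
  expect_length(enumerate_parses(lin, ""), 1L)
  expect_error(enumerate_parses(lin, strrep("A", 13)), "guard")
})

test_that("constraints force and forbid pairs in the traceback", {
  g <- build_rbgj3j4()
  set.seed(31)
  aln <- profile_alignment(replicate(6, rand_seq(24)), weighting = "none")
  forced <- rbind(c(3L, 20L), c(4L, 19L))
  res <- cyk(g, aln, fold_constraints(forced = forced))
  key <- paste(res$pairs[, 1], res$pairs[, 2])
  expect_true(all(paste(forced[, 1], forced[, 2]) %in% key))
  ## forbid a pair the unconstrained parse used
  free <- cyk(g, aln)
  stopifnot(nrow(free$pairs) > 0)
  ban <- free$pairs[1L, , drop = FALSE]
  res2 <- cyk(g, aln, fold_constraints(forbidden = ban))
  expect_false(paste(ban[1], ban[2]) %in%
               paste(res2$pairs[, 1], res2$pairs[, 2]))
  expect_lte(res2$logprob, free$logprob)
  ## forbidden columns stay unpaired
  res3 <- cyk(g, aln, fold_constraints(forbidden_columns = 1:12))
  if (nrow(res3$pairs)) expect_true(all(res3$pairs > 12))
  ## an unsatisfiable forced pair (adjacent columns: no room for a loop)
  expect_error(cyk(g, aln, fold_constraints(forced = rbind(c(5L, 6L)))),
               "no valid structure")
  ## malformed constraint sets
  expect_error(fold_constraints(forced = rbind(c(1, 10), c(5, 15))),
               "nested")
  expect_error(fold_constraints(forced = rbind(c(1, 10)),
                                forbidden = rbind(c(1, 10))), "overlap")
})

test_that("traceback is deterministic and consistent with the chart score", {
  g <- build_rbgj3j4()
  set.seed(12)
  aln <- profile_alignment(replicate(4, rand_seq(18)), weighting = "none")
  r1 <- cyk(g, aln)
  r2 <- cyk(g, aln)
  expect_identical(r1$pairs, r2$pairs)
  expect_identical(r1$rule_counts, r2$rule_counts)
  ## re-scoring the traced derivation reproduces the chart score: the parse
  ## under fully pinned constraints has the same probability
  allowed <- matrix(FALSE, aln$n_cols, aln$n_cols)
  if (nrow(r1$pairs)) allowed[r1$pairs] <- TRUE
  rc <- cyk(g, aln, fold_constraints(forced = r1$pairs, allowed = allowed))
  expect_equal(rc$logprob, r1$logprob, tolerance = 1e-9)
})

test_that("grammar serialization round-trips bit-identically", {
  g <- small_integrated_grammar()
  f <- tmpfile(".gram")
  write_grammar(g, f)
  g2 <- read_grammar(f)
  expect_identical(g$nonterminals, g2$nonterminals)
  expect_identical(vapply(g$rules, `[[`, 0, "prob"),
                   vapply(g2$rules, `[[`, 0, "prob"))
  expect_identical(g$emis_pair, g2$emis_pair)
  expect_identical(names(g$hmms), names(g2$hmms))
  expect_true(validate_grammar(g2)$ok)
  ## identical fold behaviour after the round trip
  aln <- profile_alignment(c("GGGACGAAGUCCCAU", "GGGACGAAGUCCCAU"),
                           weighting = "none")
  expect_equal(cyk(g2, aln)$logprob, cyk(g, aln)$logprob, tolerance = 1e-12)
  ## a second serialization is byte-identical
  f2 <- tmpfile(".gram")
  write_grammar(g2, f2)
  expect_identical(readLines(f), readLines(f2))
})
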