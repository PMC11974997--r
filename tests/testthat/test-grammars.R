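test_that("the base grammar has 12 nonterminals and validates", {
  g <- build_rbgj3j4()
  expect_equal(n_nonterminals(g), 12L)
  expect_true(validate_grammar(g)$ok)
  ## generic hairpin probability is the pinned trained value
  hl <- Filter(function(r) identical(r$role, "generic_HL"), g$rules)
  expect_equal(hl[[1L]]$prob, 0.3475)
})

test_that("a hairpin toy folds into the oracle's best stem-loop", {
  ## stem-favouring parameters; L = 8 single sequence
  p <- rbg_default_params()
  p$S <- c(helix = 0.90, unp = 0.05, end = 0.05)
  p$F0 <- c(stack = 0.95, loop = 0.05)
  p$F5 <- c(stack = 0.9, loop = 0.1)
  g <- build_rbgj3j4(p)
  seq <- "GGCAAAGC"
  ps <- enumerate_parses(g, seq)
  lps <- vapply(ps, `[[`, 0, "logprob")
  best <- ps[[which.max(lps)]]
  aln <- profile_alignment(seq, weighting = "none")
  res <- cyk(g, aln)
  expect_equal(res$logprob, max(lps), tolerance = 1e-9)
  expect_equal(res$pairs[order(res$pairs[, 1]), ],
               best$pairs[order(best$pairs[, 1]), ])
  ## it is a single stem-loop: pairs form one nested helix
  expect_gt(nrow(res$pairs), 1L)
  expect_false(covfold:::pairs_cross(res$pairs))
})

test_that("motif priors reproduce the published allocation arithmetic", {
  al <- allocate_motif_prior(0.3475, 0.4, 15)
  expect_equal(al$generic, 0.2085, tolerance = 1e-12)
  expect_equal(al$class_mass, 0.1390, tolerance = 1e-12)
  expect_equal(round(al$per_motif, 4), 0.0093)
})

test_that("motif integration conserves probability per loop class", {
  desc <- parse_descriptor_file(default_motif_file())
  models <- expand_all(desc)$models
  base <- build_rbgj3j4()
  gi <- integrate_r3d(base, models)
  expect_equal(n_nonterminals(gi), 12L + 96L)
  expect_true(validate_grammar(gi, tol = 1e-9)$ok)
  ## per attachment production: generic + motif alternatives = original
  sum_lhs <- function(g, lhs) {
    sum(vapply(Filter(function(r) r$lhs == lhs, g$rules), `[[`, 0, "prob"))
  }
  for (lhs in c("P", "BB"))
    expect_equal(sum_lhs(gi, lhs), sum_lhs(base, lhs), tolerance = 1e-9)
  ## HL class arithmetic with the shipped 15 hairpin motifs
  hl_generic <- Filter(function(r) identical(r$role, "generic_HL"), gi$rules)
  expect_equal(hl_generic[[1L]]$prob, 0.2085, tolerance = 1e-12)
})

test_that("a zero class fraction leaves that class untouched", {
  models <- expand_all(motif_subset(c("GNRA")))$models
  gi <- suppressWarnings(
    integrate_r3d(build_rbgj3j4(), models, motif_prior_config(HL = 0)))
  hl <- Filter(function(r) identical(r$role, "generic_HL"), gi$rules)
  expect_equal(hl[[1L]]$prob, 0.3475)
  expect_equal(n_nonterminals(gi), 12L)  # no variant nonterminals added
})

test_that("the pseudoknot-layer grammar validates and honours eligibility", {
  g6 <- build_g6x()
  expect_true(validate_grammar(g6)$ok)
  set.seed(8)
  aln <- profile_alignment(replicate(4, rand_seq(16)), weighting = "none")
  ## a single forced pair appears in the output
  allowed <- matrix(FALSE, 16, 16); allowed[3, 12] <- TRUE
  r <- cyk(g6, aln, fold_constraints(forced = rbind(c(3L, 12L)),
                                     allowed = allowed))
  expect_equal(r$pairs, rbind(c(3L, 12L)))
  ## a 3-pair helix is recovered when stacking neighbours are eligible
  helix <- cbind(4:6, 14:12)
  allowed2 <- matrix(FALSE, 16, 16)
  allowed2[helix] <- TRUE
  allowed2[3, 15] <- TRUE; allowed2[7, 11] <- TRUE  # stacking neighbours
  r2 <- cyk(g6, aln, fold_constraints(forced = helix, allowed = allowed2))
  expect_true(all(paste(helix[, 1], helix[, 2]) %in%
                  paste(r2$pairs[, 1], r2$pairs[, 2])))
})

test_that("counting training concentrates probabilities on observed rules", {
  ## three alignments, each a 3-bp helix closing a 4-nt hairpin loop
  mk <- function(seq) {
    f <- tmpfile(".sto")
    writeLines(c("# STOCKHOLM 1.0", paste("s1", seq), paste("s2", seq),
                 "#=GC SS_cons <<<....>>>", "//"), f)
    f
  }
  corpus <- lapply(c("GCGAAAACGC", "GGGUUCACCC", "CGGAGAACCG"), mk)
  tg <- train_by_counting(corpus)
  expect_true(validate_grammar(tg)$ok)
  rules <- tg$rules
  getp <- function(lhs, pick) {
    ids <- which(vapply(rules, `[[`, "", "lhs") == lhs)
    vapply(rules[ids], `[[`, 0, "prob")[pick]
  }
  ## hand counts: each derivation uses HL-extend 3x and HL-end 1x;
  ## with pseudocount 1: ext = (9+1)/(9+3+2) = 10/14, end = 4/14
  expect_equal(getp("HL", 1L), 10 / 14, tolerance = 1e-12)
  expect_equal(getp("HL", 2L), 4 / 14, tolerance = 1e-12)
  ## P -> HL used once per alignment: (3+1)/(3+7)
  expect_equal(getp("P", 1L), 4 / 10, tolerance = 1e-12)

  ## empty corpus: pure-pseudocount uniform parameters
  tu <- train_by_counting(list())
  ids <- which(vapply(tu$rules, `[[`, "", "lhs") == "P")
  expect_equal(vapply(tu$rules[ids], `[[`, 0, "prob"), rep(1 / 7, 7))

  ## single structure: counts equal that derivation's rule usage
  t1 <- train_by_counting(corpus[1])
  ids_hl <- which(vapply(t1$rules, `[[`, "", "lhs") == "HL")
  expect_equal(vapply(t1$rules[ids_hl], `[[`, 0, "prob"),
               c((3 + 1) / (4 + 2), (1 + 1) / (4 + 2)), tolerance = 1e-12)
})

test_that("sampled annotated strings have exactly one derivation", {
  gi <- small_integrated_grammar()
  set.seed(99)
  n_checked <- 0L
  while (n_checked < 12L) {
    s <- sample_derivation(gi, max_len = 9L)
    ps <- enumerate_parses(gi, s$seq, cap = 5e5)
    keys <- vapply(ps, function(d) ann_key(d$pairs, d$motifs), "")
    expect_equal(sum(keys == ann_key(s$pairs, s$motifs)), 1L,
                 info = paste("seq:", s$seq))
    n_checked <- n_checked + 1L
  }
})
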