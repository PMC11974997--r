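## The base folding grammar (explicit 3-way and 4-way junctions plus a
## generic >=5-way multiloop), the small nested-pair grammar used for
## pseudoknot layers, the motif-prior allocation that splices compiled motif
## models into the base grammar, and a counting trainer.
##
## Base grammar nonterminals (12):
##   S   start/transit: unpaired runs and helices at the top level
##   F0  first pair of a helix       F5  stacked pair (stacking context)
##   P   loop selector under a helix
##   HL  hairpin-loop run            BL  bulge / internal-loop strand run
##   J3  3-way junction interior     J4  4-way junction interior
##   MX  >=5-way multiloop interior  MT  multiloop branch recursion
##   BB  branch: optional unpaired run then a helix
##   BT  trailing branch: a branch then an optional unpaired run

pair_table <- function(x) {
  stopifnot(length(x) == 16L)
  m <- matrix(x, 4, 4, byrow = TRUE, dimnames = list(RNA_BASES, RNA_BASES))
  m
}

## 16-entry helper: named Watson-Crick-ish entries, remainder spread evenly.
wc_pair_table <- function(au, cg, gu, rest_total) {
  m <- matrix(rest_total / 10, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  m["A", "U"] <- au; m["U", "A"] <- au
  m["C", "G"] <- cg; m["G", "C"] <- cg
  m["G", "U"] <- gu; m["U", "G"] <- gu
  m
}

#' Default parameters of the base folding grammar
#'
#' Hand-curated defaults: Watson-Crick/wobble-favouring pair emissions with a
#' more concentrated table in stacking context, geometric loop-length rules,
#' and the generic hairpin-loop probability pinned at 0.3475.
#'
#' @return named list of rule-probability vectors and emission tables.
#' @export
rbg_default_params <- function() {
  list(
    S  = c(helix = 0.65, unp = 0.30, end = 0.05),
    F0 = c(stack = 0.85, loop = 0.15),
    F5 = c(stack = 0.82, loop = 0.18),
    P  = c(HL = 0.3475, BL_L = 0.10, BL_R = 0.10, IL = 0.33,
           J3 = 0.08, J4 = 0.03, MX = 0.0125),
    HL = c(ext = 0.75, end = 0.25),
    BL = c(ext = 0.60, end = 0.40),
    BB = c(unp = 0.30, helix = 0.70),
    BT = c(unp = 0.30, branch = 0.70),
    MT = c(more = 0.40, last = 0.60),
    e_unp = stats::setNames(c(0.30, 0.20, 0.22, 0.28), RNA_BASES),
    e_p0 = wc_pair_table(au = 0.16, cg = 0.22, gu = 0.09, rest_total = 0.06),
    e_p5 = wc_pair_table(au = 0.17, cg = 0.25, gu = 0.055, rest_total = 0.05)
  )
}

#' Build the base folding grammar
#'
#' Twelve nonterminals: start/transit, helix start and stacked-pair states
#' (pair emission with stacking context), hairpin-loop and bulge runs, the
#' loop selector, explicit 3-way and 4-way junctions, a generic >=5-way
#' multiloop via branch recursion, and branch/trailing-branch states. The
#' grammar is unambiguous: a given arrangement of base pairs (and motifs,
#' once integrated) is generated exactly one way.
#'
#' @param params parameter list as from [rbg_default_params()].
#' @return a validated `Grammar`.
#' @export
build_rbgj3j4 <- function(params = rbg_default_params()) {
  p <- params
  rules <- list(
    scfg_rule("S", p$S[["helix"]], list(a_nt("F0"), a_nt("S"))),
    scfg_rule("S", p$S[["unp"]], list(a_emit("e_unp"), a_nt("S"))),
    scfg_rule("S", p$S[["end"]], list()),
    scfg_rule("F0", p$F0[["stack"]], list(a_nt("F5")), pair_table = "e_p0"),
    scfg_rule("F0", p$F0[["loop"]], list(a_nt("P")), pair_table = "e_p0"),
    scfg_rule("F5", p$F5[["stack"]], list(a_nt("F5")), pair_table = "e_p5"),
    scfg_rule("F5", p$F5[["loop"]], list(a_nt("P")), pair_table = "e_p5"),
    scfg_rule("P", p$P[["HL"]], list(a_nt("HL")), role = "generic_HL"),
    scfg_rule("P", p$P[["BL_L"]], list(a_nt("BL"), a_nt("F0")),
              role = "generic_BL_left"),
    scfg_rule("P", p$P[["BL_R"]], list(a_nt("F0"), a_nt("BL")),
              role = "generic_BL_right"),
    scfg_rule("P", p$P[["IL"]], list(a_nt("BL"), a_nt("F0"), a_nt("BL")),
              role = "generic_IL"),
    scfg_rule("P", p$P[["J3"]], list(a_nt("J3")), role = "generic_J3"),
    scfg_rule("P", p$P[["J4"]], list(a_nt("J4")), role = "generic_J4"),
    scfg_rule("P", p$P[["MX"]], list(a_nt("MX"))),
    scfg_rule("HL", p$HL[["ext"]], list(a_emit("e_unp"), a_nt("HL"))),
    scfg_rule("HL", p$HL[["end"]], list(a_emit("e_unp"))),
    scfg_rule("BL", p$BL[["ext"]], list(a_emit("e_unp"), a_nt("BL"))),
    scfg_rule("BL", p$BL[["end"]], list(a_emit("e_unp"))),
    scfg_rule("J3", 1, list(a_nt("BB"), a_nt("BT"))),
    scfg_rule("J4", 1, list(a_nt("BB"), a_nt("BB"), a_nt("BT"))),
    scfg_rule("MX", 1, list(a_nt("BB"), a_nt("BB"), a_nt("BB"), a_nt("MT"))),
    scfg_rule("MT", p$MT[["more"]], list(a_nt("BB"), a_nt("MT"))),
    scfg_rule("MT", p$MT[["last"]], list(a_nt("BT"))),
    scfg_rule("BB", p$BB[["unp"]], list(a_emit("e_unp"), a_nt("BB")),
              role = "generic_BS"),
    scfg_rule("BB", p$BB[["helix"]], list(a_nt("F0"))),
    scfg_rule("BT", p$BT[["unp"]], list(a_nt("BT"), a_emit("e_unp"))),
    scfg_rule("BT", p$BT[["branch"]], list(a_nt("BB")))
  )
  g <- new_grammar("RBGJ3J4", "S",
                   c("S", "F0", "F5", "P", "HL", "BL", "J3", "J4", "MX",
                     "MT", "BB", "BT"),
                   rules,
                   emis_single = list(e_unp = p$e_unp),
                   emis_pair = list(e_p0 = p$e_p0, e_p5 = p$e_p5))
  stopifnot(n_nonterminals(g) == 12L)
  rep <- validate_grammar(g)
  if (!rep$ok) stop(paste(rep$messages, collapse = "; "))
  g
}

#' Motif-prior class fractions
#'
#' Fraction of each loop class's generic probability that is reallocated to
#' the motif models of that class.
#'
#' @param HL,BL,IL,J3,J4,BS per-class fractions in `[0, 1]`.
#' @return named list of class `MotifPriorConfig`.
#' @export
motif_prior_config <- function(HL = 0.4, BL = 0.4, IL = 0.5,
                               J3 = 0.2, J4 = 0.2, BS = 0.2) {
  f <- c(HL = HL, BL = BL, IL = IL, J3 = J3, J4 = J4, BS = BS)
  stopifnot(all(f >= 0 & f <= 1))
  structure(list(class_fractions = f), class = "MotifPriorConfig")
}

#' Allocate a generic-loop probability between the generic rule and motifs
#'
#' With generic-loop probability `p_generic` and class fraction `fraction`,
#' the generic production keeps `p_generic * (1 - fraction)`, the motif class
#' as a whole receives `p_generic * fraction`, and each of the `n_motifs`
#' motif models gets an equal share (maximum-entropy allocation).
#'
#' @param p_generic trained probability of the generic loop production.
#' @param fraction class fraction reallocated to motifs.
#' @param n_motifs number of motif models in the class.
#' @return list with `generic`, `class_mass`, `per_motif`.
#' @export
allocate_motif_prior <- function(p_generic, fraction, n_motifs) {
  stopifnot(p_generic >= 0, fraction >= 0, fraction <= 1, n_motifs >= 1)
  list(generic = p_generic * (1 - fraction),
       class_mass = p_generic * fraction,
       per_motif = p_generic * fraction / n_motifs)
}

ATTACH_ROLE <- c(HL = "generic_HL", BL_L = "generic_BL_left",
                 BL_R = "generic_BL_right", IL = "generic_IL",
                 J3 = "generic_J3", J4 = "generic_J4", BS = "generic_BS")

#' Integrate compiled motif models into the base grammar
#'
#' For each loop class with generic production probability `p_c` and class
#' fraction `f_c`, the generic production keeps `p_c * (1 - f_c)` and each of
#' the class's `n_c` variant models is added as an alternative production
#' with probability `p_c * f_c / n_c` (for bulge motifs the allocation is
#' applied per bulge side). Probability is conserved per production, so the
#' result validates. One new nonterminal is added per variant model.
#'
#' @param base grammar from [build_rbgj3j4()].
#' @param motifs list of `MotifModel`s (from [expand_all()]`$models`).
#' @param cfg a [motif_prior_config()].
#' @return the integrated `Grammar` with `12 + total variants` nonterminals.
#' @export
integrate_r3d <- function(base, motifs, cfg = motif_prior_config()) {
  g <- base
  g$name <- paste0(base$name, "-R3D")
  ## group variants by attachment role
  groups <- list()
  for (m in motifs) {
    g$hmms <- c(g$hmms, m$hmms)
    for (v in m$variants) {
      v$class <- m$class; v$name <- m$name
      groups[[v$attach]] <- c(groups[[v$attach]], list(v))
    }
  }
  rule_role <- vapply(g$rules, function(r) if (is.null(r$role)) "" else r$role, "")
  new_nts <- character(0)
  new_rules <- list()
  for (attach in names(ATTACH_ROLE)) {
    vars <- groups[[attach]]
    cls <- sub("_[LR]$", "", attach)
    f <- cfg$class_fractions[[cls]]
    if (is.null(vars) || !length(vars)) {
      if (f > 0 && length(motifs) && attach != "BL_R")
        warning(sprintf(
          "no motif models in class %s; fraction returned to the generic rule",
          cls))
      next
    }
    if (f == 0) next   # class fraction 0: grammar unchanged for this class
    rid <- which(rule_role == ATTACH_ROLE[[attach]])
    stopifnot(length(rid) == 1L)
    p <- g$rules[[rid]]$prob
    alloc <- allocate_motif_prior(p, f, length(vars))
    g$rules[[rid]]$prob <- alloc$generic
    g$rules[[rid]]$logprob <- log(alloc$generic)
    for (v in vars) {
      new_nts <- c(new_nts, v$nt)
      attach_atoms <- switch(attach,
        HL = , IL = , J3 = , J4 = list(a_nt(v$nt)),
        BL_L = list(a_nt(v$nt), a_nt("F0")),
        BL_R = list(a_nt("F0"), a_nt(v$nt)),
        BS = list(a_nt(v$nt), a_nt("F0")))
      new_rules <- c(new_rules,
        list(scfg_rule(g$rules[[rid]]$lhs, alloc$per_motif, attach_atoms),
             scfg_rule(v$nt, 1, v$atoms,
                       motif = list(name = v$name, variant = v$variant,
                                    class = v$class,
                                    seg_roles = v$seg_roles))))
    }
  }
  g <- new_grammar(g$name, g$start, c(g$nonterminals, new_nts),
                   c(g$rules, new_rules), g$emis_single, g$emis_pair, g$hmms)
  rep <- validate_grammar(g)
  if (!rep$ok) stop(paste(rep$messages, collapse = "; "))
  g
}

#' Default parameters of the pseudoknot-layer grammar
#' @return named list of rule probabilities and emission tables.
#' @export
g6x_default_params <- function() {
  list(S = c(comp = 0.88, end = 0.12),
       L = c(pair = 0.45, unp = 0.55),
       F = c(pair = 0.78, bifurc = 0.22),
       e_unp = stats::setNames(rep(0.25, 4), RNA_BASES),
       e_pair = wc_pair_table(au = 0.16, cg = 0.22, gu = 0.09,
                              rest_total = 0.06))
}

#' Build the pseudoknot-layer grammar
#'
#' A small nested-pair grammar (a classic unambiguous 6-rule design extended
#' with a distinct unpaired-emission nonterminal) used for folding layers
#' beyond the first. In those layers only the layer's covarying pairs and
#' their immediate stacking neighbours are pair-eligible.
#'
#' @param params parameter list as from [g6x_default_params()].
#' @return a validated `Grammar`.
#' @export
build_g6x <- function(params = g6x_default_params()) {
  p <- params
  rules <- list(
    scfg_rule("S", p$S[["comp"]], list(a_nt("L"), a_nt("S"))),
    scfg_rule("S", p$S[["end"]], list()),
    scfg_rule("L", p$L[["pair"]], list(a_nt("F")), pair_table = "e_pair"),
    scfg_rule("L", p$L[["unp"]], list(a_nt("U"))),
    scfg_rule("F", p$F[["pair"]], list(a_nt("F")), pair_table = "e_pair"),
    scfg_rule("F", p$F[["bifurc"]], list(a_nt("L"), a_nt("S"))),
    scfg_rule("U", 1, list(a_emit("e_unp")))
  )
  g <- new_grammar("G6X", "S", c("S", "L", "F", "U"), rules,
                   emis_single = list(e_unp = p$e_unp),
                   emis_pair = list(e_pair = p$e_pair))
  rep <- validate_grammar(g)
  if (!rep$ok) stop(paste(rep$messages, collapse = "; "))
  g
}

#' Counting trainer on structure-annotated alignments
#'
#' Maximum-likelihood rule probabilities from structure-constrained parses:
#' each alignment's consensus structure fixes a unique derivation under the
#' (unambiguous) grammar; rule usage and emission events are counted across
#' alignments, Laplace-smoothed (pseudocount 1 per rule and per emission
#' cell) and normalized. Alignments whose structure is not derivable are
#' skipped with a warning.
#'
#' @param alignments list of `ProfileAlignment`s carrying an `ss_cons`
#'   attribute (as returned by [read_stockholm()]), or paths to such files.
#' @param grammar the grammar to train; defaults to [build_rbgj3j4()].
#' @param pseudocount Laplace pseudocount.
#' @return the grammar with retrained rule probabilities and emission tables.
#' @export
train_by_counting <- function(alignments, grammar = build_rbgj3j4(),
                              pseudocount = 1) {
  counts <- rep(pseudocount, length(grammar$rules))
  sc <- lapply(grammar$emis_single, function(x) rep(pseudocount, 4))
  pc <- lapply(grammar$emis_pair, function(x) matrix(pseudocount, 4, 4))
  for (item in alignments) {
    aln <- if (is.character(item)) read_stockholm(item) else item
    ss <- attr(aln, "ss_cons")
    if (is.null(ss)) {
      warning("alignment without SS_cons skipped")
      next
    }
    pairs <- if (length(ss$pairs_by_layer)) ss$pairs_by_layer[[1L]]
             else matrix(integer(0), 0, 2)
    allowed <- matrix(FALSE, aln$n_cols, aln$n_cols)
    if (nrow(pairs)) allowed[pairs] <- TRUE
    res <- tryCatch(
      cyk(grammar, aln, fold_constraints(forced = pairs, allowed = allowed)),
      error = function(e) NULL)
    if (is.null(res)) {
      warning("structure not derivable under the grammar; alignment skipped")
      next
    }
    counts <- counts + res$rule_counts
    fnorm <- norm_col_freq(aln)
    for (ev in res$emissions$single)
      sc[[ev$table]] <- sc[[ev$table]] + fnorm[, ev$col]
    for (ev in res$emissions$pair)
      pc[[ev$table]] <- pc[[ev$table]] + outer(fnorm[, ev$i], fnorm[, ev$j])
  }
  lhs <- vapply(grammar$rules, `[[`, "", "lhs")
  for (nt in grammar$nonterminals) {
    ids <- which(lhs == nt)
    tot <- sum(counts[ids])
    for (k in ids) {
      grammar$rules[[k]]$prob <- counts[k] / tot
      grammar$rules[[k]]$logprob <- log(counts[k] / tot)
    }
  }
  for (t in names(sc))
    grammar$emis_single[[t]] <- stats::setNames(sc[[t]] / sum(sc[[t]]), RNA_BASES)
  for (t in names(pc)) {
    m <- pc[[t]] / sum(pc[[t]])
    dimnames(m) <- list(RNA_BASES, RNA_BASES)
    grammar$emis_pair[[t]] <- m
  }
  ## refresh the rules_of cache (probabilities changed in place)
  new_grammar(grammar$name, grammar$start, grammar$nonterminals,
              grammar$rules, grammar$emis_single, grammar$emis_pair,
              grammar$hmms)
}
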