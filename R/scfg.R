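## Probabilistic grammar machinery: representation, validation, compilation
## into the score tables consumed by the C++ CYK/inside engine, and a
## versionable text serialization.
##
## A rule rewrites its left-hand nonterminal into a sequence of atoms:
##   emit  - one alignment column, scored with a single-residue table
##   nt    - a nonterminal
##   hmm   - a segment profile HMM absorbing a (possibly empty) column span
## A rule may additionally be pair-wrapped: it emits the outermost columns
## (i, j) of its span as a base pair scored with a 16-entry pair table, and
## the atoms derive the inner span. Column emissions are expected
## log-probabilities under the column's residue distribution, so the grammars
## parse probabilistic sequences (alignment column profiles) directly.

a_emit <- function(table) list(type = "emit", ref = table)
a_nt   <- function(ref)   list(type = "nt", ref = ref)
a_hmm  <- function(ref)   list(type = "hmm", ref = ref)

scfg_rule <- function(lhs, prob, atoms = list(), pair_table = NULL,
                      role = NULL, motif = NULL) {
  list(lhs = lhs, prob = prob, logprob = log(prob), atoms = atoms,
       pair_table = pair_table, role = role, motif = motif)
}

#' Construct a probabilistic grammar
#'
#' @param name grammar name.
#' @param start start nonterminal.
#' @param nonterminals character vector of nonterminal symbols.
#' @param rules list of rules (internal constructor `scfg_rule`).
#' @param emis_single named list of length-4 residue distributions (A,C,G,U).
#' @param emis_pair named list of 4x4 pair distributions (rows 5' residue).
#' @param hmms named list of `ProfileHMM` objects referenced by hmm atoms.
#' @return object of class `Grammar`.
#' @export
new_grammar <- function(name, start, nonterminals, rules,
                        emis_single = list(), emis_pair = list(),
                        hmms = list()) {
  g <- structure(list(name = name, start = start,
                      nonterminals = nonterminals, rules = rules,
                      emis_single = emis_single, emis_pair = emis_pair,
                      hmms = hmms),
                 class = "Grammar")
  g$rules_of <- split(seq_along(rules),
                      factor(vapply(rules, `[[`, "", "lhs"),
                             levels = nonterminals))
  g
}

#' @export
print.Grammar <- function(x, ...) {
  cat(sprintf("Grammar '%s': %d nonterminals, %d rules, %d segment HMMs\n",
              x$name, length(x$nonterminals), length(x$rules),
              length(x$hmms)))
  invisible(x)
}

#' Number of nonterminals in a grammar
#' @param g a `Grammar`.
#' @return integer count.
#' @export
n_nonterminals <- function(g) length(g$nonterminals)

#' Validate a grammar
#'
#' Checks per-nonterminal rule-probability normalization, that every
#' referenced nonterminal / emission table / segment HMM exists, that every
#' nonterminal has at least one rule, and that all nonterminals are reachable
#' from the start symbol.
#'
#' @param g a `Grammar`.
#' @param tol normalization tolerance (default 1e-9).
#' @return list with `ok` (logical), `messages` (character) and `deficits`
#'   (named numeric, 1 - sum of rule probabilities per nonterminal).
#' @export
validate_grammar <- function(g, tol = 1e-9) {
  msgs <- character(0)
  deficits <- stats::setNames(rep(0, length(g$nonterminals)), g$nonterminals)
  for (nt in g$nonterminals) {
    ids <- g$rules_of[[nt]]
    if (!length(ids)) {
      msgs <- c(msgs, sprintf("nonterminal '%s' has no rules (dead symbol)", nt))
      deficits[nt] <- 1
      next
    }
    s <- sum(vapply(g$rules[ids], `[[`, 0, "prob"))
    deficits[nt] <- 1 - s
    if (abs(1 - s) > tol)
      msgs <- c(msgs, sprintf("nonterminal '%s' rules sum to %.12f (deficit %.3g)",
                              nt, s, 1 - s))
  }
  for (r in g$rules) {
    if (!(r$lhs %in% g$nonterminals))
      msgs <- c(msgs, sprintf("rule lhs '%s' is not a declared nonterminal", r$lhs))
    if (!is.null(r$pair_table) && !(r$pair_table %in% names(g$emis_pair)))
      msgs <- c(msgs, sprintf("unknown pair table '%s'", r$pair_table))
    for (a in r$atoms) {
      bad <- switch(a$type,
        nt   = if (!(a$ref %in% g$nonterminals))
                 sprintf("rule for '%s' references undefined nonterminal '%s'",
                         r$lhs, a$ref),
        emit = if (!(a$ref %in% names(g$emis_single)))
                 sprintf("unknown single-emission table '%s'", a$ref),
        hmm  = if (!(a$ref %in% names(g$hmms)))
                 sprintf("unknown segment HMM '%s'", a$ref),
        sprintf("unknown atom type '%s'", a$type))
      if (!is.null(bad)) msgs <- c(msgs, bad)
    }
  }
  if (!length(msgs)) {
    reach <- grammar_reachable(g)
    un <- setdiff(g$nonterminals, reach)
    if (length(un))
      msgs <- c(msgs, sprintf("unreachable nonterminals: %s",
                              paste(un, collapse = ", ")))
  }
  list(ok = !length(msgs), messages = msgs, deficits = deficits)
}

grammar_reachable <- function(g) {
  seen <- g$start
  frontier <- g$start
  while (length(frontier)) {
    nxt <- character(0)
    for (nt in frontier) {
      for (id in g$rules_of[[nt]]) {
        for (a in g$rules[[id]]$atoms)
          if (a$type == "nt" && !(a$ref %in% seen)) nxt <- c(nxt, a$ref)
      }
    }
    nxt <- unique(nxt)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

## Nonterminals that can derive the empty span. HMM atoms are treated as
## nullable (an empty span has finite forward probability whenever delta > 0
## or the consensus is empty); emit atoms never are. Fixed point iteration.
grammar_nullable <- function(g) {
  nullable <- stats::setNames(rep(FALSE, length(g$nonterminals)), g$nonterminals)
  repeat {
    changed <- FALSE
    for (r in g$rules) {
      if (!is.null(r$pair_table) || nullable[r$lhs]) next
      ok <- all(vapply(r$atoms, function(a) {
        switch(a$type, emit = FALSE, hmm = TRUE, nt = nullable[[a$ref]])
      }, TRUE))
      if (ok) { nullable[r$lhs] <- TRUE; changed <- TRUE }
    }
    if (!changed) break
  }
  nullable
}

## Topological order of nonterminals under same-span dependencies: X depends
## on Y when a non-pair-wrapped rule of X has an nt atom Y whose sibling
## atoms can all be empty, so Y can cover X's whole span. Errors on cycles.
grammar_topo_order <- function(g) {
  nullable <- grammar_nullable(g)
  nts <- g$nonterminals
  deps <- stats::setNames(vector("list", length(nts)), nts)
  for (r in g$rules) {
    if (!is.null(r$pair_table)) next
    types <- vapply(r$atoms, `[[`, "", "type")
    can_empty <- vapply(r$atoms, function(a)
      switch(a$type, emit = FALSE, hmm = TRUE, nt = nullable[[a$ref]]), TRUE)
    for (k in seq_along(r$atoms)) {
      if (types[k] != "nt") next
      if (all(can_empty[-k]))
        deps[[r$lhs]] <- union(deps[[r$lhs]], r$atoms[[k]]$ref)
    }
  }
  order <- character(0)
  mark <- stats::setNames(rep(0L, length(nts)), nts)  # 0 new, 1 visiting, 2 done
  visit <- function(nt) {
    if (mark[[nt]] == 2L) return(invisible())
    if (mark[[nt]] == 1L)
      stop(sprintf("grammar has a same-span dependency cycle through '%s'", nt))
    mark[nt] <<- 1L
    for (d in deps[[nt]]) visit(d)
    mark[nt] <<- 2L
    order <<- c(order, nt)
  }
  for (nt in nts) visit(nt)
  order
}

## ---------------------------------------------------------------------------
## Constraints

#' Pairing constraints for a constrained parse
#'
#' @param forced two-column matrix of pairs that must form (mutually
#'   nested, each column at most once).
#' @param forbidden two-column matrix of pairs that may not form.
#' @param forbidden_columns columns that must stay unpaired.
#' @param allowed optional L x L logical matrix; when given, only `TRUE`
#'   entries are pair-eligible (forbidden entries are still removed).
#' @return object of class `Constraints`.
#' @export
fold_constraints <- function(forced = NULL, forbidden = NULL,
                             forbidden_columns = integer(0),
                             allowed = NULL) {
  forced <- as_pair_matrix(forced)
  forbidden <- as_pair_matrix(forbidden)
  if (nrow(forced)) {
    if (any(forced[, 1L] >= forced[, 2L])) stop("forced pairs must have i < j")
    cols <- c(forced[, 1L], forced[, 2L])
    if (anyDuplicated(cols)) stop("a column appears in two forced pairs")
    if (pairs_cross(forced)) stop("forced pairs must be mutually nested")
    key_forced <- paste(forced[, 1L], forced[, 2L])
    key_forb <- paste(forbidden[, 1L], forbidden[, 2L])
    if (length(intersect(key_forced, key_forb)))
      stop("forced and forbidden pair sets overlap")
    if (any(cols %in% forbidden_columns))
      stop("a forced pair uses a forbidden column")
  }
  structure(list(forced = forced, forbidden = forbidden,
                 forbidden_columns = as.integer(forbidden_columns),
                 allowed = allowed),
            class = "Constraints")
}

## TRUE when any two pairs cross.
pairs_cross <- function(pairs) {
  n <- nrow(pairs)
  if (n < 2L) return(FALSE)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    i <- pairs[a, 1L]; j <- pairs[a, 2L]
    k <- pairs[b, 1L]; l <- pairs[b, 2L]
    if (i > k) { tmp <- i; i <- k; k <- tmp; tmp <- j; j <- l; l <- tmp }
    if (k < j && j < l) return(TRUE)
  }
  FALSE
}

## Resolve constraints to (mustpair partner vector, allowed matrix).
compile_constraints <- function(cons, L) {
  partner <- integer(L)
  allowed <- if (!is.null(cons$allowed)) cons$allowed else matrix(TRUE, L, L)
  if (L > 0L) {
    allowed[lower.tri(allowed, diag = TRUE)] <- FALSE
    if (nrow(cons$forbidden))
      allowed[cons$forbidden] <- FALSE
    if (length(cons$forbidden_columns)) {
      allowed[cons$forbidden_columns, ] <- FALSE
      allowed[, cons$forbidden_columns] <- FALSE
    }
    if (nrow(cons$forced)) {
      for (r in seq_len(nrow(cons$forced))) {
        i <- cons$forced[r, 1L]; j <- cons$forced[r, 2L]
        partner[i] <- j; partner[j] <- i
      }
      constrained <- which(partner > 0L)
      allowed[constrained, ] <- FALSE
      allowed[, constrained] <- FALSE
      allowed[cons$forced] <- TRUE
    }
  }
  list(partner = partner, mustpair = partner > 0L, allowed = allowed)
}

## ---------------------------------------------------------------------------
## Engine compilation: numeric tables for the C++ CYK/inside kernel

ATOM_EMIT <- 1L; ATOM_NT <- 2L; ATOM_HMM <- 3L

compile_engine <- function(g, aln, cons = fold_constraints()) {
  L <- aln$n_cols
  cc <- compile_constraints(cons, L)
  fnorm <- norm_col_freq(aln)
  ## single-emission scores, masked where a column is forced to pair
  st_names <- names(g$emis_single)
  single <- matrix(-Inf, max(length(st_names), 1L), max(L, 1L))
  for (t in seq_along(st_names)) {
    if (L > 0L)
      single[t, ] <- as.numeric(log(g$emis_single[[t]]) %*% fnorm)
  }
  if (L > 0L && any(cc$mustpair)) single[, cc$mustpair] <- -Inf
  ## pair scores with the eligibility mask applied
  pt_names <- names(g$emis_pair)
  pair_mats <- lapply(pt_names, function(t) {
    if (L == 0L) return(matrix(-Inf, 1, 1))
    m <- t(fnorm) %*% log(g$emis_pair[[t]]) %*% fnorm
    m[!cc$allowed] <- -Inf
    m
  })
  ## segment-HMM span scores
  hmm_names <- names(g$hmms)
  hmm_mats <- lapply(hmm_names, function(h) {
    sc <- hmm_column_scores(g$hmms[[h]], fnorm,
                            mask = if (L > 0L) cc$mustpair else NULL)
    hmm_span_scores(g$hmms[[h]], sc, L)
  })
  ## flattened rules
  nt_id <- stats::setNames(seq_along(g$nonterminals), g$nonterminals)
  nr <- length(g$rules)
  max_atoms <- max(c(1L, vapply(g$rules, function(r) length(r$atoms), 1L)))
  atom_type <- matrix(0L, max_atoms, nr)
  atom_ref <- matrix(0L, max_atoms, nr)
  rule_lhs <- integer(nr); rule_pt <- integer(nr); rule_na <- integer(nr)
  rule_lp <- numeric(nr)
  for (k in seq_len(nr)) {
    r <- g$rules[[k]]
    rule_lhs[k] <- nt_id[[r$lhs]]
    rule_pt[k] <- if (is.null(r$pair_table)) 0L else match(r$pair_table, pt_names)
    rule_na[k] <- length(r$atoms)
    rule_lp[k] <- r$logprob
    for (a in seq_along(r$atoms)) {
      at <- r$atoms[[a]]
      atom_type[a, k] <- switch(at$type, emit = ATOM_EMIT, nt = ATOM_NT,
                                hmm = ATOM_HMM)
      atom_ref[a, k] <- switch(at$type,
                               emit = match(at$ref, st_names),
                               nt = nt_id[[at$ref]],
                               hmm = match(at$ref, hmm_names))
    }
  }
  topo <- match(grammar_topo_order(g), g$nonterminals)
  list(L = L, n_nt = length(g$nonterminals), nt_id = nt_id,
       rule_lhs = rule_lhs, rule_pt = rule_pt, rule_na = rule_na,
       rule_lp = rule_lp, atom_type = atom_type, atom_ref = atom_ref,
       topo = topo, single = single, pair_mats = pair_mats,
       hmm_mats = hmm_mats, constraints = cc, grammar = g)
}

## ---------------------------------------------------------------------------
## Text serialization

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a grammar to its text serialization
#'
#' Nonterminal, emission, segment-HMM and rule lines in a line-oriented
#' format that round-trips losslessly (probabilities printed with 17
#' significant digits).
#'
#' @param g a `Grammar`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grammar <- function(g, path) {
  out <- c(sprintf("grammar %s", g$name),
           sprintf("start %s", g$start),
           sprintf("nonterminals %s", paste(g$nonterminals, collapse = " ")))
  for (t in names(g$emis_single))
    out <- c(out, sprintf("esingle %s %s", t,
                          paste(fmt_num(g$emis_single[[t]]), collapse = " ")))
  for (t in names(g$emis_pair))
    out <- c(out, sprintf("epair %s %s", t,
                          paste(fmt_num(as.numeric(t(g$emis_pair[[t]]))),
                                collapse = " ")))
  for (h in names(g$hmms)) {
    hm <- g$hmms[[h]]
    cons <- if (nzchar(hm$consensus)) hm$consensus else "-"
    out <- c(out, sprintf("hmm %s %s %s %s", h, cons, fmt_num(hm$delta),
                          fmt_num(hm$off_consensus)))
  }
  for (r in g$rules) {
    parts <- c("rule", r$lhs, fmt_num(r$prob))
    if (!is.null(r$pair_table)) parts <- c(parts, sprintf("pair=%s", r$pair_table))
    if (!is.null(r$role)) parts <- c(parts, sprintf("role=%s", r$role))
    if (!is.null(r$motif))
      parts <- c(parts, sprintf("motif=%s|%d|%s|%s", r$motif$name,
                                r$motif$variant, r$motif$class,
                                paste(r$motif$seg_roles, collapse = ",")))
    atoms <- vapply(r$atoms, function(a) {
      prefix <- switch(a$type, emit = "e", nt = "n", hmm = "h")
      paste0(prefix, ":", a$ref)
    }, "")
    out <- c(out, paste(c(parts, ":", atoms), collapse = " "))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a grammar from its text serialization
#'
#' @param path file path written by [write_grammar()].
#' @return a `Grammar`.
#' @export
read_grammar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  name <- NULL; start <- NULL; nts <- character(0)
  es <- list(); ep <- list(); hmms <- list(); rules <- list()
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    kw <- f[1L]
    if (kw == "grammar") name <- f[2L]
    else if (kw == "start") start <- f[2L]
    else if (kw == "nonterminals") nts <- f[-1L]
    else if (kw == "esingle") {
      es[[f[2L]]] <- stats::setNames(as.numeric(f[3:6]), RNA_BASES)
    } else if (kw == "epair") {
      ep[[f[2L]]] <- matrix(as.numeric(f[3:18]), 4, 4, byrow = TRUE,
                            dimnames = list(RNA_BASES, RNA_BASES))
    } else if (kw == "hmm") {
      cons <- if (f[3L] == "-") "" else f[3L]
      hmms[[f[2L]]] <- build_segment_hmm(cons, delta = as.numeric(f[4L]),
                                         off_consensus = as.numeric(f[5L]))
    } else if (kw == "rule") {
      sep <- match(":", f)
      hdr <- f[seq_len(sep - 1L)]; atom_toks <- if (sep < length(f)) f[(sep + 1L):length(f)] else character(0)
      lhs <- hdr[2L]; prob <- as.numeric(hdr[3L])
      pair_table <- NULL; role <- NULL; motif <- NULL
      for (tok in hdr[-(1:3)]) {
        if (startsWith(tok, "pair=")) pair_table <- sub("^pair=", "", tok)
        else if (startsWith(tok, "role=")) role <- sub("^role=", "", tok)
        else if (startsWith(tok, "motif=")) {
          mf <- strsplit(sub("^motif=", "", tok), "|", fixed = TRUE)[[1L]]
          motif <- list(name = mf[1L], variant = as.integer(mf[2L]),
                        class = mf[3L],
                        seg_roles = strsplit(mf[4L], ",", fixed = TRUE)[[1L]])
        }
      }
      atoms <- lapply(atom_toks, function(tok) {
        tp <- substr(tok, 1L, 1L); ref <- substr(tok, 3L, nchar(tok))
        switch(tp, e = a_emit(ref), n = a_nt(ref), h = a_hmm(ref),
               stop(sprintf("bad atom token '%s'", tok)))
      })
      rules[[length(rules) + 1L]] <-
        scfg_rule(lhs, prob, atoms, pair_table = pair_table, role = role,
                  motif = motif)
    } else stop(sprintf("unknown grammar-file keyword '%s'", kw))
  }
  new_grammar(name, start, nts, rules, es, ep, hmms)
}
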