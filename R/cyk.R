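## CYK maximum-probability parsing and inside summation over column
## profiles, with deterministic traceback (first rule in declaration order,
## then smallest split point), plus a brute-force derivation enumerator used
## as a test oracle and a generative sampler.

v_get <- function(V, nt, i, j) V[j + 1L, i, nt]

run_engine <- function(g, aln, cons = fold_constraints(), mode = 0L) {
  rep <- validate_grammar(g)
  if (!rep$ok)
    stop(paste(c("refusing to parse with an invalid grammar:", rep$messages),
               collapse = "\n  "))
  eng <- compile_engine(g, aln, cons)
  v <- .cyk_fill(eng$n_nt, eng$L, eng$rule_lhs, eng$rule_pt, eng$rule_na,
                 eng$rule_lp, eng$atom_type, eng$atom_ref, eng$topo,
                 eng$single, eng$pair_mats, eng$hmm_mats, as.integer(mode))
  V <- array(v, dim = c(eng$L + 1L, eng$L + 1L, eng$n_nt))
  list(eng = eng, V = V)
}

#' Maximum-probability constrained parse (CYK)
#'
#' Finds the maximum log-probability derivation of the alignment columns
#' under the grammar, honouring pairing constraints: forbidden pairs can
#' never be emitted as pairs, columns of forced pairs can only pair with
#' their designated partner and can never be emitted unpaired (directly or
#' inside a segment HMM), so every finite-score derivation realizes all
#' forced pairs.
#'
#' @param g a validated `Grammar`.
#' @param aln a `ProfileAlignment`.
#' @param cons a [fold_constraints()].
#' @return list of class `ParseResult`: `logprob`, `tree` (derivation),
#'   `pairs` (two-column matrix), `motifs` (list of placements with `name`,
#'   `variant`, `class`, `segments`), `rule_counts`, `emissions` (observed
#'   single/pair emission events for counting trainers).
#' @export
cyk <- function(g, aln, cons = fold_constraints()) {
  st <- run_engine(g, aln, cons, mode = 0L)
  start_id <- st$eng$nt_id[[g$start]]
  lp <- v_get(st$V, start_id, 1L, st$eng$L)
  if (!is.finite(lp))
    stop("no valid structure: the constraints admit no finite-probability parse")
  tree <- trace_nt(st$eng, st$V, start_id, 1L, st$eng$L)
  res <- collect_parse(st$eng, tree)
  structure(c(list(logprob = lp, tree = tree), res), class = "ParseResult")
}

#' Inside log-probability
#'
#' Log of the summed probability of all valid derivations under the same
#' constraint semantics as [cyk()]. For an unambiguous grammar and a fully
#' constrained structure the inside score equals the CYK score.
#'
#' @inheritParams cyk
#' @return total log-probability (may be `-Inf` when no parse exists).
#' @export
inside <- function(g, aln, cons = fold_constraints()) {
  st <- run_engine(g, aln, cons, mode = 1L)
  v_get(st$V, st$eng$nt_id[[g$start]], 1L, st$eng$L)
}

## Atom score mirroring the C++ kernel.
atom_score_r <- function(eng, V, type, ref, s, e) {
  if (type == ATOM_EMIT) {
    if (e == s) eng$single[ref, s] else -Inf
  } else if (type == ATOM_NT) {
    v_get(V, ref, s, e)
  } else {
    eng$hmm_mats[[ref]][s, e + 1L]
  }
}

## Suffix tables G[[pos]][w], w = s - lo + 1, for rule k over span i..j.
rule_tables <- function(eng, V, k, i, j) {
  lo <- i; hi <- j; base <- 0
  if (eng$rule_pt[k] > 0L) {
    if (j < i + 1L) return(NULL)
    base <- eng$pair_mats[[eng$rule_pt[k]]][i, j]
    if (!is.finite(base)) return(NULL)
    lo <- i + 1L; hi <- j - 1L
  }
  na <- eng$rule_na[k]
  width <- hi - lo + 2L
  G <- vector("list", na + 1L)
  G[[na + 1L]] <- c(rep(-Inf, width - 1L), 0)
  if (na > 0L) for (pos in na:1) {
    type <- eng$atom_type[pos, k]; ref <- eng$atom_ref[pos, k]
    cur <- rep(-Inf, width)
    for (w in seq_len(width)) {
      s <- lo + w - 1L
      if (type == ATOM_EMIT) {
        if (s <= hi) {
          a <- eng$single[ref, s]
          rest <- G[[pos + 1L]][s + 2L - lo]
          if (is.finite(a) && is.finite(rest)) cur[w] <- a + rest
        }
      } else {
        best <- -Inf
        for (e in (s - 1L):hi) {
          a <- atom_score_r(eng, V, type, ref, s, e)
          if (!is.finite(a)) next
          rest <- G[[pos + 1L]][e + 2L - lo]
          if (!is.finite(rest)) next
          if (a + rest > best) best <- a + rest
        }
        cur[w] <- best
      }
    }
    G[[pos]] <- cur
  }
  list(G = G, lo = lo, hi = hi, base = base,
       body = base + G[[1L]][1L])
}

TRACE_TOL <- 1e-9

trace_nt <- function(eng, V, nt, i, j) {
  target <- v_get(V, nt, i, j)
  g <- eng$grammar
  for (k in g$rules_of[[g$nonterminals[nt]]]) {
    tb <- rule_tables(eng, V, k, i, j)
    if (is.null(tb) || !is.finite(tb$body)) next
    if (eng$rule_lp[k] + tb$body < target - TRACE_TOL) next
    ## reconstruct splits: smallest end for each atom in turn
    rule <- g$rules[[k]]
    na <- eng$rule_na[k]
    spans <- vector("list", na)
    children <- vector("list", na)
    s <- tb$lo
    for (pos in seq_len(na)) {
      type <- eng$atom_type[pos, k]; ref <- eng$atom_ref[pos, k]
      need <- tb$G[[pos]][s - tb$lo + 1L]
      found <- FALSE
      for (e in (s - 1L):tb$hi) {
        a <- atom_score_r(eng, V, type, ref, s, e)
        if (!is.finite(a)) next
        rest <- tb$G[[pos + 1L]][e + 2L - tb$lo]
        if (!is.finite(rest)) next
        if (a + rest >= need - TRACE_TOL) {
          spans[[pos]] <- c(s, e)
          if (type == ATOM_NT)
            children[[pos]] <- trace_nt(eng, V, ref, s, e)
          s <- e + 1L
          found <- TRUE
          break
        }
      }
      if (!found) stop("internal error: traceback failed to split a rule")
    }
    return(list(nt = nt, rule = k, i = i, j = j,
                pair = if (!is.null(rule$pair_table)) c(i, j) else NULL,
                spans = spans, children = children))
  }
  stop("internal error: traceback found no rule achieving the chart score")
}

## Flatten a derivation tree into pairs, motif placements, rule usage and
## emission events.
collect_parse <- function(eng, tree) {
  g <- eng$grammar
  acc <- new.env(parent = emptyenv())
  acc$pairs <- list(); acc$motifs <- list()
  acc$counts <- integer(length(g$rules))
  acc$emit_single <- list(); acc$emit_pair <- list()
  walk <- function(node) {
    rule <- g$rules[[node$rule]]
    acc$counts[node$rule] <- acc$counts[node$rule] + 1L
    if (!is.null(node$pair)) {
      acc$pairs[[length(acc$pairs) + 1L]] <- node$pair
      acc$emit_pair[[length(acc$emit_pair) + 1L]] <-
        list(table = rule$pair_table, i = node$pair[1L], j = node$pair[2L])
    }
    if (!is.null(rule$motif)) {
      hmm_pos <- which(vapply(rule$atoms, `[[`, "", "type") == "hmm")
      segs <- lapply(node$spans[hmm_pos], function(sp) c(sp[1L], sp[2L]))
      acc$motifs[[length(acc$motifs) + 1L]] <-
        list(name = rule$motif$name, variant = rule$motif$variant,
             class = rule$motif$class, seg_roles = rule$motif$seg_roles,
             segments = segs,
             span = c(node$i, node$j))
    }
    for (pos in seq_along(node$spans)) {
      a <- rule$atoms[[pos]]
      if (a$type == "emit")
        acc$emit_single[[length(acc$emit_single) + 1L]] <-
          list(table = a$ref, col = node$spans[[pos]][1L])
      else if (a$type == "nt")
        walk(node$children[[pos]])
    }
  }
  walk(tree)
  pairs <- if (length(acc$pairs)) do.call(rbind, acc$pairs)
           else matrix(integer(0), 0, 2)
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  list(pairs = pairs, motifs = acc$motifs, rule_counts = acc$counts,
       emissions = list(single = acc$emit_single, pair = acc$emit_pair))
}

## ---------------------------------------------------------------------------
## Brute-force enumeration oracle

#' Enumerate all derivations of a short sequence
#'
#' Exhaustive recursive enumeration of every derivation of `seq` under the
#' grammar; segment HMMs are treated as atomic terminals scored by their
#' forward probability over the covered span, matching the CYK scoring. Used
#' as a test oracle: the CYK score is the maximum, and the inside score the
#' log-sum-exp, over the enumerated derivations.
#'
#' @param g a `Grammar`.
#' @param seq residue string of length at most `max_len`.
#' @param max_len guard on the sequence length (default 12).
#' @param cap abort if more than this many derivations would be produced.
#' @return list of derivations, each with `logprob`, `pairs`, `motifs`.
#' @export
enumerate_parses <- function(g, seq, max_len = 12L, cap = 2e5) {
  n <- nchar(seq)
  if (n > max_len)
    stop(sprintf("enumerate_parses guard: length %d exceeds %d", n, max_len))
  aln <- profile_alignment(seq, weighting = "none")
  res <- strsplit(toupper(gsub("T", "U", seq, fixed = TRUE)), "",
                  fixed = TRUE)[[1L]]
  memo <- new.env(parent = emptyenv())
  count <- new.env(parent = emptyenv()); count$n <- 0
  bump <- function(k) {
    count$n <- count$n + k
    if (count$n > cap) stop("enumerate_parses: derivation cap exceeded")
  }
  hmm_cache <- new.env(parent = emptyenv())
  hscore <- function(ref, s, e) {
    key <- paste(ref, s, e)
    if (!is.null(hmm_cache[[key]])) return(hmm_cache[[key]])
    v <- hmm_forward(g$hmms[[ref]], aln, s, e)
    hmm_cache[[key]] <- v
    v
  }
  deriv <- function(lp, pairs = NULL, motifs = list(), segs = list())
    list(logprob = lp, pairs = pairs, motifs = motifs, segs = segs)
  combine <- function(a, b, extra_lp = 0) {
    deriv(a$logprob + b$logprob + extra_lp,
          rbind(a$pairs, b$pairs), c(a$motifs, b$motifs), c(a$segs, b$segs))
  }
  enum_seq <- function(atoms, i, j) {
    if (!length(atoms)) {
      return(if (j == i - 1L) list(deriv(0)) else list())
    }
    a <- atoms[[1L]]
    rest <- atoms[-1L]
    out <- list()
    if (a$type == "emit") {
      if (i <= j) {
        sc <- log(g$emis_single[[a$ref]][[res[i]]])
        for (d in enum_seq(rest, i + 1L, j))
          out[[length(out) + 1L]] <- combine(deriv(sc), d)
      }
      return(out)
    }
    for (e in (i - 1L):j) {
      firsts <- if (a$type == "nt") {
        enum_nt(a$ref, i, e)
      } else {
        sc <- hscore(a$ref, i, e)
        if (is.finite(sc)) list(deriv(sc, segs = list(c(i, e)))) else list()
      }
      if (!length(firsts)) next
      rests <- enum_seq(rest, e + 1L, j)
      for (f in firsts) for (d in rests)
        out[[length(out) + 1L]] <- combine(f, d)
    }
    out
  }
  enum_nt <- function(nt, i, j) {
    key <- paste(nt, i, j)
    got <- memo[[key]]
    if (!is.null(got)) {
      ## re-entering a span being computed means the derivation would contain
      ## itself (left recursion); only infinite derivations do that
      if (identical(got, "computing")) return(list())
      return(got)
    }
    memo[[key]] <- "computing"
    out <- list()
    for (k in g$rules_of[[nt]]) {
      r <- g$rules[[k]]
      subs <- if (!is.null(r$pair_table)) {
        if (j < i + 1L) list()
        else {
          psc <- log(g$emis_pair[[r$pair_table]][res[i], res[j]])
          lapply(enum_seq(r$atoms, i + 1L, j - 1L), function(d)
            deriv(d$logprob + psc, rbind(matrix(c(i, j), 1L), d$pairs),
                  d$motifs))
        }
      } else enum_seq(r$atoms, i, j)
      for (d in subs) {
        d$logprob <- d$logprob + r$logprob
        if (!is.null(r$motif)) {
          d$motifs <- c(d$motifs,
                        list(list(name = r$motif$name,
                                  variant = r$motif$variant,
                                  class = r$motif$class, span = c(i, j),
                                  segments = d$segs)))
          d$segs <- list()   # segments are claimed by their motif rule
        }
        out[[length(out) + 1L]] <- d
      }
    }
    bump(length(out))
    memo[[key]] <- out
    out
  }
  enum_nt(g$start, 1L, n)
}

## ---------------------------------------------------------------------------
## Generative sampling

#' Sample a derivation from a grammar
#'
#' Draws rules, emissions and segment-HMM paths from their distributions and
#' returns the emitted sequence with its structure and motif annotation.
#' Resamples until the emitted length is at most `max_len`.
#'
#' @param g a `Grammar`.
#' @param max_len maximum emitted length accepted.
#' @param max_tries attempts before giving up.
#' @return list with `seq`, `pairs`, `motifs`.
#' @export
sample_derivation <- function(g, max_len = Inf, max_tries = 1000L) {
  for (try in seq_len(max_tries)) {
    out <- tryCatch(samp_nt(g, g$start, depth = 0L,
                            budget = min(max_len * 4 + 40, 4000)),
                    error = function(e) NULL)
    if (!is.null(out) && length(out$chars) <= max_len) {
      return(list(seq = paste(out$chars, collapse = ""),
                  pairs = out$pairs, motifs = out$motifs))
    }
  }
  stop("sample_derivation: no sample within max_len after max_tries attempts")
}

samp_nt <- function(g, nt, depth, budget) {
  if (depth > 400L) stop("sampling recursion too deep")
  ids <- g$rules_of[[nt]]
  probs <- vapply(g$rules[ids], `[[`, 0, "prob")
  k <- ids[sample.int(length(ids), 1L, prob = probs)]
  r <- g$rules[[k]]
  chars <- character(0)
  pairs <- matrix(integer(0), 0, 2)
  motifs <- list()
  segs <- list()
  for (a in r$atoms) {
    if (a$type == "emit") {
      chars <- c(chars, sample(RNA_BASES, 1L, prob = g$emis_single[[a$ref]]))
    } else if (a$type == "hmm") {
      s <- sample_hmm(g$hmms[[a$ref]])
      seg_chars <- if (nzchar(s)) strsplit(s, "")[[1L]] else character(0)
      segs[[length(segs) + 1L]] <-
        c(length(chars) + 1L, length(chars) + length(seg_chars))
      chars <- c(chars, seg_chars)
    } else {
      sub <- samp_nt(g, a$ref, depth + 1L, budget - length(chars))
      off <- length(chars)
      if (nrow(sub$pairs)) pairs <- rbind(pairs, sub$pairs + off)
      for (m in sub$motifs) {
        m$span <- m$span + off
        m$segments <- lapply(m$segments, function(sp) sp + off)
        motifs[[length(motifs) + 1L]] <- m
      }
      chars <- c(chars, sub$chars)
    }
    if (length(chars) > budget) stop("sampling budget exceeded")
  }
  if (!is.null(r$pair_table)) {
    E <- g$emis_pair[[r$pair_table]]
    idx <- sample.int(16L, 1L, prob = as.numeric(E))
    x <- RNA_BASES[(idx - 1L) %% 4L + 1L]
    y <- RNA_BASES[(idx - 1L) %/% 4L + 1L]
    if (nrow(pairs)) pairs <- pairs + 1L
    motifs <- lapply(motifs, function(m) {
      m$span <- m$span + 1L
      m$segments <- lapply(m$segments, function(sp) sp + 1L)
      m
    })
    segs <- lapply(segs, function(sp) sp + 1L)
    pairs <- rbind(matrix(c(1L, length(chars) + 2L), 1L), pairs)
    chars <- c(x, chars, y)
  }
  if (!is.null(r$motif)) {
    motifs <- c(motifs, list(list(name = r$motif$name,
                                  variant = r$motif$variant,
                                  class = r$motif$class,
                                  span = c(1L, length(chars)),
                                  segments = segs)))
  }
  list(chars = chars, pairs = pairs, motifs = motifs)
}
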