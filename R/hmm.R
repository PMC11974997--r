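## Segment profile HMMs: short position-specific models of motif segment
## consensus sequences. States emit on transition. Each junction between
## match transitions (including before the first and after the last) carries
## a geometric insert state; matches can be deleted with probability delta.
## The insert rate is solved analytically so the expected emitted length is
## exactly k + min(0.1*k, 1.5) for a consensus of length k (an empty segment
## gets expected length 0.1, keeping insertions possible).

#' Build a segment profile HMM from an IUPAC consensus
#'
#' Per consensus position, residues outside the IUPAC code's set get
#' probability 1e-4 and residues inside share the remainder equally. A
#' single geometric insert state sits at each of the k+1 junctions; its
#' self-transition probability is solved so that the analytic expected
#' emitted length equals `k + min(0.1*k, 1.5)` (0.1 for an empty consensus),
#' accounting for the expected `k*delta` residues lost to deletion.
#'
#' @param consensus string of IUPAC RNA codes; `""` or `"-"` denotes an
#'   empty segment.
#' @param delta per-position deletion probability (default 0.01).
#' @param off_consensus probability of each residue outside a position's
#'   consensus set (default 1e-4).
#' @return object of class `ProfileHMM`.
#' @export
build_segment_hmm <- function(consensus, delta = 0.01, off_consensus = 1e-4) {
  if (is.null(consensus) || consensus %in% c("-", ""))
    consensus <- ""
  consensus <- toupper(gsub("T", "U", consensus, fixed = TRUE))
  codes <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  if (length(codes) && any(!(codes %in% names(IUPAC_SETS))))
    stop(sprintf("illegal IUPAC code '%s' in consensus '%s'",
                 codes[which(!(codes %in% names(IUPAC_SETS)))[1L]], consensus))
  k <- length(codes)
  match_emis <- matrix(0, 4, max(k, 1L), dimnames = list(RNA_BASES, NULL))
  if (k > 0L) {
    for (p in seq_len(k)) {
      set <- IUPAC_SETS[[codes[p]]]
      out <- setdiff(RNA_BASES, set)
      e <- rep(0, 4); names(e) <- RNA_BASES
      e[out] <- off_consensus
      e[set] <- (1 - length(out) * off_consensus) / length(set)
      match_emis[, p] <- e
    }
  } else {
    match_emis <- matrix(numeric(0), 4, 0, dimnames = list(RNA_BASES, NULL))
  }
  extra <- if (k == 0L) 0.1 else min(0.1 * k, 1.5)
  ## expected inserts must also compensate the k*delta expected deletions
  e_junction <- (extra + k * delta) / (k + 1)
  t_ins <- e_junction / (1 + e_junction)
  structure(list(consensus = consensus, k = k,
                 off_consensus = off_consensus,
                 match_emis = match_emis,
                 insert_emis = stats::setNames(rep(0.25, 4), RNA_BASES),
                 t_ins = t_ins, delta = delta),
            class = "ProfileHMM")
}

#' Analytic expected emitted length of a segment HMM
#'
#' `k*(1-delta)` expected match emissions plus `(k+1)` junctions each
#' emitting `t/(1-t)` expected inserts.
#'
#' @param hmm a `ProfileHMM`.
#' @return expected number of emitted residues.
#' @export
expected_hmm_length <- function(hmm) {
  hmm$k * (1 - hmm$delta) + (hmm$k + 1) * hmm$t_ins / (1 - hmm$t_ins)
}

## Per-column expected log emission scores for a profile (see scfg scoring):
## match_scores is k x L, insert_scores length L. `mask` marks columns that
## may not be absorbed by the HMM (forced to pair elsewhere).
hmm_column_scores <- function(hmm, fnorm, mask = NULL) {
  L <- ncol(fnorm)
  ins <- rep(log(0.25), L)
  mat <- if (hmm$k > 0L) t(log(hmm$match_emis)) %*% fnorm
         else matrix(numeric(0), 0, L)
  if (!is.null(mask) && any(mask)) {
    ins[mask] <- -Inf
    if (hmm$k > 0L) mat[, mask] <- -Inf
  }
  list(match = mat, insert = ins)
}

#' Forward log-probability that a segment HMM emits an alignment span
#'
#' Sums over all insert/delete paths that emit exactly the columns
#' `i..j` (the empty span `j = i-1` is allowed). Column emissions are scored
#' as expected log-probabilities under the column's residue distribution.
#'
#' @param hmm a `ProfileHMM`.
#' @param aln a `ProfileAlignment`.
#' @param i,j 1-based span bounds, `i <= j + 1`.
#' @return forward log-probability; `-Inf` when the span length is
#'   unreachable (e.g. shorter than the consensus with `delta = 0`).
#' @export
hmm_forward <- function(hmm, aln, i, j) {
  if (i < 1L || j > aln$n_cols || i > j + 1L)
    stop(sprintf("invalid span %d..%d for %d columns", i, j, aln$n_cols))
  sc <- hmm_column_scores(hmm, norm_col_freq(aln))
  M <- hmm_span_scores(hmm, sc, aln$n_cols, starts = i)
  M[i, j + 1L]
}

## Span-score matrix M[(L+1) x (L+1)], M[i, j+1] = forward score of span
## i..j (empty span at column index i). Row i = L+1 holds only the empty
## span. O(k * L) per start position.
hmm_span_scores <- function(hmm, sc, L, starts = seq_len(L + 1L)) {
  k <- hmm$k
  lt <- log(hmm$t_ins); l1t <- log1p(-hmm$t_ins)
  ld <- log(hmm$delta); l1d <- log1p(-hmm$delta)
  M <- matrix(-Inf, L + 1L, L + 1L)
  for (i in starts) {
    ## A[c+1] = logprob of being at junction c having emitted the columns
    ## consumed so far
    A <- numeric(k + 1L)
    A[1L] <- 0
    if (k > 0L) for (c in seq_len(k)) A[c + 1L] <- A[c] + l1t + ld
    M[i, i] <- A[k + 1L] + l1t            # empty span
    if (i > L) next
    for (col in i:L) {
      B <- numeric(k + 1L)
      B[1L] <- A[1L] + lt + sc$insert[col]
      if (k > 0L) {
        for (c in seq_len(k)) {
          ins <- A[c + 1L] + lt + sc$insert[col]
          mat <- A[c] + l1t + l1d + sc$match[c, col]
          del <- B[c] + l1t + ld
          B[c + 1L] <- logsumexp3(ins, mat, del)
        }
      }
      M[i, col + 1L] <- B[k + 1L] + l1t
      A <- B
    }
  }
  M
}

logsumexp3 <- function(a, b, c) {
  m <- max(a, b, c)
  if (!is.finite(m)) return(-Inf)
  m + log(exp(a - m) + exp(b - m) + exp(c - m))
}

#' Sample an emitted string from a segment HMM
#'
#' @param hmm a `ProfileHMM`.
#' @return character scalar of emitted residues (possibly "").
#' @export
sample_hmm <- function(hmm) {
  out <- character(0)
  emit_inserts <- function() {
    n <- stats::rgeom(1L, 1 - hmm$t_ins)
    if (n > 0L) sample(RNA_BASES, n, replace = TRUE, prob = hmm$insert_emis)
    else character(0)
  }
  out <- c(out, emit_inserts())
  if (hmm$k > 0L) {
    for (p in seq_len(hmm$k)) {
      if (stats::runif(1L) >= hmm$delta)
        out <- c(out, sample(RNA_BASES, 1L, prob = hmm$match_emis[, p]))
      out <- c(out, emit_inserts())
    }
  }
  paste(out, collapse = "")
}
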