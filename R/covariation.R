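## Covariation analysis: classify column pairs into positive (significantly
## covarying), negative (variable but not covarying, hence disallowed from
## pairing) and neutral. The statistic is weighted mutual information with
## average-product correction; significance comes from an empirical
## column-shuffle null. Pairs where either column is mostly gaps carry no
## pairing signal and are never positive or negative.

#' Covariation analysis configuration
#'
#' @param evalue_threshold significance threshold on the E-value, the
#'   expected per-alignment count of null pair scores at or above a pair's
#'   score. Default 0.05.
#' @param n_null_shuffles number of column-wise permutations pooled into the
#'   empirical null. Default 200.
#' @param power_threshold minimum covariation power for a non-significant
#'   pair to be labelled negative. Default 0.95.
#' @param lambda calibration rate of the power proxy
#'   `1 - exp(-lambda * min(subs_i, subs_j))`, where `subs_c` is the weighted
#'   minority-residue count of column c. Default 0.5.
#' @param max_gapfrac pairs with either column's gap fraction at or above
#'   this value are ineligible (always neutral). Default 0.5.
#' @param seed integer seed controlling the null permutations.
#' @return a list of class `CovariationConfig`.
#' @export
covariation_config <- function(evalue_threshold = 0.05,
                               n_null_shuffles = 200L,
                               power_threshold = 0.95,
                               lambda = 0.5,
                               max_gapfrac = 0.5,
                               seed = 42L) {
  stopifnot(evalue_threshold > 0, n_null_shuffles >= 1)
  structure(list(evalue_threshold = evalue_threshold,
                 n_null_shuffles = as.integer(n_null_shuffles),
                 power_threshold = power_threshold,
                 lambda = lambda,
                 max_gapfrac = max_gapfrac,
                 seed = as.integer(seed)),
            class = "CovariationConfig")
}

## Weighted fractional indicator matrices premultiplied by sequence weights.
weighted_indicators <- function(aln) {
  id <- aln_indicators(aln)
  lapply(id$ind, function(m) m * aln$weights)
}

#' APC-corrected mutual information for all eligible column pairs
#'
#' The raw statistic for columns i, j is the weighted mutual information (in
#' bits) of the joint residue distribution over sequences in which both
#' columns are ungapped. The average-product correction
#' `APC(i,j) = mean_i * mean_j / mean_all` of the raw MI matrix is
#' subtracted. Pairs where either column has gap fraction >=
#' `max_gapfrac` are not scored.
#'
#' @param aln a `ProfileAlignment` with at least 2 sequences.
#' @param max_gapfrac eligibility cutoff on the per-column gap fraction.
#' @return data frame with columns `i`, `j` (1-based, i < j), `mi` (raw) and
#'   `score` (APC-corrected).
#' @export
pair_scores <- function(aln, max_gapfrac = 0.5) {
  if (aln$n_seqs < 2L)
    stop("covariation requires >=2 sequences")
  L <- aln$n_cols
  eligible <- which(aln$col_gapfrac < max_gapfrac)
  if (length(eligible) < 2L)
    return(data.frame(i = integer(0), j = integer(0),
                      mi = numeric(0), score = numeric(0)))
  wind <- weighted_indicators(aln)
  mi <- mi_matrix(wind, eligible, L)
  ut <- upper.tri(mi)
  keep <- ut & !is.na(mi)
  idx <- which(keep, arr.ind = TRUE)
  raw <- mi[keep]
  ## average-product correction over the scored pairs
  mi_sym <- mi
  mi_sym[lower.tri(mi_sym)] <- t(mi_sym)[lower.tri(mi_sym)]
  diag(mi_sym) <- NA
  rowm <- rowMeans(mi_sym, na.rm = TRUE)
  rowm[is.nan(rowm)] <- 0
  allm <- mean(raw)
  apc <- if (allm > 0) rowm[idx[, 1L]] * rowm[idx[, 2L]] / allm else 0
  out <- data.frame(i = idx[, 1L], j = idx[, 2L], mi = raw,
                    score = raw - apc)
  out[order(out$i, out$j), , drop = FALSE]
}

## Upper-triangular matrix of raw weighted MI (bits) over eligible columns;
## NA where ineligible. Computed with 16 cross-products so the cost is a few
## matrix multiplications regardless of L.
mi_matrix <- function(wind, eligible, L) {
  counts <- vector("list", 16L)
  k <- 0L
  n_ij <- matrix(0, L, L)
  for (x in RNA_BASES) for (y in RNA_BASES) {
    k <- k + 1L
    counts[[k]] <- crossprod(wind[[x]], wind[[y]])   # L x L weighted counts
    n_ij <- n_ij + counts[[k]]
  }
  safe_n <- ifelse(n_ij > 0, n_ij, 1)
  ## joint entropy term and marginals restricted to jointly ungapped rows
  hxy <- matrix(0, L, L)
  px <- vector("list", 4L); names(px) <- RNA_BASES
  for (x in RNA_BASES) px[[x]] <- matrix(0, L, L)
  py <- px
  k <- 0L
  for (x in RNA_BASES) for (y in RNA_BASES) {
    k <- k + 1L
    p <- counts[[k]] / safe_n
    hxy <- hxy - ifelse(p > 0, p * log2(p), 0)
    px[[x]] <- px[[x]] + p
    py[[y]] <- py[[y]] + p
  }
  hx <- matrix(0, L, L); hy <- matrix(0, L, L)
  for (x in RNA_BASES) {
    hx <- hx - ifelse(px[[x]] > 0, px[[x]] * log2(px[[x]]), 0)
    hy <- hy - ifelse(py[[x]] > 0, py[[x]] * log2(py[[x]]), 0)
  }
  mi <- hx + hy - hxy
  mi[n_ij <= 0] <- 0
  mask <- matrix(NA_real_, L, L)
  mask[eligible, eligible] <- 0
  mi + mask
}

#' Pooled null scores from column-shuffled alignments
#'
#' Corrected pair scores of `n_null_shuffles` independent column-wise
#' permutations of the alignment (residues permuted within each column,
#' preserving per-column composition), pooled and sorted descending. The
#' permutations are seeded deterministically from `cfg$seed`.
#'
#' @param aln a `ProfileAlignment`.
#' @param cfg a [covariation_config()].
#' @return numeric vector of null scores, sorted descending.
#' @export
null_scores <- function(aln, cfg = covariation_config()) {
  pool <- vector("list", cfg$n_null_shuffles)
  for (r in seq_len(cfg$n_null_shuffles)) {
    shuf <- column_shuffle(aln, seed = cfg$seed + r)
    shuf$weights <- aln$weights       # keep weights fixed across the null
    shuf <- recount_profiles(shuf)
    pool[[r]] <- pair_scores(shuf, max_gapfrac = cfg$max_gapfrac)$score
  }
  sort(unlist(pool), decreasing = TRUE)
}

#' Classify column pairs as positive, negative or neutral
#'
#' E-value of a pair = (number of pooled null scores >= its score) divided by
#' the number of shuffles, i.e. the expected per-alignment count of null
#' pairs scoring at least as high. A pair is positive when its E-value is at
#' or below `cfg$evalue_threshold`; a non-positive pair is negative when its
#' covariation power proxy is at least `cfg$power_threshold`; all other pairs
#' (including any pair with column gap fraction >= `cfg$max_gapfrac`) are
#' neutral.
#'
#' @param aln a `ProfileAlignment` with at least 2 sequences.
#' @param cfg a [covariation_config()].
#' @return data frame of class `CovariationResult` with columns `i`, `j`,
#'   `score`, `evalue`, `power`, `label`.
#' @export
classify_pairs <- function(aln, cfg = covariation_config()) {
  sc <- pair_scores(aln, max_gapfrac = cfg$max_gapfrac)
  if (!nrow(sc)) {
    out <- data.frame(i = integer(0), j = integer(0), score = numeric(0),
                      evalue = numeric(0), power = numeric(0),
                      label = character(0))
    class(out) <- c("CovariationResult", class(out))
    return(out)
  }
  null <- null_scores(aln, cfg)
  ## count of null scores >= score, via ranks on the descending-sorted null
  ev <- vapply(sc$score, function(s) sum(null >= s), 0) / cfg$n_null_shuffles
  subs <- column_substitutions(aln)
  pw <- 1 - exp(-cfg$lambda * pmin(subs[sc$i], subs[sc$j]))
  lab <- rep("neutral", nrow(sc))
  lab[ev <= cfg$evalue_threshold] <- "positive"
  lab[lab != "positive" & pw >= cfg$power_threshold] <- "negative"
  out <- data.frame(i = sc$i, j = sc$j, score = sc$score,
                    evalue = ev, power = pw, label = lab)
  class(out) <- c("CovariationResult", class(out))
  out
}

## Weighted count of minority residues per column (gaps excluded): total
## ungapped weight minus the weight of the most frequent residue.
column_substitutions <- function(aln) {
  f <- aln$col_freq * sum(aln$weights)   # weighted counts
  tot <- colSums(f)
  tot - apply(f, 2, max)
}

#' Load an externally computed pair classification
#'
#' Accepts whitespace-separated lines `i j label [evalue]` with 1-based
#' column coordinates, e.g. output converted from an external covariation
#' analysis. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param n_cols number of alignment columns, for range validation.
#' @return a `CovariationResult` data frame (scores and powers are `NA` for
#'   entries the file does not provide).
#' @export
load_external_pairs <- function(path, n_cols) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  out <- data.frame(i = integer(0), j = integer(0), score = numeric(0),
                    evalue = numeric(0), power = numeric(0),
                    label = character(0))
  lineno <- which(keep)
  rows <- list()
  for (k in seq_along(lineno)) {
    f <- strsplit(trimws(lines[lineno[k]]), "\\s+")[[1L]]
    if (length(f) < 3L)
      stop(sprintf("line %d: expected 'i j label [evalue]'", lineno[k]))
    i <- suppressWarnings(as.integer(f[1L])); j <- suppressWarnings(as.integer(f[2L]))
    if (is.na(i) || is.na(j))
      stop(sprintf("line %d: non-integer column index", lineno[k]))
    if (i >= j)
      stop(sprintf("line %d: require i < j, got %d >= %d", lineno[k], i, j))
    if (i < 1L || j > n_cols)
      stop(sprintf("line %d: column out of range 1..%d", lineno[k], n_cols))
    if (!(f[3L] %in% c("positive", "negative", "neutral")))
      stop(sprintf("line %d: unknown label '%s'", lineno[k], f[3L]))
    ev <- if (length(f) >= 4L) as.numeric(f[4L]) else NA_real_
    rows[[k]] <- data.frame(i = i, j = j, score = NA_real_, evalue = ev,
                            power = NA_real_, label = f[3L])
  }
  if (length(rows)) out <- do.call(rbind, rows)
  dup <- duplicated(out[, c("i", "j")])
  if (any(dup))
    stop(sprintf("duplicate pair (%d,%d)", out$i[dup][1L], out$j[dup][1L]))
  class(out) <- c("CovariationResult", class(out))
  out
}

#' Write a TSV report of all scored pairs
#'
#' @param res a `CovariationResult`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pair_report <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expected number of covarying helices under the null
#'
#' With per-alignment E-value threshold `evalue`, the expected number of
#' helices showing at least one covarying pair by chance across `n_helices`
#' helices is `evalue * n_helices`.
#'
#' @param n_helices number of helices examined.
#' @param evalue the significance threshold.
#' @return expected count.
#' @export
expected_null_helices <- function(n_helices, evalue = 0.05) {
  evalue * n_helices
}
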