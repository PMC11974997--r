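## End-to-end orchestration: covariation classification, layer decomposition,
## constrained folding of layer 1 with the motif-integrated grammar,
## pseudoknot layers with the auxiliary nested-pair grammar, and assembly of
## the consensus structure with motif placements and covariation-support
## flags.

#' Folding configuration
#'
#' @param covariation run the covariation stage (`FALSE` gives an
#'   unconstrained fold, the ablation mode).
#' @param cov a [covariation_config()].
#' @param prior a [motif_prior_config()].
#' @param params base-grammar parameters ([rbg_default_params()]).
#' @param g6x_params pseudoknot-layer grammar parameters.
#' @param delta segment-HMM deletion probability.
#' @return list of class `FoldConfig`.
#' @export
fold_config <- function(covariation = TRUE, cov = covariation_config(),
                        prior = motif_prior_config(),
                        params = rbg_default_params(),
                        g6x_params = g6x_default_params(),
                        delta = 0.01) {
  structure(list(covariation = covariation, cov = cov, prior = prior,
                 params = params, g6x_params = g6x_params, delta = delta),
            class = "FoldConfig")
}

resolve_motif_models <- function(motifs, delta) {
  if (is.character(motifs)) motifs <- parse_descriptor_file(motifs)
  if (length(motifs) && inherits(motifs[[1L]], "MotifDescriptor"))
    return(expand_all(motifs, delta = delta)$models)
  motifs
}

#' Fold an alignment jointly with 3D motif annotation
#'
#' The full pipeline: (1) classify column pairs as positive / negative /
#' neutral by covariation (or accept an external classification); (2) split
#' the positive pairs into nested layers; (3) fold layer 1 with the
#' motif-integrated grammar under constraints (layer-1 positives forced,
#' negatives and cross-layer positives forbidden); (4) fold the remaining
#' layers with the pseudoknot grammar, where only each layer's positives and
#' their immediate stacking neighbours are pair-eligible; (5) assemble the
#' layered consensus structure, motif placements and covariation-support
#' flags. An alignment with zero positives still folds (unconstrained layer
#' 1, no further layers).
#'
#' @param aln a `ProfileAlignment`.
#' @param motifs motif models: a descriptor file path, a list of
#'   `MotifDescriptor`s, or compiled `MotifModel`s. Defaults to the shipped
#'   descriptor set.
#' @param config a [fold_config()].
#' @param pairs optional externally supplied `CovariationResult` (e.g. from
#'   [load_external_pairs()]), replacing the built-in covariation stage.
#' @return object of class `FoldResult`: `structure`
#'   (a `ConsensusStructure`), `motifs` (data frame: motif, variant, class,
#'   segments, span_start, span_end, logprob, support), `layers`
#'   (a `LayerDecomposition` of the positives), `positives`, `negatives`,
#'   `extra_pairs` (cross-layer duplicates not representable in one
#'   structure string), `logprob` (layer-1 parse score) and `metadata`.
#' @export
fold_rna <- function(aln, motifs = default_motif_file(),
                     config = fold_config(), pairs = NULL) {
  models <- resolve_motif_models(motifs, config$delta)
  ## 1. covariation constraints
  cls <- if (!is.null(pairs)) pairs
         else if (config$covariation && aln$n_seqs >= 2L)
           classify_pairs(aln, config$cov)
         else NULL
  positives <- negatives <- matrix(integer(0), 0, 2)
  if (!is.null(cls) && nrow(cls)) {
    positives <- as_pair_matrix(cls[cls$label == "positive", c("i", "j")])
    negatives <- as_pair_matrix(cls[cls$label == "negative", c("i", "j")])
  }
  ## 2. layers
  layers <- decompose_layers(positives)
  forced1 <- if (length(layers$layers)) layers$layers[[1L]]
             else matrix(integer(0), 0, 2)
  cross <- if (length(layers$layers) > 1L)
    do.call(rbind, layers$layers[-1L]) else matrix(integer(0), 0, 2)
  ## 3. layer 1 with the motif-integrated grammar
  base <- build_rbgj3j4(config$params)
  gi <- suppressWarnings(integrate_r3d(base, models, config$prior))
  if (aln$n_cols == 0L) {
    return(empty_fold_result(aln, layers, positives, negatives, gi))
  }
  res1 <- cyk(gi, aln,
              fold_constraints(forced = forced1,
                               forbidden = rbind(negatives, cross)))
  pair_layers <- list(res1$pairs)
  extra <- matrix(integer(0), 0, 2)
  ## 4. pseudoknot layers
  if (length(layers$layers) > 1L) {
    g6 <- build_g6x(config$g6x_params)
    seen <- res1$pairs
    for (li in 2:length(layers$layers)) {
      lp <- layers$layers[[li]]
      allowed <- matrix(FALSE, aln$n_cols, aln$n_cols)
      allowed[lp] <- TRUE
      for (r in seq_len(nrow(lp))) {
        i <- lp[r, 1L]; j <- lp[r, 2L]
        if (i + 1L < j - 1L) allowed[i + 1L, j - 1L] <- TRUE
        if (i > 1L && j < aln$n_cols) allowed[i - 1L, j + 1L] <- TRUE
      }
      if (nrow(seen)) allowed[seen] <- FALSE
      allowed[lp] <- TRUE
      resL <- cyk(g6, aln, fold_constraints(forced = lp, allowed = allowed))
      pair_layers[[li]] <- resL$pairs
      seen <- rbind(seen, resL$pairs)
    }
  }
  ## 5. assembly: keep the structure string single-valued per column; pairs
  ## reusing a column already annotated in an earlier layer (triplets) are
  ## reported separately
  used <- rep(FALSE, aln$n_cols)
  clean_layers <- list()
  for (li in seq_along(pair_layers)) {
    m <- pair_layers[[li]]
    keep <- rep(TRUE, nrow(m))
    for (r in seq_len(nrow(m))) {
      if (used[m[r, 1L]] || used[m[r, 2L]]) keep[r] <- FALSE
      else used[c(m[r, ])] <- TRUE
    }
    extra <- rbind(extra, m[!keep, , drop = FALSE])
    clean_layers[[li]] <- m[keep, , drop = FALSE]
  }
  struct <- structure_to_wuss(clean_layers, aln$n_cols)
  motif_df <- motif_placements_df(res1$motifs, gi, aln)
  result <- structure(
    list(structure = struct, motifs = motif_df, layers = layers,
         positives = positives, negatives = negatives, extra_pairs = extra,
         logprob = res1$logprob,
         metadata = list(
           n_nonterminals = n_nonterminals(gi),
           n_motif_models = length(models),
           covariation = config$covariation,
           evalue_threshold = config$cov$evalue_threshold,
           n_null_shuffles = config$cov$n_null_shuffles,
           seed = config$cov$seed)),
    class = "FoldResult")
  motif_support(result, positives)
}

empty_fold_result <- function(aln, layers, positives, negatives, gi) {
  structure(
    list(structure = structure_to_wuss(list(), 0L),
         motifs = motif_placements_df(list(), gi, aln),
         layers = layers, positives = positives, negatives = negatives,
         extra_pairs = matrix(integer(0), 0, 2), logprob = 0,
         metadata = list(n_nonterminals = n_nonterminals(gi))),
    class = "FoldResult")
}

motif_placements_df <- function(motifs, g, aln) {
  if (!length(motifs)) {
    return(data.frame(motif = character(0), variant = integer(0),
                      class = character(0), segments = character(0),
                      span_start = integer(0), span_end = integer(0),
                      logprob = numeric(0), support = logical(0)))
  }
  rows <- lapply(motifs, function(m) {
    segs <- format_segment_string(m$segments)
    lp <- 0
    for (k in seq_along(m$segments)) {
      sp <- m$segments[[k]]
      hmm <- g$hmms[[paste0(m$name, "~", m$seg_roles[k])]]
      if (!is.null(hmm)) lp <- lp + hmm_forward(hmm, aln, sp[1L], sp[2L])
    }
    data.frame(motif = m$name, variant = m$variant, class = m$class,
               segments = segs, span_start = m$span[1L],
               span_end = m$span[2L], logprob = lp, support = NA)
  })
  do.call(rbind, rows)
}

#' @export
print.FoldResult <- function(x, ...) {
  cat(sprintf("FoldResult: %d layer(s), %d positive pair(s), %d motif(s)\n",
              length(x$structure$pairs_by_layer), nrow(x$positives),
              nrow(x$motifs)))
  cat(x$structure$wuss, "\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Covariation support

## Group nested pairs into helices: pairs (i,j) and (i+1,j-1) stack into the
## same helix. Returns an integer helix id per row of `pairs`.
helix_ids <- function(pairs) {
  if (!nrow(pairs)) return(integer(0))
  ord <- order(pairs[, 1L])
  key <- paste(pairs[, 1L], pairs[, 2L])
  id <- stats::setNames(rep(NA_integer_, nrow(pairs)), key)
  nxt <- 0L
  for (r in ord) {
    outer_key <- paste(pairs[r, 1L] - 1L, pairs[r, 2L] + 1L)
    if (!is.na(id[outer_key][1L]) && outer_key %in% key) {
      id[key[r]] <- id[[outer_key]]
    } else {
      nxt <- nxt + 1L
      id[key[r]] <- nxt
    }
  }
  as.integer(id[key])
}

#' Recompute covariation-support flags of motif placements
#'
#' A motif is covariation-supported when at least one of its bounding
#' helices contains a positive (significantly covarying) pair. The bounding
#' helices are the helix whose closing pair immediately encloses the motif's
#' host loop plus the helices headed by that pair's direct children (1 helix
#' for hairpin motifs, 2 for bulge/internal-loop, 3 for 3-way and 4 for
#' 4-way junction motifs, all branch helices for multiloop segment motifs).
#'
#' @param result a `FoldResult`.
#' @param positives two-column matrix of positive pairs.
#' @return the `FoldResult` with updated `motifs$support`.
#' @export
motif_support <- function(result, positives) {
  mdf <- result$motifs
  if (!nrow(mdf)) return(result)
  pairs <- if (length(result$structure$pairs_by_layer))
    result$structure$pairs_by_layer[[1L]] else matrix(integer(0), 0, 2)
  hid <- helix_ids(pairs)
  pos_key <- if (nrow(positives)) paste(positives[, 1L], positives[, 2L])
             else character(0)
  helix_supported <- if (nrow(pairs)) {
    tapply(paste(pairs[, 1L], pairs[, 2L]) %in% pos_key, hid, any)
  } else logical(0)
  for (r in seq_len(nrow(mdf))) {
    s <- mdf$span_start[r]; e <- mdf$span_end[r]
    ## innermost pair strictly enclosing the motif span
    enc <- which(pairs[, 1L] < s & pairs[, 2L] > e)
    if (!length(enc)) { mdf$support[r] <- FALSE; next }
    enc <- enc[which.max(pairs[enc, 1L])]
    a <- pairs[enc, 1L]; b <- pairs[enc, 2L]
    ## direct children of the enclosing pair
    inside <- which(pairs[, 1L] > a & pairs[, 2L] < b)
    children <- inside[vapply(inside, function(q) {
      !any(pairs[inside, 1L] < pairs[q, 1L] & pairs[inside, 2L] > pairs[q, 2L])
    }, TRUE)]
    bound <- unique(c(hid[enc], hid[children]))
    mdf$support[r] <- any(helix_supported[as.character(bound)])
  }
  result$motifs <- mdf
  result
}

## ---------------------------------------------------------------------------
## Reporting and evaluation

#' Write the TSV motif report of a fold result
#'
#' Columns: motif, variant, class, segments (1-based column spans),
#' span_start, span_end, logprob, support.
#'
#' @param result a `FoldResult`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motif_report <- function(result, path) {
  utils::write.table(result$motifs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Compare motif placements against planted truth
#'
#' A planted motif counts as found when a placement of the same motif name
#' matches both ends of the planted span exactly; any other placement is a
#' false positive.
#'
#' @param result a `FoldResult`.
#' @param truth_motifs list of planted motifs with `name` and `span`.
#' @return list with `n_true`, `n_found`, `sensitivity`, `false_positives`.
#' @export
evaluate_motif_predictions <- function(result, truth_motifs) {
  mdf <- result$motifs
  found <- logical(length(truth_motifs))
  matched <- rep(FALSE, nrow(mdf))
  for (k in seq_along(truth_motifs)) {
    t <- truth_motifs[[k]]
    hit <- which(!matched & mdf$motif == t$name &
                 mdf$span_start == t$span[1L] & mdf$span_end == t$span[2L])
    if (length(hit)) { found[k] <- TRUE; matched[hit[1L]] <- TRUE }
  }
  list(n_true = length(truth_motifs), n_found = sum(found),
       sensitivity = if (length(truth_motifs)) mean(found) else NA_real_,
       false_positives = sum(!matched))
}
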