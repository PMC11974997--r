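## Layer decomposition of positive pairs: repeatedly extract a
## maximum-cardinality mutually nested subset (Nussinov-style dynamic
## programming, each pair weight 1) until all pairs are consumed. Columns may
## recur across layers (triplets / long-range contacts) but not within one.

#' Split base pairs into ordered nested layers
#'
#' Layer 1 is a maximum-cardinality subset of the input pairs that is
#' mutually nested with no repeated column; the remaining pairs are
#' decomposed the same way into further layers until none are left. Ties are
#' broken deterministically, preferring the subset whose sorted pair list is
#' lexicographically smallest.
#'
#' @param pairs two-column matrix (or data frame) of 1-based pairs, i < j.
#' @return object of class `LayerDecomposition`: list with `layers` (list of
#'   two-column matrices) and `layer_of_pair` (data frame `i`, `j`, `layer`).
#' @export
decompose_layers <- function(pairs) {
  pairs <- as_pair_matrix(pairs)
  if (nrow(pairs) && any(pairs[, 1L] >= pairs[, 2L]))
    stop("pairs must satisfy i < j")
  layers <- list()
  remaining <- pairs
  assign <- list()
  while (nrow(remaining) > 0L) {
    sel <- max_nested_subset(remaining)
    layer <- remaining[sel, , drop = FALSE]
    layer <- layer[order(layer[, 1L], layer[, 2L]), , drop = FALSE]
    layers[[length(layers) + 1L]] <- layer
    assign[[length(assign) + 1L]] <-
      data.frame(i = layer[, 1L], j = layer[, 2L], layer = length(layers))
    remaining <- remaining[-sel, , drop = FALSE]
  }
  lop <- if (length(assign)) do.call(rbind, assign)
         else data.frame(i = integer(0), j = integer(0), layer = integer(0))
  structure(list(layers = layers, layer_of_pair = lop),
            class = "LayerDecomposition")
}

as_pair_matrix <- function(pairs) {
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs[, c(1L, 2L)])
  if (is.null(pairs) || length(pairs) == 0L) return(matrix(integer(0), 0, 2))
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2, byrow = TRUE)
  storage.mode(pairs) <- "integer"
  unname(pairs[, 1:2, drop = FALSE])
}

## Indices (into the rows of `pairs`) of a maximum mutually nested,
## column-disjoint subset. Nussinov-type DP over the distinct columns
## touched by the pairs, maximizing pair count; traceback prefers pairing the
## leftmost column with its smallest admissible partner, which yields the
## lexicographically smallest sorted pair list among maximum subsets.
max_nested_subset <- function(pairs) {
  n <- nrow(pairs)
  if (n == 0L) return(integer(0))
  cols <- sort(unique(c(pairs[, 1L], pairs[, 2L])))
  m <- length(cols)
  ci <- match(pairs[, 1L], cols)
  cj <- match(pairs[, 2L], cols)
  ## partner lists in compressed coordinates: by_i[[a]] = pair rows with ci == a
  by_i <- split(seq_len(n), factor(ci, levels = seq_len(m)))
  N <- matrix(0L, m + 1L, m + 1L)   # N[a, b+1] = best count on cols[a..b]
  for (len in 2:m) {
    if (m < 2L) break
    for (a in seq_len(m - len + 1L)) {
      b <- a + len - 1L
      best <- N[a + 1L, b + 1L]     # column a unpaired
      for (r in by_i[[a]]) {
        k <- cj[r]
        if (k > b) next
        cand <- 1L + (if (k > a + 1L) N[a + 1L, k] else 0L) +
                     (if (k < b) N[k + 1L, b + 1L] else 0L)
        if (cand > best) best <- cand
      }
      N[a, b + 1L] <- best
    }
  }
  sel <- integer(0)
  stack <- list(c(1L, m))
  while (length(stack)) {
    sp <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    a <- sp[1L]; b <- sp[2L]
    if (a >= b) next
    target <- N[a, b + 1L]
    paired <- FALSE
    ## prefer pairing column a with the smallest partner achieving the optimum
    for (r in by_i[[a]][order(cj[by_i[[a]]])]) {
      k <- cj[r]
      if (k > b) next
      cand <- 1L + (if (k > a + 1L) N[a + 1L, k] else 0L) +
                   (if (k < b) N[k + 1L, b + 1L] else 0L)
      if (cand == target) {
        sel <- c(sel, r)
        if (k > a + 1L) stack[[length(stack) + 1L]] <- c(a + 1L, k - 1L)
        if (k < b) stack[[length(stack) + 1L]] <- c(k + 1L, b)
        paired <- TRUE
        break
      }
    }
    if (!paired) stack[[length(stack) + 1L]] <- c(a + 1L, b)
  }
  sort(sel)
}
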