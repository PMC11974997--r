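## Seedable generators for test alignments with planted covarying helices and
## planted motifs, plus the column-shuffle negative control. Covariation is
## simulated by paired compensatory substitutions on a star phylogeny: every
## sequence derives independently from a common ancestor, and helix columns
## co-mutate to Watson-Crick-compatible pairs at a per-sequence rate.

WC_PAIRS <- matrix(c("A", "U", "U", "A", "C", "G", "G", "C", "G", "U",
                     "U", "G"), ncol = 2, byrow = TRUE)

## Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a planted synthetic alignment
#'
#' @param length alignment length (columns).
#' @param n_seqs number of sequences.
#' @param helices list of planted helices: each
#'   `list(pairs = <two-column matrix>, rate = <covariation rate in [0,1]>)`.
#'   At rate r, each sequence resamples each pair jointly to a random
#'   Watson-Crick/wobble pair with probability r (compensatory
#'   substitution), otherwise keeps the ancestral pair.
#' @param motifs list of planted motifs: each `list(name, spans =
#'   list(c(start, end), ...), consensus = <character vector of IUPAC
#'   strings, one per span>)`. Motif columns are drawn per sequence from the
#'   consensus (uniformly within each IUPAC code's residue set), with a
#'   `motif_mutation` chance of a random base instead.
#' @param background_rate per-column substitution probability outside
#'   planted elements. Default 0.05.
#' @param motif_mutation per-column deviation rate inside motif segments.
#'   Default 0.02 (strongly conserved motif consensus).
#' @param seed integer seed.
#' @return list of class `PlantSpec`.
#' @export
plant_spec <- function(length, n_seqs, helices = list(), motifs = list(),
                       background_rate = 0.05, motif_mutation = 0.02,
                       seed = 1L) {
  used <- integer(0)
  for (h in helices) {
    h$pairs <- as_pair_matrix(h$pairs)
    cols <- c(h$pairs)
    if (any(cols < 1L | cols > length)) stop("helix outside alignment")
    used <- c(used, cols)
  }
  for (m in motifs) {
    for (sp in m$spans) {
      if (sp[1L] > sp[2L]) next
      if (sp[1L] < 1L || sp[2L] > length) stop("motif segment outside alignment")
      used <- c(used, sp[1L]:sp[2L])
    }
  }
  if (anyDuplicated(used))
    stop("planted elements overlap")
  structure(list(length = length, n_seqs = n_seqs, helices = helices,
                 motifs = motifs, background_rate = background_rate,
                 motif_mutation = motif_mutation, seed = seed),
            class = "PlantSpec")
}

#' Generate a synthetic alignment with planted helices and motifs
#'
#' @param spec a [plant_spec()].
#' @param weighting profile weighting passed to [profile_alignment()].
#' @return list with `aln` (a `ProfileAlignment`) and `truth`
#'   (list with `pairs`, the planted base pairs, and `motifs`, each with
#'   `name`, `span` and `spans`).
#' @export
generate_plant <- function(spec, weighting = "henikoff") {
  with_seed(spec$seed, {
    L <- spec$length; S <- spec$n_seqs
    anc <- sample(RNA_BASES, L, replace = TRUE)
    all_pairs <- matrix(integer(0), 0, 2)
    for (h in spec$helices) {
      pm <- as_pair_matrix(h$pairs)
      for (r in seq_len(nrow(pm))) {
        wc <- WC_PAIRS[sample.int(nrow(WC_PAIRS), 1L), ]
        anc[pm[r, 1L]] <- wc[1L]; anc[pm[r, 2L]] <- wc[2L]
      }
      all_pairs <- rbind(all_pairs, pm)
    }
    motif_cols <- list()
    for (m in spec$motifs) {
      codes <- character(0); cols <- integer(0)
      for (k in seq_along(m$spans)) {
        sp <- m$spans[[k]]
        if (sp[1L] > sp[2L]) next
        cs <- strsplit(toupper(m$consensus[k]), "")[[1L]]
        stopifnot(length(cs) == sp[2L] - sp[1L] + 1L)
        codes <- c(codes, cs); cols <- c(cols, sp[1L]:sp[2L])
      }
      for (k in seq_along(cols))
        anc[cols[k]] <- sample(IUPAC_SETS[[codes[k]]], 1L)
      motif_cols[[length(motif_cols) + 1L]] <- list(cols = cols, codes = codes)
    }
    seqs <- character(S)
    for (s in seq_len(S)) {
      x <- anc
      ## background substitutions
      bg <- setdiff(seq_len(L),
                    c(all_pairs, unlist(lapply(motif_cols, `[[`, "cols"))))
      hit <- bg[stats::runif(length(bg)) < spec$background_rate]
      if (length(hit)) x[hit] <- sample(RNA_BASES, length(hit), replace = TRUE)
      ## compensatory pair substitutions
      for (h in spec$helices) {
        pm <- as_pair_matrix(h$pairs)
        for (r in seq_len(nrow(pm))) {
          if (stats::runif(1L) < h$rate) {
            wc <- WC_PAIRS[sample.int(nrow(WC_PAIRS), 1L), ]
            x[pm[r, 1L]] <- wc[1L]; x[pm[r, 2L]] <- wc[2L]
          }
        }
      }
      ## motif columns drawn from consensus
      for (mc in motif_cols) {
        for (k in seq_along(mc$cols)) {
          x[mc$cols[k]] <-
            if (stats::runif(1L) < spec$motif_mutation) sample(RNA_BASES, 1L)
            else sample(IUPAC_SETS[[mc$codes[k]]], 1L)
        }
      }
      seqs[s] <- paste(x, collapse = "")
    }
    truth_motifs <- lapply(spec$motifs, function(m) {
      cols <- unlist(lapply(m$spans, function(sp)
        if (sp[1L] <= sp[2L]) sp[1L]:sp[2L] else integer(0)))
      list(name = m$name, span = c(min(cols), max(cols)), spans = m$spans)
    })
    list(aln = profile_alignment(seqs, weighting = weighting),
         truth = list(pairs = all_pairs, motifs = truth_motifs))
  })
}

#' Column-shuffle negative control
#'
#' Permutes the residues of each column independently across sequences,
#' destroying covariation while preserving every column's residue
#' composition (and therefore any sequence signature of motifs at the
#' profile level). Deterministic under `seed`.
#'
#' @param aln a `ProfileAlignment`.
#' @param seed integer seed.
#' @param weighting profile weighting for the shuffled alignment.
#' @return a `ProfileAlignment`.
#' @export
column_shuffle <- function(aln, seed = 1L, weighting = "henikoff") {
  with_seed(seed, {
    chars <- aln_chars(aln)
    if (aln$n_cols > 0L && aln$n_seqs > 1L) {
      for (c in seq_len(aln$n_cols))
        chars[, c] <- chars[sample.int(aln$n_seqs), c]
    }
    seqs <- if (aln$n_cols == 0L) rep("", aln$n_seqs)
            else apply(chars, 1L, paste, collapse = "")
    profile_alignment(seqs, names = aln$seq_names, weighting = weighting)
  })
}
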