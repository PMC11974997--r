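## Alignment input/output and the column-profile representation parsed by the
## folding grammars. All column coordinates are 1-based throughout the package.

GAP_CHARS <- c(".", "-", "_", "~")
RNA_BASES <- c("A", "C", "G", "U")

## IUPAC ambiguity codes mapped to the residue sets they denote.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

#' Construct a profile alignment
#'
#' A `ProfileAlignment` holds aligned RNA sequences together with the
#' per-column residue frequency vectors ("probabilistic sequence") that the
#' grammars parse. `T` is mapped to `U`; the gap characters `.`, `-`, `_`,
#' `~` are unified. IUPAC ambiguity codes are kept in the sequences and
#' distributed fractionally over their residue sets when counting column
#' frequencies, so every column satisfies
#' `sum(col_freq) + col_gapfrac == 1`.
#'
#' @param seqs character vector of aligned sequences (equal lengths).
#' @param names sequence identifiers; defaults to `seq1`, `seq2`, ...
#' @param weights per-sequence weights; `NULL` means compute from
#'   `weighting`. Weights are normalized to sum to the number of sequences.
#' @param weighting `"henikoff"` (position-based weights, the default) or
#'   `"none"` (every sequence counts 1). Ignored when `weights` is given.
#' @return an object of class `ProfileAlignment` with fields `n_seqs`,
#'   `n_cols`, `seq_names`, `seqs`, `weights`, `col_freq` (4 x L matrix with
#'   rows A,C,G,U) and `col_gapfrac`.
#' @export
profile_alignment <- function(seqs, names = NULL,
                              weights = NULL,
                              weighting = c("henikoff", "none")) {
  weighting <- match.arg(weighting)
  if (length(seqs) == 0L) stop("alignment has no sequences")
  if (is.null(names)) names <- names(seqs)
  seqs <- unname(toupper(seqs))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  for (g in GAP_CHARS) seqs <- gsub(g, "-", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (is.null(names)) names <- paste0("seq", seq_along(seqs))
  if (length(unique(lens)) > 1L) {
    bad <- names[which(lens != lens[1L])[1L]]
    stop(sprintf("ragged alignment: sequence '%s' has length %d, expected %d",
                 bad, nchar(seqs[match(bad, names)]), lens[1L]))
  }
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  if (lens[1L] == 0L) chars <- matrix(character(0), nrow = length(seqs), ncol = 0)
  legal <- c(names(IUPAC_SETS), "-")
  badpos <- which(!(chars %in% legal))
  if (length(badpos)) {
    s <- ((badpos[1L] - 1L) %% nrow(chars)) + 1L
    cpos <- ((badpos[1L] - 1L) %/% nrow(chars)) + 1L
    stop(sprintf("non-IUPAC residue '%s' in sequence '%s' at column %d",
                 chars[badpos[1L]], names[s], cpos))
  }
  aln <- structure(
    list(n_seqs = length(seqs), n_cols = lens[1L], seq_names = names,
         seqs = seqs, weights = rep(1, length(seqs)),
         col_freq = NULL, col_gapfrac = NULL),
    class = "ProfileAlignment")
  if (is.null(weights)) {
    compute_profiles(aln, weighting = weighting)
  } else {
    stopifnot(length(weights) == length(seqs), all(weights >= 0))
    aln$weights <- weights / sum(weights) * length(seqs)
    recount_profiles(aln)
  }
}

#' @export
print.ProfileAlignment <- function(x, ...) {
  cat(sprintf("ProfileAlignment: %d sequences x %d columns\n",
              x$n_seqs, x$n_cols))
  invisible(x)
}

## S x L character matrix of residues/gaps.
aln_chars <- function(aln) {
  if (aln$n_cols == 0L) return(matrix(character(0), nrow = aln$n_seqs, ncol = 0))
  do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
}

## Fractional indicator arrays: list of four S x L matrices (A,C,G,U) plus a
## gap matrix; ambiguity codes contribute 1/|set| to each residue in the set.
aln_indicators <- function(aln) {
  chars <- aln_chars(aln)
  S <- aln$n_seqs; L <- aln$n_cols
  ind <- lapply(RNA_BASES, function(b) matrix(0, S, L))
  names(ind) <- RNA_BASES
  gap <- matrix(0, S, L)
  for (code in names(IUPAC_SETS)) {
    hit <- chars == code
    if (!any(hit)) next
    set <- IUPAC_SETS[[code]]
    w <- 1 / length(set)
    for (b in set) ind[[b]][hit] <- ind[[b]][hit] + w
  }
  gap[chars == "-"] <- 1
  list(ind = ind, gap = gap)
}

#' Recompute column profiles under a weighting scheme
#'
#' @param aln a `ProfileAlignment`.
#' @param weighting `"none"` (each sequence counts 1) or `"henikoff"`
#'   (position-based weights: in each column a symbol class with `s` members
#'   out of `r` distinct classes contributes `1/(r*s)` to each of its
#'   sequences; gaps count as a class).
#' @return the alignment with `weights`, `col_freq` and `col_gapfrac`
#'   recomputed; weights sum to `n_seqs`.
#' @export
compute_profiles <- function(aln, weighting = c("henikoff", "none")) {
  weighting <- match.arg(weighting)
  if (weighting == "none" || aln$n_seqs == 1L || aln$n_cols == 0L) {
    aln$weights <- rep(1, aln$n_seqs)
  } else {
    chars <- aln_chars(aln)
    w <- rep(0, aln$n_seqs)
    for (c in seq_len(aln$n_cols)) {
      col <- chars[, c]
      tab <- table(col)
      r <- length(tab)
      w <- w + 1 / (r * as.numeric(tab[col]))
    }
    if (sum(w) == 0) w <- rep(1, aln$n_seqs)
    aln$weights <- w / sum(w) * aln$n_seqs
  }
  recount_profiles(aln)
}

recount_profiles <- function(aln) {
  L <- aln$n_cols
  freq <- matrix(0, 4, L, dimnames = list(RNA_BASES, NULL))
  gapfrac <- numeric(L)
  if (L > 0L) {
    id <- aln_indicators(aln)
    wtot <- sum(aln$weights)
    for (b in RNA_BASES) freq[b, ] <- colSums(id$ind[[b]] * aln$weights) / wtot
    gapfrac <- colSums(id$gap * aln$weights) / wtot
  }
  aln$col_freq <- freq
  aln$col_gapfrac <- gapfrac
  aln
}

## Column frequencies renormalized over A,C,G,U for scoring; all-gap columns
## fall back to the uniform distribution.
norm_col_freq <- function(aln) {
  f <- aln$col_freq
  if (aln$n_cols == 0L) return(f)
  tot <- colSums(f)
  uniform <- tot <= 0
  tot[uniform] <- 1
  f <- sweep(f, 2, tot, "/")
  f[, uniform] <- 0.25
  f
}

## ---------------------------------------------------------------------------
## WUSS consensus-structure strings

WUSS_OPEN  <- c("<", "(", "[", "{")
WUSS_CLOSE <- c(">", ")", "]", "}")

#' Parse a WUSS/dot-bracket string into layered pair sets
#'
#' All bracket types (`<>`, `()`, `[]`, `{}`) are collected into layer 1;
#' each pseudoknot letter pair (`Aa`, `Bb`, ...) forms its own additional
#' layer. Unpaired annotation characters (`.,:_-~`) are ignored.
#'
#' @param wuss structure string.
#' @return object of class `ConsensusStructure`: list with `wuss`,
#'   `pairs_by_layer` (list of two-column matrices of 1-based columns, i < j).
#' @export
wuss_to_structure <- function(wuss) {
  ch <- strsplit(wuss, "", fixed = TRUE)[[1L]]
  nested <- list()
  stacks <- list()
  for (k in seq_along(WUSS_OPEN)) stacks[[k]] <- integer(0)
  letters_stacks <- list()
  layers <- list()
  for (pos in seq_along(ch)) {
    c0 <- ch[pos]
    oi <- match(c0, WUSS_OPEN)
    ci <- match(c0, WUSS_CLOSE)
    if (!is.na(oi)) {
      stacks[[oi]] <- c(stacks[[oi]], pos)
    } else if (!is.na(ci)) {
      n <- length(stacks[[ci]])
      if (n == 0L) stop(sprintf("unbalanced '%s' at position %d", c0, pos))
      nested[[length(nested) + 1L]] <- c(stacks[[ci]][n], pos)
      stacks[[ci]] <- stacks[[ci]][-n]
    } else if (grepl("[A-Z]", c0)) {
      letters_stacks[[c0]] <- c(letters_stacks[[c0]], pos)
    } else if (grepl("[a-z]", c0)) {
      up <- toupper(c0)
      n <- length(letters_stacks[[up]])
      if (n == 0L) stop(sprintf("unbalanced pseudoknot letter '%s' at position %d", c0, pos))
      layers[[up]] <- rbind(layers[[up]], c(letters_stacks[[up]][n], pos))
      letters_stacks[[up]] <- letters_stacks[[up]][-n]
    } else if (!(c0 %in% c(".", ",", ":", "_", "-", "~"))) {
      stop(sprintf("unexpected structure character '%s' at position %d", c0, pos))
    }
  }
  if (any(vapply(stacks, length, 1L) > 0L))
    stop("unbalanced open bracket in structure string")
  pair_layers <- list()
  if (length(nested)) {
    m <- do.call(rbind, nested)
    pair_layers[[1L]] <- m[order(m[, 1L]), , drop = FALSE]
  } else {
    pair_layers[[1L]] <- matrix(integer(0), 0, 2)
  }
  for (up in sort(names(layers))) {
    m <- layers[[up]]
    pair_layers[[length(pair_layers) + 1L]] <- m[order(m[, 1L]), , drop = FALSE]
  }
  ## drop the empty nested layer when there are no pairs at all
  if (nrow(pair_layers[[1L]]) == 0L && length(pair_layers) == 1L)
    pair_layers <- list()
  structure(list(wuss = wuss, pairs_by_layer = pair_layers),
            class = "ConsensusStructure")
}

#' Render layered pair sets as a WUSS string
#'
#' Layer 1 uses `<` `>` brackets; layers 2, 3, ... use pseudoknot letters
#' `Aa`, `Bb`, ... Unpaired columns are `.`.
#'
#' @param pairs_by_layer list of two-column matrices (1-based, i < j).
#' @param n_cols total number of columns.
#' @return a `ConsensusStructure`.
#' @export
structure_to_wuss <- function(pairs_by_layer, n_cols) {
  ch <- rep(".", n_cols)
  if (length(pairs_by_layer) >= 1L) {
    for (li in seq_along(pairs_by_layer)) {
      m <- pairs_by_layer[[li]]
      if (is.null(m) || nrow(m) == 0L) next
      if (li == 1L) { op <- "<"; cl <- ">" }
      else { op <- LETTERS[li - 1L]; cl <- letters[li - 1L] }
      for (r in seq_len(nrow(m))) {
        if (ch[m[r, 1L]] != "." || ch[m[r, 2L]] != ".")
          stop("column assigned twice in structure_to_wuss")
        ch[m[r, 1L]] <- op; ch[m[r, 2L]] <- cl
      }
    }
  }
  structure(list(wuss = paste(ch, collapse = ""),
                 pairs_by_layer = pairs_by_layer),
            class = "ConsensusStructure")
}

## ---------------------------------------------------------------------------
## Stockholm / FASTA

#' Read a Stockholm 1.0 alignment
#'
#' Single- or multi-block Stockholm; `#=GC SS_cons` is parsed into a
#' `ConsensusStructure` when present. Residues are uppercased, `T` mapped to
#' `U` and gap dialects unified.
#'
#' @param path file path.
#' @param weighting passed to [compute_profiles()].
#' @return a `ProfileAlignment`; if the file has an SS_cons line the result
#'   carries it as attribute `"ss_cons"` (a `ConsensusStructure`).
#' @export
read_stockholm <- function(path, weighting = c("henikoff", "none")) {
  weighting <- match.arg(weighting)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1L]))
    stop(sprintf("'%s' is not a Stockholm 1.0 file (missing '# STOCKHOLM' header)", path))
  seqs <- list(); ord <- character(0); ss <- ""
  for (ln in lines[-1L]) {
    if (grepl("^\\s*$", ln) || identical(ln, "//")) next
    if (grepl("^#=GC\\s+SS_cons\\s", ln)) {
      ss <- paste0(ss, sub("^#=GC\\s+SS_cons\\s+", "", ln))
      next
    }
    if (startsWith(ln, "#")) next
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(f) != 2L) stop(sprintf("malformed alignment line: '%s'", ln))
    if (!(f[1L] %in% ord)) { ord <- c(ord, f[1L]); seqs[[f[1L]]] <- "" }
    seqs[[f[1L]]] <- paste0(seqs[[f[1L]]], f[2L])
  }
  if (!length(ord)) stop(sprintf("no sequences found in '%s'", path))
  aln <- profile_alignment(unlist(seqs[ord]), names = ord, weighting = weighting)
  if (nzchar(ss)) {
    if (nchar(ss) != aln$n_cols)
      stop("SS_cons length does not match alignment columns")
    attr(aln, "ss_cons") <- wuss_to_structure(ss)
  }
  aln
}

#' Read FASTA sequences as an alignment
#'
#' Equal-length records are treated as an alignment; a single record becomes
#' a one-sequence alignment.
#'
#' @param path file path.
#' @param weighting passed to [compute_profiles()].
#' @return a `ProfileAlignment`.
#' @export
read_fasta <- function(path, weighting = c("henikoff", "none")) {
  weighting <- match.arg(weighting)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop(sprintf("no FASTA records in '%s'", path))
  names <- sub("^>\\s*", "", lines[hdr])
  names <- vapply(strsplit(names, "\\s+"), `[`, "", 1L)
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (starts[i] > ends[i]) return("")
    paste(lines[starts[i]:ends[i]], collapse = "")
  }, "")
  profile_alignment(seqs, names = names, weighting = weighting)
}

#' Write an alignment with a fold result to Stockholm
#'
#' Emits `#=GC SS_cons` (layer 1 in `<>` brackets, further layers in `Aa`,
#' `Bb`, ... pseudoknot letters) and, for each placed motif, a `#=GC R3D.<n>`
#' line marking the motif's segment columns with a legend in `#=GF` lines.
#' A round-trip read recovers identical pair sets.
#'
#' @param aln a `ProfileAlignment`.
#' @param result a fold result from [fold_rna()], or `NULL` to write the
#'   alignment alone.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(aln, result = NULL, path) {
  lines <- c("# STOCKHOLM 1.0")
  if (!is.null(result)) {
    struct <- result$structure
    if (nchar(struct$wuss) != aln$n_cols)
      stop("fold result column count does not match alignment")
    if (!is.null(result$motifs) && nrow(result$motifs)) {
      for (k in seq_len(nrow(result$motifs))) {
        lines <- c(lines, sprintf("#=GF R3D %d %s variant=%d cols=%s support=%s",
                                  k, result$motifs$motif[k],
                                  result$motifs$variant[k],
                                  result$motifs$segments[k],
                                  ifelse(result$motifs$support[k], "yes", "no")))
      }
    }
  }
  nw <- max(nchar(aln$seq_names), nchar("#=GC SS_cons"))
  fmt <- sprintf("%%-%ds %%s", nw)
  for (s in seq_len(aln$n_seqs))
    lines <- c(lines, sprintf(fmt, aln$seq_names[s], aln$seqs[s]))
  if (!is.null(result)) {
    lines <- c(lines, sprintf(fmt, "#=GC SS_cons", result$structure$wuss))
    if (!is.null(result$motifs) && nrow(result$motifs)) {
      for (k in seq_len(nrow(result$motifs))) {
        track <- rep(".", aln$n_cols)
        for (sp in parse_segment_string(result$motifs$segments[k])) {
          if (sp[1L] <= sp[2L]) track[sp[1L]:sp[2L]] <- "*"
        }
        lines <- c(lines, sprintf(fmt, sprintf("#=GC R3D.%d", k),
                                  paste(track, collapse = "")))
      }
    }
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

## "3..5;7..7;9..8" -> list of c(start, end); start > end denotes an empty span.
parse_segment_string <- function(s) {
  if (!nzchar(s)) return(list())
  lapply(strsplit(s, ";", fixed = TRUE)[[1L]], function(x) {
    as.integer(strsplit(x, "..", fixed = TRUE)[[1L]])
  })
}

format_segment_string <- function(spans) {
  paste(vapply(spans, function(sp) sprintf("%d..%d", sp[1L], sp[2L]), ""),
        collapse = ";")
}
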