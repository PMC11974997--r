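## Shared fixtures and independent oracles for the test suite.

lse <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(v - m)))
}

## Brute-force maximum mutually nested, column-disjoint subset size by
## exhaustive subset enumeration (guard: <= 14 pairs).
brute_max_nested <- function(pairs) {
  n <- nrow(pairs)
  stopifnot(n <= 14L)
  if (n == 0L) return(0L)
  ok <- function(idx) {
    m <- pairs[idx, , drop = FALSE]
    if (anyDuplicated(c(m))) return(FALSE)
    if (nrow(m) < 2L) return(TRUE)
    for (a in seq_len(nrow(m) - 1L)) for (b in (a + 1L):nrow(m)) {
      i <- m[a, 1L]; j <- m[a, 2L]; k <- m[b, 1L]; l <- m[b, 2L]
      if (i > k) { t <- i; i <- k; k <- t; t <- j; j <- l; l <- t }
      if (k < j && j < l) return(FALSE)
    }
    TRUE
  }
  best <- 0L
  for (mask in 0:(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) > best && ok(idx)) best <- length(idx)
  }
  best
}

rand_pair_instance <- function(n, L, seed) {
  set.seed(seed)
  out <- matrix(integer(0), 0, 2)
  seen <- character(0)
  while (nrow(out) < n) {
    ij <- sort(sample.int(L, 2L))
    key <- paste(ij, collapse = ",")
    if (ij[1L] < ij[2L] && !(key %in% seen)) {
      out <- rbind(out, ij)
      seen <- c(seen, key)
    }
  }
  unname(out)
}

## Descriptor subset from the shipped file.
motif_subset <- function(names) {
  desc <- parse_descriptor_file(default_motif_file())
  desc[vapply(desc, function(d) d$name %in% names, TRUE)]
}

## Planted GNRA hairpin: helix (8,19)(9,18)(10,17)(11,16), loop 12..15.
make_gnra_plant <- function(seed, n_seqs = 20L, length = 30L,
                            background_rate = 0.05, rate = 1.0) {
  spec <- plant_spec(length = length, n_seqs = n_seqs,
    helices = list(list(pairs = cbind(8:11, 19:16), rate = rate)),
    motifs = list(list(name = "GNRA", spans = list(c(12, 15)),
                       consensus = "GNRA")),
    background_rate = background_rate, seed = seed)
  generate_plant(spec)
}

## Planted GNRA hairpin + K-turn internal loop in one 46-column alignment.
## Truth spans: GNRA 6..9, K-turn 18..41 (GA bulge, RNN loop, AG).
make_double_plant <- function(seed, n_seqs = 20L) {
  spec <- plant_spec(length = 46, n_seqs = n_seqs,
    helices = list(list(pairs = cbind(3:5, 12:10), rate = 1.0),
                   list(pairs = cbind(15:17, 44:42), rate = 1.0),
                   list(pairs = cbind(20:22, 36:34), rate = 1.0)),
    motifs = list(list(name = "GNRA", spans = list(c(6, 9)),
                       consensus = "GNRA"),
                  list(name = "K-turn",
                       spans = list(c(18, 19), c(37, 39), c(40, 41)),
                       consensus = c("GA", "RNN", "AG"))),
    seed = seed)
  list(plant = generate_plant(spec),
       truth = list(list(name = "GNRA", span = c(6, 9)),
                    list(name = "K-turn", span = c(18, 41))))
}

## Random-parameter grammars for oracle-equivalence tests.
rdirich <- function(n) { x <- stats::rgamma(n, 1); x / sum(x) }

rand_rbg_grammar <- function(seed) {
  set.seed(seed)
  p <- rbg_default_params()
  for (nm in c("S", "F0", "F5", "P", "HL", "BL", "BB", "BT", "MT"))
    p[[nm]][] <- rdirich(length(p[[nm]]))
  p$e_unp[] <- rdirich(4)
  p$e_p0 <- matrix(rdirich(16), 4, 4, dimnames = dimnames(p$e_p0))
  p$e_p5 <- matrix(rdirich(16), 4, 4, dimnames = dimnames(p$e_p5))
  build_rbgj3j4(p)
}

rand_g6x_grammar <- function(seed) {
  set.seed(seed)
  p <- g6x_default_params()
  for (nm in c("S", "L", "F")) p[[nm]][] <- rdirich(length(p[[nm]]))
  p$e_unp[] <- rdirich(4)
  p$e_pair <- matrix(rdirich(16), 4, 4, dimnames = dimnames(p$e_pair))
  build_g6x(p)
}

rand_seq <- function(len) paste(sample(c("A", "C", "G", "U"), len,
                                       replace = TRUE), collapse = "")

## Canonical key of a (pairs, motif annotation) combination.
ann_key <- function(pairs, motifs) {
  pk <- if (is.null(pairs) || nrow(pairs) == 0L) ""
        else paste(sort(paste(pairs[, 1L], pairs[, 2L], sep = ":")),
                   collapse = ";")
  mk <- if (!length(motifs)) ""
        else paste(sort(vapply(motifs, function(m) {
          segs <- if (!is.null(m$segments))
            paste(vapply(m$segments, function(s) paste(s, collapse = "-"), ""),
                  collapse = ",")
          else ""
          paste(m$name, m$variant, paste(m$span, collapse = "-"), segs)
        }, "")), collapse = ";")
  paste(pk, "|", mk)
}

## Grammar with GNRA + K-turn motif models integrated (15 nonterminals).
small_integrated_grammar <- function() {
  models <- expand_all(motif_subset(c("GNRA", "K-turn")))$models
  suppressWarnings(integrate_r3d(build_rbgj3j4(), models))
}

tmpfile <- function(ext = "") tempfile(fileext = ext)
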