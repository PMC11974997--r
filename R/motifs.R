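## RNA 3D motif descriptors and their compilation into sub-grammars whose
## terminals are segment profile HMMs. Six architectures are supported:
##   HL  hairpin-loop motif: up to 4 correlated left/right segment pairs
##       around a final loop segment
##   BL  bulge motif: 5' flank, loop, 3' flank (left- or right-bulge variant)
##   IL  internal-loop motif: outer-stem, loop and inner-stem segments on
##       both strands around the held inner helix
##   J3  3-way junction: three correlated segments between the junction's
##       helix attachment points
##   J4  4-way junction: four correlated segments
##   BS  branch segment: one segment usable in any multiloop branch
## The closing Watson-Crick helices are emitted by the base grammar, never by
## the motif models. Each motif compiles into one sub-grammar per topological
## variant (HL 1, BL 2, IL 2, J3 3, J4 4, BS 1).

MOTIF_TYPES <- c("HL", "BL", "IL", "J3", "J4", "BS")
MAX_HL_PAIRS <- 4L

MOTIF_SEGMENT_KEYS <- list(
  BL = c("flank5", "loop", "flank3"),
  IL = c("outerL", "loopL", "innerL", "innerR", "loopR", "outerR"),
  J3 = c("s1", "s2", "s3"),
  J4 = c("s1", "s2", "s3", "s4"),
  BS = c("seg")
)

N_VARIANTS <- c(HL = 1L, BL = 2L, IL = 2L, J3 = 3L, J4 = 4L, BS = 1L)

#' Parse an R3D motif descriptor file
#'
#' One record per line: `name TYPE key=value ...` where TYPE is one of HL,
#' BL, IL, J3, J4, BS and the keys are the type's segment roles (HL:
#' `left1..left4`, `loop`, `right1..right4` with matching left/right counts;
#' BL: `flank5`, `loop`, `flank3`; IL: `outerL`, `loopL`, `innerL`,
#' `innerR`, `loopR`, `outerR`; J3: `s1..s3`; J4: `s1..s4`; BS: `seg`).
#' Values are IUPAC RNA consensus strings; `-` denotes an empty segment.
#' Missing keys default to empty. Lines starting with `#` are comments.
#'
#' @param path descriptor file path.
#' @return list of `MotifDescriptor` objects in file order.
#' @export
parse_descriptor_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  lapply(lines, parse_descriptor_record)
}

parse_descriptor_record <- function(line) {
  f <- strsplit(trimws(line), "\\s+")[[1L]]
  if (length(f) < 2L) stop(sprintf("malformed motif record: '%s'", line))
  name <- f[1L]; mtype <- f[2L]
  if (!(mtype %in% MOTIF_TYPES))
    stop(sprintf("motif '%s': unknown type keyword '%s'", name, mtype))
  kv <- list()
  for (tok in f[-(1:2)]) {
    m <- regmatches(tok, regexec("^([A-Za-z0-9]+)=(\\S+)$", tok))[[1L]]
    if (length(m) != 3L)
      stop(sprintf("motif '%s': malformed segment token '%s'", name, tok))
    kv[[m[2L]]] <- if (m[3L] == "-") "" else toupper(m[3L])
  }
  keys <- if (mtype == "HL") {
    kp <- names(kv)
    lefts <- sort(kp[grepl("^left[0-9]+$", kp)])
    rights <- sort(kp[grepl("^right[0-9]+$", kp)])
    if (length(lefts) != length(rights) ||
        !identical(sub("left", "", lefts), sub("right", "", rights)))
      stop(sprintf("motif '%s': HL left/right segment pairs must match", name))
    if (length(lefts) > MAX_HL_PAIRS)
      stop(sprintf("motif '%s': at most %d HL segment pairs supported",
                   name, MAX_HL_PAIRS))
    c(lefts, "loop", rights)
  } else MOTIF_SEGMENT_KEYS[[mtype]]
  extra <- setdiff(names(kv), keys)
  if (length(extra))
    stop(sprintf("motif '%s': segment role '%s' not valid for type %s",
                 name, extra[1L], mtype))
  segments <- stats::setNames(
    vapply(keys, function(k) if (is.null(kv[[k]])) "" else kv[[k]], ""), keys)
  for (k in keys) {
    codes <- strsplit(segments[[k]], "")[[1L]]
    bad <- setdiff(codes, names(IUPAC_SETS))
    if (length(bad))
      stop(sprintf("motif '%s': illegal residue code '%s' in segment %s",
                   name, bad[1L], k))
  }
  if (mtype == "HL" && !any(nzchar(segments)))
    stop(sprintf("motif '%s': HL motif needs at least one segment", name))
  structure(list(name = name, mtype = mtype, segments = segments),
            class = "MotifDescriptor")
}

#' Compile a motif descriptor into its variant sub-grammars
#'
#' Each topological variant becomes one new nonterminal with a single rule
#' over segment-HMM atoms (and, for internal-loop and junction motifs, the
#' held inner helices via the base grammar's helix nonterminal). The variant
#' count per type is HL 1, BL 2 (left/right bulge), IL 2, J3 3, J4 4
#' (attachment rotations), BS 1.
#'
#' @param d a `MotifDescriptor`.
#' @param delta per-position deletion probability of the segment HMMs.
#' @return object of class `MotifModel` with fields `descriptor`, `class`
#'   and `variants`.
#' @export
compile_motif <- function(d, delta = 0.01) {
  segs <- d$segments
  hmm_of <- function(role) paste0(d$name, "~", role)
  hmms <- stats::setNames(
    lapply(names(segs), function(k) build_segment_hmm(segs[[k]], delta = delta)),
    vapply(names(segs), hmm_of, ""))
  variants <- list()
  add_variant <- function(v, attach, roles) {
    atoms <- lapply(roles, function(r)
      if (r == "@helix") a_nt("F0") else a_hmm(hmm_of(r)))
    variants[[length(variants) + 1L]] <<-
      list(nt = sprintf("M:%s.v%d", d$name, v), variant = v, attach = attach,
           atoms = atoms, seg_roles = roles[roles != "@helix"])
  }
  if (d$mtype == "HL") {
    lefts <- grep("^left", names(segs), value = TRUE)
    rights <- rev(grep("^right", names(segs), value = TRUE))
    add_variant(1L, "HL", c(lefts, "loop", rights))
  } else if (d$mtype == "BL") {
    roles <- c("flank5", "loop", "flank3")
    add_variant(1L, "BL_L", roles)
    add_variant(2L, "BL_R", roles)
  } else if (d$mtype == "IL") {
    add_variant(1L, "IL", c("outerL", "loopL", "innerL", "@helix",
                            "innerR", "loopR", "outerR"))
    add_variant(2L, "IL", c("innerR", "loopR", "outerR", "@helix",
                            "outerL", "loopL", "innerL"))
  } else if (d$mtype == "J3") {
    rot <- list(c("s1", "s2", "s3"), c("s2", "s3", "s1"), c("s3", "s1", "s2"))
    for (v in 1:3)
      add_variant(v, "J3", c(rot[[v]][1L], "@helix", rot[[v]][2L], "@helix",
                             rot[[v]][3L]))
  } else if (d$mtype == "J4") {
    rot <- list(c("s1", "s2", "s3", "s4"), c("s2", "s3", "s4", "s1"),
                c("s3", "s4", "s1", "s2"), c("s4", "s1", "s2", "s3"))
    for (v in 1:4)
      add_variant(v, "J4", c(rot[[v]][1L], "@helix", rot[[v]][2L], "@helix",
                             rot[[v]][3L], "@helix", rot[[v]][4L]))
  } else { # BS
    add_variant(1L, "BS", "seg")
  }
  stopifnot(length(variants) == N_VARIANTS[[d$mtype]])
  structure(list(descriptor = d, name = d$name, class = d$mtype,
                 hmms = hmms, variants = variants),
            class = "MotifModel")
}

#' Compile every descriptor and report the total variant-model count
#'
#' @param descriptors list of `MotifDescriptor`s.
#' @param delta per-position deletion probability of the segment HMMs.
#' @return list with `models` (list of `MotifModel`) and `n_variants`.
#' @export
expand_all <- function(descriptors, delta = 0.01) {
  nm <- vapply(descriptors, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop(sprintf("duplicate motif name '%s'", nm[duplicated(nm)][1L]))
  models <- lapply(descriptors, compile_motif, delta = delta)
  list(models = models,
       n_variants = sum(vapply(models, function(m) length(m$variants), 1L)))
}

#' Path of the shipped default motif descriptor set
#'
#' A curated set of 51 recurrent RNA 3D motif architectures (15 hairpin-loop,
#' 3 bulge, 23 internal-loop, 5 three-way junction, 3 four-way junction and 2
#' branch-segment motifs) compiled in-house from the motif literature; it
#' expands to 96 variant models.
#'
#' @return file path.
#' @export
default_motif_file <- function() {
  system.file("extdata", "motifs-default.r3d", package = "covfold",
              mustWork = TRUE)
}
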