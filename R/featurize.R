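SCHEMA_VERSION <- "mirlocate-440-v1"

DINUCS <- as.vector(t(outer(RNA_BASES, RNA_BASES, paste0)))
SYMS <- c("(", ")", ".")
SYMPAIRS <- as.vector(t(outer(SYMS, SYMS, paste0)))
TRIPLET_PATTERNS <- c("(((", "((.", "(.(", "(..", ".((", ".(.", "..(", "...")

offset_tags <- function() c(paste0("u", 5:1), "0", paste0("d", 1:5))

#' The fixed 440-feature schema
#'
#' Ordered feature names and group memberships for the duplex encoding:
#' 197 sequence properties (length, mono-/di-nucleotide frequencies, one-hot
#' nucleotide context around the start and end of the duplex 5p and 3p
#' strands), 30 structural properties (duplex energy, base-pair and
#' bulge/loop counts, window pairing averages, perfect-pair runs, positional
#' bulge flags, distances to the terminal loop and to the stem base), 22
#' positional-entropy values around the guide start and end, and 191
#' sequence-structure combination counts (monoSSq, diSS, triplets, each with
#' an undefined bucket).
#'
#' @return data.frame with columns `name`, `group`; attributes
#'   `schema_version` and `energy_method`.
#' @export
feature_schema <- function() {
  ot <- offset_tags()
  nt_block <- function(strand) {
    unlist(lapply(c("start", "end"), function(anchor)
      unlist(lapply(ot, function(o)
        paste0("NT", strand, "_", anchor, "_", o, "_", c("U", "G", "C", "A"))))))
  }
  groups <- list(
    miRNALen = "miRNALen",
    MNC = paste0("MNC_", RNA_BASES),
    DNC = paste0("DNC_", DINUCS),
    NT5p = nt_block("5p"),
    NT3p = nt_block("3p"),
    MFE = "MFE",
    mlBulge = "mlBulge",
    bpNum = "bpNum",
    dist2Loop = "dist2Loop",
    dist2Helix = "dist2Helix",
    numLoop = "numLoop",
    numBulges = "numBulges",
    perfectBP = as.vector(t(outer(c(5, 10, 20), c("presence", "start"),
                                  function(k, w) paste0("perfectBP", k, "_", w)))),
    numBP_Win = paste0("numBP_Win", c(4, 6, 8)),
    Bulges = c(paste0("BulgeAtStart_", ot[3:9]),
               paste0("BulgeAtEnd_", ot[3:9])),
    posEntropy = c(paste0("posEntropyStart_", ot),
                   paste0("posEntropyEnd_", ot)),
    monoSSq = c(paste0("monoSSq_",
                       as.vector(t(outer(RNA_BASES, SYMS, paste0)))),
                "monoSSq_undef"),
    diSS = c(paste0("diSS_",
                    as.vector(t(outer(DINUCS, SYMPAIRS, paste0)))),
             "diSS_undef"),
    triplets = c(as.vector(t(outer(RNA_BASES, TRIPLET_PATTERNS,
                                   function(n, p) paste0("trip_", n, "_", p)))),
                 "trip_undef")
  )
  schema <- data.frame(
    name = unlist(groups, use.names = FALSE),
    group = rep(names(groups), lengths(groups)),
    stringsAsFactors = FALSE)
  stopifnot(nrow(schema) == 440L, !anyDuplicated(schema$name))
  attr(schema, "schema_version") <- SCHEMA_VERSION
  attr(schema, "energy_method") <- "surrogate(-3GC-2AU-1GU)"
  schema
}

# cached schema + name vector (schema construction is deterministic)
the <- new.env(parent = emptyenv())
schema_names <- function() {
  if (is.null(the$names)) the$names <- feature_schema()$name
  the$names
}

#' Precompute per-precursor featurization context
#'
#' Positional entropies, structure symbols, terminal loop and stem extents
#' are shared by every candidate on one pre-miRNA; computing them once makes
#' whole-hairpin candidate scans cheap.
#'
#' @param pre a [premirna()] with structure (and ideally a bppm).
#' @param quiet suppress the degenerate-bppm warning.
#' @return list used by [featurize()].
#' @export
featurize_context <- function(pre, quiet = FALSE) {
  pre <- ensure_bppm(pre, quiet = quiet)
  chars <- seq_chars(pre$sequence)
  symbols <- seq_chars(pre$structure)
  list(pre = pre, chars = chars, symbols = symbols,
       entropy = entropy_profile(pre$bppm),
       loop = terminal_loop(pre$pair_table),
       n = pre$n)
}

onehot_idx <- c(U = 1L, G = 2L, C = 3L, A = 4L)

# 44 bits: offsets -5..+5 around each anchor, 4 bits per position in the
# order U,G,C,A (the codes 1000, 0100, 0010, 0001); out-of-bounds or N -> 0000
nt_context_bits <- function(chars, n, anchor) {
  bits <- numeric(44)
  pos <- anchor + (-5:5)
  ok <- pos >= 1L & pos <= n
  nt <- chars[pos[ok]]
  idx <- onehot_idx[nt]
  keep <- !is.na(idx)
  slots <- (which(ok)[keep] - 1L) * 4L + idx[keep]
  bits[slots] <- 1
  bits
}

#' Sequence composition of a guide
#'
#' @param guide_seq guide (mature miRNA) sequence.
#' @return named vector: `miRNALen`, 4 mononucleotide frequencies, 16
#'   dinucleotide frequencies (N-containing words are dropped from the
#'   numerators; denominators are L and L-1).
#' @export
seq_composition <- function(guide_seq) {
  chars <- seq_chars(normalize_rna(guide_seq))
  L <- length(chars)
  if (L < 2L) ml_stop("guide must be at least 2 nt", "mirlocate_invalid_params")
  mnc <- tabulate(factor(chars, levels = RNA_BASES), nbins = 4L) / L
  di <- paste0(chars[-L], chars[-1L])
  dnc <- tabulate(factor(di, levels = DINUCS), nbins = 16L) / (L - 1L)
  c(miRNALen = L,
    stats::setNames(mnc, paste0("MNC_", RNA_BASES)),
    stats::setNames(dnc, paste0("DNC_", DINUCS)))
}

#' Pairing statistics along the guide
#'
#' @param guide_states logical vector: is each guide position paired in the
#'   duplex?
#' @return named vector: `bpNum`, `mlBulge`, windowed pairing means
#'   (`numBP_Win4/6/8`), and presence/start of perfect-pair runs of length at
#'   least 5, 10, 20 (start is 0-based from the guide 5' end; -1 if absent).
#' @export
pairing_stats <- function(guide_states) {
  L <- length(guide_states)
  runs <- true_runs(guide_states)
  win_mean <- function(X) {
    if (L < X) return(sum(guide_states))
    cs <- cumsum(c(0L, guide_states))
    mean(cs[(X + 1L):(L + 1L)] - cs[1L:(L - X + 1L)])
  }
  perfect <- function(k) {
    hit <- which(runs$length >= k)
    if (length(hit)) c(1, runs$start[hit[1]] - 1L) else c(0, -1)
  }
  out <- c(bpNum = sum(guide_states),
           mlBulge = if (length(runs$length)) max(runs$length) else 0L,
           perfectBP5 = perfect(5), perfectBP10 = perfect(10),
           perfectBP20 = perfect(20),
           numBP_Win4 = win_mean(4L), numBP_Win6 = win_mean(6L),
           numBP_Win8 = win_mean(8L))
  names(out) <- c("bpNum", "mlBulge",
                  "perfectBP5_presence", "perfectBP5_start",
                  "perfectBP10_presence", "perfectBP10_start",
                  "perfectBP20_presence", "perfectBP20_start",
                  "numBP_Win4", "numBP_Win6", "numBP_Win8")
  out
}

# 14 flags: does the position at offset -3..+3 from the guide start (then
# end) belong to a bulge run of the duplex? Out-of-bounds offsets are 0.
bulge_context_flags <- function(duplex, bulge_pos) {
  flag <- function(anchor) as.numeric((anchor + (-3:3)) %in% bulge_pos)
  c(flag(duplex$guide[1]), flag(duplex$guide[2]))
}

# 22 entropies: H at offsets -5..+5 around guide start and end; 0 outside
entropy_context_values <- function(entropy, n, duplex) {
  grab <- function(anchor) {
    pos <- anchor + (-5:5)
    ifelse(pos >= 1L & pos <= n, entropy[pmax(pmin(pos, n), 1L)], 0)
  }
  c(grab(duplex$guide[1]), grab(duplex$guide[2]))
}

#' Sequence-structure combination counts over the guide
#'
#' `monoSSq`: counts of (nucleotide, structure symbol) pairs, 12 + an
#' undefined bucket for N. `diSS`: counts of (dinucleotide, symbol pair) over
#' adjacent positions, 144 + undefined. `triplets`: counts keyed by the
#' middle nucleotide and the paired/unpaired pattern of the three positions
#' centred on it (both bracket orientations collapse to "paired"), 32 +
#' undefined. Sums equal L, L-1 and L-2 respectively.
#'
#' @param guide_chars,guide_syms character vectors of the guide's
#'   nucleotides and dot-bracket symbols.
#' @return named vector of 13 + 145 + 33 counts.
#' @export
seq_struct_combos <- function(guide_chars, guide_syms) {
  L <- length(guide_chars)
  nt <- match(guide_chars, RNA_BASES)          # NA for N
  sy <- match(guide_syms, SYMS)

  # monoSSq slot = (nt-1)*3 + sym; slot 13 = undefined
  slot <- (nt - 1L) * 3L + sy
  slot[is.na(slot)] <- 13L
  mono <- tabulate(slot, 13L)

  # diSS slot = (dinuc-1)*9 + sympair; slot 145 = undefined
  if (L >= 2L) {
    dinuc <- (nt[-L] - 1L) * 4L + nt[-1L]
    sympair <- (sy[-L] - 1L) * 3L + sy[-1L]
    slot <- (dinuc - 1L) * 9L + sympair
    slot[is.na(slot)] <- 145L
    di <- tabulate(slot, 145L)
  } else di <- numeric(145)

  # triplets: collapsed paired=0 / unpaired=1 bits of (i-1, i, i+1) index the
  # pattern ((( ((. (.( (.. .(( .(. ..( ...; slot 33 = undefined middle base
  if (L >= 3L) {
    un <- as.integer(guide_syms == ".")
    mid <- 2L:(L - 1L)
    patt <- un[mid - 1L] * 4L + un[mid] * 2L + un[mid + 1L] + 1L
    slot <- (nt[mid] - 1L) * 8L + patt
    slot[is.na(slot)] <- 33L
    tri <- tabulate(slot, 33L)
  } else tri <- numeric(33)

  out <- c(mono, di, tri)
  names(out) <- combo_names()
  out
}

combo_names <- function() {
  if (is.null(the$combo_names))
    the$combo_names <- c(
      paste0("monoSSq_", as.vector(t(outer(RNA_BASES, SYMS, paste0)))),
      "monoSSq_undef",
      paste0("diSS_", as.vector(t(outer(DINUCS, SYMPAIRS, paste0)))),
      "diSS_undef",
      as.vector(t(outer(RNA_BASES, TRIPLET_PATTERNS,
                        function(n, p) paste0("trip_", n, "_", p)))),
      "trip_undef")
  the$combo_names
}

#' Encode one (pre-miRNA, duplex) pair as the 440-feature vector
#'
#' Pure function of its inputs: the same hairpin and guide interval always
#' produce the same vector. The MFE slot uses the documented surrogate duplex
#' energy (see [duplex_energy()]); the schema records this.
#'
#' @param pre a [premirna()].
#' @param duplex a [derive_duplex()] result on `pre`.
#' @param ctx optional [featurize_context()] for `pre` (computed if missing).
#' @return named numeric vector of length 440 with attribute
#'   `schema_version`.
#' @export
featurize <- function(pre, duplex, ctx = NULL) {
  if (is.null(ctx)) ctx <- featurize_context(pre)
  gs <- duplex$guide[1]; ge <- duplex$guide[2]
  guide_chars <- ctx$chars[gs:ge]
  guide_syms <- ctx$symbols[gs:ge]

  # strand-of-arm anchors: the duplex "5p strand" is whichever of guide/star
  # lies on the 5' arm, and anchors are its 5' (start) and 3' (end) ends
  if (duplex$arm == "5p") {
    iv5 <- duplex$guide; iv3 <- duplex$star
  } else {
    iv5 <- duplex$star; iv3 <- duplex$guide
  }
  nt5 <- c(nt_context_bits(ctx$chars, ctx$n, iv5[1]),
           nt_context_bits(ctx$chars, ctx$n, iv5[2]))
  nt3 <- c(nt_context_bits(ctx$chars, ctx$n, iv3[1]),
           nt_context_bits(ctx$chars, ctx$n, iv3[2]))

  walk <- duplex_elements(duplex)
  el <- structural_elements(pre, duplex, walk)
  bulge_pos <- walk$bulge_pos
  vec <- c(seq_composition(paste(guide_chars, collapse = "")),
           nt5, nt3,
           MFE = surrogate_duplex_energy(pre, duplex),
           mlBulge = el$mlBulge,
           bpNum = el$bpNum,
           dist2Loop = el$dist2Loop,
           dist2Helix = el$dist2Helix,
           numLoop = el$numLoop,
           numBulges = el$numBulges,
           pairing_stats(duplex$guide_states)[3:11],
           bulge_context_flags(duplex, bulge_pos),
           entropy_context_values(ctx$entropy, ctx$n, duplex),
           seq_struct_combos(guide_chars, guide_syms))
  if (length(vec) != 440L)
    ml_stop(sprintf("feature encoder emitted %d values, expected 440",
                    length(vec)), "mirlocate_schema_mismatch")
  names(vec) <- schema_names()
  attr(vec, "schema_version") <- SCHEMA_VERSION
  vec
}
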