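#' Parse a dot-bracket secondary structure into a pair table
#'
#' Stack-based parse of a Vienna dot-bracket string. Position `i` paired with
#' `j` yields `pair_table[i] == j` and `pair_table[j] == i`; unpaired
#' positions map to the sentinel `0`.
#'
#' @param db dot-bracket string over `(`, `)`, `.`.
#' @return integer vector (1-based pair table) of the same length as `db`.
#' @export
#' @examples
#' parse_dotbracket("((...))")
parse_dotbracket <- function(db) {
  if (!is.character(db) || length(db) != 1L || nchar(db) == 0L)
    ml_stop("dot-bracket string must be a nonempty character scalar",
            "mirlocate_invalid_structure")
  chars <- seq_chars(db)
  if (any(!chars %in% c("(", ")", ".")))
    ml_stop("dot-bracket alphabet is {(, ), .}", "mirlocate_invalid_structure")
  n <- length(chars)
  pt <- integer(n)
  stack <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      top <- top + 1L
      stack[top] <- i
    } else if (chars[i] == ")") {
      if (top == 0L)
        ml_stop(sprintf("unbalanced structure: surplus ')' at position %d", i),
                "mirlocate_unbalanced_structure")
      pt[i] <- stack[top]
      pt[stack[top]] <- i
      top <- top - 1L
    }
  }
  if (top > 0L)
    ml_stop(sprintf("unbalanced structure: %d unmatched '('", top),
            "mirlocate_unbalanced_structure")
  pt
}

#' Serialize a pair table back to dot-bracket notation
#'
#' Inverse of [parse_dotbracket()] for nested (pseudoknot-free) tables.
#'
#' @param pt integer pair table (0 = unpaired).
#' @return dot-bracket string.
#' @export
serialize_pair_table <- function(pt) {
  out <- rep(".", length(pt))
  paired <- which(pt > 0L)
  out[paired[pt[paired] > paired]] <- "("
  out[paired[pt[paired] < paired]] <- ")"
  paste(out, collapse = "")
}

validate_bppm <- function(bppm, n, tol = 1e-6) {
  if (!is.matrix(bppm) || nrow(bppm) != n || ncol(bppm) != n)
    ml_stop("bppm must be an n x n matrix", "mirlocate_invalid_probability")
  if (anyNA(bppm) || any(bppm < -tol) || any(bppm > 1 + tol))
    ml_stop("base-pair probabilities must lie in [0, 1]",
            "mirlocate_invalid_probability")
  if (max(abs(bppm - t(bppm))) > tol)
    ml_stop("bppm must be symmetric", "mirlocate_invalid_probability")
  rs <- rowSums(bppm)
  if (any(rs > 1 + 1e-4))
    ml_stop(sprintf("total pairing probability exceeds 1 at position %d",
                    which.max(rs)), "mirlocate_invalid_probability")
  invisible(TRUE)
}

#' Construct a pre-miRNA hairpin object
#'
#' Bundles a precursor sequence with its secondary structure and, optionally,
#' its base-pair probability matrix. Sequences are normalized to uppercase RNA
#' (T becomes U); `N` is allowed but never pairs. Coordinates throughout the
#' package are 1-based inclusive (miRBase convention).
#'
#' @param id record identifier.
#' @param sequence RNA or DNA sequence.
#' @param structure dot-bracket string of the same length, or `NULL`.
#' @param mfe minimum free energy (kcal/mol) of `structure`, if known.
#' @param bppm optional symmetric matrix of base-pair probabilities.
#' @param engine optional name/version string of the folding engine used.
#' @return an object of class `premirna`.
#' @export
premirna <- function(id, sequence, structure = NULL, mfe = NA_real_,
                     bppm = NULL, engine = NA_character_) {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  pt <- NULL
  if (!is.null(structure)) {
    if (nchar(structure) != n)
      ml_stop("structure and sequence lengths differ",
              "mirlocate_invalid_structure")
    pt <- parse_dotbracket(structure)
    paired <- which(pt > 0L & pt > seq_len(n))
    if (any(pt[paired] - paired < 4L))
      ml_stop("hairpin loop shorter than 3 unpaired bases",
              "mirlocate_invalid_structure")
  }
  if (!is.null(bppm)) validate_bppm(bppm, n)
  structure(
    list(id = id, sequence = sequence, structure = structure,
         pair_table = pt, mfe = mfe, bppm = bppm, engine = engine,
         n = n),
    class = "premirna")
}

#' @export
print.premirna <- function(x, ...) {
  cat(sprintf("<premirna> %s (%d nt%s)\n", x$id, x$n,
              if (is.na(x$mfe)) "" else sprintf(", MFE %.2f kcal/mol", x$mfe)))
  cat(" ", x$sequence, "\n", sep = "")
  if (!is.null(x$structure)) cat(" ", x$structure, "\n", sep = "")
  invisible(x)
}

#' Positional entropy of the pairing state at one position
#'
#' Shannon entropy (in bits) of the pairing distribution of position `i`:
#' the outcomes are "pair with j" for each partner j (probability `p_ij`)
#' plus "unpaired" (probability `1 - sum_j p_ij`). It is 0 when the state is
#' forced (all mass on one outcome) and `log2(n)` when the mass is spread
#' uniformly over `n` partners, quantifying the cleavage specificity of each
#' position along the precursor.
#'
#' @param bppm base-pair probability matrix.
#' @param i position (1-based).
#' @return entropy in bits, `>= 0`.
#' @export
positional_entropy <- function(bppm, i) {
  n <- nrow(bppm)
  if (i < 1L || i > n)
    ml_stop("position out of range", "mirlocate_invalid_probability")
  validate_bppm(bppm, n)
  p <- bppm[i, ]
  q <- max(0, 1 - sum(p))
  p <- c(p[p > 0], if (q > 0) q)
  if (!length(p)) return(0)
  max(0, -sum(p * log2(p)))   # clamp the -0 of a pure point mass
}

# entropy at every position; skips revalidation (assumed validated upstream)
entropy_profile <- function(bppm) {
  q <- pmax(0, 1 - rowSums(bppm))
  h <- -rowSums(ifelse(bppm > 0, bppm * log2(bppm), 0))
  h - ifelse(q > 0, q * log2(q), 0)
}

# point-mass bppm from an MFE pair table: every MFE pair gets p = 1, so all
# positional entropies are exactly 0 (used when no partition function exists)
degenerate_bppm <- function(pt) {
  n <- length(pt)
  m <- matrix(0, n, n)
  paired <- which(pt > 0L)
  m[cbind(paired, pt[paired])] <- 1
  m
}

# guarantee pre$bppm, synthesizing the degenerate matrix with a warning
ensure_bppm <- function(pre, quiet = FALSE) {
  if (!is.null(pre$bppm)) return(pre)
  if (is.null(pre$pair_table))
    ml_stop(sprintf("pre-miRNA %s has no structure", pre$id),
            "mirlocate_engine_unavailable")
  if (!quiet)
    ml_warn(sprintf(paste("no base-pair probabilities for %s;",
                          "using point-mass probabilities from the MFE",
                          "structure (entropy features will be 0)"), pre$id),
            "mirlocate_degenerate_bppm")
  pre$bppm <- degenerate_bppm(pre$pair_table)
  pre
}

# number of hairpin (terminal) loops in a pair table; >1 means multibranched
hairpin_count <- function(pt) {
  br <- seq_chars(serialize_pair_table(pt))
  br <- br[br != "."]
  if (!length(br)) return(0L)
  sum(br[-length(br)] == "(" & br[-1] == ")")
}

# terminal loop interval c(lo, hi) of a single-hairpin pair table
terminal_loop <- function(pt) {
  n <- length(pt)
  paired <- which(pt > 0L)
  if (!length(paired)) return(NULL)
  if (hairpin_count(pt) != 1L)
    ml_stop("structure has more than one terminal loop (multibranched)",
            "mirlocate_multibranch")
  # innermost pair: last '(' before the first ')'
  opens <- which(pt > seq_len(n))
  closes <- which(pt > 0L & pt < seq_len(n))
  i <- max(opens[opens < min(closes)])
  c(i + 1L, pt[i] - 1L)
}
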