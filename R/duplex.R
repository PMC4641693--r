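#' Derive the miRNA:miRNA* duplex for a guide interval
#'
#' Given a folded pre-miRNA and a candidate guide (mature miRNA) interval,
#' traces the guide's outermost base pairs through the pair table to obtain
#' the passenger (star) interval on the opposite arm, then extends the star's
#' 3' end by up to 2 nt (Dicer-style overhang), truncated at the sequence end
#' and at the guide boundary. The arm label compares the guide midpoint with
#' the terminal-loop midpoint.
#'
#' Guide positions whose partner lies inside the guide itself (a guide
#' spanning the terminal loop can pair with itself) are treated as unpaired
#' for duplex purposes.
#'
#' @param pre a [premirna()] with a structure.
#' @param guide integer vector `c(start, end)`, 1-based inclusive.
#' @param loop precomputed terminal-loop interval (internal fast path for
#'   whole-hairpin candidate scans).
#' @return an object of class `mirna_duplex` with fields `guide`, `star`,
#'   `arm`, `guide_states`, `star_states`, `pairs`, `pre_ref`.
#' @export
derive_duplex <- function(pre, guide, loop = NULL) {
  if (is.null(pre$pair_table))
    ml_stop(sprintf("pre-miRNA %s has no structure", pre$id),
            "mirlocate_engine_unavailable")
  gs <- as.integer(guide[1]); ge <- as.integer(guide[2])
  if (gs < 1L || ge > pre$n || gs > ge)
    ml_stop("guide interval out of bounds", "mirlocate_invalid_params")
  pt <- pre$pair_table
  gpos <- gs:ge
  partner <- pt[gpos]
  if (is.null(loop)) loop <- terminal_loop(pt)   # rejects multibranch input
  outward <- partner > 0L & (partner < gs | partner > ge)
  if (!any(outward))
    ml_stop("guide has no base pairs outside itself",
            "mirlocate_no_paired_bases")
  g1 <- gpos[which(outward)[1]]              # first (5'-most) duplex-paired base
  g2 <- gpos[rev(which(outward))[1]]         # last duplex-paired base
  star_lo <- pt[g2]
  star_hi <- pt[g1]
  if (star_lo > star_hi || (star_lo <= ge && star_hi >= gs))
    ml_stop("guide pairs on both sides of the terminal loop; no coherent star",
            "mirlocate_no_paired_bases")
  ext_cap <- if (star_lo > ge) pre$n else gs - 1L
  star_hi <- min(star_hi + 2L, ext_cap)
  spos <- star_lo:star_hi
  guide_states <- pt[gpos] >= star_lo & pt[gpos] <= star_hi
  star_states <- pt[spos] >= gs & pt[spos] <= ge
  pairs <- list(g = gpos[guide_states], s = pt[gpos][guide_states])
  mid_guide <- (gs + ge) / 2
  mid_loop <- (loop[1] + loop[2]) / 2
  structure(
    list(pre_ref = pre$id,
         guide = c(gs, ge), star = c(star_lo, star_hi),
         arm = if (mid_guide < mid_loop) "5p" else "3p",
         guide_states = guide_states, star_states = star_states,
         pairs = pairs, loop = loop),
    class = "mirna_duplex")
}

#' @export
print.mirna_duplex <- function(x, ...) {
  cat(sprintf("<mirna_duplex> %s guide %d-%d (%s) star %d-%d, %d bp\n",
              x$pre_ref, x$guide[1], x$guide[2], x$arm,
              x$star[1], x$star[2], length(x$pairs$g)))
  invisible(x)
}

# interior bulge/loop walk between consecutive duplex pairs.
# Returns per-element classification plus the unpaired positions involved.
duplex_elements <- function(duplex) {
  p <- duplex$pairs                      # g is ascending by construction
  np <- length(p$g)
  numLoop <- 0L; numBulges <- 0L
  bulge_pos <- integer(0)
  if (np > 1L) {
    for (k in seq_len(np - 1L)) {
      a <- p$g[k + 1L] - p$g[k] - 1L          # unpaired guide bases in the gap
      b <- p$s[k] - p$s[k + 1L] - 1L          # unpaired star bases (s descends)
      gpos <- if (a > 0L) (p$g[k] + 1L):(p$g[k + 1L] - 1L) else integer(0)
      spos <- if (b > 0L) (p$s[k + 1L] + 1L):(p$s[k] - 1L) else integer(0)
      if (a > 0L && b > 0L) {
        numLoop <- numLoop + 1L
      } else if (a > 0L || b > 0L) {
        numBulges <- numBulges + 1L
        bulge_pos <- c(bulge_pos, gpos, spos)
      }
    }
  }
  # unpaired guide overhangs at either duplex end are one-sided by nature:
  # they feed the positional bulge flags but not the interior element counts
  gs <- duplex$guide[1]; ge <- duplex$guide[2]
  if (np) {
    if (p$g[1] > gs) bulge_pos <- c(bulge_pos, gs:(p$g[1] - 1L))
    if (p$g[np] < ge) bulge_pos <- c(bulge_pos, (p$g[np] + 1L):ge)
  }
  list(numLoop = numLoop, numBulges = numBulges, bulge_pos = sort(bulge_pos))
}

#' Summarize the structural elements of a duplex
#'
#' Interior unpaired runs on exactly one strand are bulges; runs facing each
#' other on both strands are internal loops; the terminal loop is never
#' counted. `mlBulge` is the longest stretch of consecutively paired guide
#' bases (the maximal bulge-free run). `dist2Loop` separates the
#' loop-proximal guide end from the first terminal-loop base, `dist2Helix`
#' the other guide end from the outermost paired base of the hairpin stem.
#'
#' @param pre a [premirna()].
#' @param duplex a [derive_duplex()] result.
#' @param el precomputed [duplex_elements()] walk (internal fast path).
#' @return list with `bpNum`, `numLoop`, `numBulges`, `mlBulge`,
#'   `dist2Loop`, `dist2Helix`.
#' @export
structural_elements <- function(pre, duplex, el = duplex_elements(duplex)) {
  runs <- true_runs(duplex$guide_states)
  pt <- pre$pair_table
  paired_all <- which(pt > 0L)
  helix_lo <- min(paired_all); helix_hi <- max(paired_all)
  loop <- duplex$loop
  gs <- duplex$guide[1]; ge <- duplex$guide[2]
  if (duplex$arm == "5p") {
    dist2Loop <- max(0L, loop[1] - ge - 1L)
    dist2Helix <- max(0L, gs - helix_lo)
  } else {
    dist2Loop <- max(0L, gs - loop[2] - 1L)
    dist2Helix <- max(0L, helix_hi - ge)
  }
  list(bpNum = length(duplex$pairs$g),
       numLoop = el$numLoop,
       numBulges = el$numBulges,
       mlBulge = if (length(runs$length)) max(runs$length) else 0L,
       dist2Loop = dist2Loop,
       dist2Helix = dist2Helix)
}

#' Free energy of a miRNA:miRNA* duplex
#'
#' With an engine that has the `two_strand` capability (the `rnafold` engine
#' wraps `RNAcofold`), the two excised strands are co-folded and the MFE
#' returned. Otherwise a documented surrogate is used: `-(3 GC + 2 AU + 1
#' GU)` summed over the duplex base pairs — a Turner-flavoured pair-stability
#' score, not a thermodynamic energy. A zero-pair duplex scores 0 by
#' convention.
#'
#' @param pre a [premirna()].
#' @param duplex a [derive_duplex()] result.
#' @param engine optional [fold_engine()]; `NULL` means surrogate.
#' @return energy-like value in kcal/mol (surrogate: pair-score units).
#' @export
duplex_energy <- function(pre, duplex, engine = NULL) {
  if (!is.null(engine) && isTRUE(engine$two_strand)) {
    g <- substr(pre$sequence, duplex$guide[1], duplex$guide[2])
    s <- substr(pre$sequence, duplex$star[1], duplex$star[2])
    out <- suppressWarnings(system2(
      "RNAcofold", "--noPS",
      input = paste0(g, "&", s), stdout = TRUE, stderr = FALSE))
    m <- regmatches(out[2], regexec("\\(\\s*(-?[0-9.]+)\\)\\s*$", out[2]))[[1]]
    if (length(m) == 2L) return(as.numeric(m[2]))
    ml_stop("RNAcofold output not parseable", "mirlocate_engine_unavailable")
  }
  surrogate_duplex_energy(pre, duplex)
}

surrogate_duplex_energy <- function(pre, duplex) {
  if (!length(duplex$pairs$g)) return(0)
  ch <- seq_chars(pre$sequence)
  a <- ch[duplex$pairs$g]; b <- ch[duplex$pairs$s]
  pair <- paste0(pmin(a, b), pmax(a, b))
  -sum(c(CG = 3, AU = 2, GU = 1)[pair], na.rm = TRUE)
}
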