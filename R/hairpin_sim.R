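#' Generate one synthetic pre-miRNA hairpin with a planted guide
#'
#' Emulates a hairpin-structured precursor: a random 5' arm, a short
#' terminal loop, and a 3' arm built as the reverse complement of the 5' arm
#' with Bernoulli(`bulge_rate`) distortions (half 1-nt insertions, half
#' mismatches). A guide strand of `guide_len` nt is planted on one arm with
#' its loop-proximal end 0-3 nt from the terminal loop; the guide's duplex
#' footprint is protected from distortions, so the planted mature miRNA sits
#' in a clean helix the way real miRNA duplexes mostly do, while the rest of
#' the stem carries the bulges. The guide emulates the documented base
#' composition of plant mature miRNAs — U-rich and G-poor
#' (U 0.35, A 0.25, G 0.20, C 0.20) with the canonical 5' U identity —
#' which is what distinguishes a mature strand from its passenger in
#' composition-aware classifiers; the rest of the hairpin is uniform.
#'
#' @param stem_len 5' arm length in nt (`>= guide_len`).
#' @param loop_len terminal loop length in nt (`>= 3`).
#' @param guide_len planted mature miRNA length (`>= 16`).
#' @param bulge_rate per-position distortion probability in `[0, 0.3)`.
#' @param seed optional RNG seed (byte-identical output for a fixed seed).
#' @param arm `"random"`, `"5p"` or `"3p"`: where the guide is planted.
#' @param id record identifier.
#' @return list with `id`, `sequence`, `guide_start`, `guide_end`, `arm`,
#'   and the generator `params` (1-based inclusive coordinates).
#' @export
generate_hairpin <- function(stem_len = 45, loop_len = 8, guide_len = 21,
                             bulge_rate = 0.05, seed = NULL,
                             arm = c("random", "5p", "3p"), id = "synth1") {
  arm <- match.arg(arm)
  if (stem_len < guide_len || guide_len < 16 || loop_len < 3 ||
      bulge_rate < 0 || bulge_rate >= 0.3)
    ml_stop("need stem_len >= guide_len >= 16, loop_len >= 3, 0 <= bulge_rate < 0.3",
            "mirlocate_invalid_params")
  if (!is.null(seed)) set.seed(seed)
  arm5 <- sample(RNA_BASES, stem_len, replace = TRUE)
  loop <- sample(RNA_BASES, loop_len, replace = TRUE)
  if (arm == "random") arm <- sample(c("5p", "3p"), 1L)
  delta <- sample(0:min(3L, stem_len - guide_len), 1L)
  b <- stem_len - delta                  # loop-proximal end of the footprint
  a <- b - guide_len + 1L
  # mature-strand composition bias (A, C, G, U): the guide itself is drawn
  # from the plant-miRNA-like distribution; for a 3p guide the footprint on
  # the 5' arm is the guide's complement, hence the mirrored weights
  guide_comp <- c(0.25, 0.20, 0.20, 0.35)
  arm5[a:b] <- if (arm == "5p") {
    sample(RNA_BASES, guide_len, replace = TRUE, prob = guide_comp)
  } else {
    sample(RNA_BASES, guide_len, replace = TRUE, prob = guide_comp[c(4, 3, 2, 1)])
  }
  # canonical 5' U: arm5[a] for a 5p guide, the complement of arm5[b] for 3p
  if (stats::runif(1) < 0.9) {
    if (arm == "5p") arm5[a] <- "U" else arm5[b] <- "A"
  }
  protected <- logical(stem_len)
  protected[a:b] <- TRUE
  arm3 <- character(0)
  pos3 <- integer(stem_len)              # arm3 index of complement of arm5[i]
  for (i in stem_len:1) {
    if (!protected[i] && stats::runif(1) < bulge_rate) {
      if (stats::runif(1) < 0.5) {       # insertion: extra unpaired base
        arm3 <- c(arm3, sample(RNA_BASES, 1L))
        arm3 <- c(arm3, RNA_COMPLEMENT[[arm5[i]]])
      } else {                           # mismatch
        arm3 <- c(arm3, sample(setdiff(RNA_BASES, RNA_COMPLEMENT[[arm5[i]]]), 1L))
      }
    } else {
      arm3 <- c(arm3, RNA_COMPLEMENT[[arm5[i]]])
    }
    pos3[i] <- length(arm3)
  }
  if (arm == "5p") {
    gs <- a; ge <- b
  } else {
    gs <- stem_len + loop_len + pos3[b]
    ge <- stem_len + loop_len + pos3[a]
  }
  list(id = id,
       sequence = paste(c(arm5, loop, arm3), collapse = ""),
       guide_start = gs, guide_end = ge, arm = arm,
       params = list(stem_len = stem_len, loop_len = loop_len,
                     guide_len = guide_len, bulge_rate = bulge_rate,
                     seed = seed))
}

#' Simulate an annotated corpus of synthetic hairpins
#'
#' @param n number of hairpins.
#' @param seed RNG seed; the whole corpus is reproducible from it.
#' @param ... passed to [generate_hairpin()] (except `seed`/`id`).
#' @param id_prefix id stem for the records.
#' @return list with `sequences` (named character vector), `annotations`
#'   (data.frame `premirna_id`, `start`, `end`, `arm`), and `params`.
#' @export
simulate_corpus <- function(n, seed = 1, id_prefix = "synth", ...) {
  set.seed(seed)
  hp <- lapply(seq_len(n), function(i)
    generate_hairpin(..., id = sprintf("%s%04d", id_prefix, i)))
  list(
    sequences = stats::setNames(vapply(hp, `[[`, character(1), "sequence"),
                                vapply(hp, `[[`, character(1), "id")),
    annotations = data.frame(
      premirna_id = vapply(hp, `[[`, character(1), "id"),
      start = vapply(hp, `[[`, numeric(1), "guide_start"),
      end = vapply(hp, `[[`, numeric(1), "guide_end"),
      arm = vapply(hp, `[[`, character(1), "arm"),
      stringsAsFactors = FALSE),
    params = c(hp[[1]]$params[c("stem_len", "loop_len", "guide_len",
                                "bulge_rate")],
               list(n = n, seed = seed)))
}
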