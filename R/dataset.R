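# resolve one annotation row to a guide interval on its pre-miRNA.
# Sequence annotations occurring several times keep the occurrence with the
# most duplex base pairs (ties: leftmost). Returns NULL when unresolvable.
resolve_annotation <- function(pre, ann) {
  if (!is.na(ann$start %||% NA) && !is.na(ann$end %||% NA))
    return(c(as.integer(ann$start), as.integer(ann$end)))
  mat <- normalize_rna(ann$mirna_seq)
  hits <- gregexpr(mat, pre$sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(NULL)
  L <- nchar(mat)
  if (length(hits) > 1L) {
    bp <- vapply(hits, function(s) {
      d <- tryCatch(derive_duplex(pre, c(s, s + L - 1L)),
                    mirlocate_error = function(e) NULL)
      if (is.null(d)) -1L else length(d$pairs$g)
    }, integer(1))
    hits <- hits[which.max(bp)]
  }
  c(hits[1], hits[1] + L - 1L)
}

#' Build the positive duplex set from annotated pre-miRNAs
#'
#' One duplex per pre-miRNA: when both the 5p and the 3p strand of the same
#' duplex are annotated as functional, only the 5p-anchored duplex is kept
#' (the 3p annotation is recorded as its star). Annotations whose mature
#' sequence is absent from the precursor, or whose guide cannot form a
#' duplex, are skipped with a warning.
#'
#' @param premirnas named list of folded [premirna()] objects.
#' @param annotations data.frame with `premirna_id` plus either `mirna_seq`
#'   or 1-based inclusive `start`, `end` columns.
#' @return list of positive samples, each `list(premirna_id, guide, duplex)`.
#' @export
build_positive_set <- function(premirnas, annotations) {
  if (!"premirna_id" %in% names(annotations))
    ml_stop("annotations need a premirna_id column", "mirlocate_data_error")
  out <- list()
  for (id in unique(annotations$premirna_id)) {
    pre <- premirnas[[id]]
    if (is.null(pre)) {
      ml_warn(sprintf("annotation references unknown pre-miRNA %s; skipped", id))
      next
    }
    rows <- annotations[annotations$premirna_id == id, , drop = FALSE]
    cands <- list()
    for (r in seq_len(nrow(rows))) {
      iv <- resolve_annotation(pre, as.list(rows[r, ]))
      if (is.null(iv)) {
        ml_warn(sprintf("mature sequence not found in %s; annotation skipped", id))
        next
      }
      d <- tryCatch(derive_duplex(pre, iv), mirlocate_error = function(e) NULL)
      if (is.null(d)) {
        ml_warn(sprintf("annotated guide %d-%d in %s forms no duplex; skipped",
                        iv[1], iv[2], id))
        next
      }
      cands[[length(cands) + 1L]] <- list(premirna_id = id, guide = iv, duplex = d)
    }
    if (!length(cands)) next
    if (length(cands) > 1L) {
      arms <- vapply(cands, function(x) x$duplex$arm, character(1))
      pick <- if (any(arms == "5p")) which(arms == "5p")[1] else 1L
      cands[[pick]]$sibling_arm <- cands[[setdiff(seq_along(cands), pick)[1]]]$guide
      cands <- cands[pick]
    }
    out[[length(out) + 1L]] <- cands[[1L]]
  }
  if (!length(out))
    ml_stop("no positive samples survived annotation resolution",
            "mirlocate_empty_positive_set")
  out
}

#' Sample pseudo-miRNA (negative) intervals from a pre-miRNA
#'
#' Negatives have exactly the length of the true miRNA in the same
#' precursor; starts are drawn uniformly without replacement from positions
#' more than 2 nt away from the true start; intervals that cannot form a
#' duplex are discarded and redrawn. A shortfall is reported as a warning,
#' not an error.
#'
#' @param pre a folded [premirna()].
#' @param true_guide the annotated guide interval `c(start, end)`.
#' @param count negatives requested.
#' @return list of `list(premirna_id, guide, duplex)`.
#' @export
sample_negatives <- function(pre, true_guide, count) {
  stopifnot(count >= 1)
  L <- true_guide[2] - true_guide[1] + 1L
  starts <- seq_len(max(0L, pre$n - L + 1L))
  starts <- starts[abs(starts - true_guide[1]) > 2L]
  starts <- sample(starts)
  out <- list()
  for (s in starts) {
    if (length(out) >= count) break
    d <- tryCatch(derive_duplex(pre, c(s, s + L - 1L)),
                  mirlocate_error = function(e) NULL)
    if (is.null(d)) next
    out[[length(out) + 1L]] <- list(premirna_id = pre$id,
                                    guide = c(s, s + L - 1L), duplex = d)
  }
  if (length(out) < count)
    ml_warn(sprintf("only %d of %d negatives available in %s",
                    length(out), count, pre$id), "mirlocate_shortfall")
  out
}

#' Assemble a labeled training dataset at a chosen RPNS
#'
#' RPNS is the ratio of positive to negative samples (1:N). The default 1:5
#' follows the conclusion that moderate extra negatives sharpen localization
#' without biasing the model toward pseudo-miRNAs.
#'
#' @param premirnas named list of folded [premirna()] objects.
#' @param annotations annotation table (see [build_positive_set()]).
#' @param rpns negatives per positive (N of 1:N); 1, 5, 10, 50 are typical.
#' @param seed RNG seed for negative sampling.
#' @return object of class `mirna_dataset`: feature matrix `x` (one row per
#'   sample), factor `y` (negative/positive), `groups` (pre-miRNA of each
#'   sample), `info` provenance table, `rpns`, `seed`, `schema_version`.
#' @export
build_training_set <- function(premirnas, annotations, rpns = 5, seed = 1) {
  set.seed(seed)
  positives <- build_positive_set(premirnas, annotations)
  samples <- list()
  for (p in positives) {
    samples[[length(samples) + 1L]] <- c(p, label = "positive")
    for (ng in sample_negatives(premirnas[[p$premirna_id]], p$guide, rpns))
      samples[[length(samples) + 1L]] <- c(ng, label = "negative")
  }
  x <- matrix(NA_real_, length(samples), 440L,
              dimnames = list(NULL, schema_names()))
  ctxs <- new.env(parent = emptyenv())
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    if (is.null(ctxs[[s$premirna_id]]))
      ctxs[[s$premirna_id]] <- featurize_context(premirnas[[s$premirna_id]],
                                                 quiet = TRUE)
    x[i, ] <- featurize(premirnas[[s$premirna_id]], s$duplex,
                        ctxs[[s$premirna_id]])
  }
  info <- data.frame(
    premirna_id = vapply(samples, `[[`, character(1), "premirna_id"),
    start = vapply(samples, function(s) s$guide[1], numeric(1)),
    end = vapply(samples, function(s) s$guide[2], numeric(1)),
    label = vapply(samples, `[[`, character(1), "label"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(info[c("premirna_id", "start", "end", "label")]))
    ml_stop("duplicate (pre-miRNA, interval, label) sample", "mirlocate_data_error")
  structure(
    list(x = x, y = factor(info$label, levels = c("negative", "positive")),
         groups = info$premirna_id, info = info, rpns = rpns, seed = seed,
         schema_version = SCHEMA_VERSION),
    class = "mirna_dataset")
}

#' @export
print.mirna_dataset <- function(x, ...) {
  cat(sprintf("<mirna_dataset> %d samples (%d positive, %d negative), RPNS 1:%d\n",
              nrow(x$x), sum(x$y == "positive"), sum(x$y == "negative"), x$rpns))
  invisible(x)
}

#' Grouped, stratified k-fold assignment
#'
#' All samples of one pre-miRNA land in the same fold (a positive and its
#' sibling negatives never straddle the train/test boundary), and folds are
#' balanced per class by greedy assignment of shuffled groups. With
#' singleton groups this reduces to exact stratified splitting (class sizes
#' differ by at most 1 across folds).
#'
#' @param dataset a `mirna_dataset`.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return integer fold id (1..k) per sample.
#' @export
split_folds <- function(dataset, k = 10, seed = 1) {
  stopifnot(k >= 2)
  y <- dataset$y; groups <- dataset$groups
  if (sum(y == "positive") < k || sum(y == "negative") < k)
    ml_stop(sprintf("need at least %d samples of each class for %d folds", k, k),
            "mirlocate_too_few_samples")
  set.seed(seed)
  gids <- sample(unique(groups))
  npos <- integer(k); nneg <- integer(k); ntot <- integer(k)
  fold_of <- stats::setNames(integer(length(gids)), gids)
  for (g in gids) {
    gp <- sum(y[groups == g] == "positive")
    gn <- sum(y[groups == g] == "negative")
    key <- if (gp > 0) npos else nneg
    f <- order(key, ntot)[1]
    npos[f] <- npos[f] + gp; nneg[f] <- nneg[f] + gn
    ntot[f] <- ntot[f] + gp + gn
    fold_of[g] <- f
  }
  unname(fold_of[groups])
}
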