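#' Enumerate candidate mature miRNA intervals
#'
#' Every interval of length `Lmin..Lmax` that fits in the precursor, ordered
#' by start then length.
#'
#' @param n precursor length (or a [premirna()]).
#' @param Lmin,Lmax candidate length bounds in nt.
#' @return data.frame `start` (1-based), `length`.
#' @export
enumerate_candidates <- function(n, Lmin = 16, Lmax = 30) {
  if (inherits(n, "premirna")) n <- n$n
  stopifnot(Lmin <= Lmax)
  if (n < Lmin) return(data.frame(start = integer(), length = integer()))
  starts <- seq_len(n - Lmin + 1L)
  counts <- pmin(Lmax, n - starts + 1L) - Lmin + 1L
  data.frame(start = rep.int(starts, counts),
             length = unlist(lapply(counts, function(k) Lmin:(Lmin + k - 1L))))
}

#' Score every candidate interval of a pre-miRNA
#'
#' Each candidate is turned into a duplex (candidates with no base pairs —
#' e.g. wholly inside the terminal loop — are skipped and contribute score
#' 0), featurized, and scored by the classifier in one batch.
#'
#' @param pre a folded [premirna()].
#' @param model a `mirna_model`.
#' @param Lmin,Lmax candidate length bounds.
#' @return data.frame `start`, `length`, `score` (class `score_grid`), with
#'   attribute `n_skipped`.
#' @export
score_candidates <- function(pre, model, Lmin = 16, Lmax = 30) {
  cands <- enumerate_candidates(pre$n, Lmin, Lmax)
  ctx <- featurize_context(pre, quiet = TRUE)
  feats <- matrix(NA_real_, nrow(cands), 440L,
                  dimnames = list(NULL, schema_names()))
  ok <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    d <- tryCatch(
      derive_duplex(pre, c(cands$start[i], cands$start[i] + cands$length[i] - 1L),
                    loop = ctx$loop),
      mirlocate_error = function(e) NULL)
    if (is.null(d)) next
    feats[i, ] <- featurize(pre, d, ctx)
    ok[i] <- TRUE
  }
  grid <- cands[ok, , drop = FALSE]
  if (any(ok)) {
    attr(feats, "schema_version") <- SCHEMA_VERSION
    grid$score <- predict_scores(model, feats[ok, , drop = FALSE])
  } else {
    grid$score <- numeric(0)
  }
  rownames(grid) <- NULL
  attr(grid, "n_skipped") <- sum(!ok)
  class(grid) <- c("score_grid", class(grid))
  grid
}

#' Locate the mature miRNA from a score grid
#'
#' The predicted start is the position maximizing the summed score
#' `S(p) = sum over L of score(p, L)`; the predicted length maximizes
#' `score(p_pred, L)`. Ties break toward the smallest start, then the
#' smallest length.
#'
#' @param grid a `score_grid` (data.frame `start`, `length`, `score`).
#' @return list `start`, `length`, `score`, `summed_score`.
#' @export
locate <- function(grid) {
  if (!nrow(grid)) ml_stop("empty score grid", "mirlocate_empty_grid")
  S <- tapply(grid$score, grid$start, sum)
  p_pred <- min(as.integer(names(S)[S == max(S)]))
  sub <- grid[grid$start == p_pred, , drop = FALSE]
  L_pred <- min(sub$length[sub$score == max(sub$score)])
  list(start = p_pred, length = L_pred,
       score = sub$score[sub$length == L_pred][1],
       summed_score = unname(S[as.character(p_pred)]))
}

#' Predict the mature miRNA of one pre-miRNA
#'
#' Composes candidate enumeration, duplex featurization, classifier scoring,
#' and the summed-score argmax; the passenger strand is the located guide's
#' star. All coordinates are 1-based inclusive.
#'
#' @param pre a folded [premirna()] (fold first via [fold()] or supply a
#'   structure).
#' @param model a `mirna_model`.
#' @param Lmin,Lmax candidate length bounds.
#' @return object of class `mirna_prediction`; `status` is `"ok"` or
#'   `"no_prediction"` (with `reason`).
#' @export
predict_mature <- function(pre, model, Lmin = 16, Lmax = 30) {
  grid <- score_candidates(pre, model, Lmin, Lmax)
  if (!nrow(grid))
    return(structure(list(premirna_id = pre$id, status = "no_prediction",
                          reason = "no candidate formed a duplex"),
                     class = "mirna_prediction"))
  loc <- locate(grid)
  dup <- derive_duplex(pre, c(loc$start, loc$start + loc$length - 1L))
  structure(
    list(premirna_id = pre$id, status = "ok",
         start = loc$start, end = loc$start + loc$length - 1L,
         length = loc$length, arm = dup$arm,
         mirna_seq = substr(pre$sequence, loc$start, loc$start + loc$length - 1L),
         passenger_start = dup$star[1], passenger_end = dup$star[2],
         passenger_seq = substr(pre$sequence, dup$star[1], dup$star[2]),
         score = loc$score, summed_score = loc$summed_score),
    class = "mirna_prediction")
}

#' @export
print.mirna_prediction <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("<mirna_prediction> %s: no prediction (%s)\n",
                x$premirna_id, x$reason))
  } else {
    cat(sprintf("<mirna_prediction> %s: %d-%d (%s, %d nt, score %.3f, S %.3f)\n  %s\n",
                x$premirna_id, x$start, x$end, x$arm, x$length, x$score,
                x$summed_score, x$mirna_seq))
  }
  invisible(x)
}

#' Predict mature miRNAs for a set of pre-miRNAs
#'
#' @param premirnas named list of folded [premirna()] objects.
#' @param model a `mirna_model`.
#' @param Lmin,Lmax candidate length bounds.
#' @return data.frame, one row per precursor (failed records carry NA
#'   coordinates and a `reason`).
#' @export
predict_corpus <- function(premirnas, model, Lmin = 16, Lmax = 30) {
  rows <- lapply(premirnas, function(pre) {
    p <- predict_mature(pre, model, Lmin, Lmax)
    if (p$status != "ok")
      return(data.frame(premirna_id = p$premirna_id, mirna_seq = NA,
                        start = NA, end = NA, arm = NA, passenger_seq = NA,
                        passenger_start = NA, passenger_end = NA, score = NA,
                        summed_score = NA, reason = p$reason,
                        stringsAsFactors = FALSE))
    data.frame(premirna_id = p$premirna_id, mirna_seq = p$mirna_seq,
               start = p$start, end = p$end, arm = p$arm,
               passenger_seq = p$passenger_seq,
               passenger_start = p$passenger_start,
               passenger_end = p$passenger_end,
               score = p$score, summed_score = p$summed_score,
               reason = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cumulative localization accuracy at resolutions 0..d_max
#'
#' Fraction of predictions whose start (end) lies within `d` nt of the true
#' start (end), for each `d`; both curves are non-decreasing in `d`.
#' Records without a prediction count as misses at every resolution.
#'
#' @param predictions data.frame from [predict_corpus()] (needs
#'   `premirna_id`, `start`, `end`).
#' @param truths data.frame with `premirna_id`, `start`, `end`.
#' @param d_max largest resolution in nt.
#' @return data.frame `d`, `start_freq`, `end_freq`.
#' @export
evaluate_resolution <- function(predictions, truths, d_max = 10) {
  miss <- setdiff(predictions$premirna_id, truths$premirna_id)
  if (length(miss))
    ml_stop(paste("no truth for:", paste(miss, collapse = ", ")),
            "mirlocate_missing_truth")
  m <- match(predictions$premirna_id, truths$premirna_id)
  ds <- abs(predictions$start - truths$start[m])
  de <- abs(predictions$end - truths$end[m])
  n <- nrow(predictions)
  data.frame(
    d = 0:d_max,
    start_freq = vapply(0:d_max, function(d) sum(ds <= d, na.rm = TRUE) / n,
                        numeric(1)),
    end_freq = vapply(0:d_max, function(d) sum(de <= d, na.rm = TRUE) / n,
                      numeric(1)))
}
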