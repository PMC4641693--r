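MODEL_FORMAT_VERSION <- "1"

# df-based learners need syntactic column names; keep a fixed sanitized set
sanitized_names <- function(p) sprintf("F%03d", seq_len(p))

#' Train a duplex classifier
#'
#' Five algorithms are supported behind one surface: random forest (`rf`,
#' the default), support vector machine with RBF kernel (`svm`), Gaussian
#' naive Bayes (`nb`), k-nearest neighbours (`knn`), and a decision tree
#' (`dt`). Class imbalance is expressed through the dataset's RPNS, not by
#' internal reweighting. All hyperparameters are surfaced via `params`;
#' defaults: rf 500 trees with sqrt(p) candidate features per split; svm
#' C=1, gamma = 1/(p * var(x)); knn k=5; dt rpart defaults.
#'
#' @param dataset a `mirna_dataset` from [build_training_set()].
#' @param algorithm one of `"rf"`, `"svm"`, `"nb"`, `"knn"`, `"dt"`.
#' @param params named list of hyperparameter overrides.
#' @param seed RNG seed recorded in the model (same seed + data = identical
#'   scores).
#' @return object of class `mirna_model`.
#' @export
train <- function(dataset, algorithm = "rf", params = list(), seed = 1) {
  if (!algorithm %in% c("rf", "svm", "nb", "knn", "dt"))
    ml_stop(paste("unknown algorithm:", algorithm), "mirlocate_unknown_algorithm")
  x <- dataset$x; y <- dataset$y
  if (nlevels(droplevels(y)) < 2L)
    ml_stop("training data contain a single class", "mirlocate_single_class")
  p <- ncol(x)
  colnames(x) <- sanitized_names(p)
  set.seed(seed)
  fit <- switch(algorithm,
    rf = randomForest::randomForest(
      x, y,
      ntree = params$ntree %||% 500,
      mtry = params$mtry %||% max(1L, floor(sqrt(p)))),
    svm = {
      v <- stats::var(as.vector(x))
      e1071::svm(x, y, kernel = "radial",
                 cost = params$cost %||% 1,
                 gamma = params$gamma %||% (1 / (p * max(v, 1e-12))),
                 scale = FALSE, probability = TRUE)
    },
    nb = {
      keep <- apply(x, 2L, stats::sd) > 0
      list(nb = e1071::naiveBayes(as.data.frame(x[, keep, drop = FALSE]), y),
           keep = keep)
    },
    knn = list(x = x, y = y, k = params$k %||% 5L,
               sd = pmax(apply(x, 2L, stats::sd), 1e-9)),
    dt = {
      df <- as.data.frame(x); df$.y <- y
      rpart::rpart(.y ~ ., df, method = "class",
                   cp = params$cp %||% 0.01)
    })
  structure(
    list(algorithm = algorithm, params = params, fit = fit,
         feature_names = colnames(dataset$x),
         schema_version = dataset$schema_version, seed = seed,
         n_pos = sum(y == "positive"), n_neg = sum(y == "negative"),
         rpns = dataset$rpns, format_version = MODEL_FORMAT_VERSION),
    class = "mirna_model")
}

#' @export
print.mirna_model <- function(x, ...) {
  cat(sprintf("<mirna_model> %s, schema %s, trained on %d pos / %d neg (RPNS 1:%s), seed %d\n",
              x$algorithm, x$schema_version, x$n_pos, x$n_neg,
              x$rpns %||% "?", x$seed))
  invisible(x)
}

check_schema <- function(model, x) {
  sv <- attr(x, "schema_version") %||% SCHEMA_VERSION
  if (!identical(model$schema_version, sv) ||
      !identical(colnames(x) %||% model$feature_names, model$feature_names))
    ml_stop(sprintf("model schema %s does not match feature schema %s",
                    model$schema_version, sv), "mirlocate_schema_mismatch")
}

#' Score samples with a trained model
#'
#' @param model a `mirna_model`.
#' @param x feature matrix (rows = samples, 440 schema-ordered columns).
#' @return positive-class probability per row, in `[0, 1]`.
#' @export
predict_scores <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, 1L, dimnames = list(NULL, names(x)))
  check_schema(model, x)
  colnames(x) <- sanitized_names(ncol(x))
  switch(model$algorithm,
    rf = unname(stats::predict(model$fit, x, type = "prob")[, "positive"]),
    svm = {
      pr <- stats::predict(model$fit, x, probability = TRUE)
      unname(attr(pr, "probabilities")[, "positive"])
    },
    nb = {
      xd <- as.data.frame(x[, model$fit$keep, drop = FALSE])
      unname(stats::predict(model$fit$nb, xd, type = "raw")[, "positive"])
    },
    knn = {
      set.seed(model$seed)
      xs <- scale(x, center = FALSE, scale = model$fit$sd)
      tr <- scale(model$fit$x, center = FALSE, scale = model$fit$sd)
      pr <- class::knn(tr, xs, model$fit$y, k = model$fit$k, prob = TRUE)
      w <- attr(pr, "prob")
      unname(ifelse(pr == "positive", w, 1 - w))
    },
    dt = unname(stats::predict(model$fit, as.data.frame(x),
                               type = "prob")[, "positive"]))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random positive outscores a random negative, with ties
#' credited 0.5 — equivalent to trapezoidal integration of the ROC curve
#' over all distinct score thresholds.
#'
#' @param scores numeric scores.
#' @param labels factor/character/logical; positives are `"positive"`,
#'   `TRUE` or `1`.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  pos <- labels == "positive" | labels == TRUE | labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    ml_stop("AUC needs both classes", "mirlocate_single_class")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Grouped k-fold cross-validation with per-fold AUC
#'
#' Folds come from [split_folds()], so samples of one pre-miRNA never span
#' the train/test boundary.
#'
#' @inheritParams train
#' @param k number of folds.
#' @return object of class `cv_report`: `fold_auc`, `mean_auc`,
#'   `fold_sizes`, `k`, `algorithm`, `seed`.
#' @export
crossval <- function(dataset, k = 10, algorithm = "rf", params = list(),
                     seed = 1) {
  folds <- split_folds(dataset, k, seed)
  fold_auc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- dataset; test_idx <- folds == f
    tr$x <- dataset$x[!test_idx, , drop = FALSE]
    tr$y <- dataset$y[!test_idx]
    tr$groups <- dataset$groups[!test_idx]
    m <- train(tr, algorithm, params, seed = seed + f)
    sc <- predict_scores(m, dataset$x[test_idx, , drop = FALSE])
    fold_auc[f] <- auc(sc, dataset$y[test_idx])
  }
  structure(list(fold_auc = fold_auc, mean_auc = mean(fold_auc),
                 fold_sizes = as.integer(table(factor(folds, 1:k))),
                 k = k, algorithm = algorithm, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold %s: mean AUC %.3f (folds %s)\n",
              x$k, x$algorithm, x$mean_auc,
              paste(sprintf("%.2f", x$fold_auc), collapse = " ")))
  invisible(x)
}

#' Rank features by Gini importance
#'
#' Mean decrease in node impurity across the ensemble, normalized to sum to
#' 1 and sorted descending with 1-based ranks. Tree-based models only.
#'
#' @param model a `mirna_model` trained with `rf` or `dt`.
#' @return data.frame `rank`, `feature`, `importance` (440 rows).
#' @export
gini_importance <- function(model) {
  imp <- switch(model$algorithm,
    rf = model$fit$importance[, "MeanDecreaseGini"],
    dt = {
      v <- model$fit$variable.importance
      full <- stats::setNames(numeric(length(model$feature_names)),
                              sanitized_names(length(model$feature_names)))
      full[names(v)] <- v
      full
    },
    ml_stop(paste("Gini importance requires a tree-based model, not",
                  model$algorithm), "mirlocate_unsupported_algorithm"))
  imp <- imp[sanitized_names(length(model$feature_names))]
  if (sum(imp) > 0) imp <- imp / sum(imp)
  ord <- order(-imp)
  data.frame(rank = seq_along(imp), feature = model$feature_names[ord],
             importance = unname(imp[ord]), stringsAsFactors = FALSE)
}

#' Persist / restore a trained model
#'
#' The file is a single binary artifact with an embedded header (algorithm,
#' hyperparameters, schema and format versions, seed, training counts); a
#' save/load round-trip preserves predictions bit-identically.
#'
#' @param model a `mirna_model`.
#' @param path file path.
#' @return `load_model` returns the `mirna_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    ml_stop(sprintf("cannot read model file %s: %s", path, conditionMessage(e)),
            "mirlocate_corrupt_model"))
  if (!inherits(model, "mirna_model") || is.null(model$format_version))
    ml_stop("file is not a mirlocate model", "mirlocate_corrupt_model")
  if (!identical(model$format_version, MODEL_FORMAT_VERSION))
    ml_stop(sprintf("model format %s != supported %s",
                    model$format_version, MODEL_FORMAT_VERSION),
            "mirlocate_corrupt_model")
  if (!identical(model$schema_version, SCHEMA_VERSION))
    ml_stop(sprintf("model schema %s != current %s",
                    model$schema_version, SCHEMA_VERSION),
            "mirlocate_schema_mismatch")
  model
}
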