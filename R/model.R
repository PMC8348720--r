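#' Session-grouped fold assignment
#'
#' Assigns whole recording sessions to cross-validation folds so that the
#' overlapping windows cut from one session can never straddle the train
#' and test sides of a fold. Sessions (distinct `(subject, session)` pairs)
#' are shuffled by `seed` and dealt round-robin to `k` folds.
#'
#' @param features A feature dataset with `subject` and `session` columns.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the session shuffle.
#' @return A tibble with columns `subject`, `session`, `fold` (1..k).
#' @export
session_folds <- function(features, k = 5, seed = 1) {
  sessions <- distinct(features, subject, session)
  if (nrow(sessions) < k) {
    abort(sprintf("need at least %d distinct sessions for %d folds, have %d",
                  k, k, nrow(sessions)))
  }
  ord <- withr_seed(seed, sample(nrow(sessions)))
  sessions <- sessions[ord, ]
  sessions$fold <- rep(seq_len(k), length.out = nrow(sessions))
  arrange(sessions, subject, session)
}

join_folds <- function(features, folds) {
  out <- left_join(features, folds, by = c("subject", "session"))
  if (anyNA(out$fold)) abort("some sessions have no fold assignment")
  out
}

#' Row-normalized confusion matrix
#'
#' Entry `(i, j)` is the fraction of true-class-`i` samples predicted as
#' class `j`. Every class must have at least one true sample.
#'
#' @param truth,pred Factors (or label vectors) over [taste_levels()].
#' @param min_display Entries below this value are set to `NA` for
#'   display; `NULL` (default) keeps all entries.
#' @return A 6 x 6 matrix whose rows sum to 1.
#' @export
confusion_matrix <- function(truth, pred, min_display = NULL) {
  truth <- as_taste(truth); pred <- as_taste(pred)
  counts <- table(truth = truth, pred = pred)
  if (any(rowSums(counts) == 0)) {
    abort(sprintf("class(es) with no true samples: %s",
                  paste(rownames(counts)[rowSums(counts) == 0], collapse = ", ")))
  }
  cm <- sweep(unclass(counts), 1, rowSums(counts), "/")
  if (!is.null(min_display)) cm[cm < min_display] <- NA_real_
  cm
}

#' Session-grouped random-forest cross-validation
#'
#' For each fold, trains a random forest on the out-of-fold windows and
#' predicts the held-out fold; accuracies, pooled predictions and
#' fold-averaged normalized Gini importances are collected. Forest
#' defaults are 500 trees with `sqrt(D)` candidate features per split.
#' Results are deterministic given `seed` (single-threaded forests).
#'
#' @param features A feature dataset ([extract_features()]).
#' @param folds Optional fold table from [session_folds()]; computed from
#'   `features` with `k` and `seed` when omitted.
#' @param k Number of folds when `folds` is omitted (default 5).
#' @param num_trees Trees per forest (default 500).
#' @param mtry Candidate features per split; default `sqrt(D)`.
#' @param seed Integer seed.
#' @return An object of class `taste_rf_cv` with elements `fold_accuracy`,
#'   `mean_accuracy`, `confusion`, `importance` (per-feature tibble),
#'   `predictions` and `settings`.
#' @export
taste_rf_cv <- function(features, folds = NULL, k = 5, num_trees = 500,
                        mtry = NULL, seed = 1) {
  folds <- folds %||% session_folds(features, k = k, seed = seed)
  ds <- join_folds(features, folds)
  fvars <- feature_columns(features)$column
  if (length(fvars) == 0) abort("no feature columns in dataset")
  ks <- sort(unique(ds$fold))

  preds <- vector("list", length(ks))
  imps <- matrix(0, length(fvars), length(ks),
                 dimnames = list(fvars, NULL))
  acc <- numeric(length(ks))
  for (i in seq_along(ks)) {
    kf <- ks[i]
    train <- ds[ds$fold != kf, , drop = FALSE]
    test <- ds[ds$fold == kf, , drop = FALSE]
    if (length(unique(droplevels(train$taste))) < 2) {
      abort(sprintf("training split for fold %d holds a single class", kf))
    }
    fit <- ranger::ranger(
      x = as.data.frame(train[fvars]), y = train$taste,
      num.trees = num_trees,
      mtry = mtry %||% max(1L, floor(sqrt(length(fvars)))),
      importance = "impurity",
      seed = seed + kf,
      num.threads = 1,
      verbose = FALSE
    )
    p <- predict(fit, data = as.data.frame(test[fvars]),
                 num.threads = 1)$predictions
    acc[i] <- mean(p == test$taste)
    preds[[i]] <- tibble(fold = kf, truth = test$taste,
                         pred = factor(as.character(p), levels = taste_levels()))
    raw <- fit$variable.importance[fvars]
    imps[, i] <- raw / sum(raw)
  }

  predictions <- bind_rows(preds)
  mean_imp <- rowMeans(imps)
  mean_imp <- mean_imp / sum(mean_imp)
  info <- feature_columns(features)
  importance <- mutate(info, importance = as.numeric(mean_imp[info$column]))

  structure(list(
    fold_accuracy = stats::setNames(acc, paste0("fold", ks)),
    mean_accuracy = mean(acc),
    confusion = confusion_matrix(predictions$truth, predictions$pred),
    importance = importance,
    predictions = predictions,
    settings = list(k = length(ks), num_trees = num_trees,
                    mtry = mtry, seed = seed,
                    n_features = length(fvars), n_samples = nrow(ds))
  ), class = "taste_rf_cv")
}

#' @export
print.taste_rf_cv <- function(x, ...) {
  cat(sprintf("Session-grouped %d-fold random-forest CV\n", x$settings$k))
  cat(sprintf("  samples: %d, features: %d, trees: %d\n",
              x$settings$n_samples, x$settings$n_features,
              x$settings$num_trees))
  cat(sprintf("  mean accuracy: %.4f  (folds: %s)\n", x$mean_accuracy,
              paste(sprintf("%.3f", x$fold_accuracy), collapse = ", ")))
  invisible(x)
}

#' Feature-type importance scores
#'
#' Aggregates per-feature Gini importances to one score per feature type:
#' the type score is the sum of the type's importances over all channels.
#' The table is sorted by descending score; ties break by ascending type
#' index for determinism.
#'
#' @param cv A `taste_rf_cv` object.
#' @return A tibble with columns `type_index`, `feature_type`, `score`,
#'   sorted descending.
#' @export
feature_type_importance <- function(cv) {
  stopifnot(inherits(cv, "taste_rf_cv"))
  cv$importance |>
    group_by(type_index, feature_type) |>
    summarise(score = sum(importance), .groups = "drop") |>
    arrange(desc(score), type_index)
}
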