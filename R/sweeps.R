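#' Enumerate non-empty subsets
#'
#' All non-empty subsets of a set of identifiers, smallest subsets first;
#' 6 channels give 63 subsets, 7 subjects give 127.
#'
#' @param ids Vector of identifiers.
#' @return List of sorted subsets.
#' @export
#' @examples
#' length(nonempty_subsets(1:6))
nonempty_subsets <- function(ids) {
  ids <- sort(unique(ids))
  out <- list()
  for (m in seq_along(ids)) {
    out <- c(out, utils::combn(ids, m, simplify = FALSE))
  }
  out
}

new_sweep <- function(points, axis) {
  structure(points, axis = axis, class = c("taste_sweep", class(points)))
}

#' Feature-type count sweep
#'
#' For `NF = 1 .. 21`, keeps only the `NF` feature types with the highest
#' importance score (all channels retained), reruns the session-grouped CV
#' on the reduced dataset, and records the accuracy. With `NF = 21` the
#' dataset is unchanged, so that point reproduces the full-model accuracy
#' under the same folds and seed.
#'
#' @param features Full feature dataset holding all 21 types.
#' @param importance Type ranking from [feature_type_importance()];
#'   computed from a CV on `features` when omitted.
#' @param folds Fold table; computed with `k`, `seed` when omitted.
#' @inheritParams taste_rf_cv
#' @return A `taste_sweep` tibble with columns `n_types`, `types`
#'   (list-column) and `accuracy`.
#' @export
sweep_feature_types <- function(features, importance = NULL, folds = NULL,
                                k = 5, num_trees = 500, seed = 1) {
  present <- sort(unique(feature_columns(features)$type_index))
  if (!identical(present, 1:21)) {
    abort("sweep_feature_types needs a dataset holding all 21 feature types")
  }
  folds <- folds %||% session_folds(features, k = k, seed = seed)
  if (is.null(importance)) {
    importance <- feature_type_importance(
      taste_rf_cv(features, folds = folds, num_trees = num_trees, seed = seed))
  }
  ranked <- importance$feature_type
  pts <- lapply(seq_along(ranked), function(nf) {
    sub <- subset_features(features, types = ranked[seq_len(nf)])
    cv <- taste_rf_cv(sub, folds = folds, num_trees = num_trees, seed = seed)
    tibble(n_types = nf, types = list(ranked[seq_len(nf)]),
           accuracy = cv$mean_accuracy)
  })
  new_sweep(bind_rows(pts), axis = "NF")
}

#' Exhaustive channel-combination sweep
#'
#' Evaluates the session-grouped CV accuracy of every non-empty channel
#' subset (63 subsets for 6 channels), all using the same folds and seed.
#' Use [sweep_summary()] for the per-size best and mean accuracies.
#'
#' @param features Feature dataset (typically already reduced to the
#'   selected feature types).
#' @param nc Optional subset sizes to evaluate (default: all sizes).
#' @inheritParams sweep_feature_types
#' @return A `taste_sweep` tibble with columns `n_channels`,
#'   `channel_set`, `channels` (list-column) and `accuracy`.
#' @export
sweep_channels <- function(features, folds = NULL, k = 5, num_trees = 500,
                           seed = 1, nc = NULL) {
  chans <- sort(unique(feature_columns(features)$channel))
  folds <- folds %||% session_folds(features, k = k, seed = seed)
  subsets <- nonempty_subsets(chans)
  if (!is.null(nc)) subsets <- subsets[lengths(subsets) %in% nc]
  pts <- lapply(subsets, function(cs) {
    sub <- subset_features(features, channels = cs)
    cv <- taste_rf_cv(sub, folds = folds, num_trees = num_trees, seed = seed)
    tibble(n_channels = length(cs),
           channel_set = paste(cs, collapse = "+"),
           channels = list(cs), accuracy = cv$mean_accuracy)
  })
  new_sweep(bind_rows(pts), axis = "NC")
}

#' Exhaustive subject-combination sweep
#'
#' Evaluates every non-empty subject subset (127 subsets for 7 subjects):
#' for each subset the windows of its subjects are pooled, session-grouped
#' folds are drawn within the pooled dataset, and the CV accuracy is
#' recorded. Every subset must contribute at least `k` sessions.
#'
#' @param features Feature dataset holding multiple subjects (typically
#'   reduced to the selected types and channels).
#' @inheritParams sweep_feature_types
#' @param ns Optional subset sizes to evaluate (default: all sizes).
#' @return A `taste_sweep` tibble with columns `n_subjects`,
#'   `subject_set`, `subjects` (list-column) and `accuracy`.
#' @export
sweep_subjects <- function(features, k = 5, num_trees = 500, seed = 1,
                           ns = NULL) {
  subjects <- sort(unique(features$subject))
  subsets <- nonempty_subsets(subjects)
  if (!is.null(ns)) subsets <- subsets[lengths(subsets) %in% ns]
  pts <- lapply(subsets, function(ss) {
    sub <- filter(features, subject %in% ss)
    cv <- taste_rf_cv(sub, k = k, num_trees = num_trees, seed = seed)
    tibble(n_subjects = length(ss),
           subject_set = paste(ss, collapse = "+"),
           subjects = list(ss), accuracy = cv$mean_accuracy)
  })
  new_sweep(bind_rows(pts), axis = "NS")
}

#' Summarise a sweep by subset size
#'
#' Best and mean accuracy per subset size (per NF, NC or NS, depending on
#' the sweep's axis). The best accuracy is by construction at least the
#' mean.
#'
#' @param sweep A `taste_sweep` from one of the sweep functions.
#' @return A tibble with the size column, `best`, `mean_acc` and `n_subsets`.
#' @export
sweep_summary <- function(sweep) {
  axis_col <- switch(attr(sweep, "axis"),
                     NF = "n_types", NC = "n_channels", NS = "n_subjects")
  sweep |>
    group_by(across(all_of(axis_col))) |>
    summarise(best = max(accuracy), mean_acc = mean(accuracy),
              n_subsets = n(), .groups = "drop")
}
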