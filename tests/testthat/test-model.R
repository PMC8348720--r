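# Small, clean studies keep the forest fits fast while preserving the
# session/subject structure the grouping logic must respect.
small_features <- function(n_subjects = 1, sessions = 5, seed = 21,
                           profiles = default_taste_profiles()) {
  spec <- quiet_spec(n_subjects = n_subjects, sessions_per_subject = sessions,
                     seed = seed, profiles = profiles)
  extract_features(preprocess_windows(segment_windows(generate_study(spec))))
}

test_that("session-grouped folds partition sessions round-robin", {
  feats <- small_features(n_subjects = 2, sessions = 5)
  folds <- session_folds(feats, k = 5, seed = 1)
  expect_equal(nrow(folds), 10)
  expect_true(all(table(folds$fold) == 2))

  ds <- dplyr::left_join(feats, folds, by = c("subject", "session"))
  # all windows of a session share the session's fold
  per_session <- dplyr::n_distinct(
    dplyr::summarise(dplyr::group_by(ds, subject, session),
                     k = dplyr::n_distinct(fold))$k)
  expect_equal(per_session, 1)
  # folds partition the samples
  expect_equal(sum(table(ds$fold)), nrow(feats))

  expect_error(session_folds(small_features(sessions = 5), k = 6),
               "at least 6")
})

test_that("cross-validation separates planted classes and is deterministic", {
  feats <- small_features(sessions = 5)
  cv1 <- taste_rf_cv(feats, num_trees = 100, seed = 4)
  cv2 <- taste_rf_cv(feats, num_trees = 100, seed = 4)
  expect_gt(cv1$mean_accuracy, 0.9)
  expect_identical(cv1$fold_accuracy, cv2$fold_accuracy)
  expect_identical(cv1$importance, cv2$importance)
  expect_equal(cv1$mean_accuracy, mean(cv1$fold_accuracy))
  expect_true(all(abs(rowSums(cv1$confusion) - 1) < 1e-9))
  expect_true(all(cv1$importance$importance >= 0))
  expect_lt(abs(sum(cv1$importance$importance) - 1), 1e-6)

  # no session straddles train and test: each session predicted in one fold
  ds <- dplyr::left_join(feats, session_folds(feats, 5, 4),
                         by = c("subject", "session"))
  expect_true(all(table(ds$subject, ds$session, ds$fold) %in%
                    c(0, table(ds$subject, ds$session))))
})

test_that("cross-validation refuses a single-class training split", {
  feats <- small_features(sessions = 5)
  feats$taste <- factor("Sour", levels = taste_levels())
  expect_error(taste_rf_cv(feats, num_trees = 10), "single class")
})

test_that("confusion matrices are row-normalized with an empty-class guard", {
  lv <- taste_levels()
  truth <- factor(rep(lv, each = 10), lv)
  cm <- confusion_matrix(truth, truth)
  expect_equal(unname(cm), diag(6))

  set.seed(30)
  n <- 60000
  truth <- factor(sample(lv, n, TRUE), lv)
  pred <- factor(sample(lv, n, TRUE), lv)
  cm <- confusion_matrix(truth, pred)
  expect_true(all(abs(cm - 1 / 6) < 0.05))
  expect_true(all(abs(rowSums(cm) - 1) < 1e-9))

  disp <- confusion_matrix(truth, pred, min_display = 0.99)
  expect_true(all(is.na(disp)))
  expect_error(confusion_matrix(truth[truth != "Sour"], pred[truth != "Sour"]),
               "no true samples")
})

test_that("type scores aggregate channel importances and rank planted bands", {
  feats <- small_features(sessions = 5)
  cv <- taste_rf_cv(feats, num_trees = 100, seed = 4)
  imp <- feature_type_importance(cv)
  expect_equal(nrow(imp), 21)
  expect_lt(abs(sum(imp$score) - 1), 1e-6)
  expect_true(all(diff(imp$score) <= 1e-12))

  # class contrast planted in the 100-400 Hz bands: those types dominate
  expect_true("band_100_200" %in% imp$feature_type[1:2] ||
                "band_200_300" %in% imp$feature_type[1:2])
})

test_that("the NF sweep reduces to top-ranked types and reproduces the full model", {
  feats <- small_features(sessions = 5)
  folds <- session_folds(feats, 5, 4)
  cv <- taste_rf_cv(feats, folds = folds, num_trees = 50, seed = 4)
  imp <- feature_type_importance(cv)
  sw <- sweep_feature_types(feats, importance = imp, folds = folds,
                            num_trees = 50, seed = 4)
  expect_equal(nrow(sw), 21)
  expect_equal(sw$accuracy[21], cv$mean_accuracy)
  expect_gte(sw$accuracy[1], 0.8 * sw$accuracy[21])
})

test_that("the channel sweep enumerates all subsets and recovers planted channels", {
  feats <- small_features(sessions = 5,
                          profiles = planted_profiles(c(2, 3)))
  folds <- session_folds(feats, 5, 4)
  sw <- sweep_channels(feats, folds = folds, num_trees = 50, seed = 4)
  expect_equal(nrow(sw), 63)
  expect_equal(as.numeric(table(sw$n_channels)), choose(6, 1:6))

  s <- sweep_summary(sw)
  expect_true(all(s$best >= s$mean_acc))
  expect_equal(s$best[s$n_channels == 6], s$mean_acc[s$n_channels == 6])

  best2 <- sw[sw$n_channels == 2, ]
  expect_equal(best2$channel_set[which.max(best2$accuracy)], "2+3")
})

test_that("the subject sweep covers every combination with pooled-session folds", {
  feats <- small_features(n_subjects = 3, sessions = 5)
  sw <- sweep_subjects(feats, num_trees = 30, seed = 4)
  expect_equal(nrow(sw), 7)
  expect_equal(as.numeric(table(sw$n_subjects)), choose(3, 1:3))

  s <- sweep_summary(sw)
  singles <- sw$accuracy[sw$n_subjects == 1]
  expect_equal(s$mean_acc[s$n_subjects == 1], mean(singles))
})
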