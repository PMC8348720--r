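#' Write a study to disk
#'
#' One CSV per trial (`sample_index`, `ch1..chC`) plus a `manifest.csv`
#' listing `trial_file`, `subject`, `session`, `taste` and `fs`.
#'
#' @param study Trial tibble ([generate_study()]).
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("trial_%04d.csv", study$trial)
  for (i in seq_len(nrow(study))) {
    x <- study$data[[i]]
    df <- as.data.frame(x)
    df <- cbind(sample_index = seq_len(nrow(x)) - 1L, df)
    readr::write_csv(df, file.path(dir, files[i]), progress = FALSE)
  }
  manifest <- tibble(trial_file = files,
                     subject = study$subject, session = study$session,
                     taste = as.character(study$taste), fs = study$fs)
  path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, path, progress = FALSE)
  invisible(path)
}

#' Read a study from a manifest
#'
#' Loads the trial files listed in a manifest CSV, validating each row:
#' the file must exist, the taste label must be one of [taste_levels()],
#' and every trial must have the same channel count. Malformed rows are
#' reported with their row number.
#'
#' @param manifest Path to a `manifest.csv` written by [write_study()] (or
#'   user-supplied in the same layout).
#' @return A trial tibble in the [generate_study()] layout.
#' @export
read_study <- function(manifest) {
  if (!file.exists(manifest)) abort(sprintf("manifest not found: %s", manifest))
  man <- readr::read_csv(manifest, show_col_types = FALSE, progress = FALSE)
  need <- c("trial_file", "subject", "session", "taste", "fs")
  miss <- setdiff(need, names(man))
  if (length(miss) > 0) {
    abort(sprintf("manifest lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  base <- dirname(manifest)
  data <- vector("list", nrow(man))
  n_ch <- NULL
  for (i in seq_len(nrow(man))) {
    if (!man$taste[i] %in% taste_levels()) {
      abort(sprintf("manifest row %d: unknown taste label '%s'", i, man$taste[i]))
    }
    path <- file.path(base, man$trial_file[i])
    if (!file.exists(path)) {
      abort(sprintf("manifest row %d: trial file not found: %s", i, path))
    }
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    chans <- grep("^ch[0-9]+$", names(df), value = TRUE)
    if (length(chans) == 0) {
      abort(sprintf("manifest row %d: no channel columns (ch1..chC) in %s",
                    i, man$trial_file[i]))
    }
    if (is.null(n_ch)) n_ch <- length(chans)
    if (length(chans) != n_ch) {
      abort(sprintf("manifest row %d: %d channels found where %d expected",
                    i, length(chans), n_ch))
    }
    data[[i]] <- as.matrix(df[chans])
  }
  tibble(trial = seq_len(nrow(man)), subject = man$subject,
         session = man$session, taste = as_taste(man$taste),
         fs = man$fs, data = data)
}

#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end run with its default. The
#' configuration can also be read from a YAML file with
#' [read_run_config()]; unspecified fields keep these defaults.
#'
#' @param synth A [study_spec()] describing a synthetic study, or `NULL`
#'   when reading recordings from `manifest`.
#' @param manifest Path to a study manifest (used when `synth` is `NULL`).
#' @param window_s,step_s Segmentation parameters.
#' @param detrend_degree,hp_cutoff,hp_order,trigger_ratio,quality_factor,reject_threshold
#'   Cleaning parameters, see [preprocess_windows()].
#' @param channels,types,literal_equations Feature configuration, see
#'   [extract_features()].
#' @param k,num_trees Model configuration.
#' @param sweeps Character subset of `c("NF", "NC", "NS")` to run.
#' @param activity Compute the muscle-activity table (default `TRUE`).
#' @param activity_channels Channels for [taste_activity()].
#' @param seed Root seed for folds and forests.
#' @return A `run_config` list.
#' @export
run_config <- function(synth = study_spec(),
                       manifest = NULL,
                       window_s = 1, step_s = 0.25,
                       detrend_degree = 4,
                       hp_cutoff = 10, hp_order = 4,
                       trigger_ratio = 4, quality_factor = 30,
                       reject_threshold = 4,
                       channels = NULL, types = NULL,
                       literal_equations = FALSE,
                       k = 5, num_trees = 500,
                       sweeps = character(),
                       activity = TRUE,
                       activity_channels = c(3, 4, 6),
                       seed = 1) {
  if (is.null(synth) && is.null(manifest)) {
    abort("a run needs either a synthetic study spec or a manifest path")
  }
  bad <- setdiff(sweeps, c("NF", "NC", "NS"))
  if (length(bad) > 0) abort(sprintf("unknown sweep(s): %s", paste(bad, collapse = ", ")))
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override the [run_config()] defaults; a `synth` mapping
#' is passed to [study_spec()].
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synth)) raw$synth <- do.call(study_spec, raw$synth)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    abort(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")))
  }
  do.call(run_config, raw)
}

#' Run the end-to-end analysis
#'
#' Sequences generation (or reading), segmentation, cleaning, feature
#' extraction, session-grouped cross-validation, feature-type importance,
#' the requested sweeps, and the muscle-activity table, writing every
#' result as CSV into `out_dir` together with the resolved configuration
#' and a log of sample counts before and after rejection. Rerunning with
#' the same configuration and seed reproduces identical outputs.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory.
#' @return A list with the in-memory results (`features`, `cv`,
#'   `importance`, `sweeps`, `activity`), invisibly.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)

  study <- if (!is.null(cfg$synth)) generate_study(cfg$synth) else read_study(cfg$manifest)
  logf("trials: %d", nrow(study))

  windows <- segment_windows(study, window_s = cfg$window_s, step_s = cfg$step_s)
  logf("windows before rejection: %d", nrow(windows))
  windows <- preprocess_windows(
    windows, detrend_degree = cfg$detrend_degree,
    hp_cutoff = cfg$hp_cutoff, hp_order = cfg$hp_order,
    trigger_ratio = cfg$trigger_ratio, quality_factor = cfg$quality_factor,
    reject_threshold = cfg$reject_threshold)
  logf("windows after rejection: %d", sum(!windows$rejected))
  readr::write_csv(
    select(windows, trial, subject, session, taste, window, rejected),
    file.path(out_dir, "windows.csv"), progress = FALSE)

  features <- extract_features(windows, channels = cfg$channels,
                               types = cfg$types,
                               literal_equations = cfg$literal_equations)
  readr::write_csv(features, file.path(out_dir, "features.csv"),
                   progress = FALSE)

  folds <- session_folds(features, k = cfg$k, seed = cfg$seed)
  cv <- taste_rf_cv(features, folds = folds, num_trees = cfg$num_trees,
                    seed = cfg$seed)
  logf("mean CV accuracy: %.4f", cv$mean_accuracy)
  readr::write_csv(tidy(cv), file.path(out_dir, "cv_accuracy.csv"),
                   progress = FALSE)
  utils::write.csv(cv$confusion, file.path(out_dir, "confusion.csv"))
  importance <- feature_type_importance(cv)
  readr::write_csv(importance, file.path(out_dir, "feature_type_importance.csv"),
                   progress = FALSE)

  sweeps <- list()
  if ("NF" %in% cfg$sweeps) {
    sweeps$NF <- sweep_feature_types(features, importance = importance,
                                     folds = folds, num_trees = cfg$num_trees,
                                     seed = cfg$seed)
    readr::write_csv(select(sweeps$NF, n_types, accuracy),
                     file.path(out_dir, "sweep_nf.csv"), progress = FALSE)
  }
  if ("NC" %in% cfg$sweeps) {
    sweeps$NC <- sweep_channels(features, folds = folds,
                                num_trees = cfg$num_trees, seed = cfg$seed)
    readr::write_csv(select(sweeps$NC, n_channels, channel_set, accuracy),
                     file.path(out_dir, "sweep_nc.csv"), progress = FALSE)
  }
  if ("NS" %in% cfg$sweeps) {
    sweeps$NS <- sweep_subjects(features, k = cfg$k,
                                num_trees = cfg$num_trees, seed = cfg$seed)
    readr::write_csv(select(sweeps$NS, n_subjects, subject_set, accuracy),
                     file.path(out_dir, "sweep_ns.csv"), progress = FALSE)
  }

  activity <- NULL
  if (isTRUE(cfg$activity)) {
    act_feats <- features
    have <- unique(feature_columns(features)$channel)
    act_ch <- intersect(cfg$activity_channels, have)
    if (length(act_ch) > 0 &&
        all(paste0("ch", act_ch[1], "_band_100_200") %in% names(features))) {
      activity <- activity_grayscale(taste_activity(features, channels = act_ch))
      readr::write_csv(activity, file.path(out_dir, "activity.csv"),
                       progress = FALSE)
    } else {
      logf("activity table skipped: required band features not in configuration")
    }
  }

  yaml::write_yaml(resolved_config_list(cfg), file.path(out_dir, "config.yaml"))

  invisible(list(features = features, folds = folds, cv = cv,
                 importance = importance, sweeps = sweeps,
                 activity = activity, out_dir = out_dir))
}

# Serializable view of a run_config (profiles reduced to their gains).
resolved_config_list <- function(cfg) {
  out <- unclass(cfg)
  if (!is.null(out$synth)) {
    sp <- unclass(out$synth)
    sp$profiles <- lapply(sp$profiles, function(p) {
      list(taste = p$taste, band_gain = apply(p$band_gain, 1, as.numeric,
                                              simplify = FALSE))
    })
    out$synth <- sp
  }
  out
}
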