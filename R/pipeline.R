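#' Detect, window, and featurize every throw in one session
#'
#' Runs resampling, gyroscope-peak detection, window cutting, and the
#' 201-feature extraction for one recording, and (when ground truth is
#' available) labels each detected event with the nearest truth row within
#' `label_tol_s`. Detected events without a truth match, and windows that
#' exceed the recording bounds, are dropped.
#'
#' @param session A `simulated_session` or `raw_recording` (with an optional
#'   `truth` element carrying approach/windup/velocity labels).
#' @param window_s Window lengths to featurize (one row per throw x window).
#' @param detection A [detection_config()].
#' @param catalogue Feature catalogue.
#' @param label_tol_s Event-to-truth matching tolerance, seconds.
#' @return data.frame: `subject_id`, `throw_id`, `window_s`, `t_peak`,
#'   label columns when truth is present, and the 201 feature columns.
#' @export
process_session <- function(session, window_s = 3,
                            detection = detection_config(),
                            catalogue = feature_catalogue(),
                            label_tol_s = 0.3) {
  streams <- to_streams(session)
  events <- detect_throws(streams$gyro, detection)
  truth <- session$truth
  rows <- list()
  for (ws in window_s) {
    cw <- cut_windows(streams, events, ws)
    for (wi in seq_along(cw$windows)) {
      w <- cw$windows[[wi]]
      ev_row <- cw$kept[wi]
      lab <- NULL
      if (!is.null(truth)) {
        dt <- abs(truth$t_event - w$event$t_peak)
        j <- which.min(dt)
        if (dt[j] > label_tol_s) next  # unmatched detection: no label
        lab <- truth[j, c("approach", "windup", "velocity"), drop = FALSE]
      }
      fv <- featurize_throw(w, catalogue)
      row <- data.frame(
        subject_id = session$subject_id %||% NA_character_,
        throw_id = ev_row, window_s = ws, t_peak = w$event$t_peak,
        stringsAsFactors = FALSE
      )
      if (!is.null(lab)) row <- cbind(row, lab, row.names = NULL)
      rows[[length(rows) + 1L]] <- cbind(row, as.data.frame(t(fv)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a study and build its labeled feature matrix
#'
#' Generates each subject's session (same random stream as
#' [simulate_study()], so the throws are identical for a given config),
#' pushes it through detection and feature extraction, and discards the raw
#' signals, keeping memory flat in the number of subjects.
#'
#' @param cfg A [simulation_config()].
#' @param window_s Window lengths to featurize.
#' @param detection A [detection_config()].
#' @return Feature matrix data.frame, one row per detected throw x window.
#' @export
build_feature_matrix <- function(cfg = simulation_config(), window_s = 3,
                                 detection = detection_config()) {
  set.seed(cfg$seed)
  catalogue <- feature_catalogue()
  ids <- sprintf("S%02d", seq_len(cfg$n_subjects))
  rows <- lapply(ids, function(id) {
    sess <- sim_session_impl(cfg, id, draw_subject_effects(cfg))
    process_session(sess, window_s, detection, catalogue)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate model families across measurement ranges under LOSO CV
#'
#' Runs [loso_evaluate()] for every requested model family on the high-g and
#' low-g feature sets of one window's feature matrix, and assembles the
#' per-subject metric table (macro F1 for classification, MAE for
#' regression) that feeds [rm_anova_two_way()] and
#' [paired_range_contrast()].
#'
#' @param fm Full feature matrix (one window size) with label columns.
#' @param task Task, see [model_spec()].
#' @param label_col Response column ("approach", "windup", or "velocity").
#' @param families Model families to run.
#' @param ranges Which feature sets to run ("high_g", "low_g").
#' @param grids Optional named list family -> hyperparameter grid.
#' @param tune_k,seed,cutoff Passed to [model_spec()] / [loso_evaluate()].
#' @return List with `results` (named list of `evaluation_result`s) and
#'   `table` (subject_id, model, range, value).
#' @export
compare_model_ranges <- function(fm, task, label_col,
                                 families = c("RF", "SVM_L", "SVM_P", "GBM"),
                                 ranges = c("high_g", "low_g"),
                                 grids = NULL, tune_k = 10, seed = 1,
                                 cutoff = 0.95) {
  catalogue <- feature_catalogue()
  sets <- range_feature_sets(catalogue)
  results <- list()
  tab <- list()
  for (family in families) {
    grid <- if (!is.null(grids)) grids[[family]] else NULL
    for (rg in ranges) {
      spec <- model_spec(family, task, grid = grid, tune_k = tune_k,
                         seed = seed)
      res <- loso_evaluate(spec, fm, sets[[rg]], label_col, cutoff = cutoff)
      key <- paste(family, rg, sep = ".")
      results[[key]] <- res
      ps <- res$per_subject
      ps$model <- family
      ps$range <- rg
      tab[[key]] <- ps
    }
  }
  table <- do.call(rbind, tab)
  rownames(table) <- NULL
  list(results = results, table = table)
}
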