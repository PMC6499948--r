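frame_columns <- c("subject_id", "task_id", "frame_index", "waypoint_id",
                   "true_x_cm", "true_y_cm", "pred_x_cm", "pred_y_cm", "status")

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Read and write the gaze-frame CSV schema
#'
#' The frame-level interchange format: one row per video frame with
#' columns `subject_id`, `task_id`, `frame_index`, `waypoint_id`,
#' `true_x_cm`, `true_y_cm`, `pred_x_cm`, `pred_y_cm`, `status`
#' (`valid`, `blink`, `segmentation_failed` or `excluded_manual`). Header
#' required; UTF-8; `.` decimal separator; a missing prediction (any
#' non-valid status) is encoded as empty fields. Coordinates are written
#' with 17 significant digits so a write/read round trip reproduces every
#' double bit-for-bit. Real tracker output supplied in this schema can be
#' fed to the same evaluation as simulated frames.
#'
#' @param frames Gaze-frame data.frame (see [simulate_session()]).
#' @param path File path.
#' @return `read_frames()`: the validated gaze-frame data.frame.
#'   Malformed rows (missing prediction on a `valid` row, non-numeric
#'   coordinates, unknown status) raise an error naming the offending
#'   line. `write_frames()`: `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  stopifnot(all(frame_columns %in% names(frames)))
  out <- frames[, frame_columns]
  for (cl in c("true_x_cm", "true_y_cm", "pred_x_cm", "pred_y_cm")) {
    out[[cl]] <- fmt_num(out[[cl]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8",
            eol = "\n")
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  raw <- read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  missing_cols <- setdiff(frame_columns, names(raw))
  if (length(missing_cols)) {
    stop("frame file is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    return(new_gaze_frames(character(0), character(0),
                           data.frame(frame_index = integer(0),
                                      waypoint_id = integer(0),
                                      x = numeric(0), y = numeric(0)),
                           numeric(0), numeric(0), character(0)))
  }
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1
  bad_status <- !(raw$status %in% frame_statuses)
  if (any(bad_status)) {
    stop("unknown status '", raw$status[bad_status][1], "' on line ",
         line_no[bad_status][1])
  }
  num <- function(col, required) {
    txt <- raw[[col]]
    v <- suppressWarnings(as.numeric(txt))
    empty <- !nzchar(trimws(txt))
    v[empty] <- NA_real_
    bad <- !empty & is.na(v)
    if (any(bad)) stop("non-numeric ", col, " on line ", line_no[bad][1])
    if (!is.null(required)) {
      need <- required & empty
      if (any(need)) stop("missing ", col, " on valid row, line ", line_no[need][1])
    }
    v
  }
  is_valid <- raw$status == "valid"
  fr <- data.frame(
    subject_id = raw$subject_id, task_id = raw$task_id,
    frame_index = as.integer(num("frame_index", rep(TRUE, nrow(raw)))),
    waypoint_id = as.integer(num("waypoint_id", rep(TRUE, nrow(raw)))),
    true_x_cm = num("true_x_cm", rep(TRUE, nrow(raw))),
    true_y_cm = num("true_y_cm", rep(TRUE, nrow(raw))),
    pred_x_cm = num("pred_x_cm", is_valid),
    pred_y_cm = num("pred_y_cm", is_valid),
    status = raw$status, stringsAsFactors = FALSE
  )
  fr$pred_x_cm[!is_valid] <- NA_real_
  fr$pred_y_cm[!is_valid] <- NA_real_
  fr
}

#' Experiment configuration
#'
#' Bundles every knob of a simulate-calibrate-score-compare experiment
#' into one object that round-trips through a YAML file, so a run is fully
#' specified by (config, nothing else) and reproducible from its file
#' form.
#'
#' @param n_subjects Cohort size.
#' @param seed Master seed (mandatory; every random draw derives from it).
#' @param screen Named list: `width`, `height`, `camera_pos`.
#' @param tasks Optional per-task layout overrides, e.g.
#'   `list(circle = list(radius = 2))`.
#' @param cohort Cohort hyperparameters, see [cohort_hyperparameters()].
#' @param calibration List: `svr_features` (`"point"`/`"quadratic"`),
#'   `cost`, `epsilon`, `gamma` (`NULL` = 1/n_features).
#' @param metrics List: `grouping` (see [misclassification_rate()]),
#'   `circle_variant` (see [circle_error()]).
#' @param output_dir Optional directory for CSV tables and the JSON run
#'   manifest; `NULL` keeps the experiment in memory only.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 16L, seed = 1L,
                              screen = list(width = 6.2, height = 11.0,
                                            camera_pos = c(3.1, -0.7)),
                              tasks = list(),
                              cohort = cohort_hyperparameters(),
                              calibration = list(svr_features = "point",
                                                 cost = 1, epsilon = 0.1,
                                                 gamma = NULL),
                              metrics = list(grouping = "eyes_vs_mouth",
                                             circle_variant = "to_outline"),
                              output_dir = NULL) {
  if (is.null(seed)) stop("seed is mandatory")
  cfg <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
              screen = screen, tasks = tasks, cohort = cohort,
              calibration = calibration, metrics = metrics,
              output_dir = output_dir)
  class(cfg) <- "experiment_config"
  cfg
}

#' @rdname experiment_config
#' @param config An `experiment_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(experiment_config, raw)
}

# Hash of the scientific configuration: output_dir is excluded so the same
# experiment written to two places yields the same manifest.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  cfg <- config
  cfg$output_dir <- NULL
  write_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

fit_subject_calibrations <- function(t1_frames, calib) {
  truth <- cbind(t1_frames$true_x_cm, t1_frames$true_y_cm)
  pred <- pred_points(t1_frames)
  list(
    linear = gaze_calibration(truth, pred, method = "linear"),
    svr = gaze_calibration(truth, pred, method = "svr",
                           features = calib$svr_features %||% "point",
                           cost = calib$cost %||% 1,
                           epsilon = calib$epsilon %||% 0.1,
                           gamma = calib$gamma)
  )
}

apply_correction <- function(frames, model) {
  ok <- frames$status == "valid"
  if (!is.null(model) && any(ok)) {
    corr <- predict(model, pred_points(frames[ok, , drop = FALSE]))
    frames$pred_x_cm[ok] <- corr[, 1]
    frames$pred_y_cm[ok] <- corr[, 2]
  }
  frames
}

#' Score a cohort of gaze frames under all corrections
#'
#' Fits per-subject linear and SVR calibrations on each subject's valid
#' grid-task (Task 1) frames, applies them to the remaining tasks, and
#' computes every metric for every (subject, task, correction) cell:
#' misclassification rate on the two face tasks, and both circle-error
#' variants on the circle task. A subject whose calibration cannot be
#' fitted (e.g. degenerate prediction variance) is recorded in `failures`
#' and scored only for the uncorrected condition; other subjects are
#' unaffected.
#'
#' @param frames Gaze-frame data.frame covering the four tasks (simulated
#'   or ingested with [read_frames()]).
#' @param specs The task layouts the frames were recorded against (named
#'   list as from [default_protocol()]).
#' @param grouping,circle_variant Metric settings, see
#'   [misclassification_rate()] and [circle_error()].
#' @param calibration Calibration settings list (see
#'   [experiment_config()]).
#' @return A list: `metrics` (long data.frame: `subject_id`, `task_id`,
#'   `correction`, `metric`, `value`), `calibrations` (per subject),
#'   `failures` (data.frame: `subject_id`, `stage`, `reason`).
#' @export
evaluate_cohort <- function(frames, specs = default_protocol(),
                            grouping = "eyes_vs_mouth",
                            circle_variant = "to_outline",
                            calibration = list()) {
  subjects <- unique(frames$subject_id)
  failures <- data.frame(subject_id = character(0), stage = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  calibs <- setNames(vector("list", length(subjects)), subjects)
  for (s in subjects) {
    t1 <- valid_frames(frames[frames$subject_id == s &
                                frames$task_id == "grid", , drop = FALSE])
    res <- tryCatch(fit_subject_calibrations(t1, calibration),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- rbind(failures,
                        data.frame(subject_id = s, stage = "calibration",
                                   reason = res, stringsAsFactors = FALSE))
    } else {
      calibs[[s]] <- res
    }
  }

  rows <- list()
  corrections <- c("none", "linear", "svr")
  for (task_id in c("face_small", "face_large", "circle")) {
    task_fr <- frames[frames$task_id == task_id, , drop = FALSE]
    if (nrow(task_fr) == 0L) next
    for (corr in corrections) {
      per_subj <- lapply(subjects, function(s) {
        fr <- task_fr[task_fr$subject_id == s, , drop = FALSE]
        if (nrow(valid_frames(fr)) == 0L) return(NULL)
        model <- if (corr != "none") calibs[[s]][[corr]]
        if (corr != "none" && is.null(model)) return(NULL)  # calibration failed
        fr <- apply_correction(fr, model)
        if (task_id == "circle") {
          rbind(
            data.frame(subject_id = s, metric = "circle_to_outline",
                       value = circle_error(fr, specs[[task_id]], "to_outline")$mean_error_cm,
                       stringsAsFactors = FALSE),
            data.frame(subject_id = s, metric = "circle_to_waypoint",
                       value = circle_error(fr, specs[[task_id]], "to_waypoint")$mean_error_cm,
                       stringsAsFactors = FALSE)
          )
        } else {
          data.frame(subject_id = s, metric = "misclassification",
                     value = misclassification_rate(fr, specs[[task_id]],
                                                    grouping)$rate,
                     stringsAsFactors = FALSE)
        }
      })
      per_subj <- do.call(rbind, per_subj)
      if (!is.null(per_subj)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = per_subj$subject_id, task_id = task_id,
          correction = corr, metric = per_subj$metric,
          value = per_subj$value, stringsAsFactors = FALSE)
      }
    }
  }
  list(metrics = do.call(rbind, rows), calibrations = calibs,
       failures = failures)
}

headline_metric <- function(task_id, circle_variant) {
  if (task_id == "circle") paste0("circle_", circle_variant) else "misclassification"
}

# Matched per-subject metric vectors for a (task, metric) cell across the
# given corrections; subjects missing any cell are dropped.
matched_values <- function(metrics, task_id, metric, corrections) {
  sub <- metrics[metrics$task_id == task_id & metrics$metric == metric, ]
  wide <- lapply(corrections, function(co) {
    v <- sub[sub$correction == co, c("subject_id", "value")]
    setNames(v$value, v$subject_id)
  })
  common <- Reduce(intersect, lapply(wide, names))
  lapply(wide, function(v) unname(v[common]))
}

run_statistics <- function(metrics, circle_variant) {
  pairs <- list(c("none", "linear"), c("none", "svr"), c("linear", "svr"))
  comp_rows <- list()
  for (task_id in c("face_small", "face_large", "circle")) {
    metric <- headline_metric(task_id, circle_variant)
    for (pr in pairs) {
      mv <- matched_values(metrics, task_id, metric, pr)
      res <- tryCatch(compare_paired(mv[[1]], mv[[2]]),
                      error = function(e) conditionMessage(e))
      comp_rows[[length(comp_rows) + 1L]] <- if (is.character(res)) {
        data.frame(task_id = task_id, metric = metric,
                   comparison = paste(pr, collapse = "_vs_"),
                   test_used = "degenerate", statistic = NA_real_,
                   df = NA_real_, p_value = NA_real_,
                   n = length(mv[[1]]), note = res, stringsAsFactors = FALSE)
      } else {
        data.frame(task_id = task_id, metric = metric,
                   comparison = paste(pr, collapse = "_vs_"),
                   test_used = res$test_used, statistic = res$statistic,
                   df = res$df, p_value = res$p_value, n = res$n,
                   note = "", stringsAsFactors = FALSE)
      }
    }
  }
  lev_rows <- list()
  for (task_id in c("face_small", "face_large")) {
    mv <- matched_values(metrics, task_id, "misclassification",
                         c("none", "linear", "svr"))
    res <- tryCatch(compare_variance(mv[[1]], mv[[2]], mv[[3]]),
                    error = function(e) conditionMessage(e))
    lev_rows[[length(lev_rows) + 1L]] <- if (is.character(res)) {
      data.frame(task_id = task_id, metric = "misclassification",
                 F_statistic = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                 p_value = NA_real_, note = res, stringsAsFactors = FALSE)
    } else {
      data.frame(task_id = task_id, metric = "misclassification",
                 F_statistic = res$F_statistic, df1 = res$df[1],
                 df2 = res$df[2], p_value = res$p_value, note = "",
                 stringsAsFactors = FALSE)
    }
  }
  list(comparisons = do.call(rbind, comp_rows),
       levene = do.call(rbind, lev_rows))
}

#' Run a full simulate-calibrate-score-compare experiment
#'
#' The end-to-end driver: simulates a cohort on the four-task protocol,
#' fits both calibrations per subject on their grid task, scores every
#' task/correction cell, and runs the statistical protocol — the six
#' paired comparisons (each face task's misclassification and the circle
#' error, each for none-vs-linear, none-vs-SVR and linear-vs-SVR) plus the
#' two Levene variance comparisons (both face tasks, uncalibrated versus
#' pooled post-calibration). Identical configs produce byte-identical
#' outputs. Per-subject stage failures are recorded and the run continues
#' with the remaining subjects.
#'
#' @param config An [experiment_config()].
#' @return An object of class `gaze_experiment`: `config`, `specs`,
#'   `frames`, `profiles`, `metrics` (long per-subject table),
#'   `comparisons` and `levene` (statistics tables), `calibrations`,
#'   `failures`, and `manifest` (config hash, seed, versions). If
#'   `config$output_dir` is set, writes `frames.csv`, `metrics.csv`,
#'   `comparisons.csv`, `levene.csv` and `manifest.json` there.
#' @examples
#' \donttest{
#' ex <- run_experiment(experiment_config(n_subjects = 4, seed = 42))
#' summary(ex)
#' }
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  scr <- screen_layout(config$screen$width, config$screen$height,
                       config$screen$camera_pos)
  specs <- default_protocol(scr, config$tasks)
  coh <- simulate_cohort(config$n_subjects, specs,
                         hyper = do.call(cohort_hyperparameters, config$cohort),
                         seed = config$seed)
  ev <- evaluate_cohort(coh$frames, specs,
                        grouping = config$metrics$grouping %||% "eyes_vs_mouth",
                        circle_variant = config$metrics$circle_variant %||% "to_outline",
                        calibration = config$calibration)
  st <- run_statistics(ev$metrics,
                       config$metrics$circle_variant %||% "to_outline")
  manifest <- list(
    config_hash = config_hash(config), seed = config$seed,
    n_subjects = config$n_subjects,
    n_frames = nrow(coh$frames),
    n_failed_subjects = nrow(ev$failures),
    package_version = as.character(utils::packageVersion("gazecal")),
    r_version = R.version.string
  )
  out <- structure(
    list(config = config, specs = specs, frames = coh$frames,
         profiles = coh$profiles, metrics = ev$metrics,
         comparisons = st$comparisons, levene = st$levene,
         calibrations = ev$calibrations, failures = ev$failures,
         manifest = manifest),
    class = "gaze_experiment"
  )
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$output_dir, f)
    write_frames(out$frames, p("frames.csv"))
    num_csv <- function(df, f) {
      for (cl in names(df)) if (is.double(df[[cl]])) df[[cl]] <- fmt_num(df[[cl]])
      write.csv(df, f, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8",
                eol = "\n")
    }
    num_csv(out$metrics, p("metrics.csv"))
    num_csv(out$comparisons, p("comparisons.csv"))
    num_csv(out$levene, p("levene.csv"))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), p("manifest.json"))
  }
  out
}

#' @export
print.gaze_experiment <- function(x, ...) {
  cat(sprintf("Gaze-tracking evaluation experiment: %d subjects, seed %d\n",
              x$config$n_subjects, x$config$seed))
  cat(sprintf("  %d frames simulated; %d subject(s) failed calibration\n",
              nrow(x$frames), nrow(x$failures)))
  cat("Use summary() for mean metrics and test results.\n")
  invisible(x)
}

#' @export
summary.gaze_experiment <- function(object, ...) {
  m <- object$metrics
  agg <- aggregate(value ~ task_id + metric + correction, data = m, FUN = mean)
  agg <- agg[order(agg$task_id, agg$metric, agg$correction), ]
  out <- list(means = agg, comparisons = object$comparisons,
              levene = object$levene, failures = object$failures)
  class(out) <- "summary.gaze_experiment"
  out
}

#' @export
print.summary.gaze_experiment <- function(x, ...) {
  cat("Mean per-subject metrics by task and correction:\n")
  print(transform(x$means, value = signif(value, 4)), row.names = FALSE)
  cat("\nPaired comparisons (normality-gated):\n")
  print(transform(x$comparisons[, c("task_id", "metric", "comparison",
                                    "test_used", "statistic", "p_value")],
                  statistic = signif(statistic, 4),
                  p_value = signif(p_value, 4)), row.names = FALSE)
  cat("\nLevene variance comparisons (pre vs pooled post-calibration):\n")
  print(transform(x$levene[, c("task_id", "F_statistic", "df1", "df2",
                               "p_value")],
                  F_statistic = signif(F_statistic, 4),
                  p_value = signif(p_value, 4)), row.names = FALSE)
  if (nrow(x$failures)) {
    cat("\nSubject failures:\n"); print(x$failures, row.names = FALSE)
  }
  invisible(x)
}

#' Plot per-subject metrics of an experiment
#'
#' Strip chart of per-subject values for one task and metric across
#' corrections — the standard pre/post-calibration summary view.
#'
#' @param x A `gaze_experiment`.
#' @param task_id Task to plot (default `"face_small"`).
#' @param metric Metric name (default the task's headline metric).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gaze_experiment <- function(x, task_id = "face_small", metric = NULL, ...) {
  if (is.null(metric)) {
    metric <- headline_metric(task_id,
                              x$config$metrics$circle_variant %||% "to_outline")
  }
  m <- x$metrics[x$metrics$task_id == task_id & x$metrics$metric == metric, ]
  if (nrow(m) == 0L) stop("no metric rows for ", task_id, "/", metric)
  corr <- factor(m$correction, levels = c("none", "linear", "svr"))
  plot(jitter(as.integer(corr), 0.3), m$value, xaxt = "n",
       xlab = "correction", ylab = metric, xlim = c(0.5, 3.5),
       main = sprintf("%s: %s", task_id, metric), pch = 19,
       col = grDevices::adjustcolor("steelblue4", 0.6), ...)
  graphics::axis(1, at = 1:3, labels = levels(corr))
  mu <- tapply(m$value, corr, mean)
  segments(1:3 - 0.2, mu, 1:3 + 0.2, mu, lwd = 2, col = "firebrick")
  invisible(x)
}
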