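#' Per-axis first and second moments of a point set
#'
#' Means and variances of the x- and y-coordinates, the sufficient
#' statistics of the moment-matching calibration. Variances use the
#' population convention (divide by n): the gain of the calibration is a
#' ratio of variances, so the convention cancels as long as it is applied
#' to both sides, and dividing by n keeps the fitted transform exactly
#' reproducible.
#'
#' @param points An n x 2 matrix (or data.frame with columns `x`, `y`) of
#'   points in cm, n >= 2.
#' @return A list of class `moment_summary`: `mu_x`, `mu_y` (cm), `var_x`,
#'   `var_y` (cm^2), `n`.
#' @examples
#' moments(rbind(c(0, 0), c(2, 0)))  # mu_x = 1, var_x = 1
#' @export
moments <- function(points) {
  p <- as_points(points)
  if (nrow(p) < 2L) stop("moments() needs at least 2 points")
  stop_if_nonfinite(p)
  n <- nrow(p)
  mu <- colMeans(p)
  v <- colMeans(p^2) - mu^2
  v <- pmax(v, 0)  # guard tiny negative from cancellation
  structure(list(mu_x = mu[[1]], mu_y = mu[[2]],
                 var_x = v[[1]], var_y = v[[2]], n = n),
            class = "moment_summary")
}

#' Fit a per-subject gaze calibration model
#'
#' Fits a correction mapping raw gaze estimates toward true fixation
#' positions, trained on a calibration task (in the standard protocol, the
#' subject's 4 x 4 grid task) and then applied to the remaining tasks via
#' [predict()].
#'
#' **Linear (moment-matching) calibration.** Chooses the unique per-axis
#' affine map \deqn{\tilde{x} = a_x \hat{x} + b_x, \qquad
#' \tilde{y} = a_y \hat{y} + b_y} under which the corrected predictions
#' share the true points' centroid and per-axis variance:
#' \deqn{a_x = \sqrt{\sigma_x^2 / \hat{\sigma}_x^2}, \qquad
#' b_x = \mu_x - a_x \hat{\mu}_x} (y analogous), where \eqn{\mu, \sigma^2}
#' are moments of the true grid points and \eqn{\hat{\mu}, \hat{\sigma}^2}
#' of the predictions. The gains are positive square roots, so the model
#' corrects shift and stretch but, by design, cannot correct a reflection.
#' Zero prediction variance on either axis (all predictions collinear with
#' an axis) is a degenerate fit and raises an error rather than silently
#' falling back to translation only.
#'
#' **SVR calibration.** The comparator: one epsilon-insensitive support
#' vector regression per output axis (RBF kernel, via \pkg{e1071}),
#' regressing the true coordinate on a feature vector derived from the raw
#' prediction — the predicted \eqn{(\hat{x}, \hat{y})} pair, optionally
#' extended with the quadratic terms \eqn{(\hat{x}^2, \hat{y}^2,
#' \hat{x}\hat{y})}. Hyperparameters default to the e1071 conventions
#' (cost 1, epsilon 0.1, gamma = 1/n_features on scaled features) and are
#' recorded in the fitted object.
#'
#' @param truth n x 2 matrix of true fixation points, cm.
#' @param predicted n x 2 matrix of raw gaze estimates, cm, row-matched to
#'   `truth`; n >= 2.
#' @param method `"linear"` (moment matching, the default) or `"svr"`.
#' @param features For `method = "svr"`: `"point"` (\eqn{\hat{x},
#'   \hat{y}}) or `"quadratic"` (adds \eqn{\hat{x}^2, \hat{y}^2,
#'   \hat{x}\hat{y}}).
#' @param cost,epsilon,gamma SVR hyperparameters; `gamma = NULL` uses
#'   1/n_features.
#' @return An object of class `c("linear_calibration", "gaze_calibration")`
#'   or `c("svr_calibration", "gaze_calibration")`, with methods
#'   [print()], [summary()], [coef()] (linear only), [predict()],
#'   [residuals()] and [plot()].
#' @examples
#' grid <- fixation_schedule(make_task_layout("grid"))
#' truth <- cbind(grid$x, grid$y)
#' raw <- truth * 0.8 + rep(c(1.5, -0.6), each = nrow(truth))
#' fit <- gaze_calibration(truth, raw)
#' coef(fit)
#' max(abs(predict(fit, raw) - truth))
#' @export
gaze_calibration <- function(truth, predicted, method = c("linear", "svr"),
                             features = c("point", "quadratic"),
                             cost = 1, epsilon = 0.1, gamma = NULL) {
  method <- match.arg(method)
  features <- match.arg(features)
  truth <- as_points(truth)
  predicted <- as_points(predicted)
  if (nrow(truth) != nrow(predicted)) {
    stop("truth and predicted must have the same number of rows")
  }
  if (nrow(truth) < 2L) stop("calibration needs at least 2 point pairs")
  stop_if_nonfinite(truth, "truth coordinates")
  stop_if_nonfinite(predicted, "predicted coordinates")

  obj <- if (method == "linear") {
    mt <- moments(truth)
    mp <- moments(predicted)
    if (mp$var_x <= 0 || mp$var_y <= 0) {
      stop("degenerate calibration: zero prediction variance on an axis")
    }
    a <- c(sqrt(mt$var_x / mp$var_x), sqrt(mt$var_y / mp$var_y))
    b <- c(mt$mu_x - a[1] * mp$mu_x, mt$mu_y - a[2] * mp$mu_y)
    structure(
      list(method = "linear",
           coefficients = c(a_x = a[1], a_y = a[2], b_x = b[1], b_y = b[2]),
           moments = list(truth = mt, predicted = mp),
           n = nrow(truth)),
      class = c("linear_calibration", "gaze_calibration")
    )
  } else {
    X <- svr_features(predicted, features)
    if (is.null(gamma)) gamma <- 1 / ncol(X)
    fit_axis <- function(y) {
      if (max(y) - min(y) < .Machine$double.eps^0.5) {
        list(constant = mean(y))  # degenerate target: predict the constant
      } else {
        e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                   cost = cost, epsilon = epsilon, gamma = gamma, scale = TRUE)
      }
    }
    structure(
      list(method = "svr", feature_set = features,
           models = list(x = fit_axis(truth[, 1]), y = fit_axis(truth[, 2])),
           hyperparameters = list(kernel = "radial", cost = cost,
                                  epsilon = epsilon, gamma = gamma),
           n = nrow(truth)),
      class = c("svr_calibration", "gaze_calibration")
    )
  }
  obj$truth <- truth
  obj$raw <- predicted
  obj$fitted <- predict(obj, predicted)
  obj
}

svr_features <- function(points, feature_set) {
  p <- as_points(points)
  X <- if (feature_set == "quadratic") {
    cbind(p, p[, 1]^2, p[, 2]^2, p[, 1] * p[, 2])
  } else {
    p
  }
  colnames(X) <- NULL
  X
}

#' Apply a fitted calibration to raw gaze estimates
#'
#' @param object A fitted [gaze_calibration()] model.
#' @param newdata n x 2 matrix of raw gaze estimates, cm. Defaults to the
#'   training predictions.
#' @param ... Unused.
#' @return n x 2 matrix of corrected points, cm.
#' @export
predict.gaze_calibration <- function(object, newdata = object$raw, ...) {
  p <- as_points(newdata, allow_empty = TRUE)
  if (nrow(p) == 0L) return(p)
  stop_if_nonfinite(p, "prediction coordinates")
  if (object$method == "linear") {
    cf <- object$coefficients
    cbind(x = cf[["a_x"]] * p[, 1] + cf[["b_x"]],
          y = cf[["a_y"]] * p[, 2] + cf[["b_y"]])
  } else {
    X <- svr_features(p, object$feature_set)
    axis_pred <- function(m) {
      if (!is.null(m$constant)) rep(m$constant, nrow(X)) else
        as.numeric(predict(m, X))
    }
    cbind(x = axis_pred(object$models$x), y = axis_pred(object$models$y))
  }
}

#' @export
coef.linear_calibration <- function(object, ...) object$coefficients

#' @export
residuals.gaze_calibration <- function(object, ...) {
  r <- object$fitted - object$truth
  colnames(r) <- c("x", "y")
  r
}

#' @export
print.gaze_calibration <- function(x, ...) {
  if (x$method == "linear") {
    cf <- x$coefficients
    cat("Moment-matching linear gaze calibration\n")
    cat(sprintf("  x: corrected = %.4f * raw %+.4f cm\n", cf[["a_x"]], cf[["b_x"]]))
    cat(sprintf("  y: corrected = %.4f * raw %+.4f cm\n", cf[["a_y"]], cf[["b_y"]]))
  } else {
    h <- x$hyperparameters
    cat("SVR gaze calibration (per-axis eps-regression, RBF kernel)\n")
    cat(sprintf("  features: %s; cost = %g, epsilon = %g, gamma = %g\n",
                x$feature_set, h$cost, h$epsilon, h$gamma))
  }
  cat(sprintf("  fitted on %d point pairs\n", x$n))
  invisible(x)
}

#' @export
summary.gaze_calibration <- function(object, ...) {
  r <- residuals(object)
  err <- sqrt(rowSums(r^2))
  out <- list(method = object$method, n = object$n,
              mean_error_cm = mean(err), max_error_cm = max(err),
              coefficients = if (object$method == "linear") object$coefficients)
  class(out) <- "summary.gaze_calibration"
  out
}

#' @export
print.summary.gaze_calibration <- function(x, ...) {
  cat(sprintf("Gaze calibration (%s), %d training pairs\n", x$method, x$n))
  cat(sprintf("  in-sample mean Euclidean error: %.4g cm (max %.4g cm)\n",
              x$mean_error_cm, x$max_error_cm))
  if (!is.null(x$coefficients)) {
    cat("  coefficients:\n")
    print(round(x$coefficients, 6))
  }
  invisible(x)
}

#' Plot a fitted calibration
#'
#' True fixation points, raw estimates, and corrected estimates on the
#' training set, with segments joining each corrected point to its truth.
#'
#' @param x A fitted [gaze_calibration()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gaze_calibration <- function(x, ...) {
  all_pts <- rbind(x$truth, x$raw, x$fitted)
  plot(all_pts[, 1], all_pts[, 2], type = "n", xlab = "x (cm)", ylab = "y (cm)",
       ylim = rev(range(all_pts[, 2])), asp = 1,
       main = sprintf("Gaze calibration (%s)", x$method), ...)
  segments(x$fitted[, 1], x$fitted[, 2], x$truth[, 1], x$truth[, 2],
           col = "grey70")
  points(x$truth[, 1], x$truth[, 2], pch = 19)
  points(x$raw[, 1], x$raw[, 2], pch = 4, col = "firebrick")
  points(x$fitted[, 1], x$fitted[, 2], pch = 1, col = "dodgerblue3")
  legend("topright", pch = c(19, 4, 1), bty = "n",
         col = c("black", "firebrick", "dodgerblue3"),
         legend = c("truth", "raw", "corrected"))
  invisible(x)
}

#' Serialize a linear calibration to or from JSON
#'
#' @param model A fitted `linear_calibration`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return `calibration_to_json()`: JSON string; `calibration_from_json()`:
#'   a `linear_calibration` usable with [predict()] (training data and
#'   fitted values are not round-tripped).
#' @export
calibration_to_json <- function(model, path = NULL) {
  if (!inherits(model, "linear_calibration")) {
    stop("only linear calibrations serialize to JSON; persist SVR models with saveRDS()")
  }
  js <- jsonlite::toJSON(as.list(model$coefficients), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname calibration_to_json
#' @param json JSON string or file path written by [calibration_to_json()].
#' @export
calibration_from_json <- function(json) {
  cf <- unlist(jsonlite::fromJSON(json))
  stopifnot(all(c("a_x", "a_y", "b_x", "b_y") %in% names(cf)))
  structure(
    list(method = "linear", coefficients = cf[c("a_x", "a_y", "b_x", "b_y")],
         n = NA_integer_),
    class = c("linear_calibration", "gaze_calibration")
  )
}
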