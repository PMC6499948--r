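valid_frames <- function(frames) frames[frames$status == "valid", , drop = FALSE]

pred_points <- function(frames) {
  cbind(x = frames$pred_x_cm, y = frames$pred_y_cm)
}

true_label <- function(frames, spec) {
  lab <- spec$waypoints$label[match(frames$waypoint_id, spec$waypoints$waypoint_id)]
  if (anyNA(lab)) stop("frames reference waypoints without landmark labels")
  lab
}

canonical_landmarks <- function(landmarks) {
  if (is.list(landmarks)) landmarks <- do.call(rbind, landmarks)
  m <- as.matrix(landmarks)
  if (is.null(rownames(m)) || nrow(m) < 2L) {
    stop("need >= 2 named landmarks")
  }
  # deterministic tie-break order: left_eye, right_eye, mouth, then others
  pref <- c("left_eye", "right_eye", "mouth")
  ord <- c(intersect(pref, rownames(m)), setdiff(rownames(m), pref))
  m[ord, , drop = FALSE]
}

#' Classify gaze points to their nearest facial landmark
#'
#' Assigns each point to the landmark with minimal Euclidean distance.
#' Exact ties (a measure-zero event under continuous noise) break
#' deterministically in the order left eye, right eye, mouth.
#'
#' @param points n x 2 matrix of gaze points, cm.
#' @param landmarks Named landmark positions: a matrix with rownames or a
#'   named list of `c(x, y)`, at least 2 landmarks.
#' @return Character vector of assigned landmark names, length n.
#' @examples
#' lms <- task_landmarks(make_task_layout("face_small"))
#' classify_fixation(lms["mouth", ], lms)
#' @export
classify_fixation <- function(points, landmarks) {
  p <- as_points(points)
  stop_if_nonfinite(p)
  m <- canonical_landmarks(landmarks)
  d2 <- outer(p[, 1], m[, 1], "-")^2 + outer(p[, 2], m[, 2], "-")^2
  rownames(m)[apply(d2, 1L, which.min)]
}

#' Per-subject nearest-landmark misclassification rate
#'
#' For each valid frame of a face task, the predicted gaze point is
#' assigned to its nearest landmark and compared with the fixated target.
#' Under the default `eyes_vs_mouth` grouping the two eyes collapse into
#' one class before comparison — the endpoint of interest is whether gaze
#' to the eye region can be told apart from gaze to the mouth, so a
#' left/right-eye confusion is not an error. `three_way` counts it as one
#' (sensitivity analysis).
#'
#' @param frames Gaze-frame data.frame (see [simulate_session()]); only
#'   `status == "valid"` frames are scored.
#' @param spec The face `task_spec` the frames belong to (supplies
#'   landmarks and the true class of each waypoint).
#' @param grouping `"eyes_vs_mouth"` (default) or `"three_way"`.
#' @return Data.frame with one row per subject: `subject_id`, `n_valid`,
#'   `n_misclassified`, `rate`.
#' @export
misclassification_rate <- function(frames, spec,
                                   grouping = c("eyes_vs_mouth", "three_way")) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(spec, "task_spec"))
  fr <- valid_frames(frames)
  if (nrow(fr) == 0L) stop("no valid frames to score")
  lms <- task_landmarks(spec)
  assigned <- classify_fixation(pred_points(fr), lms)
  truth <- true_label(fr, spec)
  if (grouping == "eyes_vs_mouth") {
    collapse <- function(z) ifelse(z == "mouth", "mouth", "eyes")
    assigned <- collapse(assigned)
    truth <- collapse(truth)
  }
  mis <- assigned != truth
  out <- do.call(rbind, lapply(split(mis, fr$subject_id), function(m) {
    data.frame(n_valid = length(m), n_misclassified = sum(m),
               rate = mean(m))
  }))
  data.frame(subject_id = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-subject circle-trace error
#'
#' Accuracy on the circle task as the mean Euclidean distance, over a
#' subject's valid frames, between the predicted gaze point and the true
#' target. Two variants:
#'
#' * `to_outline` (the headline): distance to the nearest point of the
#'   circle itself, i.e. `abs(dist(prediction, centre) - radius)` —
#'   scores how well the traced shape matches the circle regardless of
#'   timing;
#' * `to_waypoint`: distance to the waypoint scheduled for that frame —
#'   additionally penalises being at the wrong point of the sequence.
#'
#' `to_outline` never exceeds `to_waypoint` frame-wise, since the
#' scheduled waypoint lies on the circle.
#'
#' @param frames Gaze-frame data.frame for the circle task.
#' @param spec The circle `task_spec` (supplies centre and radius).
#' @param variant `"to_outline"` (default) or `"to_waypoint"`.
#' @return Data.frame with one row per subject: `subject_id`, `variant`,
#'   `n_valid`, `mean_error_cm`.
#' @export
circle_error <- function(frames, spec,
                         variant = c("to_outline", "to_waypoint")) {
  variant <- match.arg(variant)
  stopifnot(inherits(spec, "task_spec"))
  if (is.null(spec$radius)) stop("spec is not a circle task")
  if (spec$radius <= 0) stop("zero or negative circle radius")
  fr <- valid_frames(frames)
  if (nrow(fr) == 0L) stop("no valid frames to score")
  p <- pred_points(fr)
  d <- if (variant == "to_outline") {
    abs(sqrt((p[, 1] - spec$centre[1])^2 + (p[, 2] - spec$centre[2])^2) -
          spec$radius)
  } else {
    sqrt((p[, 1] - fr$true_x_cm)^2 + (p[, 2] - fr$true_y_cm)^2)
  }
  out <- do.call(rbind, lapply(split(d, fr$subject_id), function(v) {
    data.frame(n_valid = length(v), mean_error_cm = mean(v))
  }))
  data.frame(subject_id = rownames(out), variant = variant, out,
             row.names = NULL, stringsAsFactors = FALSE)
}
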