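#' Physical screen layout
#'
#' Describes the phone screen the fixation targets are shown on. The
#' canonical frame is top-left-origin: x increases rightward, y downward,
#' units cm. Gaze estimators that report positions relative to the front
#' camera can be ingested by declaring the camera position in this frame
#' and converting with [camera_to_screen()].
#'
#' @param width,height Screen dimensions in cm. The defaults describe a
#'   6.2 cm x 11.0 cm portrait phone screen.
#' @param camera_pos Position of the front camera in the top-left-origin
#'   frame, cm. May lie outside `[0, width] x [0, height]` (cameras sit in
#'   the bezel above the screen).
#' @param landmarks Optional named list of `c(x, y)` facial-landmark
#'   positions (`left_eye`, `right_eye`, `mouth`); filled in by
#'   [make_task_layout()] for the face tasks.
#' @return An object of class `screen_layout`.
#' @examples
#' scr <- screen_layout()
#' scr$width
#' @export
screen_layout <- function(width = 6.2, height = 11.0,
                          camera_pos = c(width / 2, -0.7),
                          landmarks = NULL) {
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 0) {
    stop("width must be a positive number (cm)")
  }
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) || height <= 0) {
    stop("height must be a positive number (cm)")
  }
  if (length(camera_pos) != 2L || !all(is.finite(camera_pos))) {
    stop("camera_pos must be a finite (x, y) pair")
  }
  if (!is.null(landmarks)) {
    lm <- as_points(do.call(rbind, landmarks))
    if (any(lm[, 1] < 0 | lm[, 1] > width | lm[, 2] < 0 | lm[, 2] > height)) {
      stop("all landmarks must lie on-screen")
    }
  }
  structure(
    list(width = width, height = height, camera_pos = as.numeric(camera_pos),
         origin_convention = "top-left-origin", landmarks = landmarks),
    class = "screen_layout"
  )
}

#' Convert points between the camera frame and the screen frame
#'
#' The camera frame has its origin at the declared camera position, x
#' rightward and y *upward* (the usual convention of gaze estimators that
#' predict relative to the camera); the screen frame is top-left-origin
#' with y downward. The two conversions are exact inverses.
#'
#' @param points An n x 2 matrix of (x, y) points in cm.
#' @param screen A [screen_layout()].
#' @return An n x 2 matrix in the other frame.
#' @export
camera_to_screen <- function(points, screen) {
  p <- as_points(points)
  cbind(x = screen$camera_pos[1] + p[, 1],
        y = screen$camera_pos[2] - p[, 2])
}

#' @rdname camera_to_screen
#' @export
screen_to_camera <- function(points, screen) {
  p <- as_points(points)
  cbind(x = p[, 1] - screen$camera_pos[1],
        y = screen$camera_pos[2] - p[, 2])
}

task_ids <- c("grid", "face_small", "face_large", "circle")

#' Construct one of the four fixation-task layouts
#'
#' Builds the waypoint geometry and fixation schedule parameters for the
#' evaluation protocol's tasks:
#'
#' * `grid` — a 4 x 4 calibration grid of 16 points, visited once each in
#'   row-major order; this task trains per-subject calibration.
#' * `face_small`, `face_large` — a face whose left eye, right eye and
#'   mouth are fixation targets; the subject alternates mouth, left eye,
#'   mouth, right eye, repeated 5 times. The eye–mouth separation (mouth to
#'   the midpoint of the two eyes) is 3.1 cm for the small face and 4.3 cm
#'   for the enlarged face.
#' * `circle` — 12 waypoints equally spaced on a circle, visited once
#'   around, probing smooth-pursuit-like tracking.
#'
#' Each waypoint is fixated for `dwell` seconds at `frame_rate` frames per
#' second (defaults 1 s at 30 fps, i.e. 30 frames per fixation).
#'
#' @param task_id One of `"grid"`, `"face_small"`, `"face_large"`,
#'   `"circle"`.
#' @param screen A [screen_layout()].
#' @param config Named list of layout parameters overriding the defaults:
#'   `grid_margin_x`, `grid_margin_y` (cm insets of the grid from the screen
#'   edge); `face_centre`, `separation`, `eye_gap` (cm) for face tasks;
#'   `centre`, `radius` (cm) for the circle; and `dwell`, `repetitions`,
#'   `frame_rate` for any task.
#' @return An object of class `task_spec` with fields `task_id`,
#'   `waypoints` (data.frame: `waypoint_id`, `label`, `x`, `y`),
#'   `visit_order` (indices into `waypoints`, one pass), `dwell`,
#'   `repetitions`, `frame_rate`, and `screen` (with landmarks set for the
#'   face tasks).
#' @examples
#' spec <- make_task_layout("face_small")
#' eye_mouth_separation(spec)
#' nrow(fixation_schedule(make_task_layout("grid")))
#' @export
make_task_layout <- function(task_id, screen = screen_layout(), config = list()) {
  task_id <- match.arg(task_id, task_ids)
  stopifnot(inherits(screen, "screen_layout"))
  dwell <- config$dwell %||% 1.0
  frame_rate <- config$frame_rate %||% 30
  if (dwell <= 0) stop("dwell must be positive")
  if (frame_rate <= 0) stop("frame_rate must be positive")

  if (task_id == "grid") {
    mx <- config$grid_margin_x %||% 1.0
    my <- config$grid_margin_y %||% 1.5
    xs <- seq(mx, screen$width - mx, length.out = 4)
    ys <- seq(my, screen$height - my, length.out = 4)
    wp <- expand.grid(x = xs, y = ys)[, c("x", "y")]  # row-major: y varies slowest
    wp <- data.frame(waypoint_id = seq_len(16L), label = NA_character_,
                     x = wp$x, y = wp$y, stringsAsFactors = FALSE)
    visit <- seq_len(16L)
    reps <- config$repetitions %||% 1L
  } else if (task_id %in% c("face_small", "face_large")) {
    sep <- config$separation %||% if (task_id == "face_small") 3.1 else 4.3
    if (sep <= 0) stop("eye-mouth separation must be positive")
    gap <- config$eye_gap %||% (0.7 * sep)
    if (gap <= 0) stop("eye gap must be positive")
    centre <- config$face_centre %||% c(screen$width / 2, screen$height / 2)
    # mouth below, eyes symmetric about the vertical through the mouth;
    # separation = |mouth - midpoint(eyes)| by construction (vertical).
    eye_y <- centre[2] - sep / 2
    mouth <- c(centre[1], centre[2] + sep / 2)
    left_eye <- c(centre[1] - gap / 2, eye_y)
    right_eye <- c(centre[1] + gap / 2, eye_y)
    wp <- data.frame(
      waypoint_id = 1:3,
      label = c("left_eye", "right_eye", "mouth"),
      x = c(left_eye[1], right_eye[1], mouth[1]),
      y = c(left_eye[2], right_eye[2], mouth[2]),
      stringsAsFactors = FALSE
    )
    visit <- c(3L, 1L, 3L, 2L)  # mouth, left eye, mouth, right eye
    reps <- config$repetitions %||% 5L
    screen <- screen_layout(screen$width, screen$height, screen$camera_pos,
                            landmarks = list(left_eye = left_eye,
                                             right_eye = right_eye,
                                             mouth = mouth))
  } else { # circle
    centre <- config$centre %||% c(screen$width / 2, screen$height / 2)
    radius <- config$radius %||% 2.5
    if (radius <= 0) stop("circle radius must be positive")
    k <- 0:11
    theta <- -pi / 2 + 2 * pi * k / 12  # start at the top, clockwise in y-down frame
    wp <- data.frame(waypoint_id = k + 1L, label = NA_character_,
                     x = centre[1] + radius * cos(theta),
                     y = centre[2] + radius * sin(theta),
                     stringsAsFactors = FALSE)
    visit <- k + 1L
    reps <- config$repetitions %||% 1L
  }
  if (reps < 1L) stop("repetitions must be >= 1")
  if (any(wp$x < 0 | wp$x > screen$width | wp$y < 0 | wp$y > screen$height)) {
    stop("task '", task_id, "' places waypoints off-screen; adjust config")
  }

  spec <- structure(
    list(task_id = task_id, waypoints = wp, visit_order = visit,
         dwell = dwell, repetitions = as.integer(reps),
         frame_rate = frame_rate, screen = screen),
    class = "task_spec"
  )
  if (task_id == "circle") {
    spec$centre <- c(centre[1], centre[2])
    spec$radius <- radius
  }
  spec
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("Task layout '%s': %d waypoints, %d x %d fixations/run, %.3g s dwell @ %g fps\n",
              x$task_id, nrow(x$waypoints), length(x$visit_order),
              x$repetitions, x$dwell, x$frame_rate))
  invisible(x)
}

#' Frame-level fixation schedule for a task
#'
#' Expands the task's visiting sequence into one row per video frame:
#' waypoints are visited in the task's stated order, each fixated for
#' `dwell * frame_rate` frames, the whole pass repeated `repetitions`
#' times. Frame indices are 0-based.
#'
#' @param spec A `task_spec` from [make_task_layout()].
#' @return A data.frame with columns `frame_index`, `waypoint_id`, `label`,
#'   `x`, `y` (the fixated waypoint's true position).
#' @export
fixation_schedule <- function(spec) {
  stopifnot(inherits(spec, "task_spec"))
  fpw <- round(spec$dwell * spec$frame_rate)
  seq_ids <- rep(rep(spec$visit_order, each = fpw), times = spec$repetitions)
  wp <- spec$waypoints[seq_ids, , drop = FALSE]
  data.frame(frame_index = seq_along(seq_ids) - 1L,
             waypoint_id = wp$waypoint_id,
             label = wp$label,
             x = wp$x, y = wp$y,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Facial landmarks of a face task
#'
#' @param spec A face `task_spec`.
#' @return A 3 x 2 matrix with rows `left_eye`, `right_eye`, `mouth`.
#' @export
task_landmarks <- function(spec) {
  stopifnot(inherits(spec, "task_spec"))
  lm <- spec$screen$landmarks
  if (is.null(lm)) stop("task '", spec$task_id, "' has no facial landmarks")
  m <- do.call(rbind, lm)
  colnames(m) <- c("x", "y")
  m
}

#' Eye-mouth separation of a face task
#'
#' Euclidean distance from the mouth landmark to the midpoint of the two
#' eye landmarks, in cm.
#'
#' @param spec A face `task_spec`.
#' @return Separation in cm.
#' @export
eye_mouth_separation <- function(spec) {
  lm <- task_landmarks(spec)
  mid <- (lm["left_eye", ] + lm["right_eye", ]) / 2
  sqrt(sum((lm["mouth", ] - mid)^2))
}

#' Serialize a task layout to or from JSON
#'
#' The JSON document carries `task_id`, the waypoint array, the visiting
#' order, timing parameters and the screen block (including landmarks
#' where present), and round-trips losslessly.
#'
#' @param spec A `task_spec`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return `task_to_json()`: the JSON string (invisibly, if written to a
#'   file); `task_from_json()`: the reconstructed `task_spec`.
#' @export
task_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "task_spec"))
  doc <- list(
    task_id = spec$task_id,
    waypoints = spec$waypoints,
    visit_order = spec$visit_order,
    dwell = spec$dwell,
    repetitions = spec$repetitions,
    frame_rate = spec$frame_rate,
    screen = list(width = spec$screen$width, height = spec$screen$height,
                  camera_pos = spec$screen$camera_pos,
                  landmarks = spec$screen$landmarks)
  )
  if (!is.null(spec$radius)) {
    doc$centre <- spec$centre
    doc$radius <- spec$radius
  }
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname task_to_json
#' @param json A JSON string or path to a JSON file written by
#'   [task_to_json()].
#' @export
task_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  lms <- doc$screen$landmarks
  if (!is.null(lms)) lms <- lapply(lms, as.numeric)
  scr <- screen_layout(doc$screen$width, doc$screen$height,
                       as.numeric(doc$screen$camera_pos), landmarks = lms)
  wp <- as.data.frame(doc$waypoints, stringsAsFactors = FALSE)
  # jsonlite drops an all-NA column's values; restore the schema
  wp$label <- if (is.null(doc$waypoints$label)) NA_character_ else
    as.character(doc$waypoints$label)
  wp <- wp[, c("waypoint_id", "label", "x", "y")]
  wp$waypoint_id <- as.integer(wp$waypoint_id)
  spec <- structure(
    list(task_id = doc$task_id, waypoints = wp,
         visit_order = as.integer(doc$visit_order),
         dwell = doc$dwell, repetitions = as.integer(doc$repetitions),
         frame_rate = doc$frame_rate, screen = scr),
    class = "task_spec"
  )
  if (!is.null(doc$radius)) {
    spec$centre <- as.numeric(doc$centre)
    spec$radius <- doc$radius
  }
  spec
}

#' The default four-task protocol
#'
#' @param screen A [screen_layout()].
#' @param config Optional named list of per-task config lists, e.g.
#'   `list(circle = list(radius = 2))`.
#' @return Named list of `task_spec`s: `grid`, `face_small`, `face_large`,
#'   `circle`.
#' @export
default_protocol <- function(screen = screen_layout(), config = list()) {
  setNames(lapply(task_ids, function(id) {
    make_task_layout(id, screen, config[[id]] %||% list())
  }), task_ids)
}
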