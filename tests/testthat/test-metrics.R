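face_lms <- task_landmarks(protocol$face_small)

# build a face-task frame table with given predictions over the schedule
face_frames <- function(pred, spec = protocol$face_small, subject = "s1") {
  sch <- fixation_schedule(spec)
  data.frame(subject_id = subject, task_id = spec$task_id,
             frame_index = sch$frame_index, waypoint_id = sch$waypoint_id,
             true_x_cm = sch$x, true_y_cm = sch$y,
             pred_x_cm = pred[, 1], pred_y_cm = pred[, 2],
             status = "valid", stringsAsFactors = FALSE)
}

test_that("nearest-landmark assignment matches a brute-force scan", {
  expect_equal(classify_fixation(face_lms["mouth", ], face_lms), "mouth")
  # exactly representable tie between the eyes: order puts left eye first
  tie_lms <- rbind(left_eye = c(1, 0), right_eye = c(3, 0), mouth = c(2, 10))
  expect_equal(classify_fixation(c(2, 0), tie_lms), "left_eye")
  set.seed(14)
  pts <- cbind(runif(1000, -2, 9), runif(1000, -2, 13))
  expect_equal(classify_fixation(pts, face_lms), oracle_nearest(pts, face_lms))
  expect_error(classify_fixation(c(1, 1), face_lms["mouth", , drop = FALSE]),
               ">= 2")
})

test_that("misclassification is 0 at truth and 0.5 when glued to the mouth", {
  sch <- fixation_schedule(protocol$face_small)
  at_truth <- face_frames(cbind(sch$x, sch$y))
  expect_equal(misclassification_rate(at_truth, protocol$face_small)$rate, 0)
  # all predictions on the mouth: the half of frames fixating eyes are wrong
  glued <- face_frames(matrix(rep(face_lms["mouth", ], each = nrow(sch)),
                              ncol = 2))
  expect_equal(misclassification_rate(glued, protocol$face_small)$rate, 0.5)
})

test_that("eye-eye confusions count only under three-way grouping", {
  sch <- fixation_schedule(protocol$face_small)
  # predict the *other* eye whenever an eye is fixated
  swap <- cbind(sch$x, sch$y)
  is_left <- sch$label == "left_eye"
  is_right <- sch$label == "right_eye"
  swap[is_left, ] <- matrix(rep(face_lms["right_eye", ], sum(is_left)),
                            ncol = 2, byrow = TRUE)
  swap[is_right, ] <- matrix(rep(face_lms["left_eye", ], sum(is_right)),
                             ncol = 2, byrow = TRUE)
  fr <- face_frames(swap)
  expect_equal(misclassification_rate(fr, protocol$face_small,
                                      "eyes_vs_mouth")$rate, 0)
  expect_equal(misclassification_rate(fr, protocol$face_small,
                                      "three_way")$rate, 0.5)
})

test_that("only valid frames are scored and empty subjects error", {
  sch <- fixation_schedule(protocol$face_small)
  fr <- face_frames(cbind(sch$x, sch$y))
  fr$status[1:30] <- "blink"
  fr$pred_x_cm[1:30] <- NA; fr$pred_y_cm[1:30] <- NA
  out <- misclassification_rate(fr, protocol$face_small)
  expect_equal(out$n_valid, nrow(sch) - 30)
  fr$status <- "segmentation_failed"
  expect_error(misclassification_rate(fr, protocol$face_small), "no valid")
})

test_that("two-landmark Gaussian rate matches the normal-CDF oracle", {
  p_obs <- two_landmark_rate(d = 3.1, sigma = 2, n = 10000, seed = 5)
  p_th <- pnorm(-3.1 / 4)
  expect_lt(abs(p_obs - p_th), 3 * sqrt(p_th * (1 - p_th) / 10000))
})

test_that("misclassification is invariant under joint rigid motion", {
  set.seed(6)
  pts <- cbind(rnorm(500, 3, 2), rnorm(500, 5, 2))
  base <- classify_fixation(pts, face_lms)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  v <- c(4, -2)
  move <- function(p) sweep(p %*% t(R), 2, v, "+")
  moved_lms <- move(face_lms); rownames(moved_lms) <- rownames(face_lms)
  expect_equal(classify_fixation(move(pts), moved_lms), base)
})

test_that("circle error separates the outline and waypoint variants", {
  spec <- protocol$circle
  sch <- fixation_schedule(spec)
  on_wp <- face_frames(cbind(sch$x, sch$y), spec)
  expect_equal(circle_error(on_wp, spec, "to_outline")$mean_error_cm, 0)
  expect_equal(circle_error(on_wp, spec, "to_waypoint")$mean_error_cm, 0)
  # at the centre: outline distance is exactly the radius
  at_ctr <- face_frames(matrix(rep(spec$centre, each = nrow(sch)), ncol = 2),
                        spec)
  expect_equal(circle_error(at_ctr, spec, "to_outline")$mean_error_cm,
               spec$radius)
  # on the circle but at the wrong waypoint: outline 0, waypoint > 0
  shift <- face_frames(cbind(sch$x, sch$y)[c(31:nrow(sch), 1:30), ], spec)
  expect_equal(circle_error(shift, spec, "to_outline")$mean_error_cm, 0,
               tolerance = 1e-12)
  expect_gt(circle_error(shift, spec, "to_waypoint")$mean_error_cm, 0.5)
})

test_that("outline error never exceeds waypoint error and is rotation-invariant", {
  spec <- protocol$circle
  sch <- fixation_schedule(spec)
  set.seed(9)
  pred <- cbind(sch$x, sch$y) + matrix(rnorm(2 * nrow(sch), 0, 1), ncol = 2)
  fr <- face_frames(pred, spec)
  e_out <- circle_error(fr, spec, "to_outline")$mean_error_cm
  e_wp <- circle_error(fr, spec, "to_waypoint")$mean_error_cm
  expect_lte(e_out, e_wp)
  # rotate predictions about the centre: outline unchanged, waypoint not
  th <- 2 * pi / 12 * 3
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- sweep(sweep(pred, 2, spec$centre) %*% t(R), 2, spec$centre, "+")
  fr_rot <- face_frames(rot, spec)
  expect_equal(circle_error(fr_rot, spec, "to_outline")$mean_error_cm, e_out,
               tolerance = 1e-12)
  expect_gt(abs(circle_error(fr_rot, spec, "to_waypoint")$mean_error_cm - e_wp),
            0.01)
})

test_that("misclassification falls strictly with landmark separation", {
  for (seed in 1:5) {
    r_small <- two_landmark_rate(d = 3.1, sigma = 2, n = 4000, seed = seed)
    r_large <- two_landmark_rate(d = 4.3, sigma = 2, n = 4000, seed = seed)
    expect_lt(r_large, r_small)
  }
})
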