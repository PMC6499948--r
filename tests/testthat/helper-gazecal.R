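# Shared fixtures: the default protocol, a noiseless affine profile, and a
# brute-force nearest-landmark oracle kept independent of classify_fixation().

protocol <- default_protocol()

affine_profile <- function(bias, scale, seed = 1L, ...) {
  subject_profile("fx", bias = bias, scale = scale, noise_sd = c(0, 0),
                  seed = seed, ...)
}

# Exhaustive per-point scan, same tie-break order as the package claims.
oracle_nearest <- function(points, landmarks) {
  pref <- c("left_eye", "right_eye", "mouth")
  ord <- c(intersect(pref, rownames(landmarks)),
           setdiff(rownames(landmarks), pref))
  landmarks <- landmarks[ord, , drop = FALSE]
  apply(points, 1L, function(p) {
    d <- sqrt((landmarks[, 1] - p[1])^2 + (landmarks[, 2] - p[2])^2)
    rownames(landmarks)[which.min(d)]
  })
}

# Simulate the two-landmark fixation model: half the frames fixate each of
# two landmarks separated by d, with isotropic Gaussian jitter sigma, and
# return the observed nearest-landmark misclassification rate.
two_landmark_rate <- function(d, sigma, n, seed) {
  lms <- rbind(left_eye = c(0, 0), mouth = c(0, d))
  truth_id <- rep(rownames(lms), each = n / 2)
  truth <- lms[truth_id, , drop = FALSE]
  set.seed(seed)
  pred <- truth + matrix(rnorm(n * 2, 0, sigma), ncol = 2)
  mean(classify_fixation(pred, lms) != truth_id)
}
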