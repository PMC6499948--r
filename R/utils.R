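# Internal helpers: point-matrix coercion and scoped RNG.

# Coerce to an n x 2 numeric matrix with columns x, y.
as_points <- function(p, allow_empty = FALSE) {
  if (is.data.frame(p)) {
    if (all(c("x", "y") %in% names(p))) {
      p <- cbind(p$x, p$y)
    } else {
      p <- as.matrix(p)
    }
  }
  if (is.numeric(p) && is.null(dim(p)) && length(p) == 2L) {
    p <- matrix(p, nrow = 1L)
  }
  p <- as.matrix(p)
  if (ncol(p) != 2L) {
    stop("points must be an n x 2 matrix (or data.frame with columns x, y)")
  }
  if (!allow_empty && nrow(p) == 0L) stop("empty point set")
  storage.mode(p) <- "double"
  colnames(p) <- c("x", "y")
  p
}

stop_if_nonfinite <- function(p, what = "coordinates") {
  if (!all(is.finite(p))) stop("non-finite ", what)
}

# Run `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards so simulation calls do not disturb the session.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic per-subject seed stream: cohort seed k, subject index i
# maps to (k * 10007 + i) mod 2^31-1, documented so individual subjects can
# be regenerated in isolation.
subject_seed <- function(cohort_seed, index) {
  as.integer((as.double(cohort_seed) * 10007 + index) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
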