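# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs a
# user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Derive a child seed from a master seed and a counter, kept inside the
# 32-bit integer range R requires.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 1000003 + counter) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_symmetric_matrix <- function(m, tol = 1e-9, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stopf("%s must be a square matrix", what)
  }
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stopf("%s contains a non-finite value at (%d, %d)", what, bad[1L], bad[2L])
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stopf("%s contains a negative value at (%d, %d)", what, bad[1L], bad[2L])
  }
  d <- abs(m - t(m))
  if (any(d > tol)) {
    bad <- which(d > tol, arr.ind = TRUE)
    bad <- bad[bad[, 1L] < bad[, 2L], , drop = FALSE][1L, ]
    stopf("%s is asymmetric at (%d, %d): %g vs %g",
          what, bad[1L], bad[2L], m[bad[1L], bad[2L]], m[bad[2L], bad[1L]])
  }
  invisible(m)
}

#' Trapezoidal area under a curve
#'
#' Integrates metric values sampled on a sparsity grid by the trapezoidal
#' rule, the threshold-robust summary used to compare network metrics across
#' subjects without committing to a single threshold.
#'
#' @param x Grid locations (strictly increasing).
#' @param y Metric values at `x`; a vector, or a matrix with one row per grid
#'   point (columns integrated independently, e.g. one column per node).
#' @return A scalar for vector `y`, otherwise one value per column.
#' @examples
#' auc_trapezoid(seq(0.10, 0.34, by = 0.01), rep(2, 25))  # 0.24 * 2
#' @export
auc_trapezoid <- function(x, y) {
  x <- as.numeric(x)
  if (length(x) < 2L) stopf("need at least two grid points")
  if (any(diff(x) <= 0)) stopf("grid must be strictly increasing")
  dx <- diff(x)
  if (is.matrix(y)) {
    if (nrow(y) != length(x)) stopf("nrow(y) must equal length(x)")
    mid <- (y[-1L, , drop = FALSE] + y[-nrow(y), , drop = FALSE]) / 2
    colSums(mid * dx)
  } else {
    if (length(y) != length(x)) stopf("length(y) must equal length(x)")
    sum((y[-1L] + y[-length(y)]) / 2 * dx)
  }
}
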