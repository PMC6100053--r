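#' Baseline-estimation configuration
#'
#' Asymmetric least squares (AsLS) parameters. `mu` is the roughness
#' penalty weight on squared second differences (larger = stiffer
#' baseline); `p` is the asymmetry weight given to points above the
#' baseline (`1 - p` to points below), so small `p` makes the fit hug the
#' valleys under the absorption peaks. `p = 0` is accepted literally —
#' points above the baseline then carry zero weight and the `mu` penalty
#' alone keeps the system nonsingular — but the default uses a small
#' positive `p` for numerical robustness.
#'
#' @param mu regularization weight, > 0 (default 100).
#' @param p asymmetry weight in `[0, 0.5]` (default 0.001).
#' @param max_iter maximum reweighting iterations (default 50).
#' @return A `baseline_config` list.
#' @export
baseline_config <- function(mu = 100, p = 0.001, max_iter = 50) {
  mu <- as.numeric(mu)[1]
  p <- as.numeric(p)[1]
  max_iter <- as.integer(max_iter)
  if (!is.finite(mu) || mu <= 0) stop("`mu` must be > 0", call. = FALSE)
  if (!is.finite(p) || p < 0 || p > 0.5) {
    stop("`p` must lie in [0, 0.5]", call. = FALSE)
  }
  if (max_iter < 1L) stop("`max_iter` must be >= 1", call. = FALSE)
  structure(list(mu = mu, p = p, max_iter = max_iter),
            class = "baseline_config")
}

#' Asymmetric least squares baseline estimation
#'
#' Estimates a slowly varying baseline `z` under a spectrum `y` by
#' minimizing
#' \deqn{\sum_i w_i (y_i - z_i)^2 + \mu \sum_i (\Delta^2 z_i)^2}
#' with asymmetric weights `w_i = p` where `y_i > z_i` and `w_i = 1 - p`
#' otherwise. Starting from uniform weights, the penalized weighted
#' least-squares system `(W + mu D'D) z = W y` (D = second-difference
#' operator on the index grid) is solved as a sparse banded system and the
#' weights updated from the sign of `y - z`, until no weight flips or
#' `max_iter` is reached (then the last iterate is returned with a
#' `converged = FALSE` attribute and a warning).
#'
#' @param y numeric spectrum, length >= 3, finite.
#' @param config a [baseline_config()].
#' @return the baseline `z` (numeric, same length), with attributes
#'   `iterations` and `converged`.
#' @examples
#' y <- seq(0, 1, length.out = 463) + dnorm(1:463, 231, 4) * 10
#' z <- asls_baseline(y)
#' @export
asls_baseline <- function(y, config = baseline_config()) {
  stopifnot(inherits(config, "baseline_config"))
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (!all(is.finite(y))) stop("non-finite values in spectrum", call. = FALSE)
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  P <- config$mu * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(config$max_iter)) {
    iterations <- it
    A <- P + Matrix::Diagonal(n, x = w)
    z_new <- as.numeric(Matrix::solve(A, w * y))
    # fixed point: either no weight flips, or the iterate stopped moving
    # (residuals at machine precision flip weights spuriously)
    stable <- it > 1L && max(abs(z_new - z)) <= 1e-10 * (1 + max(abs(z_new)))
    z <- z_new
    w_new <- ifelse(y > z, config$p, 1 - config$p)
    if (stable || (identical(w_new, w) && it > 1L)) {
      converged <- TRUE
      break
    }
    w <- w_new
  }
  if (!converged) {
    warning("AsLS weights did not stabilize within ", config$max_iter,
            " iterations; returning last iterate", call. = FALSE)
  }
  attr(z, "iterations") <- iterations
  attr(z, "converged") <- converged
  z
}

#' Subtract an estimated baseline from a spectrum
#'
#' Elementwise `spectrum - baseline`, pulling baseline drift back to zero
#' absorbance. Peak locations are unaffected; only the slowly varying
#' pedestal is removed.
#'
#' @param spectrum,baseline equal-length numeric vectors.
#' @return corrected spectrum.
#' @export
correct_baseline <- function(spectrum, baseline) {
  if (length(spectrum) != length(baseline)) {
    stop("length mismatch between spectrum and baseline", call. = FALSE)
  }
  as.numeric(spectrum) - as.numeric(baseline)
}
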