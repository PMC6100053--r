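#' Construct a frequency spectrum
#'
#' One-sided complex field spectrum on a THz grid. Usually produced by
#' [fourier_spectrum()]; the constructor validates invariants when building
#' synthetic spectra directly.
#'
#' @param frequency non-negative, strictly increasing THz grid.
#' @param complex_field complex field per frequency, same length.
#' @param magnitude_db optional dB magnitude column (see [to_decibel()]).
#' @param dt original sampling interval in ps (kept for inversion).
#' @param n_time original trace length (kept for inversion).
#' @return A `freq_spectrum` object.
#' @export
freq_spectrum <- function(frequency, complex_field, magnitude_db = NULL,
                          dt = NA_real_, n_time = NA_integer_) {
  frequency <- as.numeric(frequency)
  complex_field <- as.complex(complex_field)
  if (length(frequency) != length(complex_field)) {
    stop("`frequency` and `complex_field` must have equal length", call. = FALSE)
  }
  if (length(frequency) == 0) stop("empty spectrum", call. = FALSE)
  if (any(frequency < 0)) stop("frequencies must be non-negative", call. = FALSE)
  if (any(diff(frequency) <= 0)) {
    stop("frequency grid must be strictly increasing", call. = FALSE)
  }
  structure(
    list(frequency = frequency, complex_field = complex_field,
         magnitude_db = magnitude_db, dt = dt, n_time = as.integer(n_time)),
    class = "freq_spectrum"
  )
}

#' @export
print.freq_spectrum <- function(x, ...) {
  cat(sprintf("<freq_spectrum> %d bins, %.4f-%.4f THz\n",
              length(x$frequency), x$frequency[1],
              x$frequency[length(x$frequency)]))
  invisible(x)
}

#' One-sided Fourier spectrum of a time-domain trace
#'
#' Computes the discrete Fourier transform of the trace, scaled by the
#' sampling interval so that it approximates the continuous-time transform,
#' and returns the non-negative-frequency half. With `window = "none"` and
#' `pad_to` equal to the trace length, Parseval's identity holds between
#' the time trace and the two-sided spectrum. Time in ps gives frequency
#' directly in THz.
#'
#' Zero padding (default: next power of two at least 4x the trace length)
#' densifies the frequency grid; it adds no information but makes
#' interpolation onto a fixed analysis grid well conditioned.
#'
#' @param trace a [td_trace()].
#' @param window `"none"` (default) or `"hann"`.
#' @param pad_to FFT length, >= trace length. Default
#'   `next_pow2(4 * length)`.
#' @return A [freq_spectrum()] with `length(pad_to)/2 + 1` bins.
#' @examples
#' tr <- td_trace(seq(0, 33.5, length.out = 512),
#'                exp(-(seq(0, 33.5, length.out = 512) - 5)^2))
#' sp <- fourier_spectrum(tr)
#' @export
fourier_spectrum <- function(trace, window = c("none", "hann"), pad_to = NULL) {
  stopifnot(inherits(trace, "td_trace"))
  window <- match.arg(window)
  n <- length(trace$time)
  if (is.null(pad_to)) pad_to <- next_pow2(4L * n)
  pad_to <- as.integer(pad_to)
  if (pad_to < n) {
    stop("`pad_to` (", pad_to, ") must be >= trace length (", n, ")",
         call. = FALSE)
  }
  a <- trace$amplitude
  if (window == "hann") {
    a <- a * 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  }
  dt <- trace_dt(trace)
  x <- c(a, numeric(pad_to - n))
  X <- stats::fft(x) * dt
  # phase referenced to the trace's own time origin
  nh <- pad_to %/% 2L
  freq <- (0:nh) / (pad_to * dt)
  Xh <- X[1:(nh + 1L)] * exp(-2i * pi * freq * trace$time[1])
  freq_spectrum(freq, Xh, dt = dt, n_time = n)
}

next_pow2 <- function(n) {
  p <- 1L
  while (p < n) p <- p * 2L
  p
}

#' Reconstruct a time trace from a one-sided spectrum
#'
#' Inverse of [fourier_spectrum()] (window `"none"`): rebuilds the two-sided
#' Hermitian spectrum, inverts the FFT, and truncates to the original trace
#' length. The time axis starts at `t0`.
#'
#' @param spectrum a [freq_spectrum()] carrying `dt` and `n_time`.
#' @param t0 start time in ps for the reconstructed axis (default 0).
#' @return A [td_trace()].
#' @export
inverse_spectrum <- function(spectrum, t0 = 0) {
  stopifnot(inherits(spectrum, "freq_spectrum"))
  if (!is.finite(spectrum$dt) || is.na(spectrum$n_time)) {
    stop("spectrum lacks `dt`/`n_time`; cannot invert", call. = FALSE)
  }
  nh <- length(spectrum$frequency) - 1L
  npad <- 2L * nh
  dt <- spectrum$dt
  Xh <- spectrum$complex_field * exp(2i * pi * spectrum$frequency * t0)
  X <- c(Xh, Conj(rev(Xh[2:nh])))
  x <- Re(stats::fft(X, inverse = TRUE)) / (npad * dt)
  n <- spectrum$n_time
  td_trace(t0 + dt * seq(0, n - 1), x[1:n])
}

#' Convert a spectrum to decibel magnitude
#'
#' Adds `magnitude_db = 20 log10(|E(nu)| / max|E|)`, so the strongest bin is
#' at 0 dB; the scale is invariant to overall field rescaling.
#'
#' @param spectrum a [freq_spectrum()].
#' @return The spectrum with `magnitude_db` filled in.
#' @export
to_decibel <- function(spectrum) {
  stopifnot(inherits(spectrum, "freq_spectrum"))
  m <- Mod(spectrum$complex_field)
  mx <- max(m)
  if (mx == 0) stop("all-zero spectrum: dB scale undefined", call. = FALSE)
  spectrum$magnitude_db <- 20 * log10(m / mx)
  spectrum
}

#' Effective refractive index from the pulse group delay
#'
#' The sample pulse arrives later than the reference by
#' `dt = (n_eff - 1) d / c`; inverting gives a one-number index estimate
#' `n_eff = 1 + c (t_sample - t_reference) / d` with c = 0.299792458 mm/ps.
#' Pulse arrival times are the parabolic-interpolated maxima of
#' `|amplitude|` ([peak_time()]). This delay-based estimate tracks the
#' band-average of the dispersive index `n(nu)` to within a few times 0.01
#' for weakly dispersive pellets.
#'
#' @param sample,reference [td_trace()] objects with unique global maxima.
#' @param thickness_mm pellet thickness d in mm (> 0).
#' @return dimensionless effective index.
#' @examples
#' # printed arrival times 6.445 ps (sample) vs 4.169 ps (reference),
#' # d = 1.66 mm -> n_eff = 1 + 0.299792458 * 2.276 / 1.66 = 1.411
#' @export
group_delay_index <- function(sample, reference, thickness_mm) {
  stopifnot(inherits(sample, "td_trace"), inherits(reference, "td_trace"))
  thickness_mm <- as.numeric(thickness_mm)[1]
  if (!is.finite(thickness_mm) || thickness_mm <= 0) {
    stop("`thickness_mm` must be > 0", call. = FALSE)
  }
  delay <- peak_time(sample) - peak_time(reference)
  if (delay < 0) {
    warning("sample peak arrives before reference; n_eff < 1", call. = FALSE)
  }
  1 + C_MM_PS * delay / thickness_mm
}
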