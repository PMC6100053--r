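#' Construct a time-domain trace
#'
#' A `td_trace` holds one sampled THz field pulse: a strictly increasing,
#' uniformly spaced time axis in picoseconds and the measured electric-field
#' amplitude in arbitrary units. Instrument averaging is recorded in
#' `n_scans`; pellet geometry travels separately in an [acquisition_meta()]
#' object or as the `thickness_mm` attribute.
#'
#' @param time numeric vector, time axis in ps; uniform spacing required
#'   (relative tolerance 1e-9) and length >= 16.
#' @param amplitude numeric vector of field values (a.u.), same length as
#'   `time`; all values finite.
#' @param label free-text label carried through the pipeline.
#' @param n_scans positive integer, number of averaged scans.
#' @param meta optional [acquisition_meta()] record.
#' @return An object of class `td_trace`: a list with elements `time`,
#'   `amplitude`, `label`, `n_scans`, `meta`.
#' @examples
#' tr <- td_trace(seq(0, 33.5, length.out = 64), sin(seq(0, 6, length.out = 64)))
#' trace_dt(tr)
#' @export
td_trace <- function(time, amplitude, label = "", n_scans = 1L, meta = NULL) {
  time <- as.numeric(time)
  amplitude <- as.numeric(amplitude)
  if (length(time) != length(amplitude)) {
    stop("`time` and `amplitude` must have equal length", call. = FALSE)
  }
  if (length(time) < 16) {
    stop("trace too short: need at least 16 samples, got ", length(time),
         call. = FALSE)
  }
  if (!all(is.finite(time)) || !all(is.finite(amplitude))) {
    stop("trace contains non-finite values", call. = FALSE)
  }
  dt <- diff(time)
  if (any(dt <= 0)) stop("time axis must be strictly increasing", call. = FALSE)
  if (max(abs(dt - dt[1])) > 1e-9 * abs(dt[1])) {
    stop("time axis is not uniformly spaced (relative tolerance 1e-9)",
         call. = FALSE)
  }
  n_scans <- as.integer(n_scans)
  if (is.na(n_scans) || n_scans < 1L) stop("`n_scans` must be >= 1", call. = FALSE)
  if (!is.null(meta) && !inherits(meta, "acquisition_meta")) {
    stop("`meta` must be an acquisition_meta object", call. = FALSE)
  }
  structure(
    list(time = time, amplitude = amplitude, label = as.character(label)[1],
         n_scans = n_scans, meta = meta),
    class = "td_trace"
  )
}

#' Acquisition metadata for one pellet measurement
#'
#' @param thickness_mm pellet thickness d in mm, must be > 0.
#' @param temperature_K acquisition temperature (default 294 K, room
#'   temperature under dry nitrogen).
#' @param sample_id free-text identifier.
#' @return An `acquisition_meta` list.
#' @export
acquisition_meta <- function(thickness_mm, temperature_K = 294, sample_id = "") {
  thickness_mm <- as.numeric(thickness_mm)[1]
  if (!is.finite(thickness_mm) || thickness_mm <= 0) {
    stop("`thickness_mm` must be a positive number", call. = FALSE)
  }
  structure(
    list(thickness_mm = thickness_mm,
         temperature_K = as.numeric(temperature_K)[1],
         sample_id = as.character(sample_id)[1]),
    class = "acquisition_meta"
  )
}

#' Sampling interval of a trace
#' @param trace a [td_trace()].
#' @return scalar time step in ps.
#' @export
trace_dt <- function(trace) {
  stopifnot(inherits(trace, "td_trace"))
  (trace$time[length(trace$time)] - trace$time[1]) / (length(trace$time) - 1)
}

#' @export
print.td_trace <- function(x, ...) {
  cat(sprintf("<td_trace> %d samples, %.4f-%.4f ps (dt = %.5f ps)\n",
              length(x$time), x$time[1], x$time[length(x$time)], trace_dt(x)))
  if (nzchar(x$label)) cat("  label:", x$label, "\n")
  cat(sprintf("  n_scans: %d, max |amplitude| = %.4f a.u.\n",
              x$n_scans, max(abs(x$amplitude))))
  if (!is.null(x$meta)) {
    cat(sprintf("  thickness: %.3f mm\n", x$meta$thickness_mm))
  }
  invisible(x)
}

#' Interpolated time of the trace's amplitude maximum
#'
#' Locates the global maximum of `|amplitude|` and refines it by parabolic
#' interpolation through the three samples around the discrete maximum,
#' giving sub-sample (few-fs) precision on the pulse arrival time.
#'
#' @param trace a [td_trace()].
#' @return arrival time of the pulse peak in ps.
#' @export
peak_time <- function(trace) {
  stopifnot(inherits(trace, "td_trace"))
  a <- abs(trace$amplitude)
  i <- which.max(a)
  n <- length(a)
  if (i == 1L || i == n) return(trace$time[i])
  parabolic_vertex(trace$time[(i - 1):(i + 1)], a[(i - 1):(i + 1)])$x
}

# Vertex of the parabola through three points; falls back to the middle
# point when the triple is degenerate (flat or non-concave).
parabolic_vertex <- function(x, y) {
  denom <- y[1] - 2 * y[2] + y[3]
  if (denom >= 0 || !is.finite(denom)) return(list(x = x[2], y = y[2]))
  delta <- 0.5 * (y[1] - y[3]) / denom
  h <- x[2] - x[1]
  list(x = x[2] + delta * h, y = y[2] - 0.25 * (y[1] - y[3]) * delta)
}

# Speed of light in mm/ps (== 1e8 m/s units kept O(1) for THz/ps/mm work).
C_MM_PS <- 0.299792458
# and in cm/ps, for absorption coefficients in 1/cm.
C_CM_PS <- 0.0299792458
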