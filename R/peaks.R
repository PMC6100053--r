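#' Construct a peak list
#'
#' A data frame of absorption peaks — detected or theoretical — with one
#' row per line: frequency (THz), intensity (absorption units at the
#' maximum), prominence, FWHM width estimate, and an optional
#' vibration-mode label (opaque text such as `"d(C-N)ip"`).
#'
#' @param frequency THz positions.
#' @param intensity heights (default NA).
#' @param prominence topographic prominences (default NA).
#' @param width FWHM estimates in THz (default NA).
#' @param label mode labels (default "").
#' @return data frame of class `peak_list`, sorted by frequency.
#' @export
peak_list <- function(frequency = numeric(0), intensity = NA_real_,
                      prominence = NA_real_, width = NA_real_, label = "") {
  n <- length(frequency)
  df <- data.frame(frequency = as.numeric(frequency),
                   intensity = rep_len(as.numeric(intensity), n),
                   prominence = rep_len(as.numeric(prominence), n),
                   width = rep_len(as.numeric(width), n),
                   label = rep_len(as.character(label), n),
                   stringsAsFactors = FALSE)
  if (any(df$prominence < 0, na.rm = TRUE)) {
    stop("prominence must be >= 0", call. = FALSE)
  }
  if (any(df$width <= 0, na.rm = TRUE)) stop("width must be > 0", call. = FALSE)
  df <- df[order(df$frequency), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("peak_list", "data.frame")
  df
}

# topographic prominence of local maximum i in y: height above the higher
# of the two key saddles (minima toward the nearest higher terrain on each
# side, or to the signal edge).
peak_prominences <- function(y, idx) {
  vapply(idx, function(i) {
    h <- y[i]
    left <- if (i > 1) {
      seg <- y[(i - 1):1]
      stopi <- which(seg > h)[1]
      if (is.na(stopi)) min(seg) else min(seg[1:stopi])
    } else h
    right <- if (i < length(y)) {
      seg <- y[(i + 1):length(y)]
      stopi <- which(seg > h)[1]
      if (is.na(stopi)) min(seg) else min(seg[1:stopi])
    } else h
    h - max(left, right)
  }, numeric(1))
}

# half-maximum full width of the peak at index i, by linear interpolation
# down both flanks from height h to h - prom/2 (prominence-referenced)
peak_fwhm <- function(x, y, i, prom) {
  half <- y[i] - prom / 2
  xl <- x[1]
  for (j in seq(i, 2)) {
    if (y[j - 1] <= half) {
      xl <- x[j - 1] + (x[j] - x[j - 1]) * (half - y[j - 1]) / (y[j] - y[j - 1])
      break
    }
  }
  xr <- x[length(x)]
  for (j in seq(i, length(x) - 1)) {
    if (y[j + 1] <= half) {
      xr <- x[j] + (x[j + 1] - x[j]) * (y[j] - half) / (y[j] - y[j + 1])
      break
    }
  }
  max(xr - xl, x[2] - x[1])
}

#' Detect absorption peaks in a spectrum
#'
#' Finds local maxima whose topographic prominence is at least
#' `min_prominence_frac` of the spectrum's total range, enforces a minimum
#' mutual separation (keeping the more prominent peak), drops peaks within
#' `edge_margin` of either band end, and refines each position by parabolic
#' interpolation through the three samples around the discrete maximum.
#'
#' @param x either an [optical_constants()] table (the absorption column is
#'   analysed) or a numeric intensity sequence, in which case `frequency`
#'   must be supplied.
#' @param frequency THz grid when `x` is a bare numeric vector.
#' @param min_prominence_frac prominence floor as a fraction of
#'   `max - min` (default 0.25: only features at least a quarter of the
#'   corrected spectrum's dynamic range count as fingerprint peaks).
#' @param min_separation minimum peak spacing in THz (default 0.15, below
#'   the closest reported fingerprint-line spacings but wide enough to
#'   absorb shoulder artifacts of a single line).
#' @param edge_margin excluded margin at both band ends in THz
#'   (default 0.2, where extraction noise concentrates).
#' @return A [peak_list()].
#' @export
detect_peaks <- function(x, frequency = NULL, min_prominence_frac = 0.25,
                         min_separation = 0.15, edge_margin = 0.2) {
  if (inherits(x, "optical_constants")) {
    frequency <- x$frequency
    y <- x$absorption
  } else {
    y <- as.numeric(x)
    if (is.null(frequency)) stop("`frequency` grid required", call. = FALSE)
  }
  keep <- is.finite(y) & is.finite(frequency)
  y <- y[keep]; frequency <- frequency[keep]
  n <- length(y)
  if (n < 3) return(peak_list())
  band <- range(frequency)
  if (diff(band) <= 2 * edge_margin) {
    stop("band narrower than twice the edge margin", call. = FALSE)
  }
  rng <- max(y) - min(y)
  if (rng == 0) return(peak_list())
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  cand <- cand[y[cand] > y[pmax(cand - 1L, 1L)] | y[cand] > y[pmin(cand + 1L, n)]]
  if (length(cand) == 0) return(peak_list())
  prom <- peak_prominences(y, cand)
  sel <- prom >= min_prominence_frac * rng
  cand <- cand[sel]; prom <- prom[sel]
  if (length(cand) == 0) return(peak_list())
  # enforce separation, most prominent first
  ord <- order(prom, decreasing = TRUE)
  kept <- integer(0)
  for (k in ord) {
    if (all(abs(frequency[cand[k]] - frequency[cand[kept]]) >= min_separation)) {
      kept <- c(kept, k)
    }
  }
  cand2 <- cand[kept]; prom2 <- prom[kept]
  inb <- frequency[cand2] >= band[1] + edge_margin &
         frequency[cand2] <= band[2] - edge_margin
  cand2 <- cand2[inb]; prom2 <- prom2[inb]
  if (length(cand2) == 0) return(peak_list())
  fr <- numeric(length(cand2)); it <- numeric(length(cand2))
  wd <- numeric(length(cand2))
  for (k in seq_along(cand2)) {
    i <- cand2[k]
    v <- if (i > 1 && i < n) {
      parabolic_vertex(frequency[(i - 1):(i + 1)], y[(i - 1):(i + 1)])
    } else list(x = frequency[i], y = y[i])
    fr[k] <- v$x; it[k] <- v$y
    wd[k] <- peak_fwhm(frequency, y, i, prom2[k])
  }
  peak_list(frequency = fr, intensity = it, prominence = prom2, width = wd)
}

#' Anomalous-dispersion confirmation flags
#'
#' A genuine absorption line perturbs the refractive index: inside the
#' linewidth `n(nu)` falls with frequency (anomalous dispersion). For each
#' candidate peak this checks the refractive-index spectrum within
#' `+/- window` of the peak frequency for a decreasing segment — a maximum
#' followed by a lower minimum with drop of at least `min_drop` — and flags
#' the peak as confirmed when one is present. Peaks without a dispersion
#' signature (e.g. ripple artifacts) stay unflagged.
#'
#' @param peaks a [peak_list()].
#' @param constants an [optical_constants()] table.
#' @param window half-width of the inspection window in THz (default 0.1).
#' @param min_drop minimum index decrease counted as dispersion (default
#'   4e-3, above the drawdown the residual noise of a de-noised index
#'   spectrum produces at the default simulation settings).
#' @return logical vector, one flag per peak.
#' @export
dispersion_flags <- function(peaks, constants, window = 0.1, min_drop = 4e-3) {
  stopifnot(inherits(peaks, "peak_list"), inherits(constants, "optical_constants"))
  if (window <= 0) stop("`window` must be > 0", call. = FALSE)
  vapply(peaks$frequency, function(f0) {
    sel <- constants$frequency >= f0 - window &
           constants$frequency <= f0 + window &
           is.finite(constants$refractive_index)
    nn <- constants$refractive_index[sel]
    if (length(nn) < 3) return(FALSE)
    # maximum drawdown: largest decrease from a running maximum
    max(cummax(nn) - nn) >= min_drop
  }, logical(1))
}

#' Match theoretical to experimental peaks
#'
#' Greedy one-to-one matching: all theory/experiment pairs closer than
#' `tolerance` are ranked by ascending `|theory - experiment|` (stable in
#' input order on ties) and accepted in that order, each peak being used at
#' most once. Unmatched theory rows keep `NA` experiment frequency and
#' shift. The signed shift is `theory - experiment`, stored at full
#' precision; rounding happens only when writing tables.
#'
#' @param theory,experiment [peak_list()] objects (or data frames with a
#'   `frequency` column; theory labels are propagated).
#' @param tolerance maximum |shift| accepted, THz (default 0.15).
#' @return data frame of class `peak_match` with columns `theory_freq`,
#'   `experiment_freq`, `shift`, `mode_label`, one row per theory peak.
#' @examples
#' th <- peak_list(c(1.47, 1.90, 2.74))
#' ex <- peak_list(c(1.47, 1.93, 2.73))
#' match_peaks(th, ex)$shift  # 0 -0.03 0.01
#' @export
match_peaks <- function(theory, experiment, tolerance = 0.15) {
  if (tolerance <= 0) stop("`tolerance` must be > 0", call. = FALSE)
  tf <- theory$frequency
  ef <- experiment$frequency
  if (anyDuplicated(tf) || anyDuplicated(ef)) {
    warning("duplicate frequencies in a peak list; ties broken by input order",
            call. = FALSE)
  }
  lab <- if (!is.null(theory$label)) theory$label else rep("", length(tf))
  exp_match <- rep(NA_real_, length(tf))
  if (length(tf) > 0 && length(ef) > 0) {
    pairs <- expand.grid(i = seq_along(tf), j = seq_along(ef))
    pairs$d <- abs(tf[pairs$i] - ef[pairs$j])
    pairs <- pairs[pairs$d <= tolerance, , drop = FALSE]
    pairs <- pairs[order(pairs$d, pairs$i, pairs$j), , drop = FALSE]
    used_e <- rep(FALSE, length(ef))
    used_t <- rep(FALSE, length(tf))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$i[r]; j <- pairs$j[r]
      if (!used_t[i] && !used_e[j]) {
        exp_match[i] <- ef[j]
        used_t[i] <- TRUE
        used_e[j] <- TRUE
      }
    }
  }
  out <- data.frame(theory_freq = tf, experiment_freq = exp_match,
                    shift = tf - exp_match, mode_label = lab,
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_match", "data.frame")
  out
}

#' Render a theoretical line list as a broadened spectrum
#'
#' Sum of unit-area Lorentzian profiles, one per line, each scaled by the
#' line's intensity — the usual way a stick spectrum from a frequency
#' calculation is overlaid on a measured spectrum.
#'
#' @param theory a [peak_list()]; missing intensities count as 1.
#' @param fwhm full width at half maximum of each Lorentzian, THz.
#' @param grid frequency grid to evaluate on, THz.
#' @return numeric intensity sequence on `grid`.
#' @export
broaden_theoretical <- function(theory, fwhm, grid) {
  if (fwhm <= 0) stop("`fwhm` must be > 0", call. = FALSE)
  y <- numeric(length(grid))
  if (nrow(theory) == 0) return(y)
  gam <- fwhm / 2
  for (r in seq_len(nrow(theory))) {
    a <- theory$intensity[r]
    if (is.na(a)) a <- 1
    y <- y + a * (gam / pi) / ((grid - theory$frequency[r])^2 + gam^2)
  }
  y
}

#' Write / read a peak-match table as CSV
#'
#' Columns `theory_THz,experiment_THz,shift_THz,mode`; unmatched cells are
#' written as `-` and frequencies/shifts rounded to 2 decimals, mirroring
#' how assignment tables are printed.
#'
#' @param matches a [match_peaks()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_match_table <- function(matches, path) {
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.2f", v))
  rows <- sprintf("%s,%s,%s,%s", fmt(matches$theory_freq),
                  fmt(matches$experiment_freq), fmt(matches$shift),
                  matches$mode_label)
  writeLines(c("theory_THz,experiment_THz,shift_THz,mode", rows), path)
  invisible(path)
}

#' Read a peak table CSV
#'
#' Dialect `frequency_THz,intensity,label` with optional header line and
#' `#` comments; intensity and label columns optional.
#'
#' @param path file path.
#' @return A [peak_list()].
#' @export
read_peak_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  first <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (suppressWarnings(is.na(as.numeric(first[1])))) lines <- lines[-1]
  df <- utils::read.table(text = lines, sep = ",", header = FALSE,
                          stringsAsFactors = FALSE, fill = TRUE)
  peak_list(frequency = as.numeric(df[[1]]),
            intensity = if (ncol(df) >= 2) suppressWarnings(as.numeric(df[[2]]))
                        else NA_real_,
            label = if (ncol(df) >= 3) as.character(df[[3]]) else "")
}
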