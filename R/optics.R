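#' Extraction configuration
#'
#' @param band analysis band in THz, default `c(0.1, 3.5)`.
#' @param n_points length of the fixed analysis grid the optical constants
#'   are interpolated onto (default 463, so the downstream smoothing
#'   operates on the same spectral length for every measurement).
#' @param anchor_band low-frequency band (THz) used to anchor the unwrapped
#'   phase (see [unwrap_phase()]).
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(band = c(0.1, 3.5), n_points = 463,
                              anchor_band = c(0.2, 1.0)) {
  band <- as.numeric(band)
  if (length(band) != 2 || band[1] >= band[2]) {
    stop("`band` must be c(f_min, f_max) with f_min < f_max", call. = FALSE)
  }
  n_points <- as.integer(n_points)
  if (n_points < 8) stop("`n_points` must be >= 8", call. = FALSE)
  structure(list(band = band, n_points = n_points, anchor_band = anchor_band),
            class = "extraction_config")
}

#' Unwrapped phase difference between sample and reference spectra
#'
#' Forms the transfer function `H(nu) = E_sample / E_reference` on the common
#' grid and returns the continuous phase delay `dphi(nu) = -arg H(nu)`
#' (positive for a delayed sample under the `exp(-2i pi nu t)` transform
#' convention). 2*pi jumps are removed by cumulative unwrapping, started at
#' the low edge of `anchor_band` (where the signal is reliable) and
#' propagated outward in both directions, so that noise-dominated bins near
#' DC cannot corrupt the in-band phase. The remaining offset ambiguity is
#' exactly a multiple of 2*pi; it is resolved by fitting a line over
#' `anchor_band` and subtracting the multiple of 2*pi nearest to the fit
#' intercept, which drives `dphi -> 0` as `nu -> 0` without biasing the
#' phase when weak dispersion curves the anchor region.
#'
#' @param sample,reference [freq_spectrum()] objects on identical grids.
#' @param anchor_band low-frequency fit window in THz.
#' @return list with `frequency` and `dphase` (radians).
#' @export
unwrap_phase <- function(sample, reference, anchor_band = c(0.2, 1.0)) {
  stopifnot(inherits(sample, "freq_spectrum"), inherits(reference, "freq_spectrum"))
  if (length(sample$frequency) != length(reference$frequency) ||
      max(abs(sample$frequency - reference$frequency)) > 1e-12) {
    stop("sample and reference must share a common frequency grid", call. = FALSE)
  }
  nu <- sample$frequency
  zero <- Mod(reference$complex_field) == 0
  if (any(zero)) {
    stop(sprintf("reference field vanishes at %.4f THz: cannot divide",
                 nu[which(zero)[1]]), call. = FALSE)
  }
  H <- sample$complex_field / reference$complex_field
  i0 <- which(nu >= anchor_band[1])[1]
  if (is.na(i0)) i0 <- 1L
  dphase <- -unwrap_angle(Arg(H), from = i0)
  sel <- nu >= anchor_band[1] & nu <= anchor_band[2]
  if (sum(sel) >= 2) {
    fit <- stats::lm.fit(cbind(1, nu[sel]), dphase[sel])
    dphase <- dphase - 2 * pi * round(fit$coefficients[1] / (2 * pi))
  }
  list(frequency = nu, dphase = as.numeric(dphase))
}

# remove 2*pi discontinuities from a phase sequence, keeping phi[from]
# fixed and propagating continuity outward in both directions
unwrap_angle <- function(phi, from = 1L) {
  d <- diff(phi)
  steps <- -2 * pi * round(d / (2 * pi))
  corr <- c(0, cumsum(steps))
  phi + corr - corr[from]
}

#' Single-pass Fresnel transmission transfer function
#'
#' Forward model of a plane-parallel slab of complex index
#' `n_tilde = n - i kappa` in air, keeping the two interface Fresnel losses
#' and the single direct pass (no etalon/Fabry-Perot echoes):
#' `T(nu) = 4 n_tilde / (n_tilde + 1)^2 * exp(-2i pi nu (n_tilde - 1) d / c)`.
#' Under the `exp(-2i pi nu t)` transform convention a positive `kappa`
#' attenuates and a positive `n - 1` delays.
#'
#' @param nu frequency grid in THz.
#' @param n_complex complex index `n - 1i*kappa`, scalar or per-frequency.
#' @param thickness_mm slab thickness in mm.
#' @return complex transfer function on `nu`.
#' @export
fresnel_transfer <- function(nu, n_complex, thickness_mm) {
  nt <- as.complex(n_complex)
  4 * nt / (nt + 1)^2 *
    exp(-2i * pi * nu * (nt - 1) * thickness_mm / C_MM_PS)
}

#' Extract absorption coefficient and refractive index spectra
#'
#' Standard air-reference transmission extraction for optically thick
#' pellets. With amplitude ratio `rho(nu) = |E_s/E_r|` and phase delay
#' `dphi(nu)` from [unwrap_phase()]:
#' \deqn{n(\nu) = 1 + c\,\Delta\phi(\nu) / (2\pi\nu d)}
#' \deqn{\alpha(\nu) = (2/d)\,\ln[4 n(\nu) / (\rho(\nu)\,(n(\nu)+1)^2)]}
#' with `d` in cm so `alpha` is in 1/cm. Both spectra are then linearly
#' interpolated onto the `n_points` analysis grid spanning `band`.
#' Frequencies where the extracted `n <= 0` are flagged non-physical and
#' masked (`NA`).
#'
#' @param sample,reference [freq_spectrum()] objects on a common grid
#'   covering the band.
#' @param meta [acquisition_meta()] with the pellet thickness.
#' @param config an [extraction_config()].
#' @return An `optical_constants` data frame with columns `frequency`
#'   (THz), `absorption` (1/cm), `refractive_index`, and attributes
#'   `thickness_mm`, `band`.
#' @export
extract_optical_constants <- function(sample, reference, meta,
                                      config = extraction_config()) {
  stopifnot(inherits(meta, "acquisition_meta"), inherits(config, "extraction_config"))
  band <- config$band
  # crop to the analysis band (plus headroom for the phase anchor fit):
  # far above the band the pulse spectrum underflows and carries no signal
  top <- 1.05 * max(band[2], config$anchor_band[2])
  crop <- sample$frequency <= top
  sample <- freq_spectrum(sample$frequency[crop], sample$complex_field[crop])
  reference <- freq_spectrum(reference$frequency[crop],
                             reference$complex_field[crop])
  nu <- sample$frequency
  inband <- nu >= band[1] & nu <= band[2]
  if (!any(inband)) stop("spectra do not cover the analysis band", call. = FALSE)
  rho_all <- Mod(sample$complex_field) / Mod(reference$complex_field)
  if (any(rho_all[inband] <= 0)) {
    stop("amplitude ratio vanishes inside the analysis band", call. = FALSE)
  }
  uw <- unwrap_phase(sample, reference, anchor_band = config$anchor_band)
  d_mm <- meta$thickness_mm
  d_cm <- d_mm / 10
  pos <- nu > 0
  n_raw <- rep(NA_real_, length(nu))
  n_raw[pos] <- 1 + C_MM_PS * uw$dphase[pos] / (2 * pi * nu[pos] * d_mm)
  alpha_raw <- rep(NA_real_, length(nu))
  ok <- pos & n_raw > 0
  alpha_raw[ok] <- (2 / d_cm) *
    log(4 * n_raw[ok] / (rho_all[ok] * (n_raw[ok] + 1)^2))
  grid <- seq(band[1], band[2], length.out = config$n_points)
  n_i <- stats::approx(nu[pos], n_raw[pos], xout = grid, rule = 2)$y
  a_i <- stats::approx(nu[pos], alpha_raw[pos], xout = grid, rule = 2)$y
  masked <- !is.finite(n_i) | n_i <= 0
  n_i[masked] <- NA_real_
  a_i[masked] <- NA_real_
  optical_constants(grid, a_i, n_i, thickness_mm = d_mm, band = band)
}

#' Construct an optical-constants table
#'
#' @param frequency THz grid.
#' @param absorption alpha(nu) in 1/cm (NA where masked).
#' @param refractive_index n(nu), dimensionless; values below 0.8 indicate
#'   extraction trouble and trigger a warning.
#' @param thickness_mm pellet thickness.
#' @param band analysis band attribute.
#' @return data frame of class `optical_constants`.
#' @export
optical_constants <- function(frequency, absorption, refractive_index,
                              thickness_mm = NA_real_, band = NULL) {
  if (length(frequency) != length(absorption) ||
      length(frequency) != length(refractive_index)) {
    stop("columns must have equal length", call. = FALSE)
  }
  if (any(refractive_index < 0.8, na.rm = TRUE)) {
    warning("refractive index below 0.8: check extraction inputs", call. = FALSE)
  }
  structure(
    data.frame(frequency = frequency, absorption = absorption,
               refractive_index = refractive_index),
    thickness_mm = thickness_mm,
    band = if (is.null(band)) range(frequency) else band,
    class = c("optical_constants", "data.frame")
  )
}

#' Band-average refractive index
#'
#' Arithmetic mean of `n(nu)` over the analysis band, excluding masked
#' points. The single-number summary reported per compound.
#'
#' @param constants an [optical_constants()] table.
#' @return scalar mean index.
#' @export
band_average_index <- function(constants) {
  stopifnot(inherits(constants, "optical_constants"))
  n <- constants$refractive_index
  if (all(is.na(n))) stop("all points masked: no band average", call. = FALSE)
  mean(n, na.rm = TRUE)
}

#' Write / read optical constants as CSV
#'
#' Dialect: `#key=value` metadata header then
#' `frequency_THz,absorption_cm-1,refractive_index` rows.
#' @param constants an [optical_constants()] table.
#' @param path file path.
#' @return `path` invisibly (write) or the table (read).
#' @export
write_optical_constants <- function(constants, path) {
  stopifnot(inherits(constants, "optical_constants"))
  hdr <- c(sprintf("#thickness_mm=%.17g", attr(constants, "thickness_mm")),
           sprintf("#band=%.17g:%.17g", attr(constants, "band")[1],
                   attr(constants, "band")[2]),
           "frequency_THz,absorption_cm-1,refractive_index")
  rows <- sprintf("%.17g,%.17g,%.17g", constants$frequency,
                  constants$absorption, constants$refractive_index)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_optical_constants
#' @export
read_optical_constants <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- parse_meta_lines(lines[startsWith(lines, "#")])
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)][-1]  # drop column header
  df <- utils::read.table(text = body, sep = ",", header = FALSE)
  band <- if (is.null(meta$band)) NULL
          else as.numeric(strsplit(meta$band, ":", fixed = TRUE)[[1]])
  optical_constants(df[[1]], df[[2]], df[[3]],
                    thickness_mm = if (is.null(meta$thickness_mm)) NA_real_
                                   else as.numeric(meta$thickness_mm),
                    band = band)
}
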