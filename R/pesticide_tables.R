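# Published reference values for the six pesticide pellets: pulse
# amplitudes/arrival times and pellet thicknesses from the measurement
# campaign, band-average refractive indices, and the assignment tables
# (DFT-simulated line positions, experimentally observed positions, and
# vibration-mode labels). These are inputs to the pipeline — e.g. the DFT
# columns feed match_peaks() and the experimental positions seed the
# synthetic presets — not quantities the package computes.

PESTICIDES <- c("chlorpyrifos", "fipronil", "carbofuran", "dimethoate",
                "methomyl", "thidiazuron")

#' Measurement metadata for the six pesticide pellets
#'
#' Pellet thicknesses, pulse peak amplitudes and arrival times (reference:
#' 16.325 a.u. at 4.169 ps), and the reported band-average refractive index
#' over 0.1-3.5 THz, one row per compound.
#'
#' @return data frame with columns `compound`, `thickness_mm`,
#'   `amplitude_au`, `delay_ps`, `band_average_n`, plus attributes
#'   `reference_delay_ps` and `reference_amplitude_au`.
#' @export
pesticide_metadata <- function() {
  structure(
    data.frame(
      compound = PESTICIDES,
      thickness_mm = c(1.66, 1.69, 1.32, 1.79, 1.59, 1.57),
      amplitude_au = c(9.016, 12.924, 11.417, 6.737, 7.884, 9.296),
      delay_ps = c(6.445, 6.413, 5.962, 7.166, 6.961, 6.650),
      band_average_n = c(1.409, 1.400, 1.394, 1.475, 1.503, 1.464),
      stringsAsFactors = FALSE
    ),
    reference_delay_ps = 4.169,
    reference_amplitude_au = 16.325
  )
}

# assignment table: per compound, DFT line (THz), observed line (THz, NA
# where the instrument saw nothing), and the vibration-mode label
ASSIGNMENT_TABLE <- list(
  chlorpyrifos = data.frame(
    dft = c(1.47, 1.90, 2.74),
    experiment = c(1.47, 1.93, 2.73),
    mode = c("d(C-C)oop", "v(P=O)ip + d(C-C)oop", "v(P=O)ip"),
    stringsAsFactors = FALSE),
  fipronil = data.frame(
    dft = c(0.82, 1.18, 1.36, 1.67, 2.31),
    experiment = c(0.76, 1.23, NA, NA, 2.31),
    mode = c("d(C-N)ip", "d(C-N)ip", "d(C-N)ip + d(C-S)oop",
             "d(C-N)ip + d(C-S)oop", "d(C-N)ip"),
    stringsAsFactors = FALSE),
  carbofuran = data.frame(
    dft = c(1.15, 2.20, 2.72, 3.06),
    experiment = c(NA, NA, 2.72, 3.06),
    mode = c("d(C-N)ip", "d(C-N)ip + v_breathe", "d(C-O)ip", "d(C-O)ip"),
    stringsAsFactors = FALSE),
  dimethoate = data.frame(
    dft = c(0.72, 1.03, 1.93, 2.64, 2.90),
    experiment = c(NA, 1.05, 1.89, NA, 2.92),
    mode = c("d(C-C)ip", "d(C-C)ip", "d(C-N)ip + d(C-O)oop",
             "d(C-S)ip + d(C-O)oop", "d(C-S)ip + d(C-O)oop"),
    stringsAsFactors = FALSE),
  methomyl = data.frame(
    dft = c(1.01, 1.59, 2.01, 2.68, 3.09),
    experiment = c(1.01, 1.65, 1.91, 2.72, 3.20),
    mode = c("d(C-N)ip", "d(C-N)ip", "d(C-N)ip + d(C-S)oop",
             "d(C-H)ip", "d(C-O)ip"),
    stringsAsFactors = FALSE),
  thidiazuron = data.frame(
    dft = c(0.98, 1.58, 2.21, 2.63),
    experiment = c(0.99, 1.57, 2.17, 2.66),
    mode = c("v_breathe", "d(C-N)ip", "d(C-O)oop", "d(N-C-N)oop"),
    stringsAsFactors = FALSE)
)

#' Published peak tables for one pesticide
#'
#' @param compound one of `"chlorpyrifos"`, `"fipronil"`, `"carbofuran"`,
#'   `"dimethoate"`, `"methomyl"`, `"thidiazuron"`.
#' @param source `"dft"` for the simulated line list (all rows) or
#'   `"experiment"` for the observed post-processing peak list (rows the
#'   instrument resolved).
#' @return A [peak_list()] with mode labels.
#' @export
pesticide_peak_table <- function(compound,
                                 source = c("dft", "experiment")) {
  source <- match.arg(source)
  compound <- match.arg(compound, PESTICIDES)
  tab <- ASSIGNMENT_TABLE[[compound]]
  if (source == "dft") {
    peak_list(frequency = tab$dft, label = tab$mode)
  } else {
    keep <- !is.na(tab$experiment)
    peak_list(frequency = tab$experiment[keep], label = tab$mode[keep])
  }
}

# Table of per-level db5 soft thresholds determined on the instrument
# spectra (finest level first), usable as a wavelet_denoise_config
# thresholds vector.
INSTRUMENT_THRESHOLDS <- list(
  chlorpyrifos = c(0.037, 0.120, 0.150, 0.197, 0.052),
  fipronil     = c(0.018, 0.099, 0.118, 0.260, 0.227),
  carbofuran   = c(0.048, 0.432, 0.692, 0.472, 1.548),
  dimethoate   = c(0.714, 1.064, 0.893, 1.225, 1.441),
  methomyl     = c(0.428, 0.877, 0.986, 1.622, 0.074),
  thidiazuron  = c(1.172, 0.784, 0.781, 0.568, 0.054)
)

#' Instrument-calibrated wavelet thresholds for one pesticide
#'
#' Per-level db5 soft thresholds (finest first) as determined on the
#' measured spectra. Instrument-specific: for synthetic data prefer the
#' `"universal"` rule.
#'
#' @inheritParams pesticide_peak_table
#' @return numeric vector of 5 thresholds.
#' @export
pesticide_thresholds <- function(compound) {
  INSTRUMENT_THRESHOLDS[[match.arg(compound, PESTICIDES)]]
}
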