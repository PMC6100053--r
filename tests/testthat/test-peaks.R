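band_grid <- seq(0.1, 3.5, length.out = 463)

test_that("an isolated Lorentzian is found at its center", {
  y <- broaden_theoretical(peak_list(1.0, intensity = 1), fwhm = 0.08,
                           grid = band_grid)
  pk <- detect_peaks(y, frequency = band_grid)
  expect_equal(nrow(pk), 1)
  step <- band_grid[2] - band_grid[1]
  expect_lt(abs(pk$frequency - 1.0), step)
  expect_gt(pk$width, 0)
})

test_that("structureless spectra yield empty peak lists", {
  expect_equal(nrow(detect_peaks(rep(0, 463), frequency = band_grid)), 0)
  expect_equal(nrow(detect_peaks(band_grid * 2, frequency = band_grid)), 0)
})

test_that("two equal lines at the carbofuran positions are both resolved", {
  y <- broaden_theoretical(peak_list(c(2.72, 3.06), intensity = c(1, 1)),
                           fwhm = 0.08, grid = band_grid)
  pk <- detect_peaks(y, frequency = band_grid)
  expect_equal(nrow(pk), 2)
  step <- band_grid[2] - band_grid[1]
  expect_lt(abs(pk$frequency[1] - 2.72), step)
  expect_lt(abs(pk$frequency[2] - 3.06), step)
})

test_that("broadened line lists render and round trip through detection", {
  expect_equal(broaden_theoretical(peak_list(), 0.05, band_grid),
               rep(0, 463))
  y1 <- broaden_theoretical(peak_list(1.8, intensity = 1), 0.05, band_grid)
  expect_equal(band_grid[which.max(y1)], 1.8, tolerance = 0.01)
  # half-maximum width equals the nominal fwhm within grid resolution
  above <- band_grid[y1 >= max(y1) / 2]
  expect_lt(abs(diff(range(above)) - 0.05), 2.5 * (band_grid[2] - band_grid[1]))
  y2 <- broaden_theoretical(peak_list(c(1.0, 1.3), intensity = c(1, 1)),
                            0.05, band_grid)
  expect_equal(nrow(detect_peaks(y2, frequency = band_grid)), 2)
  expect_error(broaden_theoretical(peak_list(1), 0, band_grid), "> 0")
})

test_that("anomalous dispersion is flagged only at genuine resonances", {
  nu <- band_grid
  flat_n <- rep(1.4, 463)
  alpha <- broaden_theoretical(peak_list(2.0, intensity = 2), 0.06, nu)
  pk <- detect_peaks(alpha, frequency = nu)
  # alpha peak without any oscillator in n -> unconfirmed
  oc_flat <- optical_constants(nu, alpha, flat_n)
  expect_false(any(dispersion_flags(pk, oc_flat)))
  # the same peak with the matching Lorentz dispersion in n -> confirmed
  nt <- lorentz_index(nu, 2.0, 3e-3, 0.06, 1.4)
  oc_disp <- optical_constants(nu, alpha, Re(nt))
  expect_true(all(dispersion_flags(pk, oc_disp)))
  expect_error(dispersion_flags(pk, oc_disp, window = 0), "> 0")
})

test_that("published chlorpyrifos and fipronil rows match with printed shifts", {
  m <- match_peaks(peak_list(c(1.47, 1.90, 2.74)),
                   peak_list(c(1.47, 1.93, 2.73)))
  expect_equal(round(m$shift, 2), c(0, -0.03, 0.01))
  m2 <- match_peaks(peak_list(c(0.82, 1.18, 1.36, 1.67, 2.31)),
                    peak_list(c(0.76, 1.23, 2.31)))
  expect_equal(round(m2$shift, 2), c(0.06, -0.05, NA, NA, 0))
  expect_equal(m2$experiment_freq, c(0.76, 1.23, NA, NA, 2.31))
  empty <- match_peaks(peak_list(), peak_list(c(1, 2)))
  expect_equal(nrow(empty), 0)
})

test_that("matching is antisymmetric and respects tolerance limits", {
  set.seed(17)
  for (rep in 1:10) {
    a <- sort(runif(5, 0.3, 3.3))
    b <- sort(a + runif(5, -0.1, 0.1))
    fwd <- match_peaks(peak_list(a), peak_list(b))
    rev <- match_peaks(peak_list(b), peak_list(a))
    matched <- !is.na(fwd$shift)
    expect_equal(sort(fwd$shift[matched]),
                 sort(-rev$shift[!is.na(rev$shift)]), tolerance = 1e-12)
  }
  th <- peak_list(c(1.0, 2.0)); ex <- peak_list(c(1.02, 2.0))
  tiny <- match_peaks(th, ex, tolerance = 1e-9)
  expect_equal(tiny$experiment_freq, c(NA, 2.0))
  wide <- match_peaks(th, ex, tolerance = 100)
  expect_true(all(!is.na(wide$shift)))
  expect_equal(anyDuplicated(wide$experiment_freq), 0)  # one-to-one
})

test_that("labels propagate and match tables serialize with '-' cells", {
  th <- pesticide_peak_table("fipronil", "dft")
  ex <- pesticide_peak_table("fipronil", "experiment")
  m <- match_peaks(th, ex)
  expect_equal(m$mode_label[1], "d(C-N)ip")
  path <- withr::local_tempfile(fileext = ".csv")
  write_match_table(m, path)
  lines <- readLines(path)
  expect_equal(sum(grepl(",-,-,", lines, fixed = TRUE)), 2)
  expect_equal(lines[1], "theory_THz,experiment_THz,shift_THz,mode")
})

test_that("peak table CSVs read back with intensities and labels", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# theoretical lines", "frequency_THz,intensity,label",
               "1.47,0.8,d(C-C)oop", "2.74,1.0,v(P=O)ip"), path)
  pk <- read_peak_table(path)
  expect_equal(pk$frequency, c(1.47, 2.74))
  expect_equal(pk$intensity, c(0.8, 1.0))
  expect_equal(pk$label, c("d(C-C)oop", "v(P=O)ip"))
})
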