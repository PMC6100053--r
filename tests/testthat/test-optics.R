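nu_grid <- seq(0.0125, 3.6, by = 0.0125)

test_that("unwrap_phase recovers a pure delay and the identity", {
  tau <- 1.0
  ref <- freq_spectrum(nu_grid, rep(1 + 0i, length(nu_grid)))
  sam <- freq_spectrum(nu_grid, exp(-2i * pi * nu_grid * tau))
  uw <- unwrap_phase(sam, ref)
  expect_equal(uw$dphase, 2 * pi * nu_grid * tau, tolerance = 1e-9)
  expect_equal(unwrap_phase(ref, ref)$dphase, rep(0, length(nu_grid)))
})

test_that("a steep wrapped ramp unwraps back to the ramp", {
  tau <- 9.7   # many 2*pi wraps across the band
  ramp <- 2 * pi * nu_grid * tau
  wrapped <- Arg(exp(-1i * ramp))        # onto (-pi, pi]
  sam <- freq_spectrum(nu_grid, complex(modulus = 1, argument = wrapped))
  ref <- freq_spectrum(nu_grid, rep(1 + 0i, length(nu_grid)))
  expect_equal(unwrap_phase(sam, ref)$dphase, ramp, tolerance = 1e-9)
})

test_that("vacuum sample extracts to n = 1, alpha = 0", {
  pair <- slab_pair(nu_grid, 1 + 0i, 1.0)
  oc <- extract_optical_constants(pair$sample, pair$reference,
                                  acquisition_meta(1.0))
  expect_equal(oc$refractive_index, rep(1, 463), tolerance = 1e-9)
  expect_equal(oc$absorption, rep(0, 463), tolerance = 1e-9)
})

test_that("non-dispersive slab round-trips through the Fresnel model", {
  pair <- slab_pair(nu_grid, 1.5 + 0i, 1.0)
  oc <- extract_optical_constants(pair$sample, pair$reference,
                                  acquisition_meta(1.0))
  expect_lt(max(abs(oc$refractive_index - 1.5)), 1e-6)
  expect_lt(max(abs(oc$absorption)), 1e-6)
  # hand-evaluated interface loss: |H| must equal 4n/(n+1)^2 = 0.96
  expect_equal(Mod(pair$sample$complex_field[100]), 4 * 1.5 / 2.5^2,
               tolerance = 1e-12)
})

test_that("a planted Lorentz line is recovered at its center", {
  nt <- lorentz_index(nu_grid, 2.31, 4e-3, 0.05, 1.4)
  pair <- slab_pair(nu_grid, nt, 1.0)
  oc <- extract_optical_constants(pair$sample, pair$reference,
                                  acquisition_meta(1.0))
  step <- oc$frequency[2] - oc$frequency[1]
  expect_lt(abs(oc$frequency[which.max(oc$absorption)] - 2.31), step + 1e-12)
})

test_that("extraction is invariant to common field rescaling", {
  nt <- lorentz_index(nu_grid, 1.5, 2e-3, 0.06, 1.45)
  pair <- slab_pair(nu_grid, nt, 1.3)
  oc1 <- extract_optical_constants(pair$sample, pair$reference,
                                   acquisition_meta(1.3))
  sam2 <- freq_spectrum(nu_grid, pair$sample$complex_field * 37)
  ref2 <- freq_spectrum(nu_grid, pair$reference$complex_field * 37)
  oc2 <- extract_optical_constants(sam2, ref2, acquisition_meta(1.3))
  expect_equal(oc1$absorption, oc2$absorption, tolerance = 1e-12)
  expect_equal(oc1$refractive_index, oc2$refractive_index, tolerance = 1e-12)
})

test_that("raising planted absorption lowers rho and raises extracted alpha", {
  d <- 1.0
  make <- function(kappa) {
    nt <- complex(real = 1.5, imaginary = -kappa) + numeric(length(nu_grid))
    slab_pair(nu_grid, nt, d)
  }
  p1 <- make(0.002); p2 <- make(0.004)
  i <- 150
  expect_lt(Mod(p2$sample$complex_field[i]), Mod(p1$sample$complex_field[i]))
  a1 <- extract_optical_constants(p1$sample, p1$reference, acquisition_meta(d))
  a2 <- extract_optical_constants(p2$sample, p2$reference, acquisition_meta(d))
  expect_true(all(a2$absorption > a1$absorption))
})

test_that("band averaging handles constants, weak lines, and masking", {
  oc <- optical_constants(seq(0.1, 3.5, length.out = 50), rep(0, 50),
                          rep(1.5, 50))
  expect_equal(band_average_index(oc), 1.5)
  nt <- lorentz_index(nu_grid, 2.0, 5e-4, 0.08, 1.475)
  pair <- slab_pair(nu_grid, nt, 1.79)
  oc2 <- extract_optical_constants(pair$sample, pair$reference,
                                   acquisition_meta(1.79))
  expect_lt(abs(band_average_index(oc2) - 1.475), 0.005)
  suppressWarnings(ocm <- optical_constants(1:3, rep(NA_real_, 3),
                                            rep(NA_real_, 3)))
  expect_error(band_average_index(ocm), "masked")
})

test_that("extracted absorption baseline rises with frequency on noisy data", {
  sim <- simulate_measurement(synthetic_sample_spec(seed = 11))
  res <- process_pair(sim$reference, sim$sample,
                      config = pipeline_config(denoise = NULL,
                                               baseline = NULL))
  a <- res$constants$absorption
  f <- res$constants$frequency
  lo <- median(a[f > 0.3 & f < 1.0], na.rm = TRUE)
  hi <- median(a[f > 2.5 & f < 3.3], na.rm = TRUE)
  expect_gt(hi, lo)
})

test_that("optical constants CSV round trips", {
  oc <- optical_constants(seq(0.1, 3.5, length.out = 20), runif(20, 0, 30),
                          runif(20, 1.3, 1.6), thickness_mm = 1.59)
  path <- withr::local_tempfile(fileext = ".csv")
  write_optical_constants(oc, path)
  back <- read_optical_constants(path)
  expect_equal(back$absorption, oc$absorption)
  expect_equal(back$refractive_index, oc$refractive_index)
  expect_equal(attr(back, "thickness_mm"), 1.59)
})
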