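# Shared fixture builders. Everything is generated in code; no stored data.

# Gaussian pulse trace with |amplitude| maximum exactly at `center` ps
gauss_trace <- function(center, amp = 1, width = 0.15, n = 2048, t_max = 33.5,
                        label = "") {
  t <- seq(0, t_max, length.out = n)
  td_trace(t, amp * exp(-(t - center)^2 / (2 * width^2)), label = label)
}

# one-sided spectra for a planted complex-index slab measured against an
# empty (vacuum) reference on grid `nu`
slab_pair <- function(nu, n_complex, thickness_mm) {
  ref <- freq_spectrum(nu, rep(1 + 0i, length(nu)))
  sam <- freq_spectrum(nu, fresnel_transfer(nu, n_complex, thickness_mm))
  list(sample = sam, reference = ref)
}

# complex index n - 1i*kappa of a Lorentz oscillator on background n_inf
lorentz_index <- function(nu, center, strength, gamma, n_inf) {
  n_inf + strength * center^2 / (center^2 - nu^2 + 1i * gamma * nu)
}

expect_peak_near <- function(peaks, freq, tol) {
  expect_true(any(abs(peaks$frequency - freq) <= tol),
              label = sprintf("peak near %.2f THz (found: %s)", freq,
                              paste(round(peaks$frequency, 3), collapse = " ")))
}
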