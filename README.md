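# thztds

Terahertz time-domain spectroscopy (THz-TDS) records the electric field of a
sub-picosecond pulse transmitted through a sample, giving amplitude and
phase at once. For crystalline powders pressed into pellets — pesticides,
pharmaceuticals, explosives — the 0.1–3.5 THz band carries fingerprint
absorption lines from low-frequency intermolecular and skeletal vibrations.
`thztds` turns paired reference/sample time traces into assigned fingerprint
peak lists:

1. **Optical-constant extraction.** From the transfer function
   `H(ν) = E_s(ν)/E_r(ν)` of a thick slab of thickness *d* (single pass,
   two Fresnel interfaces):

   ```
   n(ν) = 1 + c·Δφ(ν) / (2πν d)
   α(ν) = (2/d) · ln[ 4n(ν) / (ρ(ν)·(n(ν)+1)²) ]       ρ(ν) = |H(ν)|
   ```

   with Δφ the unwrapped phase delay, α in cm⁻¹, on a fixed 463-point
   analysis grid over 0.1–3.5 THz.

2. **Wavelet threshold de-noising (WTD).** Multilevel db5 decomposition
   (5 levels), soft shrinkage `sign(x)·max(|x|−t, 0)` of the detail
   coefficients, reconstruction; scored by `RMSE = √(Σ(f−f̂)²/N)` and
   `PSNR = 10·log₁₀(max|f| / RMSE)` in dB.

3. **Baseline correction (SBC).** Asymmetric least squares: the baseline
   *z* minimises `Σ wᵢ(yᵢ−zᵢ)² + μ Σ (Δ²zᵢ)²` with `w = p` above and
   `1−p` below the baseline (defaults μ = 100, p = 0.001; the published
   setting p = 0 via `pipeline_config(preset = "paper")`).

4. **Peak detection and confirmation.** Prominence-based local maxima with
   sub-grid parabolic refinement; each peak is checked for the anomalous
   dispersion signature (a local decrease of n(ν) inside the linewidth)
   that separates genuine absorption lines from ripple artifacts.

5. **Assignment.** Greedy one-to-one matching of experimental peaks against
   a theoretical (DFT-computed) line table within a 0.15 THz tolerance,
   reporting the signed shift `theory − experiment` and carrying the
   vibration-mode labels.

A Lorentz-oscillator forward simulator (`simulate_measurement()`) generates
physically consistent reference/sample trace pairs — planted fingerprint
lines with matching dispersion, rising absorption background, Fresnel
losses, white noise and slow drift — so the entire chain is testable
without instrument data. Presets for six pesticides (chlorpyrifos,
fipronil, carbofuran, dimethoate, methomyl, thidiazuron) plant lines at
their published experimental frequencies with the campaign's pellet
thicknesses.

## Worked example

```r
library(thztds)

sim <- simulate_measurement(compound_preset("methomyl", seed = 42))
res <- process_pair(sim$reference, sim$sample)
res
#> <pipeline_result> 463 grid points, 5 peaks
#>   peaks (THz): 1.01 1.66 1.90 2.72 3.18
#>   band-average n = 1.505

match_peaks(pesticide_peak_table("methomyl", "dft"), res$peaks)
#>   theory_freq experiment_freq        shift mode_label
#> 1        1.01        1.008228  0.001771952  d(C-N)ip
#> 2        1.59        1.659191 -0.069191320  d(C-N)ip
#> 3        2.01        1.904018  0.105982453  d(C-N)ip + d(C-S)oop
#> 4        2.68        2.722031 -0.042031166  d(C-H)ip
#> 5        3.09        3.183667 -0.093667226  d(C-O)ip
```

The five detected peaks sit at the planted line centers (1.01, 1.65, 1.91,
2.72, 3.20 THz) to within a grid step or two; all five carry the
anomalous-dispersion confirmation flag; the band-average refractive index
(1.505) reproduces the preset's background index; and the signed shifts
against the theoretical table have the expected sub-0.11 THz magnitudes.
Rounded to two decimals they are the table a spectroscopist would publish.

The same chain is scriptable from a shell via `inst/cli/thztds.R`
(`simulate`, `process`, `peaks`, `match`, `report` subcommands), e.g.

```sh
Rscript inst/cli/thztds.R simulate --compound methomyl --seed 42 -o out/
Rscript inst/cli/thztds.R process out/ref.csv out/sample.csv --thickness 1.59 -o out/
Rscript inst/cli/thztds.R match inst/extdata/dft_methomyl.csv out/peaks.csv --tol 0.15
```

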