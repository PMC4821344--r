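# fcsfit

Analysis of in vivo fluorescence correlation spectroscopy (FCS) and
fluorescence recovery after photobleaching (FRAP) measurements of
fluorescently tagged DNA-binding proteins — the kind of experiment that
asks how a transcription factor moves inside a living nucleus: how much
of it diffuses freely, how much is transiently trapped on chromatin,
and how much is stably bound.

The package covers the full analysis chain from a raw photon-count
trace to physical quantities, plus a Brownian-dynamics simulator that
generates traces with known ground truth for validation:

* **Photobleach handling** — fit the bleaching envelope
  `y = A e^(-kt) + y0`, flag bleaching cells, excise the bleach window
  (20 s / 10 s presets), segment the record.
* **Correlation** — multi-tau autocorrelator (16 lags/octave,
  symmetric normalization), per-segment averaging with cross-segment
  dispersion as fit weights.
* **Model fitting** — weighted least squares of the M-component
  3D-Gaussian diffusion ACF

  `G(τ) = 1 + (1/N) Σᵢ Fᵢ [1 + (τ/τᵢ)^α]⁻¹ [1 + (τ/τᵢ)^α / S²]^(−1/2)`

  over 50 µs–3.4 s, with simplex-constrained fractions, ordered
  diffusion times, optional anomalous exponents and triplet term, and
  seeded multi-start Levenberg–Marquardt. `fcs_fit()` returns a classed
  model object with `print`, `summary`, `coef`, `predict`, `plot`,
  `residuals` and `simulate` methods.
* **Model selection** — corrected AIC, nested F-tests, a physicality
  screen (no sub-1% components, no bound-pinned times) and a
  parameter-dispersion screen (CV > 200% across replicates), resolved
  conservatively (`select_model()`).
* **Derived quantities** — beam-waist calibration `ω = √(4 D_ref
  τ_ref)`, diffusion coefficients `D = ω²/4τ`, EGFP-referenced
  apparent masses `Mw = 27 (τ/τ_EGFP)³` kDa, and the expected genomic
  spacing of an IUPAC consensus motif.
* **FRAP** — pre-bleach normalization and single-exponential
  association fitting, `t_half = ln2 / k` (`frap_fit()`).
* **Simulation** — `simulate_trace()` (Brownian dynamics + immobile
  bleaching + Poisson detection through a 3D-Gaussian volume),
  `synthesize_acf()`, `simulate_frap()`.

## Worked example

Simulate a "cell" with one mobile species (D = 2.5 µm²/s) plus a
stably bound, photobleaching fraction, and run the pipeline:

```r
library(fcsfit)

cfg <- sim_config(components = data.frame(D = 2.5, count = 120),
                  immobile = list(count = 250, bleach_rate = 0.3),
                  box = c(2, 2, 4), brightness = 5e4, bin_width = 5e-4,
                  duration = 24, segment_length = 4, rng_seed = 42)
sim <- simulate_trace(cfg)

rc <- run_config("custom", excision_window = 8, segment_length = 4,
                 max_lag = 0.2,
                 candidates = list(fcs_model_spec(1, fit_range = c(1e-3, 0.2)),
                                   fcs_model_spec(2, fit_range = c(1e-3, 0.2))))
out <- run_pipeline(sim$trace, rc, calibration = 0.2,
                    tau_egfp = 266.7e-6, label = "demo")
out$bleach
#> Photobleach fit: A = 15494  k = 0.1985 /s  y0 = 2464
#>   bleaching: detected  (residual norm 0.231 )
out$comparison
#> Model comparison over 2 candidates
#>   [1] M=1  chi2=1.8469  AICc=-164.98
#>   [2] M=2  chi2=0.1783  AICc=-279.59   <- selected
#>   F-test 1 vs 2: F=215.2 p=4.45e-24
out$fit
#> 2-component diffusion model (free, free); S = 5
#>   N = 1.914
#>   component 1: F = 92.22%  tau = 0.004112 s
#>   component 2: F = 7.785%  tau = 0.258 s
#>   chi2 = 0.1783 on 46 dof ( 51 lags ); converged
```

The bleaching bound fraction is detected (fitted rate 0.20 /s against a
true per-molecule rate of 0.3 /s, measured after the 8-s excision); the
dominant fitted component recovers the generating diffusion time
`ω²/4D = 4.0 ms` as 4.1 ms; the small slow component is the correlation
footprint of the still-bleaching residual bound molecules — the same
slow-tail phenomenon that motivates excising the bleach window in real
measurements.

Converting published-scale diffusion times (EGFP reference 266.7 µs,
waist 0.218 µm, monomer 51.2 kDa):

```r
derived_params(c(343.2e-6, 3.28e-3, 98.2e-3), 0.218, 266.7e-6)
#>   component       tau          D         mass mass_2sf   mass_ratio mass_ratio_2sf
#> 1         1 0.0003432 34.6182984 5.753559e+01  5.8e+01 1.123742e+00        1.1e+00
#> 2         2 0.0032800  3.6222561 5.022457e+04  5.0e+04 9.809487e+02        9.8e+02
#> 3         3 0.0982000  0.1209878 1.347812e+09  1.3e+09 2.632444e+07        2.5e+07
```

Reading: the fastest component has the apparent mass of a free monomer
(58 kDa at 2 s.f. vs 51.2 kDa actual); the intermediate and slow
components correspond to apparent masses of ~50 MDa and ~1.3 TDa —
about 10³- and 2.5×10⁷-fold the monomer — far too large for real
complexes, and hence read as transient interactions with immobile
nuclear structures rather than as diffusing assemblies.

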