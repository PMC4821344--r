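---
title: "Models and methods: in vivo FCS and FRAP analysis with fcsfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: in vivo FCS and FRAP analysis with fcsfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcsfit)
```

## The measurement and its model

Fluorescence correlation spectroscopy (FCS) watches the photon count
rate from a femtoliter confocal volume. Fluorescent molecules diffusing
through the volume produce intensity fluctuations whose normalized
autocorrelation

$$G(\tau) = \frac{\langle I(t)\, I(t+\tau)\rangle}{\langle I\rangle^2}$$

decays on the timescale of the molecular transit time. For a mixture of
$M$ species diffusing through a 3D-Gaussian detection volume with
lateral $1/e^2$ radius $\omega$ and axial/lateral ratio $S$ (the
*structure parameter*), the model fitted by `acf_model()` / `fcs_fit()`
is

$$G(\tau) = 1 + \frac{1}{N}\sum_{i=1}^{M} F_i
  \left[1 + \left(\frac{\tau}{\tau_i}\right)^{\alpha_i}\right]^{-1}
  \left[1 + \frac{1}{S^2}\left(\frac{\tau}{\tau_i}\right)^{\alpha_i}
  \right]^{-1/2},$$

where $N$ is the mean occupancy of the volume, $F_i$ and $\tau_i$ the
fraction and diffusion time of species $i$, and $\alpha_i = 1$ for free
Brownian motion ($\alpha_i < 1$ models obstructed diffusion). A
multiplicative triplet-blinking factor
$1 + \tfrac{T}{1-T}e^{-\tau/\tau_T}$ is available behind
`fcs_model_spec(triplet = TRUE)` but off by default: with the fit range
starting at 50 µs, EGFP photophysics contributes negligibly, and
including the term mainly destabilizes three-component fits.

Two printed-form ambiguities were resolved as follows. The ACF
denominator is taken as the squared mean $\langle I\rangle^2$ (the
standard normalization with $G \to 1$ baseline); a literal second
moment would force $G \le 1$ and contradict every fitted amplitude.
The model above is the standard two-factor 3D-Gaussian form with the
additive baseline 1.

Derived quantities (module `derived_quantities`) convert fitted times
into physics: $D_i = \omega^2/(4\tau_i)$ with $\omega$ calibrated from
a reference dye via `calibrate_waist()` ($\omega = \sqrt{4 D_{\rm ref}
\tau_{\rm ref}}$), and the spherical-diffuser apparent mass
$M_{w,i} = 27\,(\tau_i/\tau_{\rm EGFP})^3$ kDa referenced to EGFP
(27 kDa). Masses are reported unrounded and at two significant
figures; fold-ratios against a monomer mass are reported for both
conventions, since order-of-magnitude statements conventionally use the
rounded values. Note the Jensen gap: the mean of per-cell $D$ values
exceeds $\omega^2/(4\bar\tau)$ for a dispersed $\tau$ sample;
`derived_params()` computes from whichever $\tau$ you hand it, and the
test suite demonstrates the gap explicitly.

## Trace processing

Stably DNA-bound molecules inside the volume bleach irreversibly at the
start of a measurement, visible as an exponential decay of the mean
intensity, $y = A e^{-kt} + y_0$ (`fit_photobleach()`). The fit runs on
0.1-s re-binned intensity because the decay is an envelope phenomenon:
per-bin shot noise at 15 µs carries no information about $k$. Since
only "observable photobleaching" distinguishes bleaching from
non-bleaching cells in practice, the package uses a quantitative,
scale-free flag: bleached fraction $A/(A+y_0) > 5\%$, decay time $1/k$
shorter than the trace, and $\ge 20\%$ residual-norm improvement over a
constant fit. On bleach-free simulations this flags $<5\%$ of runs.

When bleaching is flagged, the initial window is excised before
correlation — 20 s for silk-gland (PSG) cells, 10 s for HeLa cells
(`run_config()` presets) — and the remainder is split into 10-s
segments. Per-segment ACFs are averaged and their per-lag standard
deviation (floored at $10^{-6}$) becomes the weight $\sigma_i$ in the
fit.

## The correlator

`compute_acf()` implements the multi-tau scheme: 16 lags per octave at
the native bin width, then the upper half-octave at successively
pair-averaged resolutions, up to 3.4 s. Estimation uses the symmetric
normalization $\langle I_a I_b\rangle / (\langle I_a\rangle\langle
I_b\rangle)$ over the overlapping windows, which keeps $G \to 1$ under
slow drift. The base lag equals the trace's native bin; when photon
timestamps are supplied (`read_trace(format = "photon_timestamps")`)
they are binned at 0.2 µs by default. Since the default fit range
starts at 50 µs, a 15-µs-binned trace loses no usable information.

A deliberate deviation from a stated precondition: requiring the trace
to be 10 times longer than the maximum lag would forbid the standard
analysis itself (3.4-s fit range on 10-s segments). The package
therefore errors only when the trace is shorter than twice the maximum
lag and warns below the 10-fold margin.

`compute_acf(method = "direct")` evaluates the same estimator at every
lag on the raw series without coarsening — $O(nL)$, exactly
reversal-symmetric, and the in-package cross-check for the multi-tau
path (the test suite additionally checks against an independent plain-R
correlator).

## Fitting, weighting, and numerical choices

`fcs_fit()` minimizes $\chi^2 = \sum_i \left[(G_{\rm model}(\tau_i) -
G_i)/\sigma_i\right]^2$ over the fit range (default 50 µs–3.4 s) by
Levenberg–Marquardt on an unconstrained reparameterization: $\log N$;
fractions through a softmax (simplex constraint, $\sum F_i = 1$);
diffusion times as $\log \tau_1$ plus log-ratio increments, enforcing
strict ascending order (this breaks label switching) within bounds
$[10^{-6}, 10]$ s; optional $\alpha_i \in (0.1, 1]$ via a scaled
logistic. Multi-start (8 seeded initializations with log-uniform
$\tau$ spreads and equal fractions; deterministic for a fixed seed)
defeats the local minima that three-component fits are prone to; the
best $\chi^2$ wins. Parameter uncertainties come from the numeric
Hessian at the optimum through the delta method. When no cross-segment
dispersion exists, unit weights are used with a warning — $\chi^2$ then
loses its absolute scale, but nested model comparison remains valid.

## Deciding the number of components

`select_model()` reproduces the adjudication logic used in practice:

* **AICc** (`aicc()`): $N\ln(\chi^2/N) + 2K + 2K(K+1)/(N-K-1)$, the
  least-squares AIC with small-sample correction. Differences between
  candidates are invariant to a common rescaling of all $\sigma_i$;
  absolute values are not.
* **Nested F-test** (`f_test()`): $F = \frac{(\chi^2_1 -
  \chi^2_2)/(DF_1 - DF_2)}{\chi^2_2/DF_2}$ with $DF = N - K - 1$;
  the more complex model is accepted at $p < 0.05$ (the conventional
  threshold; the source analysis reports tests without stating one).
* **Physicality screen**: components under 1% amplitude (no reliable
  diffusion time determinable) or $\tau$ pinned at the optimizer bounds
  reject a candidate.
* **Dispersion screen** (`screen_dispersion()`): with $\ge 3$ replicate
  curves, any parameter CV above 200% flags the model unstable. Note
  an arithmetic fact: the sample CV of $n$ non-negative replicates is
  bounded by $\sqrt{n}$, so this screen cannot fire with fewer than 5
  replicates.
* Disagreement between AICc and F-test resolves to the simpler model
  with a logged rationale code — conservative, mirroring their joint
  use.

Each more complex candidate is warm-started from the simpler fitted
model (a 5%-amplitude component inserted below, between, and above the
fitted times) in addition to the random starts, guaranteeing the nested
fit reaches at least the simpler model's $\chi^2$. This matters for
F-test calibration: without it, missed nested optima make the null
p-value distribution over-conservative.

## FRAP

`normalize_frap()` divides by the mean of (conventionally three)
pre-bleach frames and re-zeroes time at the first post-bleach frame;
`frap_fit()` fits the single-exponential association $y(t) = y_{\rm
offset} + A(1 - e^{-kt})$, reporting $t_{1/2} = \ln 2 / k$ and the
recovery fraction $y_{\rm offset} + A$. The bleach depth is fitted, not
fixed, for robustness to incomplete bleaching. A recovery with
$t_{1/2}$ under two frame intervals is flagged below resolution rather
than reported as a number — the honest answer for fast-diffusing
controls.

## The simulator: what it emulates, and what it does not

`simulate_trace()` is a Brownian-dynamics Monte Carlo with known ground
truth: mobile particles take per-axis Gaussian steps of variance
$2D\,\Delta t$ in a periodic box (at least 10 waists per lateral axis,
so the open-volume Gaussian ACF is a valid oracle without re-injection
logic); each particle contributes detection weight
$\exp(-2(x^2+y^2)/\omega^2 - 2z^2/(S\omega)^2)$; immobile particles
bleach irreversibly per-step (geometric survival), reproducing both the
exponential mean decay and its shot noise; counts are Poisson. The
propagation step equals the trace bin (default 15 µs, the illumination
period); at desk-scale $D \le 25\ \mu m^2 s^{-1}$ and $\omega = 0.2\
\mu m$ the per-step displacement is $\le 0.14\,\omega$, so sub-stepping
is unnecessary. One global seed drives all draws through R's RNG, so
traces are bit-reproducible. Defaults: $\omega = 0.2\ \mu m$, $S = 5$
(a volume of roughly 400 nm diameter × 2000 nm height), 60-s duration
as six 10-s segments.

The simulator deliberately omits: triplet blinking and other reversible
photophysics, flow and active transport, spatially varying chromatin
obstruction (anomalous diffusion is available in the *fitting* model
but traces are generated Brownian), detector afterpulsing and dead
time, and cell-to-cell brightness variation. Passing tests therefore
show that the analysis chain is correct and calibrated for a
shot-noise-limited, multi-component Brownian world — not that it
overcomes every artifact of live-cell data.

Discretization and finite statistics leave visible fingerprints, which
the tests quantify rather than hide: a single 3-s, 144-particle,
one-component trace recovers $\tau = \omega^2/(4D)$ with a few-percent
systematic underestimate (end-of-step sampling) and seed-to-seed
scatter of order 10%, comfortably inside the 15% oracle band over 10
seeds. Two-component parameter recovery from a single short trace is
statistics-limited (tens of percent scatter per seed), so the
two-component oracle check fits the 10-seed averaged ACF with
cross-seed dispersion weights — the averaged curve is the object the
15% band meaningfully constrains at this problem size. Problem sizes
throughout the suite (3-s traces, 72–144 particles, 120-lag synthetic
curves at $\sigma = 0.005$, 20-curve selection experiments, 200-replicate
null calibration) were chosen once as realistic desk-scale conditions.

`synthesize_acf()` (exact model curve plus optional i.i.d. Gaussian
noise) and `simulate_frap()` complete the generator set; both are exact
in their noiseless limits, which the oracle tests exploit.

## Known limitations

* Weighted $\chi^2$ with cross-segment $\sigma$ estimated from few
  segments is itself noisy; with 4–6 segments the weights carry ~30%
  relative error, and on single synthetic curves unit weights are often
  better behaved.
* The F-test on nonlinear nested fits is asymptotic; its null
  distribution at boundary alternatives ($F_{\rm new} \to 0$) is
  conservative, which the calibration test brackets at a 2–10%
  rejection band rather than asserting exact uniformity.
* `S` is fixed (default 5) rather than fitted, because free-$S$
  three-component fits are ill-conditioned; a mis-set $S$ biases
  $\tau_i$ mildly and $N$ more strongly.
* The R6G reference diffusion coefficient is a named constant the user
  must confirm against their calibration convention; literature values
  differ by ~40% across temperature conventions.
* No proprietary microscope raw-file readers: traces enter as delimited
  text or photon-timestamp lists.
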