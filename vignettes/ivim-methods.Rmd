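---
title: "Models and methods behind ivimtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ivimtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivimtools)
```

## The signal model

Intravoxel incoherent motion (IVIM) imaging interprets the diffusion-weighted
MR signal of a voxel as the sum of two exponentially decaying compartments:
water diffusing in tissue, and blood moving incoherently through a randomly
oriented capillary network, which dephases much faster,

$$ S(b) = S_0 \left[ f\, e^{-b D^*} + (1 - f)\, e^{-b D} \right], $$

with `b` the diffusion weighting (s/mm^2), `D` the tissue diffusion
coefficient, `D*` the pseudo-diffusion coefficient and `f` the perfusion
(pseudo-diffusion) *signal* fraction at `b = 0`. Units follow the field
convention (`D`, `D*` in mm^2/s, so tissue values sit near 1e-3); `D*` here is
the total pseudo-diffusion rate — no separate blood-diffusivity term is
modeled. All downstream machinery (fitting, Fisher information, design
optimization, phantoms) consumes this one forward model, `ivim_signal()`.

SNR is defined at `b = 0`: the noise standard deviation is `S0 / SNR`,
constant across b-values. Gaussian noise is additive; Rician noise is the
magnitude of a complex signal with two independent Gaussian quadrature
components, the distribution of magnitude-reconstructed images. The Gaussian
model is the analysis default (it is also what the Fisher information
assumes); the Rician option exists because magnitude data at low SNR have a
noise floor that biases signals upward — the phantom generator defaults to
it for realism.

Because `f` is a signal fraction at the acquisition TE, compartments with
different T2 see different relaxation weighting. `t2_corrected_f()` inverts
the two-compartment weighting
`f_meas = f w_b / (f w_b + (1-f) w_t)`, `w = exp(-TE/T2)`, turning the
signal fraction into a blood volume fraction. This closed-form
two-compartment inversion is this package's documented choice, and the
round-trip with the forward weighting is tested to 1e-10. (The consensus
literature recommends reporting a corrected `f` without prescribing a
formula; more elaborate corrections would distinguish arterial and venous
blood T2 and, in kidney, tubular fluid.)

## Fitting

The consensus estimation route is the **segmented fit** (`segmented_fit()`):

1. For `b >= b_threshold` the perfusion term is negligible (the threshold is
   chosen so `exp(-b D*) <= 1/20`, i.e. `b ~ 3/D*`; 200 s/mm^2 for all
   organs, 300 for brain). A straight line is fitted to the log-signal by
   weighted linear least squares with weights equal to squared signal
   amplitudes — the correct first-order weighting for log-transformed
   additive noise. The first iteration weights by the observed signals, each
   further iteration by the model predictions; the default is 2 iterations
   (one refresh), configurable. A single iteration with the observed-signal
   weights reproduces weighted OLS exactly, which is tested.
2. `f` follows from the measured mean `b = 0` signal (not a fitted
   intercept): `f = 1 - intercept / mean(S(0))`. If that estimate is not
   positive the voxel is flagged (`f_clipped`), `f` is reported as 0 and
   `D*` as undefined.
3. The full model is then fitted at all b-values with `D` frozen — and, in
   the default `segmented_fix_df` variant, `f` and `S0` frozen too — leaving
   `D*` as the single free parameter, initialized at `10 x D`. The
   `segmented_refit_f` variant re-solves `f` jointly with `D*` and `S0`
   (whether `S0` should also be frozen in that variant is not specified
   anywhere authoritative; refitting it is this package's choice, recorded
   here).

Freezing `D` and `f` is the default because it is the more reproducible of
the two variants. Segmented fitting on a biexponential truth carries a known
systematic error: the residual perfusion signal above the threshold tilts
the high-b line, giving a positive bias in `D` and a negative bias in `f`.
Both signs, and the decay of the bias as `D* b_threshold` grows, are
verified by tests on noiseless curves across all six organ presets.

`full_nlls_fit()` is the simultaneous bounded Levenberg-Marquardt fit of all
four parameters with analytic Jacobians. Internally it is parameterized in
`(S0, f, D, D* - D)` so the box constraint enforces `D* >= D` exactly.
Default bounds are `f` in [0, 1], `D` in [1e-5, 5e-3] mm^2/s, `D*` in
[D, 0.5] mm^2/s, `S0` in (0, 2 max(signal)] — wide enough to cover all organ
priors with margin. Initial values come from a segmented fit of the same
data unless supplied. Non-convergence is flagged and the initial values are
carried rather than silently returned as estimates.

Voxelwise fitting (`fit_volume()`) first collapses direction-encoded volumes
to trace-weighted signals by geometric mean within a frame (equivalent to
averaging log-signals, which matches the log-linear structure of step 1),
drops user-excluded volumes (signal-void removal is a manual, user-supplied
decision), and skips voxels with non-positive trace signals rather than
clipping them, because the log-domain step is undefined there. Nominal
b-values are taken as true b-values; imaging-gradient cross-term correction
is out of scope.

## Organ presets and compliance checking

`get_preset()` returns the per-organ consensus constants: the nested
b-value tiers (abbreviated: 3 values including 0; minimal: 6; advanced: any
superset of minimal), the threshold b-value, TR minima (4 s brain, 3 s
kidney/liver/pancreas, 4 s muscle/breast — the source table merges columns
ambiguously, so these are overridable defaults), the 2-average minimum for
skeletal muscle, fat-suppression expectations (SPIR brain, SPAIR elsewhere;
warn-level only, since fat suppression cannot affect the fit), and
resolution/slice ranges.

The parameter **priors** (mean and between-study SD of `f`, `D`, `D*` per
organ) ship in `inst/extdata/organ_priors.json` as clearly labeled
*synthetic placeholders*: plausible values assembled from the IVIM
meta-analysis literature, not a reproduction of any single published table.
They were fixed once, with two published anchors used as calibration
constraints: the brain `D*` mean (0.011 mm^2/s) reproduces the published
suppression threshold `ln(20)/D* ≈ 275 s/mm^2`, and the kidney entry
reproduces the published percentage-point differences (2, 8, 3 for `D`,
`f`, `D*`) between the heuristic kidney set (0, 30, 70, 100, 200, 800) and
the CRLB-optimal set (0, 0, 30, 150, 200, 800) under the default design
configuration below. Users with study-specific constants should pass
`priors_file =`.

`check_protocol()` verifies tier containment as multisets (so a repeated
`b = 0` requirement is honored), TR/averages/directions minima, and range
checks; it returns one finding per field and never raises on
non-compliance. `reporting_checklist()` inventories the acquisition-timing
and fitting details good practice asks to be reported, with a fixed item
count so "n of 20 provided" is comparable across studies.

## Cramér–Rao design analysis

For Gaussian noise with constant sigma, the Fisher information of the model
over `(S0, f, D, D*)` is `(1/sigma^2) sum_b g(b) g(b)^T` with the analytic
gradient of the biexponential. `S0` is treated as a free nuisance parameter
(4x4 information), a documented choice. The lower-bound standard deviations
are the square roots of the inverse-information diagonal; conditioning is
assessed on the diagonally normalized matrix because the raw entries mix
units spanning six orders of magnitude.

The design objective is the published one: the sum of *relative*
uncertainties in `D` and `D*` and the *absolute* uncertainty in `f` (so the
metric stays finite as `f -> 0`), averaged over a prior grid spanning mean
± 1 SD per parameter. Defaults, where the published description is silent:
3 grid points per parameter (27 combinations), arithmetic-mean aggregation,
`f` floored at 0.01 on the grid, SNR 25 (the reference worst case).
`optimize_bvalues()` fills the free slots of a 6-value design — the
abbreviated tier is always fixed — by exhaustive enumeration of candidate
multisets (repetition allowed, including repeated `b = 0`) on a 0–1000
step-10 grid; the inner scan is compiled (RcppArmadillo), enumeration is
lexicographic and ties resolve to the smallest multiset, so the result is
deterministic. The optimizer's output always costs no more than the
published kidney optimum evaluated under the same spec — under the
placeholder priors it is in fact ~17% cheaper, which is expected: the
published set was optimal under the original study's unpublished priors.

Key closed-form properties under test: information additivity over repeated
b-values, exact 1/SNR scaling of every lower bound, S0-scale invariance of
relative uncertainties, and information monotonicity (adding a measurement
never increases any bound).

## Monte Carlo SNR planning

`simulate_errors()` draws noisy realizations, fits each replicate, and
reports per-parameter relative bias, relative dispersion and the **total
relative error** `sqrt(bias^2 + dispersion^2)` — the quadrature combination
is this package's operationalization of "combining bias and dispersion" and
is pluggable via `metric`. Non-converged replicates are excluded from the
moments (clipped estimates would distort the bias) and reported as a
failure fraction; above 50% the result is flagged unreliable.
`min_snr_for_error()` scans an ascending SNR grid with common random
numbers (the same standard-normal draws scaled by each sigma), so the
error-versus-SNR curve is monotone up to fit nonlinearity, and returns the
smallest grid SNR meeting a 20% default target per parameter; the overall
answer is the max over parameters, with no interpolation between grid
points. Default 1000 replicates per condition; tests and the acceptance
script use 1000–10000 depending on the property, sizes chosen to keep
sampling error well below the tolerances being asserted.

At the reference SNR 25 the recovery ranking `D < f < D*` in total relative
error holds for all six organ presets — the simulated counterpart of the
reproducibility ordering reported across test-retest studies (CV ~1–10% for
`D`, ~10–40% for `f` and `D*`).

## Digital phantoms and I/O

`generate_phantom()` draws voxelwise truth from the organ prior (truncated
to `f >= 0.01`, `D > 0`, `D* >= 2D`), evaluates the forward model at the
tier's b-values, and adds seeded noise; with three directions requested it
emits three volumes per b sharing a frame id. The phantom is isotropic and
spatially uncorrelated: it emulates parameter heterogeneity and noise, not
anatomy, partial-volume structure, motion, distortion or eddy currents — so
green phantom tests validate the estimation chain, not robustness to those
real-data effects (which the consensus handles by external pre-processing,
out of scope here apart from the volume-exclusion hook).

I/O follows the FSL dialect: one-line `.bval`, 3-row `.bvec`, NIfTI volumes
(via RNifti, float32 on disk), and a JSON sidecar carrying the frame/
exclusion metadata that plain gradient tables cannot express. ROI reporting
(`roi_stats()`) gives mean, SD, median and IQR per label; quantiles use
linear interpolation (R type 7), fixed and documented because IQRs must be
comparable across implementations. Contour ROIs on the `b = 0` image are a
documentation recommendation, not code.

## Numerical and degenerate-input policy

* Negative b-values, unknown noise models and organ names, bad bounds and
  mismatched b-tables fail fast with messages naming the offending value.
* `f = 0`, `f = 1`, `D* = D`, and designs with fewer than 4 distinct
  b-values are named singularities of the information matrix.
* Estimates at bounds are clipped and flagged, never silently truncated.
* All randomness flows through explicit seeds (`noise_spec(seed =)`,
  function `seed` arguments); a fixed seed makes phantoms bit-identical and
  simulations exactly reproducible. Seed state is restored after use, so
  package calls do not perturb the caller's RNG stream.

## Known limitations

* The CRLB is an asymptotic bound. The full-NLLS estimator attains it in
  simulation at high SNR (empirical-to-bound SD ratios ~1.01 at SNR 2000),
  but at SNR 100 organs with small perfusion fractions (brain, muscle) have
  perfusion-feature SNR `f x SNR` of only ~5–8; there the likelihood is
  strongly non-Gaussian, the estimator is heavy-tailed, and empirical SDs
  exceed the bound several-fold. This is a property of the estimation
  problem — one of the reasons segmented fitting is the recommended
  baseline — and the corresponding acceptance check is expected to fail for
  those organs.
* Packaged priors are placeholders (above); absolute CRLB and Monte Carlo
  numbers move with the priors, though the structural properties (scaling,
  monotonicity, orderings, bias signs) do not.
* Rician-likelihood CRLB, direction/TE/diffusion-time optimization,
  tri-exponential and anisotropic extensions, and Bayesian or learned
  estimators are out of scope.
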