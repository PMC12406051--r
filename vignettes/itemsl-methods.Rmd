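---
title: "Trial-wise fMRI decoding with inverse transformed encoding models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-wise fMRI decoding with inverse transformed encoding models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical model the package implements, the
assumptions behind it, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## 1. The model

### Trial-wise estimation

A rapid event-related fMRI session yields a signal matrix $Y$ (scans
$\times$ voxels). The trial-wise GLM uses a design matrix $X_t$ (scans
$\times$ trials) with one HRF-convolved boxcar regressor per trial, plus
nuisance regressors (pooled non-trial conditions, drift terms, a constant).
Three single-trial estimators are provided:

* **LS-A** (`lsa_estimate()`): all trials jointly by weighted least squares,
  $\hat\Gamma = (X_t'V^{-1}X_t)^{-1}X_t'V^{-1}Y$.
* **LS-S** (`lss_estimate()`): one two-regressor model per trial (this
  trial vs. the sum of all others, plus nuisance); the trial's estimate is
  the first coefficient of its own model. The implementation assembles all
  $t$ normal equations from a single set of cross-products, so the cost is
  one cross-product plus $t$ small solves.
* **Fractional ridge** (`fracridge_estimate()`): per-voxel ridge solutions
  parameterized by the retained fraction of the OLS coefficient norm, with
  the fraction chosen per voxel by cross-validated prediction of the
  held-out session's time series. This mirrors the regularization component
  of regularized single-trial toolboxes while deliberately omitting their
  voxel-wise HRF libraries and data-driven noise regressors.

### The uncorrelation matrix and its calibration

Joint estimation induces a known covariance between trial estimates: the
trial block of $(X'V^{-1}X)^{-1}$, the *uncorrelation matrix* $U$
(`uncorrelation_matrix()`). $U$ is computed from the **full** design
including nuisance columns, so covariation between trial-evoked and
nuisance-related signal is captured; with temporally close trials its
adjacent off-diagonal entries are large and negative, and it approaches a
diagonal matrix as inter-stimulus intervals grow.

Observed estimates carry a second variance source: genuine trial-to-trial
response variability, which is white at the trial level. `reml_calibrate()`
separates the two by fitting $\mathrm{Cov} = \lambda_1 I + \lambda_2 U$ to
the voxel-pooled second moment of the estimates by restricted maximum
likelihood (voxels as replicates, the trial-level design as the mean
structure). The algorithm is Fisher scoring on the restricted
log-likelihood in log-parameter space with step halving, at most 32
iterations and a relative tolerance of $10^{-6}$; the worked example in the
README shows the fitted weights recovering the generative variances of a
simulated dataset. When the two components are indistinguishable (e.g.
$U \approx I$), the *split* is unidentifiable but the fitted covariance is
still correct, which is all the decoder needs.

### Inversion and cross-validation

With a trial-to-condition transformation matrix $T$ (indicator columns;
real-valued columns for parametric modulators), the estimates follow
$\hat\Gamma = TB + H$, $H \sim \mathcal{MN}(0, U, \Sigma)$. `item()` inverts
this model under leave-one-session-out cross-validation: per fold, weights
$\hat W = (\hat\Gamma' U^{-1} \hat\Gamma)^{-1} \hat\Gamma' U^{-1} T$ are
estimated on the training sessions (with $U$ block-diagonal across sessions
and, by default, ReML-calibrated on the training fold only), and the test
session's design variables are predicted as $\hat T = \hat\Gamma \hat W$.
Predictions are concatenated over folds and scored once: argmax
classification with decoding accuracy / balanced accuracy, or per-column
Pearson correlation / median absolute error for parametric targets. The
spatial covariance $\Sigma$ is never materialized — it is absorbed into the
weights, which is why the inversion needs only $U$.

### Searchlights

`build_searchlight_index()` places a sphere around every in-mask voxel and
keeps the in-mask voxels whose center-to-center Euclidean distance (in mm,
inclusive boundary) is within the radius; boundary voxels keep truncated
spheres, and anisotropic voxels are supported through per-axis sizes. With
3 mm isotropic voxels the common 6 mm radius equals 2 voxels and an
interior searchlight holds 33 voxels. `run_searchlight()` extracts each
searchlight's trials-by-voxels submatrix, runs the cross-validated decoder
and writes one map per metric (and per regressor for parametric targets);
searchlights are independent work units, so any execution order yields
identical maps.

## 2. Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| HRF form | double gamma, delays 6/16 s, dispersions 1, ratio 6 | — | the de-facto standard canonical shape; peak-normalized to 1 |
| microtime resolution | TR/16, sampled at mid-scan | — | event onsets need not align with acquisition |
| regressor scaling | convolution × grid spacing | s | approximates the continuous boxcar–HRF integral, putting regressors (and hence simulated signal) on an O(1) scale consistent with noise variances near 1 |
| scan covariance $V$ | identity | — | the generator produces white noise; `ar1_scan_cov()` available for real data |
| condition-number threshold | $10^8$ | — | near-singular designs fail loudly (no silent ridge) |
| ReML iterations / tolerance | 32 / $10^{-6}$ | — | convergence is typically reached in well under 10 iterations |
| fraction grid | 0.05–1.00 by 0.05 | — | spans heavy shrinkage to none |
| searchlight radius | 6 | mm | 2 voxels at 3 mm; the map resolution/sensitivity trade-off |
| SVM baseline | linear, cost 1, per-voxel training-fold standardization | — | a fixed, conventional configuration; hyperparameter search is deliberately out of scope |

## 3. What the generator emulates — and what it does not

`simulate_searchlight()` draws, per simulation: balanced random condition
sequences (exactly $t/k$ trials per condition, order permuted); voxel-wise
condition means $\mu_{c,j} \sim N(0,1)$ with the means of all conditions
set equal in the uninformative $1-r$ fraction of voxels; trial amplitudes
$\gamma_{i,j} \sim N(\mu_{c,j}, \sigma_\gamma^2)$ with $\sigma_\gamma=0.5$;
inter-stimulus intervals uniform on the configured range, each trial
occupying its 2 s duration plus its ISI, first onset at 0, and the scan
count $\lceil(\text{last offset} + 32\,\mathrm{s})/TR\rceil$ so the final
HRF tail is covered; and the signal $Y = X_t\Gamma + E$ with
$E \sim N(0, \sigma^2)$ i.i.d. over scans and voxels.
`simulate_searchlight_volume()` embeds the informative voxels as a sphere
in a 3-D grid for localization checks.

The generator deliberately omits several properties of real fMRI: spatially
correlated noise between neighboring voxels, temporal autocorrelation,
scanner drift, motion artefacts, and HRF variability across voxels and
subjects. Passing the simulation studies therefore demonstrates that the
decoder handles *design-induced trial correlation* correctly — the
mechanism the method targets — not that it is robust to every noise
structure of empirical data. The model's own assumptions (linear effects,
matrix-normal errors, trial covariance constant over voxels and spatial
covariance constant over trials) are likewise the generator's assumptions.

A master seed drives each experiment; per-simulation seeds are drawn once
from it, so enlarging $N$ extends the simulation set without reshuffling
earlier draws.

## 4. Numerical choices and degenerate inputs

* Classification ties go to the lowest column index (declared, tested).
* $U$ and all fitted covariances are symmetrized and checked for positive
  definiteness; singular cross-products raise errors naming the collinear
  columns.
* When a training fold has more voxels than trials,
  $\hat\Gamma'U^{-1}\hat\Gamma$ is singular; the default is an explicit
  error, with a Moore–Penrose pseudoinverse behind an opt-in flag
  (`fallback = "pseudoinverse"`), since the inversion is not defined by the
  method in that regime.
* Constant regression targets make the predictive correlation undefined:
  `NaN` with a warning rather than an error.
* Searchlights below the minimum voxel count (default 1) and searchlights
  whose decoding fails produce missing values in the map, encoded as `NaN`
  in written volumes.
* Trials extending beyond the last scan yield truncated regressors with a
  warning; onsets beyond the scanned interval are errors.
* An intercept column in the decoder is available but off by default: the
  simulated and typical real estimates are already mean-centered by the
  constant nuisance regressor.

## 5. Scale of the shipped experiments

The method-comparison experiments shipped with the package run the nine
(noise variance $\times$ ISI range) scenarios at $N = 200$–$300$ seeded
simulations per scenario (the headline short-ISI/low-noise comparison at
$N = 500$), and the chance-calibration and four-condition variants at
$N = 100$; these sizes give median/mean accuracy estimates stable to well
under one percentage point and are the package's chosen desk-scale
conditions. The localization check uses a $10\times10\times10$ grid with a
radius-2 informative sphere and full-volume searchlight decoding.

## 6. Known limitations

* The inversion is linear: non-linear class boundaries, saturating
  modulator effects, and non-stationary responses are out of scope.
* The fractional-ridge baseline is a stated-configuration reconstruction of
  the regularization core of regularized single-trial estimation, not of
  any full toolbox (no HRF library, no data-driven noise regressors);
  comparisons against it should be read with that in mind.
* ROI and searchlight decoding assume more pooled training trials than
  voxels; very large ROIs require the explicit pseudoinverse opt-in.
* Group-level inference on the resulting maps (normalization, ANOVA,
  multiple-comparison correction) is downstream of this package.
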