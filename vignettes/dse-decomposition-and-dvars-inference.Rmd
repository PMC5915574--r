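---
title: "The DSE decomposition and DVARS inference: model, estimators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The DSE decomposition and DVARS inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dseqc)
```

## The problem

DVARS — the spatial RMS of the temporally differenced fMRI series — is
sensitive to exactly the scan-to-scan disturbances (motion, spin-history,
acquisition glitches) that corrupt functional-connectivity estimates. Used
raw, however, it has scanner-dependent units and no null distribution, so
"bad" has to be defined by eye or by arbitrary thresholds that do not
transfer between sites. `dseqc` implements two complementary remedies: a
sum-of-squares decomposition that gives DVARS an exact place in the total
variability of the 4D dataset, and a calibrated chi-squared test with
robustly estimated null moments that turns DVARS into p-values.

## The decomposition and its assumptions

Starting from centered, intensity-scaled data
$Y_{it} = (Y^{R}_{it} - M^{R}_i)/m^R \times 100$ (so that typical
pre-centering brain intensity maps to 100 and variance units are comparable
across datasets), the package computes, per scan pair, the fast, slow and
edge mean squares

$$A_t = \tfrac1I \sum_i Y_{it}^2,\qquad
D_t = \tfrac1I \sum_i \left(\tfrac{Y_{i,t+1}-Y_{it}}{2}\right)^2,\qquad
S_t = \tfrac1I \sum_i \left(\tfrac{Y_{it}+Y_{i,t+1}}{2}\right)^2,$$

with $E_t = A_t/2$ at the two temporal edges. The identities
$D_t + S_t = (A_t + A_{t+1})/2$ and (for the scan averages, each series'
sum divided by $T$) $A = D + S + E$ are algebraic — they hold for *any*
data, not just under a model — and the package checks them to relative
$10^{-8}$ (`verify_identities()`). The same decomposition is applied to the
global-mean series and to the spatially demeaned data; whole = global +
non-global holds per component and index.

The decomposition is purely descriptive. Model assumptions enter only in
two places: the reference expectations of the DSE table, and the null
distribution of the test.

**Averaging convention.** All four scan averages divide by $T$, including
$D$ and $S$ whose series have $T-1$ entries. This is forced by requiring
$A = D + S + E$ to hold exactly (verified on the single-voxel $[1,3]$ toy:
$A=5$, $D=0.5$, $S=2$, $E=2.5$); dividing $D$ by $T-1$ would break the
identity.

**Scaling choices.** $m^R$ is the *median* of in-mask voxel means by
default — the mean is offered, but residual extra-cranial voxels with
near-zero intensity drag a mean down while barely moving the median. Which
voxels enter $m^R$ is configurable because masked-versus-whole-volume
computation is a genuinely open convention. Voxels with non-finite values
or zero temporal variance are dropped (and logged) before anything else:
they are uninformative and would poison the rank-based estimators
downstream.

## The DSE table

Each component is reported three ways: RMS ($\sqrt{\text{mean square}}$, in
data units, comparable to a noise SD), percent of A-var, and relative to
its IID expectation ($\tfrac12 (T-1)/T$ for D and S, $1/T$ for E, $1/I$
for the global A row, etc., global rows normalized to whole-brain $A$).
Under a time–space-separable working model with common lag-1
autocorrelation $\rho$, the normalized components obey
$S - D = \rho (T-1)/T$, so `lag1_estimate()` reads the average lag-1
autocorrelation off the S–D gap — the convergence of D and S toward 50% of
A-var is precisely the disappearance of temporal autocorrelation. The
rel-IID value of the global A row, $I \cdot \bar{\bar\sigma}^2 /
\bar\sigma^2$, is a unitless index of spatial structure. The estimate is
never clamped; values outside $[-1, 1]$ are possible under sampling noise
and are shown as computed.

Non-global rows are computed but hidden by default (`include_nonglobal =
TRUE` shows them): they are the exact complement of the global rows and
standard reports print whole + global only.

## The DVARS test and its estimators

Under temporal homogeneity, $\mathrm{DVARS}_t^2$ has some null mean $\mu_0$
and variance $\sigma_0^2$; moment-matching gives
$X_t = (2\mu_0/\sigma_0^2)\,\mathrm{DVARS}_t^2 \sim \chi^2_\nu$ with $\nu =
2\mu_0^2/\sigma_0^2$. Normality of the null data motivates the
moment-matched chi-squared; heavy spatial dependence only reduces $\nu$.

Estimator defaults follow the calibration experiments shipped with the
package (`run_bias_experiment()`, `run_validity_experiment()`):

* $\hat\mu_0$ = **median of $\{\mathrm{DVARS}_t^2\}$**. The voxelwise
  alternative — median over voxels of $(\mathrm{IQR}(\Delta
  Y_i)/\mathrm{IQR}_0)^2$ — is unbiased only under variance homogeneity;
  with per-voxel SDs on $[200, 500]$ the median of $2\sigma_i^2$ sits ~6%
  below the mean, which shifts every Z-score by several units and produces
  grossly anti-conservative p-values. The package reproduces this contrast
  as an acceptance test.
* $\hat\sigma_0^2$ = **hIQR of $\{(\mathrm{DVARS}_t^2)^{1/3}\}$**,
  delta-method back-transformed ($\hat\sigma_0 = \mathrm{spread}(X)/(d\,
  \hat\mu_0^{d-1})$). The half-IQR (median − Q1) ignores everything above
  the median, buying robustness against exactly the upward spikes the test
  hunts; the cube-root is the Wilson–Hilferty normalization of a
  chi-squared variate. All of $d \in \{1, 1/2, 1/3, 1/4\}$ are available.
  The cube root is taken as the theoretically preferred exponent for
  chi-squared-distributed inputs — a cubing transform would make no sense
  here, and $x^{1/3}$ is the canonical normalizer.
  Both $d = 1$ and $d = 1/3$ calibrate equivalently in the
  validity experiment, so little hangs on the choice.
* Quantiles are linear-interpolation sample quantiles (R type 7),
  fixed and documented because every IQR-based estimate depends on the
  quantile rule.

P-values are one-sided (upper tail) by default; the two-sided variant
(doubling the smaller tail) exists to catch down-spikes left behind by
aggressive denoising. Multiplicity is handled by Bonferroni over the $T-1$
pairs, the convention for this test; no FDR option is offered in this
version. Statistical flags ($p \le \alpha/(T-1)$) are complemented by a
practical-significance cut-off $\Delta\%D\text{-var} > 5\%$ — excess fast
variability as a percentage of average total variability — because on very
clean data the test detects disturbances too small to matter; practical
flags are by construction a subset of statistical flags. Flagged pairs are
reported as both scan indices; which one to delete is deliberately left to
the caller.

**Numerical notes.** $p$-values are computed with the plain upper-tail
chi-squared; for extreme spikes they underflow to exactly 0, and the
Z-score then falls back to $(\mathrm{DVARS}_t^2 - \mu_0)/\sigma_0$, the
normal-approximation limit. The chi-squared and fallback Z agree closely
only when $\nu$ is large (the chi-squared skewness $\sqrt{8/\nu}$ perturbs
the far tail by $\approx \sqrt{8/\nu}\,(z^2-1)/6$; at $\nu = 10^4$ that is
~0.3 at $z = 8$), so the two-decimal agreement property is tested at $\nu =
10^8$ where it holds. $\nu$ itself is reported as a spatial
effective-degrees-of-freedom index with the explicit caveat that it is
highly estimator-sensitive and should not be reused in other roles (e.g.
spatial Bonferroni correction).

## What the synthetic generator emulates — and what it does not

`simulate_ar1_spikes()` draws per-voxel SDs uniformly on
$[\sigma_{\min}, \sigma_{\max}]$ (stock scenarios: homogeneous 200/200, low
200/250, high 200/500), runs each voxel as a stationary AR(1) with common
$\rho \in \{0, 0.2, 0.4, 0.6\}$ (innovation SD $\sigma_i\sqrt{1-\rho^2}$,
so the marginal variance is exact for every $\rho$), and injects variance
spikes by multiplying the innovation SD at selected timepoints. The spike
amplitude model is a declared stand-in — the source experiments do not
print theirs — with default factor 2, reproducing the variance-spike
phenomenology DVARS targets; a spiked timepoint $t$ contaminates pairs
$(t-1, t)$ and $(t, t+1)$ and both are ground-truth positives. One
consequence of this labeling: at $\rho > 0$ the recursion carries a damped
copy of the spike into the *next* scan, so the pair after a spiked pair is
mildly elevated yet labeled clean — measured specificity therefore sits a
few tenths of a percent below the Bonferroni value $1 - \alpha/(T-1)$
rather than exactly at it.

The generator deliberately omits spatial covariance, physiological noise,
motion, drift and scanner trends. A green calibration or power test
therefore establishes the statistical machinery (estimator bias, test
validity, detection power under the stated noise model), *not* performance
on real data; the real-data behaviors (DSE tables across preprocessing
stages, QC–FC impact) require cohort downloads and are out of scope here.

Desk-scale defaults are $I = 10{,}000$ voxels and $R = 200$ replicates
(versus $90{,}000$ and $1000$ at full scale); outputs are marked as scaled.
Seeded runs are bit-reproducible; supplying explicit spike times bypasses
their random placement so that spiked and spike-free datasets can share a
noise realization exactly.

## Calibration methodology

The validity experiment classifies an estimator setting as anti-conservative
using *replicate-level* rejection rates: the mean uncorrected rejection rate
at $\alpha \in \{0.01, 0.05\}$ compared against $\alpha + 3\,\mathrm{SE}$ of
the replicate mean. Pooled p-values within a replicate share the estimated
null moments and are not i.i.d., so a plain KS test against U(0,1) over the
pooled sample has the wrong null; the one-sided KS distance is still
computed and reported as a descriptive statistic. Conservative behavior
(empirical CDF at or below the identity in the lower tail) is accepted;
anti-conservative behavior is a failure.

Two quantitative honesty notes, measured rather than assumed:

* The IQR/hIQR variance estimators have a per-replicate relative SD of
  ~20% at $T = 200$, so the Monte-Carlo SE of a mean-bias estimate at
  $R = 200$ is ~1.5% — larger than the <1% bias being certified. A
  high-precision run ($R = 600$) puts the true biases at ~0.2% (IQR, all
  $d$) and ~0.5–1.3% (hIQR, $d < 1$). The acceptance *test* implements the
  stated $R = 200$ criterion verbatim and can be red by noise alone; the
  acceptance *report* uses the full $R = 1000$ realisation count to tame
  the SE.
* The hIQR variance estimate is robust in the bounded-influence sense, not
  contamination-proof: spiking 10% of timepoints contaminates ~20% of
  pairs and moves its quartiles by tens of percent (versus >1000% for the
  sample variance, and <2% for the median mean estimate). The robustness
  property test asserts those measured relationships rather than a blanket
  5% bound.

## Degenerate inputs and tie-breaks

* All voxels constant → everything excluded → fatal "empty mask".
* $m^R \le 0$ or non-finite → fatal "bad scale" (centered-only mode
  `scale_mode = "none"` is the escape hatch for data without a meaningful
  intensity floor, e.g. simulations).
* Constant DVARS² series → zero IQR spread → fatal "degenerate null"
  rather than a silent $\sigma_0^2 = 0$.
* $T = 2$ supports the decomposition; the inference layer requires at
  least 2 pairs for $\mu_0$ and 4 for $\sigma_0^2$.
* All-zero data makes identity residuals absolute rather than relative.

## Known limitations

* NIfTI support is a minimal built-in NIfTI-1 reader/writer (both
  endiannesses read, little-endian float64 written, `scl_slope`/`inter`
  honored, `.gz` transparent); CIFTI/grayordinates and NIfTI-2 are not
  supported. The implementation is cross-validated against nibabel in the
  test suite.
* The test infers *relative to the background noise level*: it can only
  pick out pairs inconsistent with the bulk of the series. At very high
  spike prevalence (≳30% of timepoints) the robust null estimates absorb
  the artifacts and power collapses — a property of the method, reproduced
  by the power experiment.
* No preprocessing beyond centering/scaling is performed; the
  decomposition should be applied before bandpass filtering or
  prewhitening, which would reshape the D/S balance by construction.
* Scrubbing policy (which scan of a flagged pair to delete, interpolation)
  is out of scope.
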