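---
title: "Methods: linking exhaled and plasma propofol concentrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking exhaled and plasma propofol concentrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breath2plasma)
```

## The problem

During intravenous anaesthesia the clinically relevant quantity is the
plasma drug concentration, but plasma can only be sampled by discrete blood
draws, while online mass spectrometry delivers an exhaled-breath
concentration every 20 seconds. `breath2plasma` implements and tests the
chain that turns that breath signal into a plasma estimate in a rat bolus
study: instrument calibration, compartmental modelling of each matrix,
an empirical breath-to-plasma link, and agreement statistics quantifying
how well breath-based predictions track measured plasma values.

## Models and assumptions

### Compartmental kinetics

Both matrices are described by linear mammillary models. After an
instantaneous bolus of dose $D$ into a central compartment of apparent
volume $V_1$, the two-compartment concentration is

$$C(t) = A e^{-\alpha t} + B e^{-\beta t},$$

with hybrid rates $\alpha > \beta$ the roots of
$\lambda^2 - (K_{10}+K_{12}+K_{21})\lambda + K_{10}K_{21} = 0$ and
amplitudes $A = \tfrac{D}{V_1}\tfrac{\alpha - K_{21}}{\alpha-\beta}$,
$B = \tfrac{D}{V_1}\tfrac{K_{21}-\beta}{\alpha-\beta}$. The identity
$A + B = D/V_1$ (the back-extrapolated $C(0)$) and the inverse map
($K_{21} = (A\beta + B\alpha)/(A+B)$, $K_{10}=\alpha\beta/K_{21}$,
$K_{12} = \alpha+\beta-K_{10}-K_{21}$) are exercised as round-trip
invariants in the tests. One- and three-compartment closed forms follow the
same pattern; the three-compartment hybrid rates are the roots of the
characteristic cubic of the rate matrix, solved in closed trigonometric
form because the optimiser evaluates them thousands of times per fit.

Assumptions worth stating: kinetics are linear (first-order) over the dose
range; the administration, physically a constant-rate infusion of roughly
0.3–1 min, is modelled as a bolus because the first sample is drawn at
1 min, after the infusion has ended, and back-extrapolated parameters are
conventionally reported in bolus form. The zero-order-infusion closed form
is available (`dose_event(amount, duration = tau)`) for sensitivity
checks.

The "breath compartment model" is *descriptive*, not mechanistic: the same
two-compartment form is fitted to breath concentrations as a summary of
their decay, which is how such data are conventionally reported, even
though breath is generated here (and plausibly in vivo) as a nonlinear
transform of plasma. A consequence the pipeline reproduces: with a
power-law link of exponent $1/1.42 < 1$, the apparent breath elimination
rate is systematically smaller than the plasma $K_{10}$.

### Calibration

The instrument response to gas concentration $x$ (ppbv) is a second-order
polynomial $y = c_0 + c_1 x + c_2 x^2$, upward-curved because adsorption
losses saturate with concentration. Inversion uses the positive quadratic
root; signals below the curve's intercept are clamped to 0 ppbv and
flagged below-LOD (physical non-negativity). LOD (0.04 ppbv) and LOQ
(0.12 ppbv) are instrument properties stored on the curve, not derivable
from the standards themselves; a conventional blank-based
$(\bar y_{blank} + k\,s_{blank})$ estimator with $k = 3$ and $10$ is
provided separately (`estimate_lod()`).

A caution the tests encode: with 5 % multiplicative noise on seven
standards spanning 0.04–55.68 ppbv, the *quadratic* coefficient is
recovered to ~8 % (median) but the *linear* coefficient only to ~15 %,
because the high standards are dominated by the $c_2 x^2$ term and only
the low standards identify $c_1$. Recovery claims for calibration
coefficients should therefore be read as distributional statements, not
per-run guarantees.

### Censoring and pairing

Sub-LOD values are handled asymmetrically around the observed peak: before
the peak they are informative zeros (the drug has not yet arrived) and are
retained as 0; from the peak onwards they are non-detects and excluded
from fitting and pairing. "The peak" is the argmax of the raw,
pre-censoring series (earliest index on ties). Excluded rows keep their
row and flag in every CSV written, so censoring is auditable and
reversible. Pre-dose (t = 0) baseline rows never enter fits or pairs.

Pairing anchors on the plasma schedule — the sparse, reference matrix —
and takes the nearest breath bin within half a breath sampling interval
(1/6 min), which guarantees at most one candidate bin per draw on a 20-s
grid; ties break to the earlier bin.

### The log-log link and agreement

The link is ordinary least squares of $\ln C_p$ on $\ln C_e$, with the
unit convention fixed to pptv (breath) and ng/mL (plasma). Prediction
inverts it: $\hat C_p = \exp(b \ln C_e + a)$. Agreement between predicted
and measured plasma uses the two-way, absolute-agreement, single-measure
intraclass correlation computed from ANOVA mean squares,

$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},\quad k = 2,$$

chosen because the scientific question is absolute agreement of values,
not mere consistency, and this is the strictest standard form. Its
p-value and 95 % CI follow the usual F-based construction. Bland-Altman
bias and $\pm 1.96\,SD$ limits are computed on raw concentrations by
default (`log_scale = TRUE` switches to ratios), since the appropriate
scale for method-comparison of strongly right-skewed concentrations is a
judgement call left to the user.

Breath-vs-plasma parameter comparisons are paired t-tests (the same
animal yields both matrices). Comparisons of $V_1$, CL and AUC are
*refused* by design: their units embed the matrix's concentration unit
(mg per ppbv vs mg per µg/mL), so a cross-matrix difference is
meaningless.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `lod`, `loq` | 0.04, 0.12 | ppbv | instrument detection/quantification limits |
| rate bounds | [1e-4, 10] | 1/min | generous physical range for a 120-min study |
| `V1` bounds | [1e-3, 10] | mg/(conc unit) | spans all observed central volumes |
| `pair_tolerance` | 1/6 | min | half the 20-s breath interval |
| `iiv_cv` | 0.25 | — | matches the SD/mean ratios of reported group parameters |
| `noise_cv` | 0.05 | — | typical multiplicative assay noise |
| `body_mass_mean/sd` | 330 / 25 | g | adult male rat, single batch |
| AIC penalty | $2p$, $p = 2k$ | — | least-squares AIC; $k$ compartments fit $V_1$ + $2k-1$ rates |

## Numerical choices

* **Optimisation**: parameters are fitted on the log scale (positivity for
  free, better conditioning), L-BFGS-B within bounds followed by a
  Nelder-Mead polish; starting values come from deterministic curve
  stripping (log-linear terminal fit, then residual peeling), plus one
  scaled second start that is skipped when the first already explains the
  data essentially exactly. Repeated fits are therefore bit-identical.
* **Degeneracy**: micro parameter sets whose hybrid rates coalesce
  (relative separation below 1e-10) are rejected as degenerate rather than
  propagated as near-singular amplitudes.
* **Model selection**: the selection criterion is AIC from SSR,
  $n\ln(SSR/n) + 2p$ — a reproducible default where the original software's
  criterion is unknowable. The reporting convention is nonetheless the
  two-compartment fit (`model_selection = "fixed2"`), with the full AIC
  table logged.
* **Ties**: equal maxima resolve to the earliest time ("time to maximum"
  semantics); equal pairing distances resolve to the earlier breath bin.
* **Weights**: unweighted least squares by default (plain "least squares"
  is the stated method); `1/ŷ²` weighting is available as a flag.
* **CSV numbers** are written with `%.6g`, making read-write cycles
  byte-stable at that documented precision.

## What the synthetic generator does and does not emulate

`generate_cohort()` reproduces the study *design*: three groups × six
rats, 6/12/24 mg/kg dosing by body mass (normal, 330 ± 25 g, truncated
positive), plasma two-compartment kinetics with group-mean parameters set
to the published plasma estimates, lognormal between-animal variability,
the nine-draw plasma schedule and 20-s breath grid, multiplicative
measurement noise, and LOD censoring at 0.04 ppbv.

Breath is derived from plasma by inverting the published power-law link
with independent noise — *not* by a mechanistic lung model. This is
deliberate: it gives the agreement stage an exactly known truth, so a
green end-to-end test certifies that censoring, pairing, regression,
prediction and ICC recover a configured link. It does **not** certify lung
physiology, ventilation effects, tubing adsorption dynamics, or the
absolute breath concentration scale. Indeed, taking the published link at
its stated units (pptv, ng/mL) literally yields breath peaks of roughly
2–6 ppbv, below the reported group means (5.9–25.4 ppbv) — the published
unit convention cannot be fully reconciled from the text, so the package
implements the stated convention, asserts only the dose-ordering of group
means (low < medium < high), and leaves units as explicit parameters
rather than silently rescaling.

Inter-individual variability is lognormal and independent per parameter
(CV 0.25). Real PK parameters are correlated within animals; independence
slightly inflates profile diversity, which is conservative for recovery
tests.

## Runtime scaling in tests

The 20-seed stochastic-recovery check runs the pipeline with
`fit_structures = "two-only"`, fitting only the two-compartment structure
whose parameters are being recovered; the 1- and 3-compartment side fits
exist for the AIC log and do not enter the recovered values. This is a
runtime economy (~5×), not a change to the measured quantity.

## Known limitations

* Individual fits then group summaries ("two-stage" PK) only; no
  mixed-effects pooling, so small-n group means inherit full sampling
  noise.
* Group-mean half-lives are summarised per subject then averaged;
  nonlinear averaging means they need not match half-lives computed from
  group-mean rate constants, and the package does not force consistency.
* The breath model is descriptive (see above); no alveolar/dead-space
  physiology, no breath-phase gating.
* Calibration treats signal intensity as an abstract scalar; no spectral
  processing or peak integration.
* P-values are reported without multiple-testing correction, matching the
  original analysis style.
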