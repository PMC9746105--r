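---
title: "Deriving spirometry reference equations with spirolms"
author: "spirolms authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving spirometry reference equations with spirolms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spirolms)
```

## The problem

Spirometric indices — FEV1, FVC, their ratio, and FEF25–75% — vary with
sex, age and height, with right- or left-skewed, heteroscedastic
distributions.  Whether a patient's measurement is "low" is judged against
a reference population: the conventional threshold is the lower limit of
normal (LLN), the 5th centile of healthy subjects with the same sex, age
and height.  A reference equation therefore has to model an entire
conditional distribution, not just a conditional mean.

`spirolms` implements the standard solution, the lambda–mu–sigma (LMS)
method: at each combination of covariates the measurand $y$ is described by
three quantities — the median $M$, the coefficient of variation $S$, and a
Box–Cox skewness power $L$ — under the Box–Cox Cole–Green (BCCG)
distribution, in which

$$z = \frac{(y/M)^L - 1}{L\,S}$$

is standard normal ($z = \log(y/M)/S$ in the lognormal limit $L = 0$).
Smooth curves for $M$, $S$ and $L$ across age and height turn this into a
full reference model, the same construction used by modern multi-centre
lung-function reference equations.

## Model structure

For each index and sex separately, the median is modelled on the log scale,

$$M = \exp\{a + b\,\ln(\text{height}) + c\,\ln(\text{age}) +
\text{spline}(\text{age})\},$$

with a natural cubic regression spline in age.  $S$ is modelled on the log
scale (which enforces $S > 0$) with an optional $\ln(\text{age})$ term and
age spline, and $L$ on the identity scale, constant by default with an
optional age spline.  For the FEV1/FVC ratio the height term is dropped by
default: across populations, age rather than height drives the ratio; the
default can be overridden per spec.

The LLN and Z-score follow the conventions in which such equations are
published:

$$\mathrm{LLN} = \exp\{\ln M + \ln(1 - 1.645\,L\,S)/L\}, \qquad
\mathrm{SD} = (M - \mathrm{LLN})/1.645, \qquad
Z = (y - M)/\mathrm{SD}.$$

The literal constant 1.645 is used in this "paper" mode because that is
what printed equations use; an "exact" mode replaces it with the
full-precision 95th normal quantile and computes $Z$ through the BCCG
transform.  Every prediction row is labelled with the mode that produced
it.

### The linear Z-score is an approximation

The printed $Z$ is linear in the observed value.  It agrees with the exact
BCCG $z$-transform exactly at $y = M$ (both give 0) and at
$y = \mathrm{LLN}$ (both give $-1.645$), and closely in between: over
spirometry-like parameter ranges ($S \le 0.15$, $L \in [0.6, 1.4]$) the
absolute disagreement stays below 0.25 for $|z| \le 2$ (asserted in the
test suite).  For strongly skewed, high-variability settings (e.g.
$S = 0.2$ with $L = 0.6$, FEF-like) the disagreement can reach about 0.3
at $|z| = 2$, and the linear $Z$ acquires a small mean offset of order
$(1 - L)S^2/(2\,\mathrm{SD}/M)$ under the skewed distribution — up to
about $\pm 0.04$ for the most skewed indices here.  This is a property of
the published formula, not of the fit; the exact mode is free of it.

A related numerical point: the LLN formula is ill-conditioned as
$1 - 1.645\,L\,S \to 0$ (the 5th centile approaches the support boundary).
There the $10^{-4}$-level agreement between the rounded-constant formula
and the exact 5th centile degrades to $\sim 10^{-3}$; the relative
difference is $0.0001464\,S/(1 - 1.645\,L\,S)$.  Fitted spirometry models
have $L\,S \le 0.25$ and never approach this regime.

## Fitting

The BCCG log-likelihood

$$\ell = \sum_i \left[(L_i - 1)\ln y_i - L_i \ln M_i - \ln S_i -
\tfrac{1}{2} z_i^2\right] + \text{const}$$

is maximised over all curve coefficients.  `fit_lms()` cycles block updates
of the $M$, $S$ and $L$ coefficient blocks (BFGS within each block, with a
monotone-acceptance guard so the recorded objective never decreases — an
asserted invariant), stops when the relative log-likelihood change falls
below $10^{-8}$, then polishes all coefficients jointly and takes standard
errors from the observed information.  Starting values come from a
lognormal least-squares fit with $L = 1$.  The fit is deterministic:
refitting identical data reproduces the log-likelihood and coefficients
exactly.

**Splines and degrees of freedom.**  Age curvature is represented by
natural cubic regression splines with knots at age quantiles; `df` is the
basis dimension, so the effective df equals the parameter count exactly and
`df = 0` reduces a curve to its parametric part.  The alternative —
penalised splines with a ridge penalty calibrated to a target effective
df — fits the same family of curves but makes the "effective df" an
approximation and the optimum penalty-dependent; with candidate df of 0–5
on cohorts of a few hundred subjects the unpenalised regression-spline
maximum-likelihood solution is equivalent in practice, exactly
reproducible, and keeps AIC/SBC definitions ($-2\ell + 2\,\text{edf}$,
$-2\ell + \ln(n)\,\text{edf}$) literal.  `select_lms()` fits a candidate
grid (default df 0–5 for the median curve), reports both criteria, selects
by SBC by default (the more conservative of the two when both are reported
without a stated tie-break), and breaks ties toward fewer parameters.

**Diagnostics.**  `diagnose()` computes exact BCCG residual z-scores,
normal Q–Q points and a normality p-value (Shapiro–Wilk up to $n = 5000$,
Kolmogorov–Smirnov beyond).  Residuals of a well-specified model are
standard normal; the package's tests assert mean within $\pm 0.05$, SD
within $[0.95, 1.05]$, and maxima well inside the $\pm 5$ band
conventionally quoted as the acceptable residual range.  Q–Q agreement
with the identity line is asserted over the central region
($|q| \le 2.33$): the extreme order statistics of even a perfectly normal
sample have spread of a few tenths at these sample sizes, so a tight bound
there would reject correct models.

**Degenerate inputs.**  Per index, subjects with missing or non-positive
values are dropped with a logged count; fewer than 50 usable subjects is
an error; prediction outside the fitted age/height hull is flagged as
extrapolation, not refused.  After fitting, the model verifies
$1 - 1.645\,L\,S > 0$ and a truncation mass below $10^{-6}$ over its hull;
violations mark the model invalid for LLN use.

## The synthetic-cohort generator

No individual-level reference data ship with the package, so validation
runs on synthetic cohorts drawn from a fully known BCCG-LMS "truth"
(`default_truth()`), giving every downstream stage a ground truth.  The
generator emulates a healthy reference population aged 4–82:

- **Ages** are uniform over the configured range.  A real convenience
  sample is not uniform, but uniform sampling gives the spline fit equal
  information across ages and makes recovery results easy to interpret;
  the choice is recorded in the configuration so alternative profiles can
  be plugged in.
- **Heights** follow a saturating growth curve reaching the adult means of
  the emulated population (172 cm men, 158 cm women) by age 18, plus
  Gaussian noise with SD growing from 5 cm in young children to 7 cm in
  adults (the emulated population's adult height SD of 8 cm still
  contains some age structure, so the residual SD is set slightly below
  it).
- **Weights** come from an age-dependent BMI model with lognormal noise;
  they are carried for I/O fidelity but used by no model, matching
  equations that use age and height only.
- **Spirometry values** are drawn independently per index from the truth's
  BCCG distribution at each subject's covariates.  Adult medians are
  calibrated to the emulated population's means (male FEV1 ~3.8 L at age
  38/172 cm against a population mean of 3.65 L, female ~2.6 L at 45/156
  cm against 2.63 L, FVC 4.6/3.2 L, ratio 0.82/0.83); FEF25–75% targets
  are set to physiologically typical adult values (male ~4.2, female
  ~3.4 L/s).  $S$ is constant per index (0.13 for volumes, 0.08 for the
  ratio, 0.20 for FEF25–75%) and $L$ constant (0.9 volumes, 2.0 ratio,
  0.6 FEF), giving mild right skew for volumes and the ratio's
  characteristic left skew.
- **Reproducibility**: a single integer seed drives all randomness; the
  caller's RNG state is restored afterwards.  Identical configuration and
  seed reproduce the cohort byte-for-byte through the CLI.

Because indices are drawn independently, the physiological coupling
FEV1 ≤ FVC is not guaranteed; `enforce_fev1_le_fvc = TRUE` redraws
violating subjects and is off by default (the violation rate is small and
independence matches how the models are fitted — one index at a time).

What passing tests on these cohorts do **not** show: robustness to
measurement error and quality-control failures, non-uniform age
distributions, secular height trends, between-site heterogeneity, or
diseased/smoking subjects — all excluded upstream in real reference
studies and deliberately not simulated.

## The comparison battery

`z_summary()` reproduces the age-group Z-score analysis: per group and sex
it reports n, mean, SD, an exact t-based 95% CI (normal approximation by
flag), a two-sided one-sample t-test against zero, and the
clinical-significance flag |mean Z| > 0.5 — the conventional agreement
threshold for adopting external reference equations.  Degenerate groups
follow documented conventions: empty groups are emitted with n = 0;
zero-variance groups get p = 1 at the null and p = 0 off it.  No
multiple-testing correction is applied across groups (matching practice in
this literature); the output records that.  The default grouping
`<10, 10–21, 22–29, …, >70` is implemented as contiguous half-open bins
`[0,10), [10,22), [22,30), …, [70,∞)` — the printed labels are gappy and
this interpretation is a documented choice.

`below_lln_table()` tabulates observed-below-LLN counts per group and sex
with `n (pct)` cells; on a cohort scored against its own generating model
the overall rate is ~5% by construction, with small-group percentages
dominated by sampling noise.

`bland_altman()` summarises agreement between two models' predictions via
the mean difference, SD of differences and 1.96-SD limits of agreement.
Differences are oriented (external − newly fitted), so an external model
that predicts lower values yields a negative mean difference.

## Problem sizes and seeds in the shipped checks

The package's validation suite uses cohorts of a few hundred to a few
thousand subjects: study-scale refit checks use 418 females + 204 males
(the unequal sex sizes are emulated by drawing two seeded cohorts and
keeping one sex from each, since the generator configuration is symmetric
per sex); parameter-recovery and residual-bound checks use 20 replicate
cohorts of 600; distributional checks use $10^5$ Monte-Carlo draws.  At
these sizes the median relative RMSE of the recovered median curve is
about 2.4% on an age grid, and fitted 5th-centile coverage on fresh draws
centres on 5%.  All stochastic assertions fix their seeds.

## Known limitations

- The generator's truth has constant $S$ and $L$ per index; age-varying
  dispersion and skewness are supported by the fitter (`df_s`, `df_l`) but
  not exercised by the default truth.
- The linear "paper" Z-score inherits the biases described above; use
  `z_mode = "exact"` when the approximation matters.
- Model selection searches a df grid per curve rather than a continuous
  smoothness parameter; with very large cohorts a penalised fit with
  fractional edf could select smoother curves than the integer grid
  allows.
- External reference models are supported only through the package's YAML
  coefficient format; no third-party coefficient values are bundled.
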