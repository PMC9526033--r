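---
title: "Methods: length-based assessment and overwintering habitat suitability"
author: "stockhab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: length-based assessment and overwintering habitat suitability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stockhab)
```

`stockhab` implements two estimation engines for data-limited, seasonally
migrating fish stocks — a length-based stock assessment and a
habitat-suitability-index (HSI) model for overwintering grounds — together
with seeded simulators that generate both kinds of input data with known
ground truth. This vignette is the package's account of the underlying
models, the tunable parameters, the numerical choices made where the
design was genuinely open, and what the simulation-based tests do and do
not demonstrate about real data.

## 1. The growth model

Somatic growth follows the seasonally oscillating von Bertalanffy growth
function (soVBGF),

$$L(t) = L_\infty\!\left(1 - e^{-\left[K(t - t_0) + S(t) - S(t_0)\right]}\right),
\qquad S(t) = \frac{CK}{2\pi}\,\sin 2\pi(t - t_s),$$

with asymptotic length $L_\infty$ (mm), growth coefficient $K$ (1/yr),
age at zero length $t_0$ (yr), oscillation amplitude $C \in [0,1]$
($C=1$ means growth stalls once a year) and summer point $t_s$ (the year
fraction of fastest growth). With $C = 0$ this is the ordinary VBGF.
Length is non-decreasing in age for any $C \le 1$; the constructor
rejects $C > 1$. When cohorts are traced through calendar time the
oscillation is evaluated at absolute calendar dates so that fish born at
different times of year experience the seasons in phase
(`vbgf_length(params, age, birth = )`).

Length-converted analyses need the inverse age-at-length
$t(L) = t_0 - \ln(1 - L/L_\infty)/K$. The seasonal form has no
closed-form inverse, so the non-seasonal inverse is used even for
seasonal fits — the standard practice in length-converted catch curves,
and a documented approximation of this package.

## 2. ELEFAN: scoring and search

Electronic length frequency analysis fits the soVBGF to date-stamped
binned length counts in two stages.

**Restructuring** (`restructure()`) turns each sample's counts into
signed peak scores. Per column: (i) a centred moving average (MA) over
`ma_window` bins (edge windows shrink to the available neighbours);
(ii) raw score $= n_i/\mathrm{MA}_i - 1$ (zero where the MA is zero);
(iii) positive scores are divided by their column mean so that the
average peak value is 1 and the transform is invariant to rescaling the
column; (iv) the $j$-th consecutive zero-count bin in a run has
$0.01\,j$ subtracted, so long empty troughs count increasingly against
a curve crossing them; (v) each positive score is halved once per
adjacent zero-count bin, de-emphasizing isolated spikes. The constants
in (iv) and (v) follow the classical ELEFAN-I sequence; the test suite
pins the whole transform against an independent step-by-step
transcription.

**Scoring** (`score_rn()`) traces annual cohorts — birthdays at
`year + t_anchor` — through the samples. At each sample date each
cohort's predicted length selects a bin; its restructured value
accumulates into the explained sum of peaks (ESP). A *peak* (maximal
run of positive bins in one column) is creditable **once**, by the
first trajectory crossing it; negative values count on every crossing.
With ASP the sum of all positive scores, the goodness score is
$R_n = 10^{ESP/ASP}/10 \in (0, 1]$. Crediting a peak once globally
(rather than once per cohort) is what guarantees $ESP \le ASP$ and
hence $R_n \le 1$; it is also the classical convention.

**Search.** Four workflows maximize $R_n$: a K-scan at fixed
$L_\infty$; response surface analysis (RSA) over an
$L_\infty \times K$ grid (ties go to the smaller parameter values, for
reproducibility); simulated annealing (SA); and a generational genetic
algorithm (GA) with tournament selection, blend crossover, Gaussian
mutation and one elite. In all four, the cohort anchor `t_anchor` is a
nuisance alignment parameter and is profiled out on a 1/24-year grid
inside the objective: each candidate $(L_\infty, K, C, t_s)$ is scored
at its best anchor. Treating the anchor as a fifth free dimension makes
the stochastic searches wander a surface that is virtually flat except
on thin ridges; profiling gives every workflow the same, much
better-behaved objective.

SA defaults: 200 temperature stages of 50 proposals, geometric cooling
0.95 from an initial temperature of 0.2, Gaussian proposal steps of 8%
of each bound range. The step size matters: with very small steps
(a few percent) the annealer reliably stalls on local plateaus of the
multimodal $R_n$ surface within any reasonable budget. GA defaults:
population 50, 100 generations, mutation sd 2% of range. All knobs sit
in `sa_control()`/`ga_control()`; both workflows require a seed and are
bit-reproducible given one. `elefan_sweep()` runs the full factorial of
bin widths (10, 20 mm), MA windows (5, 7, 9, 11) and the four
workflows — 32 scenario fits — and ranks them by $R_n$.

## 3. Mortality, selectivity, and length–weight

`catch_curve()` pools the samples, converts bins to relative age with
the inverse VBGF, and regresses $\ln(N_i/\Delta t_i)$ on the mid-bin
relative age over the descending limb; $Z$ is the negative slope, with
its OLS standard error. $\Delta t_i$ is the time a cohort needs to grow
through bin $i$. The descending limb is auto-selected as the first bin
strictly after the peak through the last bin with at least `min_count`
(default 5) fish; bins reaching $L_\infty$ are excluded. Fewer than
three usable points is an error, not a fit.

Natural mortality is deliberately *not* estimated implicitly: the
choice of empirical estimator changes downstream conclusions, so
`natural_mortality()` exposes Pauly's temperature formula and the
growth-based Then et al. estimator, and accepts a user/literature value
— the recommended route when an assessment's $M$ was fixed externally.
`exploitation()` then applies the identities $F = Z - M$ and $E = F/Z$
exactly, rounding only at print time.

`catch_ogive()` back-extrapolates the catch-curve line over the
ascending limb; observed/expected ratios (clipped to $[0,1]$) estimate
capture probability per bin, and an OLS fit on the logit scale gives
$t_{50}$ and $t_{95}$. Probabilities within `p_tol` (default 0.005) of
0 or 1 are excluded: near-saturated bins carry no information about the
ogive and amplify extrapolation error on the logit scale.
`fit_length_weight()` fits $w = aL^b$ by OLS on logs.

## 4. The habitat-suitability-index model

The response is standardized abundance: per-cell annual winter catch
divided by the dataset maximum (`standardize_abundance()`), giving an
observed suitability $\in [0,1]$. Standardization uses the global
maximum of the dataset at hand (training, testing, or pooled), not
per-year maxima; per-year standardization would erase between-year
abundance signal.

Per-variable suitability curves (`fit_si()`) come in two forms.

* **Fitting-based (envelope)**: the variable is split into 10
  equal-width bins; the maximum observed suitability per bin — paired
  with the variable value attaining it, not the bin midpoint —
  forms the suitability envelope, following the empirical-SI idea that
  somewhere in each bin the *other* variables are near-optimal. The
  curve $y = A e^{-(x-\mu)^2/2\sigma^2} + D$ is fitted by
  Levenberg–Marquardt least squares and normalized to peak at 1. The
  baseline $D \ge 0$ acknowledges that suitability need not decay to
  zero within the observed domain; without it the envelope of any
  multi-variable habitat (whose minimum is set by the other variables'
  contribution) cannot be represented and the fit is systematically
  biased. A Gaussian was chosen as the smooth unimodal family
  consistent with reported closed optimal ranges; the form is pluggable.
* **Regression-based**: an OLS polynomial (default cubic) of suitability
  on the variable, clipped to $[0,1]$, normalized to peak at 1 over the
  observed domain, with the regression F-test p-value recorded.

The *optimal range* of a curve is $\{x: SI(x) \ge 0.8\}$; the 0.8 cut
is a convention exposed as `threshold`.

`combine_hsi()` aggregates per-variable suitabilities by arithmetic
(AM) or geometric (GM) mean; GM $\le$ AM always, and GM is zero
whenever any component is.

**Selection** (`hsi_select()`) enumerates all non-empty subsets of
{depth, SST, SSS} × two SI forms × two combiners — 28 candidates. SI
curves are fitted on the training winters; HSI is predicted for the
held-out testing winters; each candidate is scored by the linear
regression of observed on predicted suitability, via $R^2$ and
$AICc = n\ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)$ with $k = 3$ (intercept,
slope, residual variance). Maximum $R^2$ wins; ties within $10^{-9}$
go to minimum AICc. The winner's curves are refitted on the pooled
training + testing winters.

**Aggregation.** A winter belongs to its December year (winter 1971 =
Dec 1971–Feb 1972); `winter_mean()` errors if a month is missing,
naming it. Habitat classes use closed upper boundaries: HSI $\ge 0.7$
optimal, $\ge 0.3$ average, else poor (strict inequalities would leave
the boundaries undefined; the rule is configurable). Class areas weight
each 0.5° cell by $\cos(\text{latitude})$, since equal-angle cells
shrink poleward; percentages sum to 100 exactly. Decadal differences
are tested with a fixed-effects one-way ANOVA (`stats::aov`) followed
by Scheffé's simultaneous pairwise contrasts,
$F_s = (\bar y_i - \bar y_j)^2 / [MSE(1/n_i + 1/n_j)]$ against
$(g-1)F_{g-1,N-g}$ — always at least as conservative as unadjusted
pairwise tests. The long-term winter SST trend is the OLS slope of the
area-mean winter SST on year.

## 5. What the simulators emulate

`simulate_length_frequencies()` draws, per survey date, cohort ages
from the equilibrium exponential age distribution at rate $Z$
(truncated where survival drops below $10^{-4}$), maps age to mean
length through the soVBGF in calendar phase with each cohort's
birthday, adds Gaussian individual variation (`cv_length`), and retains
fish by logistic gear selectivity, resampling until exactly
`n_per_sample` are kept. Defaults mirror a collapsed, heavily exploited
croaker stock: $L_\infty = 434$ mm, $K = 0.43$/yr, $Z = 1.87$/yr, a
six-date seasonal bottom-trawl survey, 6% individual length CV.

`simulate_environment_and_catch()` builds a 0.5° grid over the
mid-southern East China Sea overwintering ground (120–126°E, 25–29°N;
96 cells): a shelf deepening offshore (22–110 m plus bathymetric
roughness), monthly SST with a meridional gradient, a fixed monthly
anomaly table, a linear long-term trend (default −0.028 °C/yr) and
fixed per-cell offsets, and a weak SSS field. Expected annual winter
catch per cell is proportional to a known true HSI — the arithmetic
mean of Gaussian suitability curves in depth (mode 54 m) and winter SST
(mode 19.35 °C), widths set so suitability is 0.8 at the conventional
optimal-range endpoints (36–72 m, 18.2–20.5 °C) — times mean-one
lognormal noise (`catch_noise_cv`, default 0.3). The true per-cell HSI
is stored for recovery tests. Because the per-cell spatial structure is
held fixed across years, the SST trend is exactly estimable from winter
means; and because the noise-free fields attain both suitability modes
exactly at grid points, the noise-free selection experiment recovers
the generating model with test $R^2 = 1$ to machine precision.

The simulators deliberately omit: fish movement and spatial population
structure, effort-driven catchability, environmental autocorrelation in
time, and any coupling between the population and habitat worlds.
Passing recovery tests therefore demonstrates estimator correctness —
not that real survey or logbook data meet these assumptions.

## 6. Design of the recovery experiments

Two experiment-design choices deserve explanation.

*Growth recovery.* The SA/GA recovery tests simulate a quarterly,
two-year survey of 500 fish per date from a population with $Z =
0.5$/yr and 2% individual length CV, full selection. Two alternatives
fail for reasons unrelated to estimator correctness. With literally
zero individual variation every cohort occupies a single 10-mm bin, so
the $R_n$ surface collapses to measure-zero spikes (±2 mm in
$L_\infty$) that grid search can hit but no stochastic optimizer can
find. And under the heavy mortality of a collapsed stock
($Z \approx 1.9$) a two-year window contains essentially no fish older
than 2.5 years, leaving $L_\infty$ on a flat $L_\infty$–$K$ ridge —
curves with $L_\infty$ differing by 20% are observationally equivalent
over the sampled ages. A moderately exploited population keeps all age
classes in the samples and makes the asymptote identifiable; the 2% CV
(well below the bin width) spreads cohorts over adjacent bins without
blurring modes.

*Habitat selection.* The selection experiment requires that the
candidate set be discriminable in principle: SSS must not be an exact
affine proxy of depth (hence its independent weak gradient and cell
noise), and the fields must span enough suitability contrast that AM
and GM models differ materially. With the default noise (catch CV 0.3)
the generating combiner and variable set are re-identified in well
over 90% of replicates; the SI *form* (envelope vs polynomial) is
genuinely harder to distinguish under noise and is not part of that
claim.

## 7. Numerical choices and degenerate inputs

* Bin membership is half-open $[\ell, \ell + \Delta)$; a length exactly
  on an edge belongs to the upper bin.
* Survey dates convert to decimal years as
  $(\text{day of year} - 0.5)/365.25$.
* Grid-search ties break toward smaller parameter values; stochastic
  workflows are seeded and never touch the global RNG state.
* All-zero length-frequency columns restructure to zeros (not an
  error); a restructured matrix with no positive scores has undefined
  $R_n$ and errors.
* Catch-curve bins crossing $L_\infty$ are excluded with a warning;
  empty bins cannot enter the regression.
* The envelope SI fit requires at least 5 distinct variable values and
  at least 4 non-empty envelope bins; constant responses are rejected
  as degenerate rather than fitted.
* A constant SST series yields slope 0 with an explicit `constant`
  flag instead of an undefined $R^2$.
* Problem sizes in the test suite are scaled for a single CPU: reduced
  SA/GA budgets (thousands, not tens of thousands, of objective
  evaluations), 50 selection replicates, and grids of a few hundred
  cells; these sizes are stated in the tests themselves.

## 8. Known limitations

* The inverse-VBGF age conversion ignores the seasonal oscillation.
* $R_n$ is a relative score: values are comparable across candidate
  parameter sets on the same restructured data, not across datasets,
  bin widths, or MA windows.
* The envelope SI method is sensitive to extreme-value noise in the
  response (the binned maximum of a heavy-tailed observation grows with
  sample size); with noisy catches the polynomial form often validates
  better, which the selection step handles by design.
* AICc uses the Gaussian-likelihood form with $k = 3$ regardless of
  how many SI parameters were estimated upstream; it compares the
  *validation regressions*, not the full model complexities.
* Scheffé contrasts assume the usual ANOVA homoscedasticity; yearly
  area percentages from a common model are correlated across years,
  which the decadal ANOVA (like the convention it follows) ignores.
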