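---
title: "Methods: partial ageing, multi-model growth and maturity ogives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partial ageing, multi-model growth and maturity ogives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sharpnose)
```

This vignette documents the statistical content of the package: what each
stage computes, the assumptions behind it, the defaults and why they were
chosen, and the numerical decisions that a maintainer would otherwise have
to reverse-engineer from the code.

## The setting

The package implements the standard life-history workflow for a small,
fast-growing, seasonally reproducing coastal shark sampled as fishery
bycatch. One vertebral centrum per animal is read for band pairs (one
opaque plus one translucent increment, assumed deposited annually after the
birthmark), two readers count independently, and each animal carries a
total length (cm TL), sex, capture date and a macroscopic maturity stage.
From these the pipeline estimates growth curves, compares candidate growth
models, tests for sex differences, and estimates length- and
age-at-maturity.

## Partial ages

With a single annual birth pulse, an integer band-pair count can be refined
to a decimal age: the count plus the fraction of a year elapsed between the
most recent birth anniversary and capture.

`assign_partial_age()` counts calendar days from the most recent
`birth_month_day` (default 15 January, the observed pupping pulse) on or
before capture and divides by a fixed `days_per_year = 365`, in leap years
too. A fixed denominator keeps the fraction convention transparent; the
elapsed span is capped just below one year so that the result always lies
in `[count, count + 1)`. An animal with one band pair caught on 30 August
gets `1 + 227/365 = 1.62` years.

Final counts come from a consensus process. `consensus_ages()` accepts
agreement automatically but resolves disagreements **only** from an
explicit user-supplied resolution table: the consensus read is a human
judgement made at the microscope, and any automatic rule (mean, maximum,
reader 2 wins, ...) would fabricate data. Unresolved disagreements are
flagged excluded and counted, never silently dropped.

## Reader precision and bias

Four standard statistics summarise between-reader agreement
(`precision_report()`):

* **APE** (Beamish–Fournier): per fish, the mean absolute deviation of the
  reads from their mean, scaled by the mean; averaged across fish.
* **Chang's CV**: per fish, the sample standard deviation (denominator
  `R - 1`) over the mean; averaged across fish.
* **PA ± t**: the share of fish whose two reads differ by at most `t`
  years (default 1).
* **Bowker's test of symmetry** for systematic bias, computed over
  unordered off-diagonal pairs of the reader-1 × reader-2 crosstab:
  `X² = Σ (n_ij − n_ji)² / (n_ij + n_ji)`.

Fish whose mean read is zero (both readers saw no completed band pair)
cannot contribute to APE or CV — the denominator is their mean — so they
are excluded from those two averages but still count for PA, which is well
defined at zero. Bowker's degrees of freedom count only pairs with
`n_ij + n_ji > 0`; empty pairs carry no information about asymmetry and
inflating the df with them would make the chi-square reference too heavy.
With no non-empty pair the statistic is 0 and the p-value is reported as
`NA` rather than 1. For very short-lived species these indices run high
relative to long-lived ones: a one-band disagreement on a two-year-old fish
is a 50% error, so absolute levels should be compared only across studies
of similar longevity.

## Growth functions

Three families, all parameterized by length-at-birth `L0`, asymptotic
length `L∞` and a per-year growth-completion coefficient, so each satisfies
`L(0) = L0` and `L(∞) = L∞`:

| family | `L(t)` |
|---|---|
| von Bertalanffy | `L0 + (L∞ − L0)(1 − e^{−kt})` |
| logistic | `L∞ L0 e^{gt} / (L∞ + L0 (e^{gt} − 1))` |
| Gompertz | `L∞ exp( ln(L0/L∞) · e^{−gt} )` |

These are the standard `L0`-anchored forms of the multi-model growth
literature; anchoring at `L0` rather than the conventional `t0` is the
natural choice for sharks, where length at birth is observable (embryos,
umbilical scars) and age-zero animals are real.

## Fitting strategies

Samples from fisheries often miss small young-of-year animals, which lets
the fitted curve drift to biologically impossible lengths-at-birth. Three
strategies are provided (`model_spec()`):

1. **`three_param`** — estimate all of `L0`, `L∞`, coefficient.
2. **`two_param_fixed_L0`** — hold `L0` at a known value and estimate the
   other two. The default fixed value is 26 cm, the midpoint of a 22–30 cm
   plausible length-at-birth range (`choose_fixed_L0(22, 30)`); the
   midpoint rule is a transparent way to combine an embryo-based lower
   bound with published upper bounds.
3. **`three_param_augmented`** — append `n_hypothetical = 4` hypothetical
   age-zero animals at the fixed `L0` value and fit the three-parameter
   model; the pseudo-animals act as a soft anchor instead of a hard
   constraint.

None of these is a free lunch: fixing `L0` biases the coefficient upward
when the true birth length differs, and four pseudo-observations barely
move a 186-fish likelihood. The comparison tables make the trade explicit
rather than hiding it.

### Numerical details

`fit_growth()` minimises the residual sum of squares with
Levenberg–Marquardt (`minpack.lm::nlsLM`) from a **multi-start grid**:
`L∞ ∈ {1, 1.1, 1.3} × max(length)`, coefficient `∈ {0.3, 1, 3}` per year,
and for three-parameter fits `L0 ∈ {0.8, 1} × min(length)`. The grid
brackets every estimate a short-lived coastal shark can plausibly produce
(coefficients above 3/yr included). Among converged starts the lowest RSS
wins; exact ties go to the fewest iterations, which makes refits
deterministic. Parameters are box-bounded away from zero and far above the
data; an estimate landing on a bound raises a warning flag on the fit.
Standard errors come from the curvature of the least-squares objective at
the optimum. Data that sit exactly on a curve (zero RSS) get `AIC = −∞`,
i.e. a perfect fit dominates every ranking, instead of a log-of-zero error.

Bootstrap uncertainty (`bootstrap_ci()`) is **case resampling**: records
are resampled with replacement, hypothetical age-zero animals are
re-appended (they are design, not data), and each replicate refits starting
from the point estimate. Percentile intervals are reported; replicates that
fail to converge are dropped and counted, with a warning above 20% failures
and an error above 50%. Case resampling is robust to the heteroscedastic
lengths typical of length-at-age data, where residual spread grows with
age. The default is `B = 1000`; all examples in the tests use `B = 200`,
which is ample for 95% percentile endpoints of a two-parameter fit.

## Model selection

Model support is ranked by the small-sample AIC computed from the
least-squares fit:

`AIC = n ln(RSS/n) + 2k`, with `k` = estimated curve parameters + 1 for
the error variance, and `AICc = AIC + 2k(k+1)/(n − k − 1)`.

The `RSS/n` (maximum-likelihood) variance is used rather than
`RSS/(n − p)`: the AIC formula above is the concentrated Gaussian
log-likelihood, and mixing in the unbiased variance estimator would break
the correspondence. Deltas are `AICc_i − min AICc`; Akaike weights are
`w_i = e^{−Δ_i/2} / Σ_j e^{−Δ_j/2}`. Deltas of 0–2 indicate the strongest
support, 2–10 less, above 10 the least.

**Kimura's likelihood-ratio test** (`kimura_lrt()`) compares a common
growth curve against separate per-group curves:
`X² = N ln(RSS_common / RSS_separate)` with
`df = (groups − 1) × p` estimated parameters, distributed chi-square under
the null. The statistic is algebraically `−2×` the difference of the
concentrated Gaussian log-likelihoods under a shared error variance (a
property the test suite checks). In the pipeline the test is run, by
default, on the AICc-best family of the combined-sex *three-parameter*
table, giving the familiar `df = 3` two-sex comparison; the strategy is an
argument.

## Maturity ogives

Macroscopic stages are collapsed to binary states (`binarize_stage()`):
females staged 1 (immature) and 2 (maturing) → 0, stages 3–5 (mature,
pregnant, post-partum) → 1; males NC/PC (claspers not/partially calcified)
→ 0, FC → 1.

The ogive is the `ln(19)` logistic
`P(x) = Pmax (1 + e^{−ln(19)(x − x50)/(x95 − x50)})^{-1}`, which passes
through `Pmax/2` at `x50` and `0.95·Pmax` at `x95` by construction. With
`Pmax = 1` this is exactly a binomial GLM with logit link, which is how
`fit_ogive()` estimates it: `x50 = −β0/β1`, `x95 = (ln 19 − β0)/β1`, with
delta-method standard errors and optional case-resampling bootstrap
intervals (both are reported because the two uncertainty routes need not
agree at small `n`). `Pmax` is fixed at 1 by default — estimating an
asymptote below 1 from a modest sample is fragile and rarely identified —
but `estimate_pmax = TRUE` switches to direct maximum likelihood over
`(β0, β1, Pmax)` when a study population genuinely never fully matures.
Age-at-maturity is estimated by refitting the same model on partial ages,
not by inverting the growth curve at `L50`: inversion would entangle the
maturity estimate with growth-model error. The length- and age-scale fits
share one code path; the scale is a label.

Degenerate inputs are refused loudly: one maturity class only, fewer than
10 observations, or a non-rising fitted slope are errors; complete
separation is flagged on the result.

## The synthetic population generator

No specimen data ship with the package, so `simulate_population()`
generates tables with the statistical structure the analysis assumes,
which is what every simulation-based check runs on:

* capture dates uniform over a June 2014 – August 2015 window;
* integer age classes 0–4 with geometrically declining frequency (ratio
  `age_decay = 0.45` per class), matching the qualitative shape of a
  bycatch sample dominated by age 0–1 animals — no age-structure model is
  imposed beyond that;
* true age = class + the day fraction implied by the capture date and the
  mid-January birth pulse, so simulated partial ages are internally
  consistent with the ageing convention;
* length = the sex's growth curve at the true age plus Gaussian noise,
  floored at 1 cm and recorded to 0.1 cm (field measurement precision);
* two readers displace the true class by −1/0/+1 independently
  (default probabilities 0.1/0.8/0.1); the consensus count equals the true
  class;
* maturity is a Bernoulli draw from the sex's length ogive, back-mapped
  uniformly to a stage code consistent with the binary state.

Default parameters are the fixed-`L0` von Bertalanffy estimates and
maturity ogives for the population the package was written around: females
`L∞ = 57.78` cm, `k = 1.17`/yr, residual SD 5.40 cm, `L50 = 47.0`,
`L95 = 53.5` cm (n = 131); males `L∞ = 46.11` cm, `k = 3.69`/yr, residual
SD 4.44 cm, `L50 = 41.7`, `L95 = 47.2` cm (n = 55); `L0 = 26` cm for both.

What the generator does **not** emulate: gear selectivity (lengths enter
only through the growth curve, not through a capture-probability model),
spatial or temporal structure in sampling, individual growth heterogeneity
(one curve per sex plus i.i.d. noise), count-dependent reader error beyond
±1, or embryonic diapause timing. Passing simulation-recovery tests
therefore demonstrates that the estimators are correct and well calibrated
*under the stated model*, not that the model captures every feature of a
real bycatch sample — in particular, real three-parameter fits can behave
far worse than simulated ones when selectivity truncates the small animals.

## Validation design and problem sizes

The test suite checks every deterministic worked example exactly, verifies
the precision statistics against brute-force oracles on random tables, and
runs three simulation studies sized for routine re-running: 200 replicate
female datasets (n = 131, residual SD 5.4 cm) for parameter recovery and
95% bootstrap coverage (B = 200 per replicate); 200 replicates each under
identical and sex-specific truths for the likelihood-ratio test's size and
power; and an 1800-observation binomial design (lengths 31–66 cm, 50 draws
per cm) for ogive recovery. Published model-comparison triples are
reproduced to two decimals in the weights; recomputed deltas are allowed
±0.011 because the published deltas were formed before the AICc columns
were rounded.

## Known limitations

* The growth functions are monotone by construction; in floating point the
  sigmoid families saturate at `L∞` once `g·t` exceeds ~30, where
  increments underflow.
* Curvature-based standard errors and bootstrap spreads agree only up to
  ~30% at these sample sizes; neither is privileged, and both are exposed.
* The LRT is asymptotic; its size holds at the default sample sizes
  (checked by simulation) but has not been characterised for much smaller
  groups.
* Fixing `L0` at a single value ignores individual variation in birth
  size; the resulting coefficient should be read as conditional on that
  choice.

## A worked run

```{r example, eval = FALSE}
pop <- simulate_population(sim_config(), seed = 1)
ana <- run_full_analysis(pop, seed = 2)
print(ana)
plot(attr(ana$tables$two_param_fixed_L0$female, "fits")[[1]])
plot(ana$ogives$female$length)
```
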