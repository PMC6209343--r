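# sharpnose

Age, growth and maturity analysis for small, fast-growing coastal sharks —
the complete life-history workflow used when a bycatch sample of vertebrae,
lengths and maturity stages has to be turned into growth parameters and
maturity ogives for fisheries assessment.

The package is aimed at fisheries biologists and stock-assessment
scientists working with vertebral band-pair ages. It covers:

* **Partial ageing** — band-pair counts plus the day fraction elapsed
  since a single annual birth pulse (default 15 January, fixed 365-day
  year), giving decimal ages in `[count, count + 1)`.
* **Reader precision and bias** — average percent error (APE), Chang's
  CV, percent agreement (PA ± 1 yr), and Bowker's test of symmetry
  `X² = Σ_{i<j} (n_ij − n_ji)² / (n_ij + n_ji)` on the two-reader
  crosstab, with df counting only non-empty pairs.
* **Multi-model growth** — von Bertalanffy
  `L(t) = L₀ + (L∞ − L₀)(1 − e^{−kt})`, logistic and Gompertz functions,
  each anchored at length-at-birth `L₀`, fitted by multi-start nonlinear
  least squares under three strategies: free three-parameter, fixed-`L₀`
  two-parameter, and three-parameter with hypothetical age-zero animals
  appended.
* **Model selection** — `AIC = n ln(RSS/n) + 2k`,
  `AICc = AIC + 2k(k+1)/(n−k−1)`, deltas, Akaike weights
  `w_i = e^{−Δ_i/2}/Σ_j e^{−Δ_j/2}` and support classes; Kimura's
  likelihood-ratio test `X² = N ln(RSS_common/RSS_separate)` for sex
  differences.
* **Maturity** — binary states from macroscopic stages, and `ln(19)`
  logistic ogives `P(x) = Pmax(1 + e^{−ln19·(x−x50)/(x95−x50)})⁻¹` fitted
  as binomial GLMs on the length and age scales (L50/L95, A50/A95), with
  delta-method SEs and bootstrap intervals.
* **A synthetic population generator** so the whole pipeline can be
  validated by simulation when the underlying specimen data cannot be
  distributed.

See the methods vignette (`vignettes/growth-maturity-methods.Rmd`) for the
full statistical account.

## Worked example

```r
library(sharpnose)

pop <- simulate_population(sim_config(), seed = 1)  # 131 F + 55 M specimens
ana <- run_full_analysis(pop, seed = 2)
print(ana)
```

```
Age-growth-maturity analysis: 186 specimens (186 used, 0 excluded)

Between-reader ageing precision (n = 186 doubly-read fish)
  APE:         38.1 %
  Chang's CV:  53.8 %
  PA +/- 1:   100.0 %
  Bowker's symmetry: X^2 = 4.17, df = 5, p = 0.525

Two-parameter (fixed L0) comparison, sexes combined:
  group    model                n   aicc   delta weight support_class
1 combined von Bertalanffy (2p) 186 663.67 0.00  0.82   strong
2 combined Gompertz (2p)        186 666.95 3.28  0.16   less
3 combined Logistic (2p)        186 670.82 7.15  0.02   less
  Linf       coeff     rse
1 54.40±1.09 1.40±0.14 5.89
2 53.62±0.96 1.84±0.15 5.94
3 53.00±0.89 2.34±0.17 6.00

Likelihood-ratio test for common vs separate von Bertalanffy curves
  groups: female, male
  X^2 = 52.33, df = 3, p = 2.54e-11

Maturity ogive (length scale, n = 131)
  L50 = 47.22 cm (SE 0.64), L95 = 52.21 cm (SE 1.35)
Maturity ogive (length scale, n = 55)
  L50 = 41.78 cm (SE 0.78), L95 = 46.68 cm (SE 1.40)
```

Reading this: the readers' counts disagree often in relative terms (APE
38%, CV 54% — expected for a species only a few years old, where a
one-band disagreement is a large fraction of the age) but show no
systematic bias (Bowker p = 0.53). Among the fixed-`L₀` models the von
Bertalanffy function carries 82% of the Akaike weight and its Δ = 0 row is
the supported model; the likelihood-ratio test rejects a common curve for
the sexes (X² = 52.3, df = 3), so growth is reported per sex. Females
mature at about 47 cm and males at about 42 cm total length. Because the
input here is simulated, the estimates recover the generator's parameters
(female L∞ 57.8 cm, k 1.17/yr; male L∞ 46.1 cm, k 3.69/yr; the combined
fit lies between the sexes).

Individual stages are available directly: `assign_partial_age()`,
`precision_report()`, `fit_growth()`, `comparison_report()`,
`kimura_lrt()`, `fit_ogive()`, `bootstrap_ci()`.

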