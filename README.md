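# hiexpr

Case–control qRT-PCR analysis with high-expressor subgroup detection.

## What this is for

Postmortem cortical expression studies often find that a transcript is not
uniformly shifted in cases; instead a *subgroup* of subjects — more of them
cases than controls — express it far above a shared "normal core"
distribution. hiexpr is for analysts of such case–control qRT-PCR cohorts.
It covers the full chain:

* **Quantification.** Raw cycle-threshold (Ct) triplicates →
  ΔCt = Ct<sub>target</sub> − geomean(Ct of ≥3 housekeepers) →
  ΔΔCt anchored on the control group → relative quantity
  rq = 2<sup>−ΔΔCt</sup>, with replicate cleaning (±0.5 Ct from the
  triplicate median) and an iterative two-sided Grubbs population screen
  that flags but never silently removes.
* **Subgroup estimator** (`high_expressor()`, the package's core fit). High
  expression is defined against controls only, T = median + 1.25 × IQR;
  flag status × diagnosis is tested with the uncorrected 2×2 Pearson
  chi-square and summarized as a risk ratio and odds ratio; the normal core
  is estimated by reiteratively removing the largest value until a
  Lilliefors-corrected Kolmogorov–Smirnov test no longer rejects normality
  (p > 0.05), and the flagged samples' mean is reported as
  (x̄<sub>flagged</sub> − μ<sub>core</sub>)/σ<sub>core</sub> core SD.
* **Group statistics** with the conventions of the field: pooled t (raw or
  published summary statistics), SPSS-convention Mann–Whitney U (exact p
  for small untied samples), one-tailed p only for predicted directions,
  effect sizes r = √(t²/(t²+df)), |Z|/√N, √(χ²/N), Spearman covariate
  screens, Type-II two-way ANOVA.
* **Hierarchical regression decomposition**: R² of a dependent transcript
  explained by a ligand transcript alone, tissue pH alone, and the
  increment ΔR² of the ligand over pH with an F-change test and
  standardized β.
* **Synthetic cohorts** (`simulate_study()`): seeded generators for
  manifests, expression with planted high-expressor subpopulations and
  pH-coupled genes, and noisy Ct triplicates — so every stage is testable
  end to end with known ground truth.

## A worked example

Fit the subgroup model to a cohort of 71 controls and 72 cases with a
planted high-expressor component (5 core SD above the core, prevalence
13% vs 32%):

```r
library(hiexpr)
set.seed(42)
grp  <- rep(c("control", "schizophrenia"), c(71, 72))
sub  <- runif(143) < ifelse(grp == "control", 0.13, 0.32)
expr <- rnorm(143, 0.9, 0.43) + ifelse(sub, 5 * 0.43, 0)
fit  <- high_expressor(expr, grp, control = "control")
summary(fit)
#> High-expressor subgroup fit
#>   threshold: median + 1.25 x IQR of 'control' = 1.785
#>   flagged: 20/72 schizophrenia (27.8%) vs 7/71 control (9.9%)
#>   association: chi2(1) = 7.494, p = 0.00619 (two-tailed)
#>   risk ratio 2.817, odds ratio 3.516
#>   normal core (all): 0.839 +/- 0.438 (n = 117), KS D = 0.07753, p = 0.08066
#>   flagged controls sit 5.431 core SD above the core mean
#>
#> 2x2 table (group x flag):
#>                high
#> group           high normal
#>   control          7     64
#>   schizophrenia   20     52
#> ...
```

Reading the output: the control-anchored threshold (1.785) flags 27.8% of
cases but only 9.9% of controls; the chi-square says that imbalance is
unlikely under independence (p ≈ 0.006); cases are ~2.8 times more likely
to be high expressors; and after trimming, the surviving core
(0.84 ± 0.44, n = 117) is normal by the Lilliefors-corrected KS test,
with the flagged controls sitting ~5.4 core SD above it — i.e. a genuinely
separated subpopulation, not a stretched tail. `plot(fit)` draws the
histogram with the fitted core density and threshold;
`predict(fit, newdata)` classifies new values; `simulate(fit)` draws
cohorts from the fitted geometry.

Published summary tables can be checked directly, e.g. a pooled t-test
from printed group summaries:

```r
pooled_t_test(n1 = 71, mean1 = 27.04, sd1 = 12.15,
              n2 = 72, mean2 = 29.89, sd2 = 14.63)
#> pooled t: statistic(141) = -1.266, p = 0.2075 (two-tailed), effect size r = 0.106
```

For the full pipeline (CSV manifest + Ct table in, expression/tests/
subgroup/correlation/regression CSVs out) see `?run_pipeline` and the
methods vignette in `vignettes/`.

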