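---
title: "Methods: delta-delta Ct quantification and high-expressor subgroup detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delta-delta Ct quantification and high-expressor subgroup detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiexpr)
```

## The problem

Case–control comparisons of postmortem cortical gene expression often show
something subtler than a uniform group shift: most subjects in both groups
share one unimodal "core" distribution of transcript abundance, while a
minority — over-represented among cases — express the transcript at levels
far outside that core. A plain location test dilutes such signal. hiexpr
implements the full analysis chain such studies need: relative
quantification of raw qRT-PCR cycle-threshold (Ct) data, a battery of
group tests with correlation-scale effect sizes, an estimator for the
high-expressor subgroup and its distance from the core distribution, a
covariate screen, and a hierarchical regression separating tissue-pH
variance from ligand-transcript variance. A seeded synthetic-cohort
generator makes every stage testable without any external data.

## Quantification model

A target gene's abundance in sample $i$ is summarized by

$$\Delta Ct_i = Ct^{target}_i - \mathrm{geomean}(Ct^{hk1}_i, Ct^{hk2}_i, Ct^{hk3}_i),$$

the geometric mean being taken of the housekeeper Ct values themselves.
Relative quantities are obtained by anchoring on a calibrator group
(the unaffected controls of the same region and collection):

$$\Delta\Delta Ct_i = \Delta Ct_i - \overline{\Delta Ct}_{calibrator},
\qquad rq_i = 2^{-\Delta\Delta Ct_i}.$$

The calibrator's mean $\Delta\Delta Ct$ is zero by construction, so
control relative quantities have geometric mean 1 and group fold changes
read directly off the rq scale. No amplification-efficiency correction is
applied: the plain $2^{-\Delta\Delta Ct}$ form is used, which assumes
near-doubling per cycle; with reported assay efficiencies below 100% this
under- or over-states absolute fold changes but preserves ordering and
group contrasts.

Technical replicates (triplicates) are cleaned before averaging: a
replicate deviating from the replicate median by more than `max_dev`
(default 0.5 Ct, conventional instrument practice) is dropped. Pairs are
never trimmed — with two replicates there is no majority to identify the
aberrant one — and at least one replicate is always retained. Population
outliers on the rq scale are screened per gene with an iterative
two-sided Grubbs test (default $\alpha = 0.05$, critical value from the
standard Student-quantile formula). Grubbs results are *flags*: the
pipeline logs them with sample IDs but removes nothing silently, because
which distributions (if any) should lose samples is a judgement call the
analyst must see.

## The high-expressor subgroup estimator

`high_expressor()` is the package's core fit, with three components.

**Threshold.** High expression is defined relative to the unaffected
controls only: $T = \mathrm{median} + 1.25 \times \mathrm{IQR}$ of the
control values, applied to all groups. The quartile convention matters in
small samples: the default is linear interpolation between order
statistics (`quantile type 7`); a weighted-average convention
(`qtype = 6`, the SPSS style) is available because published thresholds
computed in other software can differ slightly and the choice cannot be
adjudicated without raw data.

**Association.** Flag status (above/below $T$) versus diagnosis forms a
2×2 table tested with the uncorrected Pearson chi-square (no Yates
correction — the package reproduces published cohort-table chi-squares
exactly only without it). The risk ratio (case prevalence of the flag
over control prevalence) and the odds ratio are both reported: "times
more likely" phrasing in the literature does not distinguish them.
Degenerate tables (no flags, or no flagged controls) warn and report what
remains computable rather than failing.

**Normal core.** The core distribution is estimated by reiterative
maximum-removal: test the current set for normality with the
Kolmogorov–Smirnov statistic, and while $p \le 0.05$ remove the single
largest value and retest. Because the normal's parameters are estimated
from the same data, the significance is Lilliefors-corrected
(`nortest::lillie.test`); an uncorrected KS p-value would be strongly
anti-conservative and trim far too much. Ties at the maximum lose one
occurrence per iteration (the last index, making removal deterministic),
and the surviving core may not shrink below 5 values (the smallest set on
which the corrected test is meaningful); hitting that floor sets a
non-convergence flag. The flagged samples' mean is finally expressed as
$(\bar{x}_{flagged} - \mu_{core}) / \sigma_{core}$, an affine-invariant
"SD distance" that conveys how separated the subpopulation is.

By default the core is trimmed from the pooled control + case values of
the analysed pair of groups, with a controls-only mode available
(`core_pool = "controls"`): published core sizes suggest pooling, but the
original choice is not recoverable, so both are provided.

## Group-statistics conventions

* Pooled-variance t ($df = n_1 + n_2 - 2$), accepting raw vectors or
  printed summary statistics so published tables can be checked directly.
* Mann–Whitney U reported in the SPSS convention
  $\min(U_1, n_1 n_2 - U_1)$; exact p (null Wilcoxon distribution) when
  both groups are ≤ 20 without ties, otherwise the normal approximation
  with tie-corrected variance and a continuity correction. The effect
  size uses the uncorrected $Z$: $r = |Z|/\sqrt{N}$.
* One-tailed tests are reserved for directions predicted in advance;
  when the observed direction contradicts the prediction the conservative
  $1 - p/2$ is reported rather than $p/2$.
* Effect sizes: $r = \sqrt{t^2/(t^2+df)}$, $r = |Z|/\sqrt{N}$,
  $r = \sqrt{\chi^2/N}$, with $N$ the observations entering that
  particular table (published values are sometimes ambiguous about this
  denominator; the output records the $N$ used).
* Covariate screens are Spearman by default (average ranks, asymptotic
  two-tailed p, pairwise-complete), Pearson optionally; constant columns
  are reported as missing rather than erroring.
* The two-way ANOVA (for the cell-culture style pH × time designs) uses
  Type II sums of squares so unbalanced designs attribute main-effect
  variance sensibly, with Tukey HSD post-hoc contrasts.

## Hierarchical regression decomposition

For a dependent transcript $y$, predictor transcript $x$ and tissue pH
$z$, three OLS fits on z-scored, listwise-complete data give
$R^2_x$, $R^2_z$ and $R^2_{z+x}$; the increment
$\Delta R^2 = R^2_{z+x} - R^2_z$ is the variance the ligand explains
over and above pH, tested with the one-step F-change statistic
$F = \Delta R^2 / \left[(1 - R^2_{z+x})/(n-3)\right]$. Standardized
$\beta$ are reported from both the single-predictor models (where a lone
$\beta$ equals the Pearson correlation) and the joint model, labelled,
because published tables do not always state which model their $\beta$
comes from. Significance stars use the conventional 0.05/0.01/0.001
thresholds.

## What the synthetic generator emulates — and what it does not

`cohort_spec()` defaults reproduce the covariate structure of a combined
schizophrenia brain-bank cohort: 71 controls / 72 cases; age ≈ 47 ± 12 y;
tissue pH ≈ 6.64/6.55 ± 0.28; PMI ≈ 27/30 ± 12–15 h; sex, hemisphere,
and strongly group-dependent smoking (46%/81%) and suicide (0%/21%)
proportions. Covariates are drawn independently within group (smoking and
suicide group-conditionally), which reproduces marginal distributions but
not, e.g., the empirical age–PMI covariance of real collections.

`gene_spec()` models a gene's log2 relative quantity as
core + group effect + pH term + high-expressor displacement. The pH term
is linear with slope $b = \rho/\sqrt{1-\rho^2}\cdot\sigma_{core}/s_{pH}$,
chosen so the induced *Pearson* correlation equals `ph_coupling` — the
simplest mechanism with an analytically known target (the rank
correlation of a bivariate normal is attenuated to
$\tfrac{6}{\pi}\arcsin(\rho/2) \approx 0.96\rho$, so a planted −0.48
yields Spearman ≈ −0.46). The displacement
$s \cdot \sigma_{core}$ (default $s = 5$) is applied *after* the pH term,
so quoted SD distances refer to the core residual scale. Default
prevalences 0.13 (controls) and 0.32 (cases) reflect the subgroup
geometry reported for a pro-apoptotic ligand transcript in cortical
case–control work.

`ct_noise_spec()` adds triplicate noise (default 0.15 Ct — replicate
variance is rarely published; this is a conventional figure for TaqMan
assays, not an estimated one) and sporadic aberrant replicates (2 Ct
displacement at 2% rate). The target-gene baseline embeds
$-\log_2(rq)$ below the geometric mean of the housekeeper baselines, so
with zero noise quantification recovers the planted values exactly *on
the calibrator-centred scale*: $\Delta\Delta Ct$ re-centres on the
calibrator mean, so recovery is exact up to division by the calibrator's
geometric-mean rq (equivalently, exact when the truth is generated
centred). The generator does not model RNA degradation kinetics, probe
efficiency differences, plate effects, or medication pharmacology —
passing tests show the statistical machinery is correct under the stated
model, not that real data meet that model.

One scale subtlety follows from the generator's log-normal structure: the
core is normal on the log2 scale, so planted-recovery and calibration
properties are asserted there, while the pipeline applies the published
threshold rule on the rq scale (where published thresholds like a control
median + 1.25 IQR live). The threshold rule is affine-equivariant, so
either scale is coherent; on the rq scale the right-skewed core inflates
both the null flag rate and SD distances relative to the normal-scale
geometry.

## Numerical and design choices

* Quantile convention for the IQR threshold: type 7 default, type 6
  (SPSS-style) option — see above.
* Minimum surviving core of 5; no published floor exists, and the
  corrected KS test is meaningless below that.
* Replicate cleaning: deviation > 0.5 Ct from the triplicate median;
  pairs never trimmed; singletons pass through.
* Grubbs screening: two-sided, iterative, $\alpha = 0.05$ per step,
  zero-variance input yields no outliers.
* Under the null the subgroup threshold flags
  $P(Z > 1.25 \times 1.349) \approx 4.6\%$ of normal samples (about 5%
  once threshold estimation noise at $n \approx 70$ is included): the
  "high expressor" rule is a tail definition, not a discovery test, and
  the chi-square on the induced table is what carries inference.
* Simulation problem sizes: property tests use 100–200 replicates of
  cohorts of 140–600 samples, and parameter-recovery checks use
  10,000-sample cohorts; these sizes put Monte-Carlo error well inside
  the asserted tolerances while keeping the full suite under a minute.

## A worked fit

The fit below runs on delta-delta-Ct-scale values, where the planted core
is normal:

```{r example}
set.seed(42)
grp <- rep(c("control", "schizophrenia"), c(71, 72))
sub <- runif(143) < ifelse(grp == "control", 0.13, 0.32)
expr <- rnorm(143, 0.9, 0.43) + ifelse(sub, 5 * 0.43, 0)
fit <- high_expressor(expr, grp, control = "control")
summary(fit)
```

```{r plot, fig.width = 6, fig.height = 4}
plot(fit)
```

## Limitations

* The trimming estimator is one-sided by design (it removes maxima only);
  low-expressor subgroups would need the mirrored procedure.
* Lilliefors significance in `nortest` is itself an approximation
  (Dallal–Wilkinson); stopping decisions within ±0.005 of the 0.05
  boundary should not be over-interpreted.
* The risk ratio is undefined when no control is flagged (reported as
  infinite with a warning); small flagged counts make both ratios
  unstable, and the 2×2 chi-square is asymptotic.
* No multiple-testing correction is applied anywhere; the tidy outputs
  record how many tests were run so users can apply their own.
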