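---
title: "Methods: points-based expression scoring for survival stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: points-based expression scoring for survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roscore)
```

## The procedure

`roscore` implements a three-stage prognostic scoring procedure for
gene-expression survival cohorts, of the kind used to build
reactive-oxygen-species (ROS) pathway signatures for serous ovarian cancer,
though nothing in the code is specific to that gene set.

**Stage 1 — screening.** Every candidate gene is dichotomized at its cohort
median: samples strictly above the median form the "high" group, samples at
or below it (including exact ties) the "low" group. High vs low overall
survival is compared with the standard unweighted log-rank test, and genes
with $P < 0.15$ (strict) are selected. The threshold is deliberately
permissive and **no multiple-testing correction is applied** — with $m$
null candidates the screen admits about $0.15\,m$ false genes by
construction, which is why any panel it produces must be validated on
independent cohorts. The direction of effect is taken from the univariate
Cox hazard ratio of the high indicator: $\mathrm{HR} < 1$ means above-median
expression is favorable (`high_good`), otherwise `low_good`.

**Stage 2 — scoring.** For each selected gene a patient earns one point
when their expression lies on the gene's favorable side of the cohort
median. The integer sum over the $K$ panel genes is the patient's score
($0\ldots K$). The score range is split into two equal halves: scores
$\le \lfloor K/2 \rfloor$ are "low", the rest "high" — for $K = 25$ this is
the published low 0–12 / high 13–25 grouping. Because every ingredient sees
only ranks, both score and grouping are invariant under strictly monotone
per-gene transforms; microarray intensities, log RNA-seq abundances and
qPCR $-\Delta C_t$ values (or $2^{-\Delta C_t}$) all give identical scores.

**Stage 3 — evaluation.** The scored cohort is analyzed exactly as such
signatures are reported: Kaplan–Meier curves and censoring-aware medians
per group with the log-rank test; univariate and multivariable Cox
proportional-hazards models of the score (continuous or high-vs-low)
against age, grade, stage, and residual disease; Pearson correlation
between each observed score value and the Kaplan–Meier median survival of
the patients holding it; and a survival-threshold ROC comparison (below).

## From-scratch survival statistics

All estimators are implemented directly rather than wrapped:

* **Kaplan–Meier**: product-limit estimate
  $\hat S(t)=\prod_{t_i\le t}(1-d_i/n_i)$ with Greenwood standard errors.
  Censored observations at an event time count as at risk at that time
  (right-continuity). The median is the *first event time with
  $\hat S(t)\le 0.5$*, undefined when the curve never reaches 0.5.
* **Log-rank**: observed minus hypergeometric-expected deaths per group,
  covariance with the multiple-death factor $(n_t-d_t)/(n_t-1)$, chi-square
  on $g-1$ df.
* **Cox regression**: Newton–Raphson on the partial likelihood starting at
  $\beta=0$ with step-halving, convergence when
  $\max|\Delta\beta|<10^{-8}$, cap 50 iterations. Covariates are centered
  and scaled internally for numerical stability and back-transformed. Tied
  deaths use the **Efron** correction by default (Breslow available);
  confidence intervals and p-values are Wald,
  $\exp(\hat\beta \pm 1.96\,\mathrm{se})$, matching the "HR; 95% CI"
  reporting convention. A monotone likelihood (perfect separation) returns
  the fit with `converged = FALSE` and a warning rather than an error.
* **AUC**: the Mann–Whitney concordance probability with midrank tie
  handling, plus the full operating-point list.

Unit tests check each of these against independent oracles: a
redistribute-to-the-right construction for Kaplan–Meier, an
independently-coded permutation test for the log-rank p, grid plus
golden-section maximization of a naively-coded partial likelihood for Cox,
exhaustive pair enumeration for the AUC, and `survival::coxph` /
`survival::survdiff` as an extra cross-check.

## The survival-threshold ROC

Patients are binarized at the cohort's Kaplan–Meier median OS. A patient
is "long-surviving" when the observed or censored time is at or above the
median — a patient censored *after* the median has already outlived the
threshold, so censoring does not matter for them. A patient who died
before the median is "short-surviving". Patients censored before the
median are excluded because their class is unknown; no event-flagged
patient is ever excluded. Cox models are then fit on the included subset
for three covariate sets — clinical covariates only (age, grade, stage,
residual; "AGSR"), score only, and both — and each model's in-sample
linear predictor is scored by AUC with short survival as the positive
class. The three AUCs are computed on one shared complete-case subset so
they are comparable. No cross-validation is applied; these are in-sample
("apparent") AUCs, mirroring the original procedure.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `screen_threshold` | 0.15 | strict log-rank p cutoff for panel entry |
| `ties` | `"efron"` | Cox tie handling (`"breslow"` available) |
| `medians` | per-cohort | per-gene thresholds; a frozen named vector supports prospective single-platform use |
| `max_missing_frac` | 0.2 | group assignment refuses when more of the panel is missing, since the equal-range boundary presumes the full $K$ |
| `min_bin_size` | 3 | smallest score bin entering the score–median-OS correlation (smaller bins make KM medians unstable) |
| `age_coding` | continuous | `binary60` (≤59 vs ≥60) reproduces forest-plot-style coding |

Choices the source material left open, decided here once:

* **Selection under non-convergence.** A perfectly separated gene (all
  above-median patients outliving the rest) produces a monotone Cox
  likelihood. Since the screen statistic is the log-rank test and the
  direction sign is well-defined even then, such genes *are* selectable;
  only an inestimable or exactly-1 hazard ratio (no direction) vetoes
  selection. The convergence flag is kept in the audit record.
* **Ties at the median** go to the low group: deterministic, and keeps the
  split non-empty for even $n$ with distinct values. A log message flags
  genes where >10% of samples tie the median.
* **Per-cohort medians by default**, because the method is applied across
  incomparable platforms (two microarrays and qPCR); whether the original
  validation cohorts re-derived medians is not stated, so this is exposed
  as the `medians` argument.
* **Duplication invariance** of Cox estimates — used as a sanity check —
  holds exactly only under Breslow ties (Efron's within-tie averaging is
  not duplication-stable), which is why that check runs with
  `ties = "breslow"`.

## The synthetic cohort generator

`simulate_cohort()` draws per-gene expression i.i.d. standard normal and
gives each patient the hazard
$\lambda_i = \lambda_0 \exp\!\big(\sum_g \beta_g\,
[\text{patient } i \text{ on gene } g\text{'s unfavorable median side}]\big)$,
with exponential or Weibull (proportional-hazards) baseline and
independent exponential or administrative censoring. The signal acts
through the *median-group indicator*, not the continuous expression value,
so the dichotomized point score is the correctly specified model and
recovery tests are clean; this is an idealization — on real data the
dichotomization loses information relative to the underlying continuous
biology. A continuous-effect variant can be emulated by passing covariate
hazard links.

The `tcga_like` (n = 511, 179 candidate genes), `tothill_like` (n = 240)
and `tj_like` (n = 105, 25 genes) presets mirror the published cohort
dimensions. Each plants 25 signal genes (12 `high_good` / 13 `low_good`,
the published panel's direction split) with $\beta = 0.13$ per gene, so a
patient's hazard is proportional to $\exp(-0.13 \times \text{true score})$
— the per-point hazard ratio of $e^{-0.13} \approx 0.878$ reported for the
discovery cohort. The baseline rate is calibrated so a typical patient's
median OS is ≈ 3.8 years and the exponential censoring rate (0.08/yr)
yields ≈ 30% censoring, both typical of the published cohorts. One
consequence of the uncorrected $P<0.15$ screen is worth stating plainly:
with 154 null candidates the expected number of false panel entries is
≈ 23, so a discovery run on a `tcga_like` cohort selects ≈ 35–50 genes,
not 25 — a 25-gene panel cannot be reproduced at these dimensions without
a stricter threshold or correction.

**What a green test does and does not establish.** The generator emulates
continuous expression, median-group hazard effects, proportional hazards
and independent censoring. It does not emulate probe effects, FFPE
degradation, qPCR efficiency, batch structure, covariate–expression
correlation, or non-proportional hazards. Passing recovery tests therefore
establishes the *implementation* is faithful, not that the signature works
on real tumors.

## Numerical and degenerate-input conventions

* Constant ("degenerate") genes cannot be dichotomized and are skipped
  with an audit record; genes with any missing value in a cohort are
  excluded from screening and scoring for that cohort (medians and points
  would otherwise be undefined per-sample).
* The KM median comparison uses a $10^{-9}$ tolerance so exact-0.5 plateaus
  (e.g. 4 equal-weight deaths) resolve to the first qualifying event time
  despite floating-point rounding.
* An all-censored group yields a curve identically 1 with an undefined
  median — a value, not an error.
* Log-rank with a singular covariance (e.g. duplicated groups) falls back
  to a pseudo-inverse.
* Aliased covariate columns (e.g. complementary stage dummies when no
  stage I–II patient is present) are detected by QR rank and dropped with
  a warning, as are single-level covariates.

## Scaling of the stochastic test suites

The acceptance suite runs the published-scale experiments where cheap
(2000 null genes at n = 500; 200 direction-recovery replicates at n = 500;
20 full `tcga_like` discovery pipelines). The selection-leakage guard
(screen on one cohort, score a fresh cohort, demand uniform log-rank p)
runs its 400 replicates at n = 120 patients × 40 genes to stay inside the
test-time budget; the leakage property it probes does not depend on scale.

## Known limitations

Time-dependent covariates, stratified/frailty Cox, competing risks,
time-dependent AUC, calibration and cross-validated ROC are out of scope.
The equal-range group boundary presumes the full panel was measured;
scoring proceeds with missing panel genes (with a reduced attainable
maximum) but group assignment refuses beyond the missingness gate. The
179-gene candidate list itself is user input — the original publication
does not enumerate it, only the 25 selected genes, which ship as the
builtin `table1` panel.
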