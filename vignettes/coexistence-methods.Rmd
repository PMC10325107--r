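---
title: "Methods: quantifying human-bird coexistence in croplands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying human-bird coexistence in croplands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropbirds)
```

`cropbirds` implements the quantitative workflow of a global synthesis of
bird effects in agricultural fields: standardized effect sizes from
exclosure and crop-loss-mitigation experiments, multilevel random-effects
meta-analysis, a publication-bias suite, recursive partitioning of
effect-size direction, binomial mixed models for social-survey proportions
with information-theoretic model averaging, and a gridded bivariate
prioritization of win-win regions. This vignette explains the models, the
defaults, and the choices made where the design was genuinely open.

## Effect sizes

Each experimental comparison contributes a bias-corrected standardized mean
difference (Hedges' *g*). With group means $\bar X_t, \bar X_c$, standard
deviations $S_t, S_c$ and sizes $n_t, n_c$:

$$d = \frac{\bar X_t - \bar X_c}{SD_{within}}, \qquad
SD_{within} = \sqrt{\frac{(n_t-1)S_t^2 + (n_c-1)S_c^2}{n_t+n_c-2}},$$

$$V_d = \frac{n_c+n_t}{n_c n_t} + \frac{d^2}{2(n_c+n_t)}, \qquad
J = 1 - \frac{3}{4(n_t+n_c-2)-1}, \qquad g = J\,d,\; V_g = J^2 V_d.$$

We use the standard pooled (summed) within-groups variance and the standard
degrees of freedom $n_t + n_c - 2$ in $J$; these are the only forms under
which $SD_{within}$ is always real and $J \in (0,1)$ deserves the name
"bias correction". Records with a zero standard deviation are rejected with
a per-row diagnostic rather than imputed — a zero pooled SD leaves both the
effect and its variance undefined.

Outcomes reported as losses (e.g. "50% loss versus 30% loss") point the
opposite way from outcomes reported as production, so effects from
loss-polarity records are multiplied by $-1$. After alignment, positive *g*
always means *birds increase production* (exclosure data) or *the measure
reduces crop loss* (mitigation data). When only a two-sample *t* statistic
or means with standard errors are available, `g_from_convertible()` converts
them ($d = t\sqrt{1/n_t + 1/n_c}$; $SD = SE\sqrt{n}$) and proceeds
identically.

## Multilevel random-effects meta-analysis

Comparisons are nested in studies, so effects from one study are not
independent. The model places a random intercept on the study and on the
comparison-within-study level ("nested groups"): the marginal variance of
effect $i$ in study $s$ is $v_i + \tau^2_{study} + \tau^2_{within}$, with
effects in the same study sharing the $\tau^2_{study}$ component. Variance
components are estimated by restricted maximum likelihood (REML) with
non-negativity constraints; the likelihood is evaluated block-by-study with
a rank-one (Sherman–Morrison) update, and optimized by bounded quasi-Newton
iterations from several starting points (moment-based, boundary, diffuse) to
a criterion tolerance of about 1e-10. Coefficients are generalized
least-squares estimates with weights $1/(v_i + \hat\tau^2_{study} +
\hat\tau^2_{within})$ — each effect weighted by the inverse of its
within-study plus between-study variance. Confidence intervals are normal
(z) Wald intervals, matching the defaults of the standard meta-analytic
toolchain; Knapp–Hartung adjustments are deliberately out of scope. When
every study has exactly one comparison the inner component is not
identifiable and is dropped automatically, reducing the model to the
classical random-effects form.

Heterogeneity is summarized by the Q-test: $Q_E = \sum_i w_i (g_i -
x_i'\hat\beta_{FE})^2$ with fixed-effects weights $w_i = 1/v_i$ at the
fixed-effects projection, chi-square with $k-p$ degrees of freedom under
homogeneity. Moderators enter as fixed effects (explicit dummy coding,
lexicographic level order, listwise deletion of missing values with a
logged count) and are tested with the omnibus Wald chi-square $Q_M$ over all
non-intercept coefficients. Subgroup estimates use a no-intercept
level-indicator design so all levels share the variance components. The
implementation is cross-validated in the test suite against
`metafor::rma.mv` to six or more digits on the pooled estimate, standard
error, variance components and heterogeneity statistics.

## Publication bias

Five diagnostics are bundled in `publication_bias()`:

* **Funnel data**: per-effect $(g, \sqrt{v_g})$, exported rather than drawn.
* **Rosenthal fail-safe number**: $N = \max(0, \lfloor (\sum Z_i)^2 /
  z_\alpha^2 - k \rfloor)$ with one-sided $\alpha = 0.05$; robust when
  $N > 5k + 10$.
* **Rank-correlation test**: Kendall's tau-b between variance-standardized
  effects (centered at the fixed-effects mean, standardized by
  $\sqrt{v_i - s^2}$) and their variances. Variance is the default
  surrogate for sample size — monotone in *n* and always available; ranking
  an explicit total-n column is exposed as an option. The p-value is exact
  for $k \le 10$ without ties, computed from the inversion-count (Mahonian)
  null distribution, which equals full permutation enumeration; otherwise a
  tie-corrected normal approximation is used.
* **Regression test**: weighted meta-regression of effects on standard
  errors under a single-level random-effects model — the multilevel
  structure is collapsed for this diagnostic, as is conventional for
  funnel-asymmetry regressions.
* **Trim-and-fill**: iterative Duval–Tweedie with the L0 rank estimator.
  The side with suppressed studies defaults to `auto`, chosen by the sign of
  the rank-correlation statistic; each iteration trims the current $k_0$
  most extreme effects on the observed-surplus side, re-centers with a
  single-level random-effects REML fit, and re-estimates $k_0$ until it
  stabilizes; filled effects mirror the trimmed ones about the final center
  with their variances copied. Absolute deviations are snapped to 12
  significant digits before ranking so exactly mirrored pairs tie
  deterministically and perfectly symmetric funnels return $k_0 = 0$. The
  adjusted estimate is a single-level random-effects fit on the augmented
  set. The estimator agrees replicate-for-replicate with
  `metafor::trimfill(..., estimator = "L0")` in the tests. Note the
  estimator's honest behavior: on mirrored-pair funnels of 20 effects with
  the 3 most negative censored, it typically reports $k_0 = 2$–$3$ —
  slightly conservative, because the center must itself be estimated from
  the censored data.

## Direction tree

To find which moderators predict the *sign* of the effect, a conditional
inference tree is grown over the binary response "is $g$ positive?"
(exactly zero counts as non-positive; ties at zero are vanishingly rare in
continuous effects). At each node the independence of the response and each
covariate is tested: Fisher's exact test for 2x2 tables, a Monte-Carlo
permutation null (9,999 draws, seeded, default seed 20230706) of the
Pearson chi-square statistic for wider categorical tables, and maximally
selected two-sample statistics over observed cutpoints for numeric
covariates. P-values are Bonferroni-adjusted across covariates and the node
splits on the smallest adjusted p only when it is below `alpha` (default
0.05) — so stopping is a multiplicity-adjusted significance test, not
pruning, and a null dataset is usually left unsplit. Categorical splits
search all two-set level partitions for the largest collapsed 2x2
chi-square; children must contain at least 7 observations and nodes below
20 observations are not split. Covariates may be reused along a path.

## Survey models

Per-survey proportions are reconstructed into integer success/failure
counts (`round(proportion * n)`, with a warning when the product is not an
integer) and modeled with a binomial random-intercept logit model fitted by
Laplace-approximated maximum likelihood (`lme4::glmer`); the survey is the
cluster, which with one row per survey also absorbs overdispersion. Model
support uses the small-sample information criterion with the number of
surveys as $n$:
$AICc = -2\ell + 2p + 2p(p+1)/(n-p-1)$, where $p$ counts the fixed effects
plus the random-intercept variance. `dredge_and_average()` fits every
subset of the candidate terms (the four survey-level variables — national
income, bird group, stakeholder, climate — as main effects; the candidate
set is capped at 12 terms), ranks by AICc, and averages coefficients over
the models within `delta = 2` using Akaike weights renormalized over that
set. Full (zero-substituted) averaging is the default, matching the common
convention of the ranking tool this mirrors; conditional averaging is an
option. Averaged standard errors use the Burnham–Anderson form
$\sqrt{\sum_m w_m (se_m^2 + (\hat\beta_m - \bar\beta)^2)}$ and the reported
p-values are normal approximations on them — approximate by construction.
Negative-attitude outcomes are not modeled separately (their results mirror
the positive-attitude models inversely); descriptive summaries are plain
unweighted means and SDs across surveys. Temporal trends in study counts
use a two-sided Spearman rank correlation against the period index.

## Prioritization grids

The crop-benefit index is the woody share of total crop production per
cell; cells with zero total production become missing rather than
zero-benefit, so oceans and no-crop land cannot compress the terciles. The
integrative conservation value is the cellwise product of min–max
standardized threatened-bird richness and all-bird richness (a constant
layer standardizes to 0 with a warning so products stay defined). Both
indices are cut at the 1/3 and 2/3 linear-interpolation quantiles of their
non-missing cells, boundary ties to the lower class; the 3x3 cross of
terciles gives class codes 1–9 and the joint top tercile is the priority
mask. Because classification is rank-based, the mask is invariant under any
strictly monotone transformation of either input. Grids are plain matrices
with cell-center registration (row 1 northernmost); co-analyzed layers must
be co-registered — mismatches are errors, never silent resampling. ESRI
ASCII grid read/write is built in.

## Synthetic data

The generators produce every input the analyses consume, so the whole
pipeline is testable without downloads. They are pure functions of
(configuration, seed).

* `simulate_effects()` defaults mirror the exclosure dataset's structure:
  40 studies with 1–6 comparisons each, true pooled effect 0.4,
  between-study variance 0.04, a smaller within-study component (0.02), 4–30
  replicates per arm, and log-normal group SDs around 1 so sampling
  variances vary realistically. True effects are built as mean + moderator
  shift + study effect + within-study effect, and raw group summaries are
  drawn so the population standardized difference equals the true effect —
  the effect-size module is exercised end to end. Optional one-sided
  censoring suppresses a comparison with probability increasing in its
  standard error and decreasing in its one-sided *z*, mimicking small
  studies being published only when they show large effects.
* `simulate_surveys()` defaults mirror the attitude dataset: 39 surveys of
  50–1,500 respondents with a wide survey-level intercept spread (SD 1.5 on
  the logit scale, intercept 0.9), which reproduces the observed pattern of
  a roughly two-thirds mean positive proportion with a between-survey SD
  near 0.28.
* `simulate_grids()` produces smoothed (separable Gaussian blur),
  non-negative, co-registered layers with woody $\le$ total everywhere and a
  shared nodata mask. The optional planted "hot corner" uses opposing
  spatial gradients for benefit and richness outside the corner so that the
  joint top tercile is *exactly* the planted block — a validation
  construction for the priority mask, not a model of real geography.

What passing tests on these data do **not** show: real experiment sets have
non-normal outcomes, correlated moderators, clustered crop types and far
messier variance structure; the generators make none of those features, so
the tests certify the estimators under their stated assumptions, not
robustness to violations.

## Reproduction of the published analysis

`reproduce()` chains the full pipeline on supplied comparison, survey and
count files and writes a JSON report (overall and per-stem-type pooled
estimates with bias suites and trim-and-fill, moderator tests, the
direction tree root, survey descriptives and averaged models, trend tests).
The original supplementary spreadsheets are not redistributable with this
package; when they are placed under `inst/extdata/supplementary/` the
acceptance suite compares the report against the published estimates. The
reader's column maps exist precisely to absorb their headers without
editing the files.

## Problem sizes and numerical notes

The test suite sizes its simulations to be decisive yet quick: 1,000-record
oracle sweeps for the effect-size formulas; 500 replicates at k = 100 for
pooled-estimate recovery and coverage; 500 null replicates for the
regression test's type-I error; 200 replicates each for trim-and-fill
recovery, tree null-refusal and survey-effect recovery; a 0.01-step grid
over both variance components for the REML-optimality check on a k = 6
fixture. Optimizations use bounded `nlminb` with multiple restarts;
degenerate designs (rank deficiency, constant standard errors, constant
layers, all-tied ranks) raise informative errors or warnings rather than
returning silently wrong numbers.
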