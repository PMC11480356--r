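---
title: "Detecting density-dependent somatic growth in age-structured stocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting density-dependent somatic growth in age-structured stocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddgrowth)
library(dplyr)
```

## The scientific question

Compensatory density-dependent (DD) somatic growth — fish growing faster
when the population is small — is routinely invoked to argue that fishing a
stock down should be partially self-correcting. Whether it actually
operates at the population scale is an empirical question, and one that is
easy to get wrong: weight-at-age series are strongly autocorrelated
(cohorts pass through the population over several years), and an
autocorrelated response regressed on a trending density covariate produces
spurious "significant" slopes at far above the nominal rate.

`ddgrowth` implements the full analysis chain for asking this question of
age-structured assessment output:

1. **Reference points.** Unfished spawning biomass `SSB0`, virgin
   recruitment `R0` and spawner-per-recruit `SPR0` give each stock a
   carrying-capacity scale, so density can be expressed as the
   dimensionless ratios `SSB_y/SSB0` and `R_y/R0` and stocks become
   comparable in one model.
2. **Responses.** Instantaneous weight responses (`W_recr`, `W_old`,
   `W_std`) paired with same-year relative density, and intracohort
   standardized weight increments (`W_cohort`, `W_cohort_age`) paired with
   the cohort's own relative abundance.
3. **Inference.** Linear mixed models with per-stock density slopes, stock
   random effects and AR1 residual correlation, estimated by maximum
   likelihood, compared by delta-AIC, with and without the AR1 term.
4. **A synthetic-stock generator** with a known injected DD effect, so the
   whole chain can be validated end to end without any external data.

## Unfished equilibrium reference points

The stock-recruitment relationship is a hockey stick ("segmented
regression") with the breakpoint fixed at the stock's biomass limit
`B_lim`: recruitment rises proportionally with spawning biomass up to the
breakpoint and is flat above it,

$$R(S) = a\,\min(S, b), \qquad b = B_\mathrm{lim}.$$

The slope $a$ is the only free parameter and is estimated by least squares
on the log scale, which is the natural choice under lognormal recruitment
variability; the residual standard deviation and lag-1 autocorrelation
become the simulation's recruitment noise parameters. When every observed
biomass sits on the plateau the slope is taken from the plateau mean and
the fit is flagged — the data then carry no information about the
ascending limb.

Reference points come from stochastic projection at zero fishing
mortality: 200 years per replicate, the last 50 retained, with biology
vectors (weight, maturity, natural mortality, selectivity-at-age) averaged
over the last three observed years, lognormal AR1 recruitment deviations,
and an AR1 lognormal assessment-error process on intended fishing
mortality (sd 0.212, autocorrelation 0.423) that is inert at F = 0 but
active whenever a fished equilibrium is projected. `SSB0` and `R0` are
reported as both the median and the mean over replicates: the replicate
distribution is lognormal-skewed, the median is the robust choice, and the
paper trail of any particular assessment tool may use either.

Two analytic anchors pin the simulator down. In the deterministic limit
with $a \cdot SPR_0 > 1$ the equilibrium is exactly $R_0 = ab$,
$SSB_0 = ab\,SPR_0$, with

$$SPR_0 = \sum_a l(a)\,e^{-s M(a)}\,mat(a)\,w(a), \qquad
  l(a+1) = l(a)e^{-M(a)},$$

and plus-group survivorship $l(A) = l(A-1)e^{-M(A-1)}/(1 - e^{-M(A)})$
(the geometric series of the accumulator). `spawn_frac` ($s$) defaults to 0
— spawning biomass at 1 January — and is configurable; assessments differ
and nothing downstream is sensitive to it at the default. With
$a \cdot SPR_0 \le 1$ the unfished population cannot replace itself and
the projection collapses to zero; this is flagged rather than treated as
an error, because a badly estimated SRR slope should be visible, not
fatal.

## Response variables

- `W_recr(y)`: weight of the youngest assessed age class, paired with
  relative recruitment `R_y/R0`.
- `W_old(y)`: unweighted mean weight over ages strictly above `A50`, the
  average age at 50% maturity obtained by linear interpolation of the
  maturity ogive per year and averaged over years. "Above" is read
  strictly (smallest integer age greater than the fractional `A50`); the
  boundary age is arguably ambiguous, and strictness is the literal
  reading. One time-averaged `A50` per stock is used throughout.
- `W_std(y)`: unweighted mean weight over all ages except the first and,
  for plus-group stocks, the last. Unweighted, because abundance-weighting
  would let the youngest (most numerous) ages dominate.

Both biomass-covariate responses use a de-circularized covariate: ordinary
SSB contains the same weight-at-age as the response, so the covariate is
instead $SSB_{std}(y) = \sum_a N(a,y)\,mat(a,y)\,\bar W(a)$ with
cross-year mean weights — by construction invariant to year-to-year weight
fluctuation. The cross-year mean is computed after pruning (pruned years
are assessment artifacts, not observations).

Intracohort responses follow each cohort's growth trajectory along the
diagonal of the age-year matrix: $\Delta W(a,c) = W(a{+}1, c{+}a{+}1) -
W(a, c{+}a)$, standardized per age transition across cohorts to mean 0 and
sd 1, so transitions with very different absolute increments become
comparable. `W_cohort` averages a cohort's standardized increments over
pre-maturation transitions (terminal age at most `ceiling(A50)` — growth
compensation is expected mainly before energy is diverted to
reproduction) and is paired with the cohort's `R/R0`. `W_cohort_age` keeps
each increment separate and pairs it with the relative abundance of that
age class in the year before the increment completes, `N(a, y)/N0(a)`,
with `N0` from the unfished projection. Transitions into a plus-group age
are excluded: the accumulator's mean weight mixes many cohorts, so its
"increment" is not an intracohort growth increment. Transitions observed
for fewer than three cohorts, or with zero variance (assessments that
assume constant weight), carry no information and are dropped with a
report.

## Data pruning

Assessment inputs often hold weight-at-age constant over whole periods;
those repeats would otherwise enter the regressions as exact duplicates.
A year is excluded for a response when the response-relevant weight
sub-vector is identical (relative difference below `1e-9` — stored
repeats are exact, so the tolerance only needs to absorb serialization
round-off) to an adjacent year's; entire constant series are flagged fully
excluded. Stock-by-response groups with fewer than `min_obs = 5` usable
years are removed: five observations is the smallest count at which a
slope, intercept and AR1 coefficient are all identified. The threshold is
configurable; the original analyses list their exclusions by name rather
than by rule, so the default is a judgement call and is surfaced in the
prune report rather than buried.

## The mixed-model engine

All structures share one marginal Gaussian form. Observations are grouped
by stock; within group $g$ the covariance is

$$\Sigma_g \;=\; \tau^2 z_g z_g^\top \;+\; \sigma^2 C_g(\varphi),
\qquad C(\varphi)_{ij} = \varphi^{|t_i - t_j|},$$

with $z_g = \mathbf 1$ for a random intercept (stock-level structures) or
$z_g$ the covariate vector for the random-slope global models. Gaps from
pruning are handled as continuous-time AR1: a gap of $\Delta t$ steps
contributes correlation $\varphi^{\Delta t}$. For the per-age intracohort
model the AR1 sub-groups are stock-by-age-transition ordered by cohort —
each transition is its own time series — while the random effect stays at
the stock level.

Estimation is by maximum likelihood, not REML, because the model ladder
compares structures that differ in fixed effects (the species factor) by
AIC, and REML likelihoods are not comparable across fixed-effect
structures. $\beta$ and the total scale $\sigma^2$ are profiled out in
closed form, leaving at most a two-dimensional optimization over
$(\log\lambda, \operatorname{atanh}\varphi)$ with $\lambda =
\tau^2/\sigma^2$; the likelihood is evaluated by per-stock Cholesky
factorization and the optimizer restarts from an AR1 grid of
$\{-0.5, 0, 0.5\}$. Degrees of freedom count every estimated quantity:
fixed coefficients, $\sigma^2$, the random-effect variance and the AR1
coefficient each add one.

Model selection follows the delta-AIC rule: $\Delta_i = AIC_i -
AIC_{min}$; models with $\Delta_i > 10$ are discarded; among survivors the
most parsimonious (fewest estimated parameters) wins, with remaining ties
going to the lower AIC. Per-stock slope standard errors come from the GLS
information matrix at the fitted covariance, and p-values from Wald t
statistics with within-group residual degrees of freedom
($n_g - 2$). No multiple-testing correction is applied across stocks — the
published per-stock significance counts are uncorrected — and summaries
report uncorrected counts likewise.

The global models drop the per-stock slope interaction and estimate one
shared slope with per-stock random slopes on the covariate. As printed in
the source analyses they carry no random intercept; `fit_global()` exposes
`random_intercept = TRUE` because with heterogeneous stock baselines the
slope-only form is misspecified, but the default follows the printed
model. Both the AR1 and no-AR1 variants are always reported.

Two diagnostics close the loop: `residual_acf(type = "raw")` shows the
autocorrelation a no-AR1 fit leaves behind, and `type = "whitened"`
standardizes residuals by the fitted within-group covariance — a
well-specified AR1 fit leaves white noise inside the
$\pm 1.96/\sqrt{n}$ bands.

## What the generator emulates — and what it does not

`simulate_stock_panel()` produces panels with the statistical structure
the analysis assumes: unfished-equilibrium initial age composition (no
burn-in artifacts), hockey-stick recruitment with lognormal AR1
deviations, a fishing history (fishing-down by default, so relative
density trends the way real assessment series do), von Bertalanffy
baseline weight-at-age, and realized weights

$$W(a,y) = W_\mathrm{base}(a)\,\{1 + \beta_{dd}(D_y - \bar D)\}\,
  e^{u_y + c_{y-a}},$$

where $D_y$ is relative density computed with baseline weights — matching
the de-circularized covariate, so the injected linear effect is exactly
the estimand — $u_y$ is AR1 year noise and $c$ a cohort effect shared
along diagonals, which generates the along-cohort correlation that
motivates the AR1 residual term in the first place.

Default conditions (chosen once as a realistic mid-size demersal stock
and used by every validation): 20 stocks of 45 years, ages 1–8 with a
plus group, $W_\infty = 3$ kg, $k = 0.3$, $t_0 = -0.5$, M = 0.2,
maturity ogive centred at age 2.5, breakpoint 20 000 t with unfished
replacement ratio $a \cdot SPR_0 = 5$, recruitment noise
$\sigma_R = 0.5$, $\rho_R = 0.4$, weight noise $\sigma_w = 0.08$,
$\varphi_w = 0.4$, cohort effect sd 0.05, and F ramping from 0.05 to 0.6
(a one-way trip). Stocks share the growth curve by default (all
parameters accept per-stock vectors); homogeneous baselines keep the
random-slope-only global model well specified, which is exactly the
regime in which its calibration can be tested cleanly. Reproducibility is
by a single master seed with per-stock substreams derived by stable
hashing of the stock index, so stock 1's series does not change when more
stocks are added.

What the generator does **not** emulate: multispecies interaction,
spatial structure, fishery-induced selection on growth, environmental
covariates, assessment-model estimation error in N-at-age, or
time-varying maturity and natural mortality. Passing validation on these
panels therefore demonstrates that the estimator chain is correct and
calibrated under its own assumptions — it does not show that real stocks
satisfy those assumptions, which is precisely why the AR1/no-AR1 contrast
is reported rather than a single model.

## Numerical choices and degenerate inputs

- Constancy tolerance `1e-9` (relative) for pruning; stored repeats are
  exact.
- The optimizer works on unconstrained transforms, clamped at
  $|\varphi| \le 0.999$ and $\lambda \le e^{30}$; covariance factorization
  failures and non-positive profiled variances propagate as infinite
  negative log-likelihood so the optimizer backs away rather than crashes.
- Non-convergence from every restart yields a flagged fit that
  `select_model()` refuses to rank.
- A zero plus-group natural mortality makes the accumulator survivorship
  diverge; this is an instructive error, not a silent cap.
- Equilibrium non-convergence is screened by the trend of the retained
  years' median SSB path (warning above 1% per year).
- Ties and boundaries: "above A50" is strict; the pre-maturation window
  for `W_cohort` is inclusive at `ceiling(A50)`; min-obs filtering is
  inclusive at the threshold.

## Validation problem sizes

The test suite validates each stage at sizes chosen to make Monte-Carlo
error small relative to the tolerance being asserted: the likelihood is
checked against a dense multivariate-normal evaluation on 200 random
instances of up to 30 observations (tolerance `1e-8`); slope recovery and
Wald coverage use 100 replicates of 20 stocks by 40 years with
$\beta_{dd} = -0.3$; the autocorrelation-inflation contrast uses one
200-stock null panel with $\varphi_w = 0.6$; equilibrium checks use 500
stochastic replicates. `scripts/acceptance.R` re-runs the main chain at
the same sizes from a command-line seed.

## Known limitations

- One random term per model: random intercept or random slope, not both.
  The printed global structure needs only one; fitting both would require
  a two-column random-effects design.
- The AR1 process is Gaussian and stationary within groups; structural
  breaks in assessment inputs (e.g. a weight-sampling protocol change)
  will be absorbed into $\varphi$.
- `A50` from strongly non-monotone ogives is a warning, not a model; if
  maturity data are unusable, `W_old` should be interpreted accordingly.
- The equilibrium module deliberately stops at F = 0 reference points;
  MSY-type quantities depend on selectivity assumptions this analysis was
  designed to avoid.
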