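# ddgrowth

Detection and quantification of density-dependent (DD) somatic growth in
age-structured fish stocks.

## The problem

Whether fish grow faster when their population is depleted — compensatory
DD growth — matters directly for fisheries reference points: if it were
strong and general, fishing a stock down would be partly self-correcting.
Testing for it from stock-assessment output is statistically treacherous,
because weight-at-age series are temporally autocorrelated (cohorts pass
through the population over several years) and population density trends
over time, so naive regressions of weight on density produce spurious
"significant" compensation at many times the nominal rate.

`ddgrowth` is for quantitative fisheries scientists who want to run this
analysis on age-structured assessment output (numbers-, weight-,
maturity-, and mortality-at-age), and to know that the machinery is
calibrated. It provides:

- **Reference points**: unfished equilibrium SSB₀, R₀, SPR₀ and
  numbers-at-age N₀ by stochastic projection at F = 0, with a hockey-stick
  stock-recruitment relationship R(S) = a·min(S, B_lim), lognormal AR1
  recruitment deviations, and the deterministic closed form
  SSB₀ = a·B_lim·SPR₀ as an exact anchor.
- **Response construction**: instantaneous weight responses W_recr
  (recruit weight vs R/R₀), W_old and W_std (adult and population mean
  weight vs de-circularised SSB_std/SSB₀), and intracohort standardized
  weight increments W_cohort and W_cohort_age (vs the cohort's own
  relative abundance), plus the pruning rules that remove
  assumed-constant weight periods and under-observed series.
- **Inference**: Gaussian linear mixed models with per-stock density
  slopes, stock random effects and AR1 within-group residual correlation,

      Σ_g = τ² z_g z_gᵀ + σ² C(φ),   C(φ)_ij = φ^|t_i − t_j|,

  estimated by maximum likelihood (β and σ² profiled out), compared by
  the delta-AIC rule (Δ > 10 discarded, parsimony tie-break), with
  per-stock Wald slope inference, global-slope models, and residual
  whitening diagnostics — always with and without the AR1 term, because
  the contrast between the two is the scientific point.
- **A synthetic multi-stock generator** with a known injected linear DD
  effect, AR1 year noise and cohort effects, so every stage is testable
  end to end without any external data.

## Worked example

Simulate six stocks with a strong injected compensatory effect
(β = −0.4 on relative density) and run the full pipeline:

```r
library(ddgrowth)

cfg <- generator_config(n_stocks = 6, n_years = 40, beta_dd = -0.4)
sim <- simulate_stock_panel(cfg, seed = 42)
res <- run_dd_pipeline(sim$panel, responses = c("W_recr", "W_old", "W_std"),
                       n_reps = 100, seed = 1)

res$refpts$refpts[, 1:4]
#> # A tibble: 6 × 4
#>   stock    ssb0     r0  spr0
#>   <chr>   <dbl>  <dbl> <dbl>
#> 1 stk01 129374. 18369.  7.02
#> 2 stk02 116272. 17186.  6.78
#> 3 stk03 132186. 19414.  6.71
```

SSB₀ is in tonnes, R₀ in thousands of recruits, SPR₀ in kg per recruit;
each stock's unfished equilibrium is the median over stochastic
projections. The model ladder for the population mean weight W_std is
selected by delta-AIC:

```r
res$models$W_std$selection$report
#> # A tibble: 3 × 7
#>   model          df   AIC logLik delta discarded chosen
#>   <chr>       <dbl> <dbl>  <dbl> <dbl> <lgl>     <lgl>
#> 1 species_ar1    15 -408.   219.  0    FALSE     FALSE
#> 2 ar1            10 -399.   210.  8.36 FALSE     TRUE
#> 3 plain           9 -379.   199. 28.3  TRUE      FALSE
```

The no-AR1 model loses by Δ = 28 (strong residual autocorrelation); among
the supported models the ladder picks the most parsimonious. The global
compensation slope is recovered with the right sign and magnitude —
−0.695 kg of W_std per unit relative density, i.e. ≈ −0.4 after dividing
by the ~1.7 kg mean baseline weight of the averaged ages:

```r
res$globals$W_std$ar1$global
#> # A tibble: 1 × 4
#>   estimate     se     t        p
#>      <dbl>  <dbl> <dbl>    <dbl>
#> 1   -0.695 0.0583 -11.9 5.47e-26
```

and every stock's individual slope is significantly negative
(`summarize_slopes(res$stock_slopes)`: 6/6 negative under both the AR1
and no-AR1 models for this strong effect). On *null* panels with
autocorrelated weight noise the same comparison shows the opposite
pattern — the no-AR1 model flags several times more "significant" stocks
than the AR1 model, whose rate stays near nominal — which is the
cautionary result the package is built to expose.

Plots: `plot_slope_density()` (slope distributions with/without AR1),
`plot_stock_slopes()` (per-stock slopes by taxonomic group),
`autoplot(fit)` (per-stock slope forest plot). Fitted models have
`tidy()` and `glance()` methods.

## Data format

Stocks are exchanged as long CSV, one value per row, with columns
`stock, species, order, year, age, variable, value`, where `variable` is
one of `N` (thousands), `W` (kg), `MAT`, `M`, `F`, plus per-stock
metadata rows `blim` (tonnes) and `plus_group`. `read_stocks()` /
`write_stocks()` round-trip this format losslessly; see
`vignettes/dd-growth-methods.Rmd` for the science and the modelling
choices.
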