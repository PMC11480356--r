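#' Configuration for the synthetic multi-stock generator
#'
#' Bundles the data-generating assumptions behind the analysis: a von
#' Bertalanffy baseline weight-at-age, logistic maturity, hockey-stick
#' recruitment with lognormal AR1 deviations, a fishing history, and a
#' weight process with a linear density effect, AR1 year noise and cohort
#' effects. Growth-curve and noise parameters accept either scalars (shared
#' by all stocks) or vectors of length `n_stocks`.
#'
#' @param n_stocks Number of stocks.
#' @param n_years Series length in years (assessments typically span 25-80).
#' @param ages Integer vector of consecutive ages; first age = recruitment.
#' @param w_inf,k,t0 Von Bertalanffy weight parameters: asymptotic weight
#'   (kg), growth rate (per year) and theoretical age at zero weight;
#'   baseline weight `w_inf * (1 - exp(-k (a - t0)))^3`.
#' @param m_base Natural mortality (per year).
#' @param a50_true,mat_slope Logistic maturity ogive: age at 50% maturity and
#'   steepness, `mat(a) = 1 / (1 + exp(-mat_slope (a - a50_true)))`.
#' @param blim Hockey-stick breakpoint (tonnes); reported as the stock's
#'   biomass limit.
#' @param steepness Unfished replacement ratio `a * SPR0`; the SRR slope is
#'   `a = steepness / SPR0` (thousand recruits per tonne). Must exceed 1 for
#'   a persistent unfished stock.
#' @param sigma_r,rho_r Marginal sd and AR1 coefficient of lognormal
#'   recruitment deviations.
#' @param f_history Shape of the fishing-mortality trajectory:
#'   `"one-way-trip"` ramps linearly from 0.05 to `f_max` (fishing down),
#'   `"constant"` holds `f_max`, `"two-way"` ramps up then halfway back down.
#' @param f_max Peak fishing mortality (per year).
#' @param beta_dd Linear density-dependent growth slope: realized weight is
#'   `W_base(a) * (1 + beta_dd * (D_y - mean(D)))` before noise, where `D_y`
#'   is relative density SSB_y/SSB0 computed with baseline weights.
#'   Negative = compensatory.
#' @param sigma_w,phi_w Marginal sd and AR1 coefficient of the lognormal
#'   year noise shared by all ages of a stock.
#' @param cohort_sd Sd of the lognormal cohort effect shared along cohort
#'   diagonals.
#' @param plus_group Treat the last age as an accumulator?
#' @param start_year First calendar year.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_stocks = 20, n_years = 45, ages = 1:8,
                             w_inf = 3, k = 0.3, t0 = -0.5,
                             m_base = 0.2, a50_true = 2.5, mat_slope = 2,
                             blim = 2e4, steepness = 5,
                             sigma_r = 0.5, rho_r = 0.4,
                             f_history = c("one-way-trip", "constant", "two-way"),
                             f_max = 0.6,
                             beta_dd = 0, sigma_w = 0.08, phi_w = 0.4,
                             cohort_sd = 0.05,
                             plus_group = TRUE, start_year = 1978L) {
  f_history <- match.arg(f_history)
  stopifnot(sigma_r >= 0, abs(rho_r) < 1, sigma_w >= 0, abs(phi_w) < 1,
            cohort_sd >= 0, n_years >= 3, length(ages) >= 2,
            all(diff(ages) == 1))
  structure(list(n_stocks = n_stocks, n_years = n_years, ages = as.integer(ages),
                 w_inf = w_inf, k = k, t0 = t0, m_base = m_base,
                 a50_true = a50_true, mat_slope = mat_slope,
                 blim = blim, steepness = steepness,
                 sigma_r = sigma_r, rho_r = rho_r,
                 f_history = f_history, f_max = f_max,
                 beta_dd = beta_dd, sigma_w = sigma_w, phi_w = phi_w,
                 cohort_sd = cohort_sd, plus_group = plus_group,
                 start_year = as.integer(start_year)),
            class = "generator_config")
}

# per-stock parameter lookup (scalar recycled or vector indexed)
cfg_par <- function(cfg, name, s) {
  v <- cfg[[name]]
  if (length(v) == 1) v else v[[s]]
}

# stationary AR1 series, marginal sd `sdev`
ar1_series <- function(n, sdev, rho) {
  if (sdev == 0) return(numeric(n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sdev)
  if (n > 1) {
    isd <- sdev * sqrt(1 - rho^2)
    for (t in 2:n) x[t] <- rho * x[t - 1] + stats::rnorm(1, 0, isd)
  }
  x
}

# stable per-stock substream seed below 2^31
stock_seed <- function(seed, s) {
  as.integer((as.double(seed) * 1000003 + as.double(s) * 7919) %% 2147483629)
}

#' Simulate a multi-stock assessment panel with known DD growth
#'
#' Forward-projects each stock's numbers-at-age under natural mortality, the
#' configured fishing history and hockey-stick recruitment with lognormal
#' AR1 deviations, starting from the unfished equilibrium age structure.
#' Realized weight-at-age is
#' \deqn{W(a,y) = W_{base}(a)\,\{1 + \beta_{dd}(D_y - \bar D)\}\,
#'       e^{u_y + c_{y-a}}}
#' where \eqn{D_y} is relative density SSB_y/SSB0 computed with baseline
#' (time-constant) weights — so the injected linear effect is exactly the
#' estimand of the de-circularised instantaneous analysis — \eqn{u_y} is
#' AR1(`phi_w`) year noise and \eqn{c} a cohort effect shared along
#' diagonals.
#'
#' @param cfg A [generator_config()].
#' @param seed Master integer seed; each stock draws from a substream derived
#'   by stable hashing of the stock index, so panels are reproducible
#'   independent of stock count.
#' @return A list of class `dd_sim`: `panel` (a [stock_panel()]), `truth`
#'   (per-stock tibble of injected parameters and implied SSB0/R0/SPR0,
#'   with a `collapse` flag when `a * SPR0 <= 1`) and `density` (per stock x
#'   year relative density `d` used for injection).
#' @export
simulate_stock_panel <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "generator_config"))
  ages <- cfg$ages
  A <- length(ages)
  years <- seq(cfg$start_year, length.out = cfg$n_years)
  ny <- cfg$n_years

  orders <- c("Gadiformes", "Pleuronectiformes", "Clupeiformes")
  data_l <- truth_l <- dens_l <- vector("list", cfg$n_stocks)

  for (s in seq_len(cfg$n_stocks)) {
    set.seed(stock_seed(seed, s))
    id <- sprintf("stk%02d", s)
    sp_i <- ((s - 1) %% 6) + 1
    species <- sprintf("species_%02d", sp_i)
    order <- orders[((sp_i - 1) %% length(orders)) + 1]

    w_inf <- cfg_par(cfg, "w_inf", s); kk <- cfg_par(cfg, "k", s)
    t0 <- cfg_par(cfg, "t0", s)
    w_base <- w_inf * (1 - exp(-kk * (ages - t0)))^3
    mat <- 1 / (1 + exp(-cfg$mat_slope * (ages - cfg$a50_true)))
    m <- rep(cfg$m_base, A)
    sel <- 1 / (1 + exp(-2 * (ages - 2)))
    f_y <- switch(cfg$f_history,
      "one-way-trip" = seq(0.05, cfg$f_max, length.out = ny),
      "constant" = rep(cfg$f_max, ny),
      "two-way" = {
        up <- ceiling(0.6 * ny)
        c(seq(0.05, cfg$f_max, length.out = up),
          seq(cfg$f_max, cfg$f_max / 4, length.out = ny - up)[-1],
          cfg$f_max / 4)[1:ny]
      })

    spr0 <- compute_spr0(w_base, mat, m, cfg$plus_group)
    a_srr <- cfg$steepness / spr0
    collapse <- a_srr * spr0 <= 1
    if (collapse)
      warning("stock ", id, ": a * SPR0 <= 1, unfished stock collapses")
    r0 <- a_srr * cfg$blim
    ssb0 <- r0 * spr0
    l0 <- survivorship(m, cfg$plus_group)

    rdev <- ar1_series(ny, cfg$sigma_r, cfg$rho_r)
    N <- matrix(0, A, ny, dimnames = list(age = ages, year = years))
    N[, 1] <- r0 * l0 * exp(rdev[1] * c(1, rep(0, A - 1)))
    ssb_b <- numeric(ny)
    for (y in seq_len(ny)) {
      ssb_b[y] <- sum(N[, y] * mat * w_base)
      if (y < ny) {
        z <- m + sel * f_y[y]
        N[1, y + 1] <- a_srr * min(ssb_b[y], cfg$blim) * exp(rdev[y + 1])
        N[2:A, y + 1] <- N[1:(A - 1), y] * exp(-z[1:(A - 1)])
        if (cfg$plus_group)
          N[A, y + 1] <- N[A, y + 1] + N[A, y] * exp(-z[A])
      }
    }

    d <- ssb_b / ssb0
    dd_fac <- 1 + cfg_par(cfg, "beta_dd", s) * (d - mean(d))
    if (any(dd_fac <= 0)) {
      warning("stock ", id, ": density effect drives weight non-positive; ",
              "clamping at 5% of baseline")
      dd_fac <- pmax(dd_fac, 0.05)
    }
    u <- ar1_series(ny, cfg_par(cfg, "sigma_w", s), cfg$phi_w)
    cohorts <- seq(min(years) - max(ages), max(years) - min(ages))
    ce <- stats::rnorm(length(cohorts), 0, cfg$cohort_sd)
    names(ce) <- cohorts
    eps <- outer(ages, years, function(a, y) ce[as.character(y - a)]) +
      matrix(u, A, ny, byrow = TRUE)
    W <- w_base * sweep(matrix(1, A, ny), 2, dd_fac, `*`) * exp(eps)
    dimnames(W) <- dimnames(N)

    data_l[[s]] <- tibble::tibble(
      stock = id,
      year = rep(years, each = A),
      age = rep(ages, ny),
      N = as.vector(N), W = as.vector(W),
      MAT = rep(mat, ny), M = rep(m, ny),
      F = as.vector(outer(sel, f_y)))
    truth_l[[s]] <- tibble::tibble(
      stock = id, species = species, order = order,
      beta_dd = cfg_par(cfg, "beta_dd", s), phi_w = cfg$phi_w,
      sigma_w = cfg_par(cfg, "sigma_w", s), cohort_sd = cfg$cohort_sd,
      a = a_srr, b = cfg$blim, sigma_r = cfg$sigma_r, rho_r = cfg$rho_r,
      spr0 = spr0, r0 = r0, ssb0 = ssb0,
      w_base_mean_std = mean(w_base[-c(1, if (cfg$plus_group) A)]),
      collapse = collapse)
    dens_l[[s]] <- tibble::tibble(stock = id, year = years, d = d)
  }

  truth <- dplyr::bind_rows(truth_l)
  panel <- stock_panel(
    dplyr::bind_rows(data_l),
    dplyr::transmute(truth, stock = .data$stock, species = .data$species,
                     order = .data$order, blim = cfg$blim,
                     plus_group = cfg$plus_group))
  structure(list(panel = panel, truth = truth,
                 density = dplyr::bind_rows(dens_l), config = cfg),
            class = "dd_sim")
}

#' @export
print.dd_sim <- function(x, ...) {
  cat("<dd_sim> ", nrow(x$truth), " stocks x ", x$config$n_years,
      " years, beta_dd = ",
      paste(unique(x$truth$beta_dd), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Write the named fixture panels used by the test suite
#'
#' Deterministic given `seed`: a null-effect panel, a strong-DD panel, a
#' pathological constant-weight stock and a short series. Each panel is
#' written in the long-CSV interchange format next to a `truth_*.csv`
#' sidecar.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed.
#' @return Named character vector of panel file paths, invisibly.
#' @export
make_fixture_suite <- function(dir, seed = 42) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  specs <- list(
    null = generator_config(n_stocks = 6, n_years = 30),
    strong_dd = generator_config(n_stocks = 6, n_years = 40, beta_dd = -0.5,
                                 sigma_w = 0.05, phi_w = 0.3, cohort_sd = 0),
    constant = generator_config(n_stocks = 1, n_years = 20, beta_dd = 0,
                                sigma_w = 0, cohort_sd = 0),
    short = generator_config(n_stocks = 1, n_years = 4))
  paths <- character(0)
  for (nm in names(specs)) {
    sim <- simulate_stock_panel(specs[[nm]], seed = seed)
    p <- file.path(dir, paste0("panel_", nm, ".csv"))
    write_stocks(sim$panel, p)
    readr::write_csv(sim$truth, file.path(dir, paste0("truth_", nm, ".csv")))
    paths[nm] <- p
  }
  invisible(paths)
}
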