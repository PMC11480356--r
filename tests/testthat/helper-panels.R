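# Shared fixtures, built in code and cached for the run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small noisy panel used across io/response tests
tiny_sim <- function() cached("tiny_sim", {
  simulate_stock_panel(generator_config(n_stocks = 3, n_years = 20), seed = 101)
})

# hand-built two-stock toy panel: 3 ages x 4 years, fully deterministic
toy_panel <- function(mat2 = 0.5) {
  ages <- 1:3; years <- 2001:2004
  grid <- expand.grid(age = ages, year = years)
  mk <- function(id, w_shift) tibble::tibble(
    stock = id, year = grid$year, age = grid$age,
    N = 100 / grid$age + grid$year - 2000,
    W = grid$age + 0.1 * (grid$year - 2000) + w_shift,
    MAT = c(0, mat2, 1)[grid$age],
    M = 0.2, F = 0.1 * grid$age)
  stock_panel(
    dplyr::bind_rows(mk("A", 0), mk("B", 0.5)),
    tibble::tibble(stock = c("A", "B"), species = c("sp1", "sp2"),
                   order = c("Ord1", "Ord2"), blim = 100,
                   plus_group = FALSE))
}

# single-stock panel with an explicit weight matrix (ages x years)
panel_from_W <- function(W, ages = seq_len(nrow(W)),
                         years = 2000 + seq_len(ncol(W)),
                         mat = NULL, plus_group = FALSE, N = NULL) {
  if (is.null(mat)) mat <- pmin(1, (ages - 1) / max(ages - 1))
  grid <- expand.grid(age = seq_along(ages), year = seq_along(years))
  if (is.null(N)) N <- matrix(100, nrow(W), ncol(W))
  stock_panel(
    tibble::tibble(stock = "S", year = years[grid$year], age = ages[grid$age],
                   N = N[cbind(grid$age, grid$year)],
                   W = W[cbind(grid$age, grid$year)],
                   MAT = mat[grid$age], M = 0.2, F = 0.1),
    tibble::tibble(stock = "S", species = "sp", order = "Ord", blim = 100,
                   plus_group = plus_group))
}

# grouped AR1 regression data with known parameters
sim_lmm_data <- function(n_stocks, n_years, beta = -0.3, tau = 0.5,
                         sigma = 0.4, phi = 0.4, beta_sd = 0,
                         x_trend = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(n_stocks), function(g) {
    x <- if (x_trend) seq(1, 0.2, length.out = n_years) +
      stats::rnorm(n_years, 0, 0.05) else stats::rnorm(n_years)
    e <- numeric(n_years)
    e[1] <- stats::rnorm(1, 0, sigma)
    for (t in 2:n_years)
      e[t] <- phi * e[t - 1] + stats::rnorm(1, 0, sigma * sqrt(1 - phi^2))
    bg <- beta + stats::rnorm(1, 0, beta_sd)
    tibble::tibble(stock = sprintf("s%03d", g), year = seq_len(n_years),
                   covariate = x,
                   value = 1 + stats::rnorm(1, 0, tau) + bg * x + e,
                   true_slope = bg)
  })
  dplyr::bind_rows(out)
}
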