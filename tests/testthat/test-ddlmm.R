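# dense multivariate-normal oracle for the block-structured likelihood
dense_loglik <- function(data, beta, sigma2, tau2, phi, random = "intercept",
                         ar_group = NULL) {
  d <- data
  d$..ar <- if (is.null(ar_group)) d$stock else
    paste(d$stock, d[[ar_group]], sep = "\r")
  d <- d[order(d$stock, d$..ar, d$year), ]
  n <- nrow(d)
  X <- cbind(1, vapply(unique(d$stock), function(g)
    d$covariate * (d$stock == g), numeric(n)))
  S <- matrix(0, n, n)
  for (g in unique(d$stock)) {
    i <- which(d$stock == g)
    z <- switch(random, intercept = rep(1, length(i)),
                slope = d$covariate[i])
    C <- matrix(0, length(i), length(i))
    for (a in unique(d$..ar[i])) {
      j <- which(d$..ar[i] == a)
      C[j, j] <- phi^abs(outer(d$year[i][j], d$year[i][j], `-`))
    }
    S[i, i] <- tau2 * outer(z, z) + sigma2 * C
  }
  e <- d$value - X %*% beta
  -0.5 * (n * log(2 * pi) + as.numeric(determinant(S)$modulus) +
            drop(t(e) %*% solve(S) %*% e))
}

test_that("block likelihood equals the dense evaluation on random instances", {
  set.seed(42)
  for (r in 1:60) {
    n_g <- sample(2:4, 1)
    sizes <- sample(3:10, n_g, replace = TRUE)
    d <- dplyr::bind_rows(lapply(seq_len(n_g), function(g) {
      yrs <- sort(sample(1:15, sizes[g]))
      tibble::tibble(stock = paste0("g", g), year = yrs,
                     covariate = stats::rnorm(sizes[g]),
                     value = stats::rnorm(sizes[g]))
    }))
    beta <- stats::rnorm(1 + n_g)
    s2 <- stats::runif(1, 0.2, 2)
    t2 <- stats::runif(1, 0, 1)
    phi <- stats::runif(1, -0.8, 0.8)
    ll <- dd_lmm_loglik(d, beta, s2, t2, phi)
    expect_equal(ll, dense_loglik(d, beta, s2, t2, phi), tolerance = 1e-8)
  }
})

test_that("likelihood reduces to iid normal when phi = 0 and tau2 = 0", {
  set.seed(1)
  d <- tibble::tibble(stock = rep(c("a", "b"), each = 10), year = rep(1:10, 2),
                      covariate = stats::rnorm(20), value = stats::rnorm(20))
  beta <- c(0.2, -0.1, 0.4)
  s2 <- 0.7
  ll <- dd_lmm_loglik(d, beta, s2, 0, 0)
  X <- cbind(1, d$covariate * (d$stock == "a"), d$covariate * (d$stock == "b"))
  mu <- drop(X %*% beta)
  expect_equal(ll, sum(stats::dnorm(d$value, mu, sqrt(s2), log = TRUE)),
               tolerance = 1e-10)
})

test_that("a large random-intercept variance absorbs common shifts", {
  set.seed(2)
  d <- tibble::tibble(stock = rep(c("a", "b"), each = 8), year = rep(1:8, 2),
                      covariate = stats::rnorm(16),
                      value = stats::rnorm(16) - mean(stats::rnorm(16)))
  beta <- c(0, 0.1, -0.1)
  ll1 <- dd_lmm_loglik(d, beta, 1, 1e6, 0)
  d2 <- dplyr::mutate(d, value = value + 5)
  ll2 <- dd_lmm_loglik(d2, beta, 1, 1e6, 0)
  expect_lt(abs(ll1 - ll2), 0.01)
})

test_that("parameter domain violations are rejected", {
  d <- tibble::tibble(stock = "a", year = 1:5, covariate = stats::rnorm(5),
                      value = stats::rnorm(5))
  expect_error(dd_lmm_loglik(d, c(0, 0), 1, 0, 1.2), "domain")
  expect_error(dd_lmm_loglik(d, c(0, 0), -1, 0, 0), "domain")
  expect_error(dd_lmm_loglik(d, c(0, 0), 1, -0.5, 0), "domain")
})

test_that("with phi and tau2 pinned at zero the fit is exactly OLS", {
  set.seed(3)
  d <- tibble::tibble(stock = "s1", year = 1:40,
                      covariate = stats::rnorm(40))
  d$value <- 2 - 0.5 * d$covariate + stats::rnorm(40, 0, 0.3)
  f <- fit_dd_lmm(d, ar1 = FALSE, random = "none")
  ols <- stats::coef(stats::lm(value ~ covariate, d))
  expect_equal(unname(f$beta), unname(ols), tolerance = 1e-6)
  expect_equal(f$per_stock$slope, unname(ols[2]), tolerance = 1e-6)
})

test_that("duplicating every row keeps estimates and shrinks SEs", {
  set.seed(4)
  d <- sim_lmm_data(4, 25, beta = -0.3, tau = 0.3, sigma = 0.4, phi = 0)
  f1 <- fit_dd_lmm(d, ar1 = FALSE, random = "none")
  d2 <- dplyr::bind_rows(d, dplyr::mutate(d, year = year + 0.5))
  f2 <- fit_dd_lmm(d2, ar1 = FALSE, random = "none")
  expect_equal(f2$beta, f1$beta, tolerance = 1e-4)
  expect_equal(f2$se / f1$se, rep(1 / sqrt(2), length(f1$se)),
               tolerance = 0.05, ignore_attr = TRUE)
})

test_that("ML estimates agree with nlme::lme on a shared model", {
  skip_if_not_installed("nlme")
  set.seed(5)
  d <- sim_lmm_data(6, 30, beta = -0.3, tau = 0.4, sigma = 0.35, phi = 0.4,
                    beta_sd = 0.15)
  f <- fit_dd_lmm(d, ar1 = TRUE)
  g <- nlme::lme(value ~ covariate:stock, random = ~1 | stock,
                 correlation = nlme::corAR1(form = ~year | stock),
                 data = d, method = "ML")
  expect_equal(f$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-4)
  expect_equal(f$sigma2, g$sigma^2, tolerance = 1e-3)
  expect_equal(f$phi,
               as.numeric(stats::coef(g$modelStruct$corStruct,
                                      unconstrained = FALSE)),
               tolerance = 1e-3)
  ps <- f$per_stock[order(f$per_stock$stock), ]
  nl <- nlme::fixef(g)[paste0("covariate:stock", ps$stock)]
  expect_equal(ps$slope, unname(nl), tolerance = 1e-3)
})

test_that("simulation recovers mixed-model parameters on average", {
  set.seed(6)
  reps <- 30
  est <- matrix(NA_real_, reps, 3)
  for (r in seq_len(reps)) {
    d <- sim_lmm_data(12, 35, beta = -0.3, tau = 0.5, sigma = 0.4,
                      phi = 0.4, beta_sd = 0)
    f <- fit_dd_lmm(d, ar1 = TRUE)
    est[r, ] <- c(mean(f$per_stock$slope), f$phi, sqrt(f$tau2))
  }
  mc_se <- apply(est, 2, stats::sd) / sqrt(reps)
  expect_lt(abs(mean(est[, 1]) + 0.3), 2.5 * mc_se[1] + 0.01)
  expect_lt(abs(mean(est[, 2]) - 0.4), 2.5 * mc_se[2] + 0.03)
  expect_lt(abs(mean(est[, 3]) - 0.5), 2.5 * mc_se[3] + 0.05)
})

test_that("delta-AIC selection applies discard, parsimony and AIC tie-breaks", {
  mk <- function(aic, df) structure(
    list(aic = aic, df = df, loglik = -(aic - 2 * df) / 2, converged = TRUE),
    class = "dd_lmm")
  # Delta = 12 discarded; then smaller df wins despite higher AIC
  s1 <- select_model(list(m1 = mk(100, 10), m2 = mk(104, 8), m3 = mk(112, 7)))
  expect_equal(s1$chosen, "m2")
  expect_true(s1$report$discarded[s1$report$model == "m3"])
  # single survivor chosen trivially
  s2 <- select_model(list(m1 = mk(100, 5), m2 = mk(150, 3)))
  expect_equal(s2$chosen, "m1")
  # tie on df broken by lower AIC
  s3 <- select_model(list(m1 = mk(100, 5), m2 = mk(109.9, 5)))
  expect_equal(s3$chosen, "m1")
  expect_error(select_model(list(m1 = structure(list(converged = FALSE),
                                               class = "dd_lmm"))),
               "converged")
})

test_that("the global model pools a shared slope and flags its sign", {
  set.seed(7)
  # all stocks share the same slope, tiny noise: global slope recovered and
  # random-slope variance collapses
  d <- sim_lmm_data(8, 25, beta = -0.25, tau = 0, sigma = 0.02, phi = 0,
                    beta_sd = 0)
  g <- fit_global(d, ar1 = FALSE)
  expect_equal(g$global$estimate, -0.25, tolerance = 0.01)
  expect_lt(g$tau2, 0.01)
  # compensatory injection -> negative estimate, significant
  d2 <- sim_lmm_data(10, 30, beta = -0.2, tau = 0.1, sigma = 0.15,
                     phi = 0.3, beta_sd = 0.05)
  g2 <- fit_global(d2, ar1 = TRUE)
  expect_lt(g2$global$estimate, 0)
  expect_lt(g2$global$p, 0.05)
  # heterogeneous slopes: global estimate near the population mean slope
  d3 <- sim_lmm_data(20, 30, beta = -0.2, tau = 0.2, sigma = 0.2,
                     phi = 0, beta_sd = 0.1, seed = 8)
  g3 <- fit_global(d3, ar1 = FALSE)
  expect_lt(abs(g3$global$estimate - mean(unique(d3$true_slope))),
            3 * g3$global$se + 0.02)
})

test_that("residual autocorrelation is seen raw and removed by whitening", {
  set.seed(9)
  d <- sim_lmm_data(10, 60, beta = 0, tau = 0, sigma = 0.5, phi = 0.7)
  f_no <- fit_dd_lmm(d, ar1 = FALSE, random = "none")
  raw <- residual_acf(f_no, max_lag = 3, type = "raw")
  expect_equal(raw$acf[1], 0.7, tolerance = 0.12)
  f_yes <- fit_dd_lmm(d, ar1 = TRUE, random = "none", fix_tau2 = 0)
  wh <- residual_acf(f_yes, max_lag = 3, type = "whitened")
  expect_lt(abs(wh$acf[1]), wh$band[1] * 1.5)
})

test_that("likelihood at the optimum dominates a post-hoc parameter grid", {
  set.seed(10)
  d <- sim_lmm_data(5, 25, beta = -0.3, tau = 0.4, sigma = 0.4, phi = 0.3)
  f <- fit_dd_lmm(d, ar1 = TRUE)
  for (phi in c(-0.4, 0, 0.2, 0.5)) {
    for (lam in c(0.1, 0.5, 2)) {
      alt <- ddgrowth:::profiled_nll(f$structures, lam, phi)
      expect_gte(f$loglik + 1e-6, -alt$nll)
    }
  }
})
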