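test_that("A50 interpolates the maturity ogive", {
  # exact crossing at an observed age
  M1 <- matrix(rep(c(0, 0.5, 1), 4), 3, 4)
  expect_equal(compute_a50(M1, ages = 1:3), 2)
  # linear interpolation between bracketing ages
  M2 <- matrix(rep(c(0.2, 0.8), 3), 2, 3)
  expect_equal(compute_a50(M2, ages = 2:3), 2.5)
  # mean over years of per-year crossings
  M3 <- cbind(c(0, 0.5, 1), c(0, 0, 0.5))
  expect_equal(compute_a50(M3, ages = 1:3), 2.5)
  # first age already mature counts as the first age
  M4 <- matrix(rep(c(0.7, 0.9), 2), 2, 2)
  expect_equal(compute_a50(M4, ages = 3:4), 3)
  # never reaching 0.5 anywhere is an error
  expect_error(compute_a50(matrix(0.2, 2, 2), ages = 1:2), "A50")
  # years that never mature are skipped with a warning
  M5 <- cbind(c(0, 1), c(0.1, 0.3))
  expect_warning(a <- compute_a50(M5, ages = 1:2), "skipped")
  expect_equal(a, 1.5)
})

test_that("weight responses follow their age-window definitions", {
  # ages 1-5 plus group, W constant in year: hand values
  W <- matrix(rep(c(1, 2, 3, 4, 9), 6), 5, 6)
  W <- W * (1 + 0.02 * matrix(0:5, 5, 6, byrow = TRUE))  # avoid constancy
  mat <- c(0, 0.2, 0.6, 1, 1)    # crosses 0.5 between ages 2 and 3 -> 2.75
  p <- panel_from_W(W, ages = 1:5, mat = mat, plus_group = TRUE)
  r <- compute_weight_responses(p, "S")
  y1 <- dplyr::filter(r, year == 2001)
  expect_equal(y1$value[y1$response == "W_std"], mean(c(2, 3, 4)))
  expect_equal(y1$value[y1$response == "W_recr"], 1)
  # a50 = 2.75 -> ages {3,4,5} strictly above
  expect_equal(y1$value[y1$response == "W_old"], mean(c(3, 4, 9)))

  # supplying a50 directly follows the strict "above A50" rule
  r2 <- compute_weight_responses(p, "S", a50 = 2.5)
  y2 <- dplyr::filter(r2, year == 2001)
  expect_equal(y2$value[y2$response == "W_old"], mean(c(3, 4, 9)))
  # W_recr does not depend on a50
  expect_equal(y2$value[y2$response == "W_recr"], 1)

  # a50 at the top of the age range leaves W_old undefined
  r3 <- compute_weight_responses(p, "S", a50 = 5)
  expect_false("W_old" %in% r3$response)
})

test_that("standardized SSB removes weight circularity", {
  # constant weights: SSB_std equals ordinary SSB
  W <- matrix(rep(c(1, 2), 4), 2, 4)
  N <- matrix(c(10, 5), 2, 4) * matrix(rep(1:4, each = 2), 2, 4)
  p <- panel_from_W(W, ages = 1:2, mat = c(1, 1), N = N)
  sm <- ddgrowth:::stock_matrices(p, "S")
  s <- compute_standardized_ssb(p, "S")
  expect_equal(s$ssb_std, unname(colSums(sm$N * sm$MAT * sm$W)))

  # one age, N = (10, 10), W = (1, 3): cross-year mean weight 2
  p2 <- panel_from_W(matrix(c(1, 1, 3, 3), 2, 2), ages = 1:2,
                     mat = c(1, 1), N = matrix(10, 2, 2))
  s2 <- compute_standardized_ssb(p2, "S")
  expect_equal(s2$ssb_std, c(40, 40))

  # linear in N
  p3 <- p
  p3$data$N <- p3$data$N * 2
  expect_equal(compute_standardized_ssb(p3, "S")$ssb_std, 2 * s$ssb_std)
})

test_that("cohort increments standardize exactly along diagonals", {
  sim <- tiny_sim()
  inc <- compute_cohort_increments(sim$panel, "stk01")
  moments <- inc |>
    dplyr::group_by(age_from) |>
    dplyr::summarise(m = mean(z), s = stats::sd(z))
  expect_equal(moments$m, rep(0, nrow(moments)), tolerance = 1e-12)
  expect_equal(moments$s, rep(1, nrow(moments)), tolerance = 1e-12)

  # diagonal indexing: increment of cohort c at a->a+1 uses
  # W(a+1, c+a+1) - W(a, c+a)
  sm <- ddgrowth:::stock_matrices(sim$panel, "stk01")
  row <- dplyr::filter(inc, age_from == 2, cohort == 1990)
  expect_equal(row$d_w, sm$W["3", "1993"] - sm$W["2", "1992"])

  # location-scale: increments {0.5, 1.0, 1.5} across cohorts -> z {-1, 0, 1}
  W <- matrix(1, 3, 4)
  W[2, 2:4] <- W[1, 1:3] + c(0.5, 1.0, 1.5)
  W[1, ] <- c(1, 1.01, 1.02, 1.03)
  W[3, ] <- 9
  p <- panel_from_W(W)
  z <- compute_cohort_increments(p, "S") |> dplyr::filter(age_from == 1)
  expect_equal(sort(z$z), c(-1, 0, 1))

  # zero-variance transitions are dropped with a warning
  Wc <- matrix(rep(c(1, 2, 4), 5), 3, 5)
  Wc[1, ] <- Wc[1, ] + 0.1 * (1:5)^2   # transition 1->2 varies, 2->3 constant
  pc <- panel_from_W(Wc)
  expect_warning(ic <- compute_cohort_increments(pc, "S"), "constant")
  expect_false(2 %in% ic$age_from)
})

test_that("cohort-mean increments use the pre-maturation window", {
  inc <- tibble::tibble(stock = "S", cohort = rep(1:3, 2),
                        age_from = rep(1:2, each = 3),
                        age_to = rep(2:3, each = 3),
                        d_w = 0, z = c(0.4, 1, -1, -0.2, 2, -2))
  rel_r <- tibble::tibble(cohort = 1:3, rel_r = c(1, 0.5, 2))
  # a50 = 3: both transitions eligible; cohort 1 mean of (0.4, -0.2)
  w3 <- assemble_wcohort(inc, a50 = 3, rel_r = rel_r)
  expect_equal(w3$w_cohort[w3$cohort == 1], 0.1)
  # a50 = 1.4: only the transition ending at age 2 eligible
  w14 <- assemble_wcohort(inc, a50 = 1.4, rel_r = rel_r)
  expect_equal(w14$w_cohort, c(0.4, 1, -1))
  # cohorts without recruitment are skipped
  w_miss <- assemble_wcohort(inc, a50 = 3, rel_r = rel_r[1:2, ])
  expect_equal(sort(unique(w_miss$cohort)), 1:2)
})

test_that("per-age increments pair with prior-year relative abundance", {
  sim <- tiny_sim()
  inc <- compute_cohort_increments(sim$panel, "stk01")
  sm <- ddgrowth:::stock_matrices(sim$panel, "stk01")
  n0 <- tibble::tibble(age = sm$ages, n0 = sm$N[, 1])  # any reference works
  out <- assemble_wcohort_age(inc, sim$panel, "stk01", n0)
  # N(a, y) = N0(a) -> covariate 1 by construction in year 1 cells
  first_year_rows <- dplyr::filter(out, cohort + age_from == sm$years[1])
  expect_equal(first_year_rows$rel_n, rep(1, nrow(first_year_rows)),
               ignore_attr = TRUE)
  # halving N0 doubles the covariate (linearity)
  out2 <- assemble_wcohort_age(inc, sim$panel, "stk01",
                               dplyr::mutate(n0, n0 = n0 / 2))
  expect_equal(out2$rel_n, out$rel_n * 2)
})

test_that("response panels pair each response with its covariate", {
  sim <- tiny_sim()
  rp <- compute_reference_points(sim$panel, n_reps = 20, seed = 8)
  resp <- build_response_panel(sim$panel, rp)
  expect_setequal(unique(resp$response), c("W_recr", "W_old", "W_std"))
  expect_true(all(resp$covariate_name[resp$response == "W_recr"] == "R/R0"))
  expect_true(all(resp$covariate_name[resp$response != "W_recr"] ==
                    "SSB_std/SSB0"))
  expect_true(all(resp$covariate >= 0))
  # W_std and W_old are N-invariant: perturbing N leaves values unchanged
  pert <- sim$panel
  pert$data$N <- pert$data$N * stats::runif(nrow(pert$data), 0.5, 2)
  resp2 <- build_response_panel(pert, rp)
  a <- dplyr::filter(resp, response == "W_std") |>
    dplyr::arrange(stock, year)
  b <- dplyr::filter(resp2, response == "W_std") |>
    dplyr::arrange(stock, year)
  expect_equal(a$value, b$value)
})
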