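#' Age at 50% maturity from a maturity ogive
#'
#' For each year, the fractional age at which the ogive first crosses 0.5,
#' by linear interpolation between the bracketing ages; years whose first
#' age is already >= 0.5 mature contribute the first age, and years never
#' reaching 0.5 are skipped with a warning. The result is the mean over
#' contributing years.
#'
#' @param MAT Age x year matrix of proportion mature.
#' @param ages Integer ages matching the rows of `MAT`.
#' @return A50 as a fractional age.
#' @export
compute_a50 <- function(MAT, ages = as.integer(rownames(MAT))) {
  stopifnot(length(ages) == nrow(MAT))
  non_mono <- sum(apply(MAT, 2, function(m) any(diff(m[!is.na(m)]) < -1e-12)))
  if (non_mono > 0)
    warning(non_mono, " year(s) have a non-monotone maturity ogive")
  per_year <- apply(MAT, 2, function(m) {
    ok <- !is.na(m)
    a <- ages[ok]; mm <- m[ok]
    if (!length(mm) || max(mm) < 0.5) return(NA_real_)
    if (mm[1] >= 0.5) return(a[1])
    i <- which(mm >= 0.5)[1]
    a[i - 1] + (0.5 - mm[i - 1]) / (mm[i] - mm[i - 1]) * (a[i] - a[i - 1])
  })
  if (all(is.na(per_year)))
    stop("maturity never reaches 0.5 in any year; A50 undefined")
  if (anyNA(per_year))
    warning(sum(is.na(per_year)), " year(s) never reach 50% maturity; skipped")
  mean(per_year, na.rm = TRUE)
}

#' Annual weight responses for one stock
#'
#' Builds the three instantaneous responses: `W_recr`, the weight of the
#' first (recruitment) age class; `W_old`, the unweighted mean weight over
#' ages strictly above A50; and `W_std`, the unweighted mean over all ages
#' except the first and (for plus-group stocks) the last. Averages are not
#' abundance-weighted. A response needing at least two ages that has fewer
#' is skipped; `W_old` is skipped entirely when A50 is at or above the
#' oldest age.
#'
#' @param panel A `stock_panel`.
#' @param stock Stock id.
#' @param a50 Fractional A50; computed from the stock's ogive when `NULL`.
#' @return Tibble (stock, year, response, value).
#' @export
compute_weight_responses <- function(panel, stock, a50 = NULL) {
  sm <- stock_matrices(panel, stock)
  if (is.null(a50))
    a50 <- tryCatch(compute_a50(sm$MAT, sm$ages), error = function(e) NA_real_)
  ra <- response_ages(sm, a50 = if (is.na(a50)) NULL else a50)
  rows <- list()
  add <- function(resp, ages, min_ages) {
    if (is.null(ages) || length(ages) < min_ages) return()
    Wsub <- sm$W[as.character(ages), , drop = FALSE]
    rows[[resp]] <<- tibble::tibble(
      stock = sm$stock, year = sm$years, response = resp,
      value = unname(colMeans(Wsub, na.rm = TRUE)))
  }
  add("W_recr", ra$W_recr, 1)
  add("W_old", ra$W_old, 2)
  add("W_std", ra$W_std, 2)
  out <- dplyr::bind_rows(rows)
  out[is.finite(out$value), ]
}

#' De-circularized spawning biomass
#'
#' Annual weight responses are not independent of same-year SSB, which is
#' itself computed from weight-at-age. The standardized SSB removes the
#' circularity by valuing abundance with the cross-year mean weight-at-age:
#' \deqn{SSB_{std}(y) = \sum_a N(a,y)\,MAT(a,y)\,\bar W(a)}.
#'
#' @param panel A `stock_panel`.
#' @param stock Stock id.
#' @return Tibble (stock, year, ssb_std), in tonnes.
#' @export
compute_standardized_ssb <- function(panel, stock) {
  sm <- stock_matrices(panel, stock)
  w_bar <- rowMeans(sm$W, na.rm = TRUE)
  tibble::tibble(stock = sm$stock, year = sm$years,
                 ssb_std = unname(colSums(sm$N * sm$MAT * w_bar, na.rm = TRUE)))
}

#' Standardized intracohort weight increments
#'
#' Along each cohort diagonal the weight increment between consecutive ages
#' is \eqn{\Delta W(a,c) = W(a+1, c+a+1) - W(a, c+a)} (cohort = year - age).
#' Increments are standardized per age transition across cohorts:
#' \eqn{z = (\Delta W - \bar{\Delta W}) / sd(\Delta W)} (sample sd), so each
#' transition has mean 0 and sd 1 over cohorts. Transitions observed for
#' fewer than 3 cohorts are dropped, as are zero-variance transitions
#' (constant increments carry no signal); the transition into a plus-group
#' age is excluded because the accumulator weight mixes cohorts.
#'
#' @param panel A `stock_panel`.
#' @param stock Stock id.
#' @return Tibble (stock, cohort, age_from, age_to, d_w, z).
#' @export
compute_cohort_increments <- function(panel, stock) {
  sm <- stock_matrices(panel, stock)
  ages <- sm$ages
  last_true_age <- if (sm$plus_group) ages[length(ages) - 1] else
    ages[length(ages)]
  rows <- list()
  for (a in ages[ages < last_true_age]) {
    i <- match(a, ages)
    w0 <- sm$W[i, ]
    w1 <- sm$W[i + 1, ]
    ny <- length(sm$years)
    dw <- w1[-1] - w0[-ny]            # increment completed in year y+1
    cohort <- sm$years[-ny] - a
    ok <- is.finite(dw)
    if (sum(ok) < 3) next
    s <- stats::sd(dw[ok])
    if (s == 0) {
      warning("stock ", stock, ": constant increments at transition ",
              a, "->", a + 1, "; dropped")
      next
    }
    z <- (dw - mean(dw[ok])) / s
    rows[[length(rows) + 1]] <- tibble::tibble(
      stock = sm$stock, cohort = cohort[ok],
      age_from = a, age_to = a + 1L,
      d_w = unname(dw[ok]), z = unname(z[ok]))
  }
  if (!length(rows))
    return(tibble::tibble(stock = character(), cohort = integer(),
                          age_from = integer(), age_to = integer(),
                          d_w = double(), z = double()))
  dplyr::bind_rows(rows)
}

#' Cohort-mean pre-maturation increments versus cohort recruitment
#'
#' `W_cohort(c)` averages the standardized increments of cohort `c` over the
#' transitions completed at or before maturation (terminal age <=
#' `ceiling(a50)`), and pairs it with the cohort's relative recruitment
#' strength R/R0, where R is the cohort's abundance at the recruitment age.
#'
#' @param increments Output of [compute_cohort_increments()].
#' @param a50 Fractional A50 for the stock.
#' @param rel_r Tibble (cohort, rel_r) of relative recruitment per cohort;
#'   cohorts without a value are skipped.
#' @return Tibble (stock, cohort, w_cohort, rel_r).
#' @export
assemble_wcohort <- function(increments, a50, rel_r) {
  elig <- dplyr::filter(increments, .data$age_to <= ceiling(a50))
  if (!nrow(elig))
    return(tibble::tibble(stock = character(), cohort = integer(),
                          w_cohort = double(), rel_r = double()))
  elig |>
    dplyr::group_by(.data$stock, .data$cohort) |>
    dplyr::summarise(w_cohort = mean(.data$z), .groups = "drop") |>
    dplyr::inner_join(rel_r, by = "cohort")
}

#' Per-age increments versus prior-year age-class abundance
#'
#' Each standardized increment for transition `a -> a+1` of cohort `c`
#' (completed in year `c + a + 1`) is paired with the relative abundance of
#' the age class the year before the increment completes:
#' `N(a, c + a) / N0(a)`, the unfished expectation supplying the
#' denominator.
#'
#' @param increments Output of [compute_cohort_increments()].
#' @param panel A `stock_panel`.
#' @param stock Stock id.
#' @param n0_at_age Tibble (age, n0) of unfished numbers-at-age.
#' @return Tibble (stock, cohort, age_from, z, rel_n). Rows with `n0 = 0`
#'   are skipped (reported via warning).
#' @export
assemble_wcohort_age <- function(increments, panel, stock, n0_at_age) {
  if (!nrow(increments))
    return(tibble::tibble(stock = character(), cohort = integer(),
                          age_from = integer(), z = double(),
                          rel_n = double()))
  sm <- stock_matrices(panel, stock)
  out <- increments |>
    dplyr::mutate(year_before = .data$cohort + .data$age_from) |>
    dplyr::left_join(n0_at_age, by = c(age_from = "age")) |>
    dplyr::mutate(
      n_obs = unname(sm$N[cbind(match(.data$age_from, sm$ages),
                                match(.data$year_before, sm$years))]),
      rel_n = .data$n_obs / .data$n0)
  bad <- !is.na(out$n0) & out$n0 == 0
  if (any(bad))
    warning(sum(bad), " increment row(s) skipped: N0 = 0 at their age")
  out <- out[!bad & is.finite(out$rel_n), ]
  dplyr::select(out, "stock", "cohort", "age_from", "z", "rel_n")
}

# relative recruitment per cohort for one stock: R at the recruitment age in
# the cohort's recruitment year, over R0
cohort_rel_r <- function(sm, r0) {
  rec_age <- sm$ages[1]
  tibble::tibble(cohort = sm$years - rec_age,
                 rel_r = unname(sm$N[1, ] / r0))
}

#' Build the instantaneous response panel
#'
#' Assembles per stock x year rows of the three weight responses with their
#' density covariates: `W_recr` is paired with relative recruitment
#' `R_y / R0` (recruitment = first-age abundance in year y), `W_old` and
#' `W_std` with de-circularized relative biomass `SSB_std(y) / SSB0`.
#' Constant-weight exclusions from [prune_constant_periods()] are applied,
#' then stock x response groups with fewer than `min_obs` usable years are
#' dropped.
#'
#' @param panel A `stock_panel`.
#' @param refpts A `ref_points_set` from [compute_reference_points()], or a
#'   tibble with columns `stock`, `ssb0`, `r0`.
#' @param prune Optional `dd_prune`; computed from `panel` when `NULL`.
#' @param min_obs Minimum usable years per stock x response (default 5).
#' @return Tibble (stock, species, year, response, value, covariate_name,
#'   covariate).
#' @export
build_response_panel <- function(panel, refpts, prune = NULL, min_obs = 5) {
  rp <- if (inherits(refpts, "ref_points_set")) refpts$refpts else refpts
  if (is.null(prune)) prune <- prune_constant_periods(panel)
  rows <- list()
  for (id in stock_ids(panel)) {
    sm <- stock_matrices(panel, id)
    r <- rp[rp$stock == id, ]
    if (!nrow(r)) next
    resp <- compute_weight_responses(panel, id)
    if (!nrow(resp)) next
    ssb <- compute_standardized_ssb(panel, id)
    rel_r <- tibble::tibble(year = sm$years, rr = unname(sm$N[1, ] / r$r0))
    resp <- resp |>
      dplyr::left_join(ssb[, c("year", "ssb_std")], by = "year") |>
      dplyr::left_join(rel_r, by = "year") |>
      dplyr::mutate(
        covariate_name = ifelse(.data$response == "W_recr",
                                "R/R0", "SSB_std/SSB0"),
        covariate = ifelse(.data$response == "W_recr",
                           .data$rr, .data$ssb_std / r$ssb0)) |>
      dplyr::select("stock", "year", "response", "value",
                    "covariate_name", "covariate")
    rows[[id]] <- resp
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(out)
  out <- dplyr::anti_join(out, prune$exclusions,
                          by = c("stock", "response", "year"))
  out <- filter_min_obs(out, min_obs = min_obs)
  dplyr::left_join(out, panel$meta[, c("stock", "species", "order")],
                   by = "stock") |>
    dplyr::select("stock", "species", "order", "year", "response",
                  "value", "covariate_name", "covariate")
}

#' Build the intracohort panels
#'
#' Computes standardized cohort increments per stock and assembles both
#' intracohort datasets: `w_cohort` (cohort-mean pre-maturation increment
#' vs. R/R0 of the cohort) and `w_cohort_age` (per-transition increment vs.
#' lagged N/N0 of the age class).
#'
#' @inheritParams build_response_panel
#' @param min_obs Minimum rows per stock in each panel (default 5).
#' @return List of tibbles `w_cohort` and `w_cohort_age`, each with species
#'   and order labels attached.
#' @export
build_cohort_panels <- function(panel, refpts, min_obs = 5) {
  rp <- if (inherits(refpts, "ref_points_set")) refpts$refpts else refpts
  n0 <- if (inherits(refpts, "ref_points_set")) refpts$n0 else
    attr(refpts, "n0")
  wc <- list(); wca <- list()
  for (id in stock_ids(panel)) {
    sm <- stock_matrices(panel, id)
    r <- rp[rp$stock == id, ]
    if (!nrow(r)) next
    inc <- compute_cohort_increments(panel, id)
    if (!nrow(inc)) next
    a50 <- tryCatch(compute_a50(sm$MAT, sm$ages), error = function(e) NA_real_)
    if (!is.na(a50))
      wc[[id]] <- assemble_wcohort(inc, a50, cohort_rel_r(sm, r$r0))
    if (!is.null(n0)) {
      n0_s <- n0[n0$stock == id, c("age", "n0")]
      if (nrow(n0_s))
        wca[[id]] <- assemble_wcohort_age(inc, panel, id, n0_s)
    }
  }
  lab <- panel$meta[, c("stock", "species", "order")]
  keep_min <- function(x) {
    if (!nrow(x)) return(x)
    x |>
      dplyr::group_by(.data$stock) |>
      dplyr::filter(dplyr::n() >= min_obs) |>
      dplyr::ungroup() |>
      dplyr::left_join(lab, by = "stock")
  }
  list(w_cohort = keep_min(dplyr::bind_rows(wc)),
       w_cohort_age = keep_min(dplyr::bind_rows(wca)))
}

#' Extract model-ready data for one response
#'
#' Reshapes a response panel (or cohort panel) into the column layout the
#' mixed-model fitters expect: `stock`, `species`, `value`, `covariate`,
#' `year` (the AR1 ordering variable) and, for per-age intracohort data,
#' `transition` as the AR1 sub-group.
#'
#' @param x A response panel from [build_response_panel()] or a tibble from
#'   [build_cohort_panels()].
#' @param response For response panels: one of `"W_recr"`, `"W_old"`,
#'   `"W_std"`; for cohort panels: `"W_cohort"` or `"W_cohort_age"`.
#' @return Tibble ready for [fit_dd_lmm()] / [fit_dd_models()].
#' @export
model_data <- function(x, response) {
  if (response %in% c("W_recr", "W_old", "W_std")) {
    x |>
      dplyr::filter(.data$response == !!response) |>
      dplyr::transmute(stock = .data$stock, species = .data$species,
                       year = .data$year, value = .data$value,
                       covariate = .data$covariate)
  } else if (response == "W_cohort") {
    dplyr::transmute(x, stock = .data$stock, species = .data$species,
                     year = .data$cohort, value = .data$w_cohort,
                     covariate = .data$rel_r)
  } else if (response == "W_cohort_age") {
    dplyr::transmute(x, stock = .data$stock, species = .data$species,
                     year = .data$cohort,
                     transition = paste0("t", .data$age_from),
                     value = .data$z, covariate = .data$rel_n)
  } else stop("unknown response: ", response)
}
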