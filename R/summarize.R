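#' Sign / significance frequency table of per-stock slopes
#'
#' Counts, percentages and mean coefficients of per-stock density slopes by
#' response, model variant (AR1 / no-AR1) and slope sign, over all analysed
#' stocks and over the significant-only subset. Percentages are always
#' relative to the number of analysed stocks for that response x model, so
#' within the `all` stratum the negative and positive percentages sum to
#' 100. The mean coefficient of an empty cell is reported as `NA`.
#'
#' @param slopes Tibble with columns `response`, `model`, `stock`, `slope`,
#'   `p` (e.g. assembled from `dd_lmm$per_stock` tables).
#' @param alpha Significance level (default 0.05).
#' @return Tibble (response, model, significance, sign, n, percent,
#'   mean_coef).
#' @export
summarize_slopes <- function(slopes, alpha = 0.05) {
  if (!nrow(slopes))
    return(tibble::tibble(response = character(), model = character(),
                          significance = character(), sign = character(),
                          n = integer(), percent = double(),
                          mean_coef = double()))
  one_stratum <- function(d, label) {
    tot <- d |> dplyr::count(.data$response, .data$model, name = "n_analysed")
    kept <- if (label == "all") d else dplyr::filter(d, .data$p < alpha)
    grid <- tidyr::expand_grid(
      dplyr::distinct(d, .data$response, .data$model),
      sign = c("neg", "pos"))
    kept |>
      dplyr::mutate(sign = ifelse(.data$slope < 0, "neg", "pos")) |>
      dplyr::group_by(.data$response, .data$model, .data$sign) |>
      dplyr::summarise(n = dplyr::n(), mean_coef = mean(.data$slope),
                       .groups = "drop") |>
      dplyr::right_join(grid, by = c("response", "model", "sign")) |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
      dplyr::left_join(tot, by = c("response", "model")) |>
      dplyr::mutate(significance = label,
                    percent = round(100 * .data$n / .data$n_analysed)) |>
      dplyr::select("response", "model", "significance", "sign",
                    "n", "percent", "mean_coef")
  }
  dplyr::bind_rows(one_stratum(slopes, "all"),
                   one_stratum(slopes, paste0("p<", alpha))) |>
    dplyr::arrange(.data$significance, .data$model, .data$response,
                   .data$sign)
}

#' Slope summaries stratified by taxonomic order
#'
#' [summarize_slopes()] within each taxonomic group, plus the raw slope
#' lists per group for density plots. Stocks without a label fall into
#' group `"unknown"`.
#'
#' @param slopes As in [summarize_slopes()].
#' @param orders Tibble (stock, order) of group labels.
#' @param alpha Significance level.
#' @return List with `table` (grouped frequency table) and `slopes` (input
#'   rows with the group label attached).
#' @export
group_summaries <- function(slopes, orders, alpha = 0.05) {
  lab <- slopes |>
    dplyr::left_join(orders, by = "stock") |>
    dplyr::mutate(order = dplyr::coalesce(.data$order, "unknown"))
  tab <- lab |>
    dplyr::group_by(.data$order) |>
    dplyr::group_modify(~summarize_slopes(.x, alpha = alpha)) |>
    dplyr::ungroup()
  list(table = tab, slopes = lab)
}

#' Run the full DD-growth analysis pipeline
#'
#' Orchestrates every stage on a stock panel: constant-period pruning,
#' reference points (SSB0, R0, SPR0, N0-at-age), response-panel assembly,
#' the stock-level model ladder with delta-AIC selection, global-slope
#' models with and without AR1, per-stock slope extraction for both AR1
#' variants, and the frequency summaries. Optionally writes every table as
#' CSV to `out_dir`.
#'
#' @param panel A `stock_panel` (e.g. from [read_stocks()] or
#'   [simulate_stock_panel()]).
#' @param responses Which responses to analyse (any of `W_recr`, `W_old`,
#'   `W_std`, `W_cohort`, `W_cohort_age`).
#' @param n_reps Equilibrium simulation replicates per stock.
#' @param min_obs Minimum usable observations per stock x response.
#' @param seed Seed for the equilibrium simulations.
#' @param out_dir Optional output directory for CSV artifacts.
#' @param alpha Significance level for the summaries.
#' @return A list of class `dd_pipeline`: `refpts`, `response_panel`,
#'   `cohort_panels`, per-response `models` (fits + selection report),
#'   `globals`, `stock_slopes`, `slope_summary`, `group_summary`.
#' @export
run_dd_pipeline <- function(panel,
                            responses = c("W_recr", "W_old", "W_std",
                                          "W_cohort", "W_cohort_age"),
                            n_reps = 100, min_obs = 5, seed = 1,
                            out_dir = NULL, alpha = 0.05) {
  responses <- match.arg(responses, several.ok = TRUE)
  refpts <- compute_reference_points(panel, n_reps = n_reps, seed = seed)
  prune <- prune_constant_periods(panel)
  resp_panel <- build_response_panel(panel, refpts, prune = prune,
                                     min_obs = min_obs)
  cohort <- if (any(c("W_cohort", "W_cohort_age") %in% responses))
    build_cohort_panels(panel, refpts, min_obs = min_obs) else NULL

  models <- list(); globals <- list(); slopes <- list()
  for (resp in responses) {
    md <- switch(resp,
                 W_cohort = model_data(cohort$w_cohort, resp),
                 W_cohort_age = model_data(cohort$w_cohort_age, resp),
                 model_data(resp_panel, resp))
    if (!nrow(md) || length(unique(md$stock)) < 2) next
    arg <- if (resp == "W_cohort_age") "transition" else NULL
    fits <- fit_dd_models(md, ar_group = arg)
    sel <- select_model(fits)
    models[[resp]] <- list(fits = fits, selection = sel)
    globals[[resp]] <- list(
      ar1 = fit_global(md, ar_group = arg, ar1 = TRUE),
      no_ar1 = fit_global(md, ar_group = arg, ar1 = FALSE))
    ps <- function(fit, lab)
      dplyr::mutate(fit$per_stock, response = resp, model = lab)
    slopes[[resp]] <- dplyr::bind_rows(
      ps(fits$ar1, "AR1"), ps(fits$plain, "no-AR1"))
  }
  stock_slopes <- dplyr::bind_rows(slopes)
  slope_summary <- summarize_slopes(stock_slopes, alpha = alpha)
  group_summary <- group_summaries(
    stock_slopes, dplyr::distinct(panel$meta[, c("stock", "order")]),
    alpha = alpha)

  out <- structure(list(
    refpts = refpts, prune = prune, response_panel = resp_panel,
    cohort_panels = cohort, models = models, globals = globals,
    stock_slopes = stock_slopes, slope_summary = slope_summary,
    group_summary = group_summary,
    settings = list(responses = responses, n_reps = n_reps,
                    min_obs = min_obs, seed = seed, alpha = alpha)),
    class = "dd_pipeline")
  if (!is.null(out_dir)) write_pipeline_csvs(out, out_dir)
  out
}

#' @export
print.dd_pipeline <- function(x, ...) {
  cat("<dd_pipeline> ", nrow(x$refpts$refpts), " stocks; responses: ",
      paste(names(x$models), collapse = ", "), "\n", sep = "")
  invisible(x)
}

write_pipeline_csvs <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(x$refpts$refpts, file.path(out_dir, "refpts.csv"))
  readr::write_csv(x$refpts$n0, file.path(out_dir, "n0_at_age.csv"))
  readr::write_csv(x$response_panel, file.path(out_dir, "responses.csv"))
  model_table <- dplyr::bind_rows(lapply(names(x$models), function(r)
    dplyr::mutate(x$models[[r]]$selection$report, response = r,
                  .before = 1)))
  readr::write_csv(model_table, file.path(out_dir, "model_table.csv"))
  readr::write_csv(x$stock_slopes, file.path(out_dir, "stock_slopes.csv"))
  readr::write_csv(x$slope_summary, file.path(out_dir, "slope_summary.csv"))
  readr::write_csv(x$group_summary$table,
                   file.path(out_dir, "group_summary.csv"))
  if (!is.null(x$cohort_panels)) {
    readr::write_csv(x$cohort_panels$w_cohort,
                     file.path(out_dir, "w_cohort.csv"))
    readr::write_csv(x$cohort_panels$w_cohort_age,
                     file.path(out_dir, "w_cohort_age.csv"))
  }
  invisible(out_dir)
}
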