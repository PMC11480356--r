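#' Stock panel objects
#'
#' A `stock_panel` bundles the age-structured assessment output for one or
#' more stocks: a long cell table (one row per stock x year x age) carrying
#' numbers-at-age `N` (thousands), mean individual weight-at-age `W` (kg),
#' proportion mature `MAT`, natural mortality `M` and fishing mortality `F`
#' (both per year), plus a per-stock metadata table with the biomass limit
#' `blim` (tonnes), a plus-group flag and species / taxonomic-order labels.
#'
#' @param data Tibble with columns `stock`, `year`, `age`, `N`, `W`, `MAT`,
#'   `M`, `F`. Missing cells are `NA`, never zero.
#' @param meta Tibble with columns `stock`, `species`, `order`, `blim`,
#'   `plus_group`.
#' @return A validated object of class `stock_panel` (a list with elements
#'   `data` and `meta`).
#' @export
stock_panel <- function(data, meta) {
  data <- tibble::as_tibble(data)
  meta <- tibble::as_tibble(meta)
  x <- structure(list(data = data, meta = meta), class = "stock_panel")
  validate_stock_panel(x)
  x
}

#' @export
print.stock_panel <- function(x, ...) {
  cat("<stock_panel> ", nrow(x$meta), " stock(s), ",
      nrow(x$data), " cells\n", sep = "")
  rng <- range(x$data$year)
  cat("  years ", rng[1], "-", rng[2], ", ages ",
      min(x$data$age), "-", max(x$data$age), "\n", sep = "")
  invisible(x)
}

#' @export
#' @method as_tibble stock_panel
#' @importFrom tibble as_tibble
as_tibble.stock_panel <- function(x, ...) {
  dplyr::left_join(x$data, x$meta, by = "stock")
}

#' Validate a stock panel
#'
#' Checks the structural invariants of the interchange format: no duplicate
#' (stock, year, age) cells, consecutive ages and years within every stock,
#' maturities in \[0, 1\], strictly positive weights and blim, non-negative
#' mortalities.
#'
#' @param x A `stock_panel`.
#' @return `x`, invisibly; errors describe the offending stock/year/age.
#' @export
validate_stock_panel <- function(x) {
  d <- x$data
  m <- x$meta
  need <- c("stock", "year", "age", "N", "W", "MAT", "M", "F")
  if (!all(need %in% names(d)))
    stop("stock_panel data must have columns: ", paste(need, collapse = ", "))
  if (!all(c("stock", "species", "order", "blim", "plus_group") %in% names(m)))
    stop("stock_panel meta must have columns stock, species, order, blim, plus_group")
  if (!all(d$stock %in% m$stock))
    stop("data contains stocks absent from meta: ",
         paste(setdiff(d$stock, m$stock), collapse = ", "))

  dup <- duplicated(d[, c("stock", "year", "age")])
  if (any(dup)) {
    rows <- which(dup)
    stop("duplicate (stock, year, age) cells at data rows: ",
         paste(utils::head(rows, 10), collapse = ", "))
  }
  for (id in unique(d$stock)) {
    di <- d[d$stock == id, ]
    ages <- sort(unique(di$age))
    yrs <- sort(unique(di$year))
    if (length(ages) > 1 && any(diff(ages) != 1))
      stop("stock ", id, ": ages not consecutive; gap after age ",
           ages[which(diff(ages) != 1)[1]])
    if (length(yrs) > 1 && any(diff(yrs) != 1))
      stop("stock ", id, ": years not consecutive; gap after year ",
           yrs[which(diff(yrs) != 1)[1]])
  }
  bad <- which(!is.na(d$MAT) & (d$MAT < 0 | d$MAT > 1))
  if (length(bad)) {
    b <- d[bad[1], ]
    stop("MAT outside [0, 1] for stock ", b$stock,
         ", year ", b$year, ", age ", b$age, " (value ", b$MAT, ")")
  }
  if (any(!is.na(d$W) & d$W <= 0)) stop("non-positive weight-at-age present")
  if (any(!is.na(d$N) & d$N <= 0)) stop("non-positive numbers-at-age present")
  if (any(!is.na(d$M) & d$M < 0) || any(!is.na(d$F) & d$F < 0))
    stop("negative mortality present")
  if (any(!is.na(m$blim) & m$blim <= 0)) stop("blim must be positive")
  invisible(x)
}

#' Read stocks from long-format CSV
#'
#' The interchange file is one value per row with columns
#' `stock, species, order, year, age, variable, value`; `variable` is one of
#' `N`, `W`, `MAT`, `M`, `F` for age-structured cells, or `blim` /
#' `plus_group` for the per-stock metadata block (metadata rows leave `year`
#' and `age` empty).
#'
#' @param path Path to a CSV file.
#' @return A [stock_panel()].
#' @export
#' @examples
#' \dontrun{
#' panel <- read_stocks("stocks.csv")
#' }
read_stocks <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           stock = readr::col_character(),
                           species = readr::col_character(),
                           order = readr::col_character(),
                           year = readr::col_integer(),
                           age = readr::col_integer(),
                           variable = readr::col_character(),
                           value = readr::col_double()))
  cell_vars <- c("N", "W", "MAT", "M", "F")
  cells <- dplyr::filter(raw, .data$variable %in% cell_vars)
  metar <- dplyr::filter(raw, !.data$variable %in% cell_vars)
  bad_var <- setdiff(unique(metar$variable), c("blim", "plus_group"))
  if (length(bad_var))
    stop("unknown variable(s) in ", path, ": ", paste(bad_var, collapse = ", "))

  dup <- duplicated(cells[, c("stock", "year", "age", "variable")])
  if (any(dup))
    stop("duplicate (stock, year, age, variable) rows: ",
         paste(utils::head(which(dup), 10), collapse = ", "))

  data <- cells |>
    dplyr::select("stock", "year", "age", "variable", "value") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "value")
  for (v in setdiff(cell_vars, names(data))) data[[v]] <- NA_real_
  data <- data[, c("stock", "year", "age", cell_vars)]
  data <- dplyr::arrange(data, .data$stock, .data$year, .data$age)

  meta <- metar |>
    dplyr::select("stock", "species", "order", "variable", "value") |>
    dplyr::distinct() |>
    tidyr::pivot_wider(names_from = "variable", values_from = "value") |>
    dplyr::mutate(plus_group = as.logical(.data$plus_group))
  stock_panel(data, meta)
}

#' Write stocks to long-format CSV
#'
#' Inverse of [read_stocks()]; the round trip is lossless.
#'
#' @param panel A `stock_panel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stocks <- function(panel, path) {
  long <- panel$data |>
    tidyr::pivot_longer(cols = c("N", "W", "MAT", "M", "F"),
                        names_to = "variable", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::left_join(panel$meta[, c("stock", "species", "order")], by = "stock") |>
    dplyr::select("stock", "species", "order", "year", "age", "variable", "value")
  metal <- panel$meta |>
    dplyr::mutate(blim = as.numeric(.data$blim),
                  plus_group = as.numeric(.data$plus_group)) |>
    tidyr::pivot_longer(cols = c("blim", "plus_group"),
                        names_to = "variable", values_to = "value") |>
    dplyr::mutate(year = NA_integer_, age = NA_integer_) |>
    dplyr::select("stock", "species", "order", "year", "age", "variable", "value")
  readr::write_csv(dplyr::bind_rows(long, metal), path, na = "")
  invisible(path)
}

# Extract one stock as age x year matrices (internal workhorse).
stock_matrices <- function(panel, id) {
  d <- panel$data[panel$data$stock == id, ]
  if (!nrow(d)) stop("unknown stock: ", id)
  m <- panel$meta[panel$meta$stock == id, ]
  ages <- sort(unique(d$age))
  years <- sort(unique(d$year))
  shape <- function(v) {
    mat <- matrix(NA_real_, length(ages), length(years),
                  dimnames = list(age = ages, year = years))
    mat[cbind(match(d$age, ages), match(d$year, years))] <- d[[v]]
    mat
  }
  list(stock = id, species = m$species, order = m$order,
       ages = ages, years = years,
       N = shape("N"), W = shape("W"), MAT = shape("MAT"),
       M = shape("M"), F = shape("F"),
       blim = m$blim, plus_group = isTRUE(m$plus_group))
}

#' Stock ids present in a panel
#'
#' @param panel A `stock_panel`.
#' @return Character vector of stock identifiers.
#' @export
stock_ids <- function(panel) panel$meta$stock

# Ages entering each weight response for one stock. W_old needs the maturity
# ogive; if A50 is undefined the response is undefined for that stock (NULL).
response_ages <- function(sm, a50 = NULL) {
  ages <- sm$ages
  std <- setdiff(ages, ages[1])
  if (sm$plus_group) std <- setdiff(std, ages[length(ages)])
  if (is.null(a50)) {
    a50 <- tryCatch(compute_a50(sm$MAT, ages), error = function(e) NULL)
  }
  old <- if (is.null(a50)) NULL else ages[ages > a50]
  list(W_recr = ages[1], W_old = old, W_std = std)
}

#' Exclude constant-weight periods
#'
#' Years during which a weight response is flat are uninformative about
#' density effects: assessments that assume weight-at-age constant over a
#' period store exact repeats. For each response (`W_recr`, `W_old`,
#' `W_std`) a year is excluded when the response-relevant weight-at-age
#' sub-vector is identical (relative difference below `tol` at every
#' relevant age) to an adjacent year's, so whole constant runs drop out.
#' Stocks whose entire series is constant are flagged fully excluded.
#'
#' @param panel A `stock_panel`.
#' @param responses Character vector of responses to screen.
#' @param tol Relative-difference tolerance under which two weights count as
#'   identical (default `1e-9`).
#' @return A list of class `dd_prune` with tibbles `exclusions`
#'   (stock, response, year), `fully_excluded` (stock, response) and
#'   `usable` (stock, response, n_usable).
#' @export
prune_constant_periods <- function(panel,
                                   responses = c("W_recr", "W_old", "W_std"),
                                   tol = 1e-9) {
  excl <- list()
  usable <- list()
  for (id in stock_ids(panel)) {
    sm <- stock_matrices(panel, id)
    ra <- response_ages(sm)
    for (resp in responses) {
      ages <- ra[[resp]]
      if (is.null(ages) || !length(ages)) {
        usable[[length(usable) + 1]] <-
          tibble::tibble(stock = id, response = resp, n_usable = 0L)
        next
      }
      Wsub <- sm$W[as.character(ages), , drop = FALSE]
      ny <- ncol(Wsub)
      same_as_prev <- vapply(seq_len(ny - 1), function(j) {
        a <- Wsub[, j]; b <- Wsub[, j + 1]
        ok <- !is.na(a) & !is.na(b)
        any(ok) && all(abs(b[ok] - a[ok]) <= tol * pmax(abs(a[ok]), 1e-300))
      }, logical(1))
      flat <- logical(ny)
      flat[seq_len(ny - 1)] <- same_as_prev        # equals next year
      flat[-1] <- flat[-1] | same_as_prev          # equals previous year
      if (any(flat)) {
        excl[[length(excl) + 1]] <- tibble::tibble(
          stock = id, response = resp, year = sm$years[flat])
      }
      usable[[length(usable) + 1]] <- tibble::tibble(
        stock = id, response = resp, n_usable = sum(!flat))
    }
  }
  usable <- dplyr::bind_rows(usable)
  exclusions <- if (length(excl)) dplyr::bind_rows(excl) else
    tibble::tibble(stock = character(), response = character(), year = integer())
  fully <- usable |>
    dplyr::filter(.data$n_usable == 0L) |>
    dplyr::select("stock", "response")
  structure(list(exclusions = exclusions, fully_excluded = fully,
                 usable = usable, tol = tol),
            class = "dd_prune")
}

#' @export
print.dd_prune <- function(x, ...) {
  cat("<dd_prune> ", nrow(x$exclusions), " excluded (stock, response, year) triples; ",
      nrow(x$fully_excluded), " fully excluded stock x response series\n", sep = "")
  invisible(x)
}

#' Drop stock-by-response groups with too few observations
#'
#' Groups (stock x response) with fewer than `min_obs` usable rows cannot
#' support a slope + intercept + AR1 fit and are removed. Values are never
#' modified, only membership.
#'
#' @param rows A tibble with at least `stock` and `response` columns (e.g. a
#'   response panel).
#' @param min_obs Minimum rows per (stock, response) group; must be >= 2.
#' @return The filtered tibble, with a `dropped` attribute listing removed
#'   groups.
#' @export
filter_min_obs <- function(rows, min_obs = 5) {
  if (!is.numeric(min_obs) || min_obs < 2)
    stop("min_obs must be >= 2")
  out <- rows |>
    dplyr::group_by(.data$stock, .data$response) |>
    dplyr::filter(dplyr::n() >= min_obs) |>
    dplyr::ungroup()
  dropped <- rows |>
    dplyr::count(.data$stock, .data$response) |>
    dplyr::filter(.data$n < min_obs)
  attr(out, "dropped") <- dropped
  out
}
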