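#' Biology vectors for equilibrium calculations
#'
#' Per-age weight, maturity, natural mortality and selectivity, averaged over
#' the last `n_last` years of the series. Selectivity is mean fishing
#' mortality-at-age rescaled to a maximum of one.
#'
#' @param panel A `stock_panel`.
#' @param stock Stock id.
#' @param n_last Number of terminal years to average (default 3). Shorter
#'   series fall back to all years, with a warning.
#' @return Tibble with columns `age`, `w`, `mat`, `m`, `sel`.
#' @export
biology_vectors <- function(panel, stock, n_last = 3) {
  sm <- stock_matrices(panel, stock)
  ny <- length(sm$years)
  if (ny < n_last) {
    warning("stock ", stock, ": series shorter than n_last = ", n_last,
            "; using all ", ny, " years")
    n_last <- ny
  }
  idx <- seq(ny - n_last + 1, ny)
  mean_last <- function(mat) unname(rowMeans(mat[, idx, drop = FALSE], na.rm = TRUE))
  fbar_age <- mean_last(sm$F)
  sel <- if (max(fbar_age, na.rm = TRUE) > 0) fbar_age / max(fbar_age, na.rm = TRUE)
         else fbar_age * 0
  tibble::tibble(age = sm$ages,
                 w = mean_last(sm$W),
                 mat = mean_last(sm$MAT),
                 m = mean_last(sm$M),
                 sel = sel)
}

# Unfished survivorship at age, with plus-group accumulation
# l(A) = l(A-1) exp(-m(A-1)) / (1 - exp(-m(A))).
survivorship <- function(m, plus_group = FALSE) {
  A <- length(m)
  l <- numeric(A)
  l[1] <- 1
  if (A > 1) for (a in 2:A) l[a] <- l[a - 1] * exp(-m[a - 1])
  if (plus_group) {
    if (m[A] <= 0)
      stop("plus-group natural mortality is zero: the accumulator diverges; ",
           "cap M at the terminal age before calling")
    l[A] <- if (A > 1) l[A - 1] * exp(-m[A - 1]) / (1 - exp(-m[A]))
            else 1 / (1 - exp(-m[A]))
  }
  l
}

#' Unfished spawner biomass per recruit
#'
#' \deqn{SPR_0 = \sum_a l(a)\,e^{-s\,M(a)}\,mat(a)\,w(a)}
#' with survivorship \eqn{l(1) = 1}, \eqn{l(a+1) = l(a) e^{-M(a)}} and, for a
#' plus group, \eqn{l(A) = l(A-1) e^{-M(A-1)} / (1 - e^{-M(A)})}. `spawn_frac`
#' (\eqn{s}) is the fraction of natural mortality occurring before spawning;
#' the default 0 takes spawning biomass at the start of the year.
#'
#' @param w,mat,m Aligned per-age vectors of weight (kg), maturity and
#'   natural mortality.
#' @param plus_group Is the last age an accumulator?
#' @param spawn_frac Fraction of M before spawning, in \[0, 1\].
#' @return SPR0 in kg per recruit (equivalently tonnes per thousand recruits).
#' @export
compute_spr0 <- function(w, mat, m, plus_group = FALSE, spawn_frac = 0) {
  stopifnot(length(w) == length(mat), length(w) == length(m))
  l <- survivorship(m, plus_group)
  sum(l * exp(-spawn_frac * m) * mat * w)
}

#' Fit a hockey-stick stock-recruitment relationship with fixed breakpoint
#'
#' Predicted recruitment is \eqn{R(S) = a \min(S, b)} with the breakpoint `b`
#' fixed at `blim`. The slope `a` is estimated by least squares on the log
#' scale (lognormal recruitment errors): \eqn{\log \hat a = \overline{\log R -
#' \log \min(S, b)}}. `sigma_r` is the standard deviation and `rho_r` the
#' lag-1 autocorrelation of the log residuals. When every observed SSB sits
#' on the plateau the slope reduces to `exp(mean(log R)) / b` and the fit is
#' flagged.
#'
#' @param ssb Spawning biomass series (tonnes), already lagged so that
#'   element `i` spawned recruitment `rec[i]`.
#' @param rec Recruitment series (thousands), aligned with `ssb`.
#' @param blim Breakpoint (tonnes).
#' @return An object of class `segreg_srr`: list with `a`, `b`, `sigma_r`,
#'   `rho_r`, `n`, `plateau_only`.
#' @export
fit_segreg <- function(ssb, rec, blim) {
  ok <- !is.na(ssb) & !is.na(rec) & ssb > 0 & rec > 0
  ssb <- ssb[ok]; rec <- rec[ok]
  if (length(ssb) < 5) stop("fit_segreg needs at least 5 paired observations")
  pred_core <- pmin(ssb, blim)
  res0 <- log(rec) - log(pred_core)
  log_a <- mean(res0)
  res <- res0 - log_a
  sigma_r <- stats::sd(res)
  rho_r <- if (length(res) > 2 && sigma_r > 0)
    stats::cor(res[-1], res[-length(res)]) else 0
  structure(list(a = exp(log_a), b = blim,
                 sigma_r = sigma_r, rho_r = rho_r,
                 n = length(ssb), plateau_only = all(ssb >= blim)),
            class = "segreg_srr")
}

#' @export
print.segreg_srr <- function(x, ...) {
  cat("<segreg_srr> a = ", signif(x$a, 4), " (thousand recruits / tonne), b = ",
      signif(x$b, 4), " t, sigma_r = ", signif(x$sigma_r, 3),
      ", rho_r = ", signif(x$rho_r, 3),
      if (x$plateau_only) "  [plateau-only data]" else "", "\n", sep = "")
  invisible(x)
}

#' Predict recruitment from a hockey-stick SRR
#'
#' @param object A `segreg_srr`.
#' @param ssb Spawning biomass values (tonnes).
#' @param ... Unused.
#' @return Predicted recruitment (thousands), `a * min(ssb, b)`.
#' @export
predict.segreg_srr <- function(object, ssb, ...) {
  object$a * pmin(ssb, object$b)
}

#' Unfished equilibrium reference points by stochastic projection
#'
#' Projects numbers-at-age forward under natural mortality and (by default)
#' zero fishing, with hockey-stick recruitment perturbed by lognormal AR1
#' deviations, and reads the equilibrium off the tail of each replicate:
#' SSB0 and R0 are the across-replicate medians (means also reported) of the
#' mean of the last `n_keep` years; unfished numbers-at-age N0 analogously
#' per age. With `sigma_r = 0` the projection is deterministic and, for
#' `a * SPR0 > 1`, converges to the closed-form plateau equilibrium
#' `R0 = a b`, `SSB0 = a b SPR0`.
#'
#' An assessment-error process multiplies the intended fishing mortality by
#' a lognormal AR1 factor with marginal sd `fcv` and autocorrelation `fphi`;
#' at the default `fbar = 0` it has no effect but it is active whenever a
#' non-zero target F is projected.
#'
#' @param panel A `stock_panel`.
#' @param stock Stock id.
#' @param srr A `segreg_srr`.
#' @param n_years Projection horizon (default 200).
#' @param n_keep Tail years retained as equilibrium (default 50).
#' @param n_reps Stochastic replicates (default 100; forced to 1 when the
#'   projection is deterministic).
#' @param fcv,fphi Assessment-error sd and AR1 coefficient on intended F
#'   (defaults 0.212 and 0.423).
#' @param fbar Intended equilibrium fishing mortality multiplier on the
#'   selectivity vector (default 0 = unfished).
#' @param spawn_frac Fraction of total mortality before spawning.
#' @param seed Optional RNG seed.
#' @return An object of class `ref_points`.
#' @export
simulate_unfished <- function(panel, stock, srr,
                              n_years = 200, n_keep = 50, n_reps = 100,
                              fcv = 0.212, fphi = 0.423,
                              fbar = 0, spawn_frac = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bio <- biology_vectors(panel, stock)
  sm <- stock_matrices(panel, stock)
  A <- nrow(bio)
  spr0 <- compute_spr0(bio$w, bio$mat, bio$m, sm$plus_group, spawn_frac)
  deterministic <- srr$sigma_r == 0 && (fbar == 0 || fcv == 0)
  reps <- if (deterministic) 1L else as.integer(n_reps)
  collapsed <- srr$a * spr0 <= 1 && fbar == 0

  # recruitment deviations: stationary AR1, innovations N(0, s^2 (1 - rho^2))
  ar1_matrix <- function(nrep, nyr, sdev, rho) {
    if (sdev == 0) return(matrix(0, nrep, nyr))
    d <- matrix(0, nrep, nyr)
    d[, 1] <- stats::rnorm(nrep, 0, sdev)
    if (nyr > 1) {
      innov_sd <- sdev * sqrt(1 - rho^2)
      for (y in 2:nyr) d[, y] <- rho * d[, y - 1] + stats::rnorm(nrep, 0, innov_sd)
    }
    d
  }
  rdev <- ar1_matrix(reps, n_years, srr$sigma_r, srr$rho_r)
  fdev <- if (fbar > 0) ar1_matrix(reps, n_years, fcv, fphi) else
    matrix(0, reps, n_years)

  l0 <- survivorship(bio$m, sm$plus_group)
  r_init <- srr$a * srr$b
  N <- matrix(rep(r_init * l0, each = reps), reps, A)   # reps x ages
  ssb_w <- bio$mat * bio$w
  keep <- seq(n_years - n_keep + 1, n_years)
  ssb_tr <- matrix(0, reps, n_years)
  rec_tr <- matrix(0, reps, n_years)
  n_acc <- matrix(0, reps, A)   # running sum of kept years

  for (y in seq_len(n_years)) {
    Fy <- fbar * exp(fdev[, y])                    # reps
    Z <- outer(Fy, bio$sel) + rep(bio$m, each = reps)  # reps x ages
    ssb <- as.vector((N * exp(-spawn_frac * Z)) %*% ssb_w)
    ssb_tr[, y] <- ssb
    rec_tr[, y] <- N[, 1]
    if (y %in% keep) n_acc <- n_acc + N
    if (y < n_years) {
      Nn <- matrix(0, reps, A)
      Nn[, 1] <- srr$a * pmin(ssb, srr$b) * exp(rdev[, y + 1])
      if (A > 1) Nn[, 2:A] <- (N * exp(-Z))[, 1:(A - 1), drop = FALSE]
      if (sm$plus_group) Nn[, A] <- Nn[, A] + (N * exp(-Z))[, A]
      N <- Nn
    }
  }

  rep_ssb <- rowMeans(ssb_tr[, keep, drop = FALSE])
  rep_rec <- rowMeans(rec_tr[, keep, drop = FALSE])
  n0 <- n_acc / n_keep

  # non-convergence heuristic: trend of the median SSB path over kept years
  med_path <- apply(ssb_tr[, keep, drop = FALSE], 2, stats::median)
  trend_flag <- FALSE
  if (mean(med_path) > 0) {
    sl <- stats::coef(stats::lm(med_path ~ seq_along(med_path)))[2]
    trend_flag <- abs(sl) / mean(med_path) > 0.01
  }
  if (trend_flag)
    warning("stock ", stock, ": retained-year SSB still trending > 1%/year; ",
            "equilibrium may not be reached")

  structure(list(
    stock = stock,
    ssb0 = stats::median(rep_ssb), r0 = stats::median(rep_rec),
    ssb0_mean = mean(rep_ssb), r0_mean = mean(rep_rec),
    spr0 = spr0,
    n0_at_age = tibble::tibble(age = bio$age,
                               n0 = apply(n0, 2, stats::median)),
    collapsed = collapsed, trend_flag = trend_flag,
    settings = list(n_years = n_years, n_keep = n_keep, n_reps = reps,
                    fcv = fcv, fphi = fphi, fbar = fbar,
                    spawn_frac = spawn_frac, seed = seed)),
    class = "ref_points")
}

#' @export
print.ref_points <- function(x, ...) {
  cat("<ref_points> ", x$stock, ": SSB0 = ", signif(x$ssb0, 5),
      " t, R0 = ", signif(x$r0, 5), " thousand, SPR0 = ",
      signif(x$spr0, 5), " kg/recruit",
      if (x$collapsed) "  [collapsed: a*SPR0 <= 1]" else "", "\n", sep = "")
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.ref_points <- function(x, ...) {
  tibble::tibble(stock = x$stock, ssb0 = x$ssb0, r0 = x$r0, spr0 = x$spr0,
                 ssb0_mean = x$ssb0_mean, r0_mean = x$r0_mean,
                 collapsed = x$collapsed, trend_flag = x$trend_flag)
}

# Observed SSB series from assessment matrices (tonnes).
ssb_series <- function(sm) {
  unname(colSums(sm$N * sm$MAT * sm$W, na.rm = TRUE))
}

#' Reference points for every stock in a panel
#'
#' Fits the hockey-stick SRR per stock from its own assessment series
#' (recruitment at the first age paired with SSB lagged by the recruitment
#' age) with the breakpoint at that stock's `blim`, then runs
#' [simulate_unfished()].
#'
#' @param panel A `stock_panel`.
#' @param n_reps,n_years,n_keep,seed Passed to [simulate_unfished()].
#' @param ... Further arguments to [simulate_unfished()].
#' @return A list of class `ref_points_set`: `refpts` (one row per stock),
#'   `n0` (stock x age) and the per-stock `ref_points` objects in `fits`.
#' @export
compute_reference_points <- function(panel, n_reps = 100, n_years = 200,
                                     n_keep = 50, seed = NULL, ...) {
  ids <- stock_ids(panel)
  fits <- vector("list", length(ids))
  names(fits) <- ids
  for (i in seq_along(ids)) {
    sm <- stock_matrices(panel, ids[i])
    rec_age <- sm$ages[1]
    lag <- max(rec_age, 1L)
    yrs <- seq_along(sm$years)
    rec <- sm$N[1, ]
    ssb <- ssb_series(sm)
    pair <- yrs[yrs > lag]
    srr <- fit_segreg(ssb[pair - lag], rec[pair], blim = sm$blim)
    fits[[i]] <- simulate_unfished(
      panel, ids[i], srr, n_years = n_years, n_keep = n_keep,
      n_reps = n_reps,
      seed = if (is.null(seed)) NULL else seed + i, ...)
  }
  refpts <- dplyr::bind_rows(lapply(fits, tidy))
  n0 <- dplyr::bind_rows(lapply(fits, function(f)
    dplyr::mutate(f$n0_at_age, stock = f$stock, .before = 1)))
  structure(list(refpts = refpts, n0 = n0, fits = fits),
            class = "ref_points_set")
}

#' @export
print.ref_points_set <- function(x, ...) {
  cat("<ref_points_set> ", nrow(x$refpts), " stocks\n", sep = "")
  print(x$refpts)
  invisible(x)
}
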