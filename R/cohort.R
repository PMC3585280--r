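#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation; the p-value derives from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom
#' (two-sided), as implemented by [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length, at least 3 points,
#'   non-constant.
#' @return A list with `r` and `p`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3) stop("at least 3 points are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Ordinary least-squares regression
#'
#' OLS fit of `y` on `x` reporting slope, intercept, root-mean-square error
#' and the Pearson correlation. RMSE uses denominator `n` by default (common
#' in reporting); `rmse_df = "residual"` divides by `n - 2` instead.
#'
#' @inheritParams pearson
#' @param rmse_df `"n"` (default) or `"residual"`.
#' @return A list with `slope`, `intercept`, `rmse`, `r`.
#' @export
linregress <- function(x, y, rmse_df = c("n", "residual")) {
  rmse_df <- match.arg(rmse_df)
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3) stop("at least 3 points are required")
  if (stats::sd(x) == 0) stop("constant x: regression undefined")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  denom <- if (rmse_df == "n") length(x) else length(x) - 2
  list(slope = stats::coef(fit)[[2]], intercept = stats::coef(fit)[[1]],
       rmse = sqrt(ss_res / denom),
       r = if (stats::sd(y) == 0) 1 else stats::cor(x, y))
}

#' Assemble a cohort table from per-unit results
#'
#' One row per unit: fitted warm-up constants, derived constants and pouch
#' geometry.
#'
#' @param fits List of [warmup_fit()] objects.
#' @param geometries List of [geometry_summary()] objects, same length.
#' @param t_storage,t_ambient Per-unit storage/ambient temperatures
#'   (recycled).
#' @return A data frame of class `cohort_table`.
#' @export
cohort_table <- function(fits, geometries, t_storage, t_ambient) {
  stopifnot(length(fits) == length(geometries))
  n <- length(fits)
  t_storage <- rep_len(t_storage, n); t_ambient <- rep_len(t_ambient, n)
  rows <- lapply(seq_len(n), function(i) {
    f <- fits[[i]]; g <- geometries[[i]]; dc <- derived_constants(f)
    data.frame(unit = i,
               tau_mean = f$tau_mean, tau_surface = f$tau_surface,
               tau_core = f$tau_core, delta_surface = f$delta_surface,
               delta_core = f$delta_core,
               r2_mean = f$r2_mean, r2_surface = f$r2_surface,
               r2_core = f$r2_core,
               t_spread = dc$t_spread, theta_spread_max = dc$theta_spread_max,
               ratio_sm = dc$ratio_sm, ratio_sc = dc$ratio_sc,
               rbc_volume_ml = g$rbc_volume_ml,
               pouch_volume_ml = g$pouch_volume_ml,
               height_cm = g$height_cm, width_cm = g$width_cm,
               wh_ratio = g$wh_ratio,
               t_storage = t_storage[i], t_ambient = t_ambient[i])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_table", class(out))
  out
}

#' Cohort summary statistics
#'
#' Means and standard deviations of all fitted and derived constants, plus
#' the correlation matrix of the time constants and `t_spread` against the
#' geometric pouch parameters with two-sided p-values and significance flags
#' at the 0.01 level (no multiple-testing correction is applied).
#'
#' @param table A [cohort_table()] with at least 3 units.
#' @param alpha Significance level (default 0.01).
#' @return A list of class `cohort_summary` with `n_units`, `means`, `sds`
#'   and `correlations` (long data frame: constant, geometry, r, p,
#'   significant; `NA` r where an input was constant).
#' @export
cohort_summary <- function(table, alpha = 0.01) {
  if (nrow(table) < 3) stop("at least 3 units are required")
  const_cols <- c("tau_mean", "tau_surface", "tau_core", "delta_surface",
                  "delta_core", "t_spread", "theta_spread_max",
                  "ratio_sm", "ratio_sc")
  geom_cols <- c("rbc_volume_ml", "pouch_volume_ml", "height_cm", "width_cm",
                 "wh_ratio")
  num <- table[unlist(lapply(table, is.numeric))]
  rows <- expand.grid(constant = c("tau_mean", "tau_surface", "tau_core",
                                   "t_spread"),
                      geometry = geom_cols, stringsAsFactors = FALSE)
  cor_df <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    x <- table[[rows$geometry[i]]]; y <- table[[rows$constant[i]]]
    res <- tryCatch(pearson(x, y),
                    error = function(e) list(r = NA_real_, p = NA_real_))
    data.frame(constant = rows$constant[i], geometry = rows$geometry[i],
               r = res$r, p = res$p,
               significant = !is.na(res$p) && res$p < alpha)
  }))
  structure(list(n_units = nrow(table),
                 means = colMeans(num[const_cols]),
                 sds = vapply(num[const_cols], stats::sd, numeric(1)),
                 correlations = cor_df, alpha = alpha),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (%d units)\n", x$n_units))
  for (nm in names(x$means))
    cat(sprintf("  %-18s %8.3f +- %.3f\n", nm, x$means[[nm]], x$sds[[nm]]))
  cat(sprintf("Correlations vs geometry (p < %.2g flagged *):\n", x$alpha))
  cd <- x$correlations
  for (i in seq_len(nrow(cd)))
    cat(sprintf("  %-12s ~ %-16s r = %6.3f  p = %.3g%s\n",
                cd$constant[i], cd$geometry[i], cd$r[i], cd$p[i],
                if (isTRUE(cd$significant[i])) " *" else ""))
  invisible(x)
}

#' Generate a synthetic cohort with geometry-dependent time constants
#'
#' Draws per-unit pouch geometry (height, width) around the default phantom
#' values and generates time constants with a known positive dependence on
#' the width-height ratio, then fits the warm-up models to noisy model curves
#' per unit. Exercises the full fit + cohort-statistics path without the
#' cost of per-unit finite-difference simulations.
#'
#' @param n_units Number of units, at least 3.
#' @param seed Integer seed.
#' @param wh_slope Sensitivity of `tau_mean` (minutes) to the width-height
#'   ratio, around its cohort mean.
#' @param curve_noise_sd Noise on the generated theta curves.
#' @return A [cohort_table()].
#' @export
generate_synthetic_cohort <- function(n_units = 8, seed = 1L,
                                      wh_slope = 120, curve_noise_sd = 0.003) {
  if (n_units < 3) stop("at least 3 units are required")
  set.seed(seed)
  h <- stats::rnorm(n_units, 13.1, 0.5)
  w <- stats::rnorm(n_units, 3.4, 0.2)
  wh <- w / h
  tau_m <- 55.3 + wh_slope * (wh - mean(wh)) + stats::rnorm(n_units, 0, 1)
  tau_s <- 0.75 * tau_m + stats::rnorm(n_units, 0, 1)
  tau_c <- tau_m / 0.72 + stats::rnorm(n_units, 0, 1.5)
  d_s <- pmax(stats::rnorm(n_units, 0.07, 0.02), 0.01)
  d_c <- pmax(stats::rnorm(n_units, 0.04, 0.01), 0.01)
  unit_seeds <- sample.int(1e6, n_units)
  fits <- vector("list", n_units); geoms <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    cur <- generate_model_curves(tau_m[i], tau_s[i], tau_c[i], d_s[i], d_c[i],
                                 noise_sd = curve_noise_sd,
                                 seed = unit_seeds[i])
    fm <- fit_exponential(cur$t_min, cur$theta_mean)
    fs <- fit_shifted_exponential(cur$t_min, cur$theta_surface, "surface")
    fc <- fit_shifted_exponential(cur$t_min, cur$theta_core, "core")
    fits[[i]] <- suppressWarnings(
      warmup_fit(fm$tau, fs$tau, fc$tau, fs$delta, fc$delta,
                 r2_mean = fm$r2, r2_surface = fs$r2, r2_core = fc$r2,
                 sd_tau_mean = fm$sd_tau, sd_tau_surface = fs$sd_tau,
                 sd_tau_core = fc$sd_tau, sd_delta_surface = fs$sd_delta,
                 sd_delta_core = fc$sd_delta))
    vol <- 255 * (h[i] / 13.1) * (w[i] / 3.4)
    geoms[[i]] <- structure(list(
      rbc_volume_ml = vol, pouch_volume_ml = vol / 0.8885,
      height_cm = h[i], width_cm = w[i], wh_ratio = wh[i],
      center = c(row = NA, col = NA, slice = NA)),
      class = "geometry_summary")
  }
  cohort_table(fits, geoms, t_storage = 3.6, t_ambient = 21.25)
}
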