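#' Temperature-map time series
#'
#' Container for a time-resolved stack of temperature maps. The voxel grid is
#' indexed `(row, col, slice)` with the vertical pouch axis along rows
#' (1-based, as usual in R); time is the fourth dimension.
#'
#' @param maps 4-D numeric array `(row, col, slice, time)` of temperatures in
#'   degrees Celsius.
#' @param times Acquisition times in minutes, one per time point.
#' @param t_storage,t_ambient Storage and ambient temperatures in degrees
#'   Celsius.
#' @param voxel_mm Voxel dimensions in mm, `c(row, col, slice)`.
#' @return An object of class `temperature_series`.
#' @export
temperature_series <- function(maps, times, t_storage, t_ambient,
                               voxel_mm = c(1.1, 1.1, 7.5)) {
  maps <- as.array(maps)
  if (length(dim(maps)) != 4) stop("maps must be a 4-D (row, col, slice, time) array")
  if (dim(maps)[4] != length(times))
    stop("length of times must match the 4th dimension of maps")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  structure(list(maps = maps, times = as.numeric(times),
                 t_storage = t_storage, t_ambient = t_ambient,
                 voxel_mm = as.numeric(voxel_mm)),
            class = "temperature_series")
}

#' @export
print.temperature_series <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf(
    "Temperature series: %d x %d x %d voxels, %d time points (%.1f-%.1f min)\n",
    d[1], d[2], d[3], d[4], min(x$times), max(x$times)))
  cat(sprintf("  storage %.2f degC, ambient %.2f degC\n",
              x$t_storage, x$t_ambient))
  invisible(x)
}

.mask_3d <- function(mask, maps) {
  mask <- as.array(mask) > 0
  if (!all(dim(mask) == dim(maps)[1:3]))
    stop("mask shape does not match the spatial grid")
  if (!any(mask)) stop("mask is empty")
  mask
}

#' Mean RBC temperature per time point
#'
#' Unweighted mean over all masked voxels, per time point.
#'
#' @param series A [temperature_series()].
#' @param rbc_mask Logical 3-D array marking RBC voxels.
#' @return Numeric vector of mean temperatures (degC), one per time point.
#' @export
mean_temperature <- function(series, rbc_mask) {
  stopifnot(inherits(series, "temperature_series"))
  mask <- .mask_3d(rbc_mask, series$maps)
  apply(series$maps, 4, function(m) mean(m[mask]))
}

#' Geometry summary of the segmented pouch
#'
#' Volumes are voxel counts times voxel volume; pouch height `h` and width `w`
#' are the bounding-box extents of the pouch mask in the central slice
#' (vertical axis = rows), and the geometric centre is the bounding-box
#' midpoint, i.e. `h/2` along the vertical axis.
#'
#' @param rbc_mask Logical 3-D array of RBC voxels.
#' @param pouch_mask Logical 3-D array of the full pouch (RBC plus SAGM
#'   supernatant layer). Defaults to the RBC mask.
#' @param voxel_mm Voxel dimensions in mm, `c(row, col, slice)`.
#' @return A list of class `geometry_summary`: `rbc_volume_ml`,
#'   `pouch_volume_ml`, `height_cm`, `width_cm`, `wh_ratio`, `center`
#'   (voxel coordinate `c(row, col, slice)`).
#' @export
geometry_summary <- function(rbc_mask, pouch_mask = rbc_mask, voxel_mm) {
  rbc <- as.array(rbc_mask) > 0
  pouch <- as.array(pouch_mask) > 0
  if (!any(rbc) || !any(pouch)) stop("mask is empty")
  if (!all(dim(rbc) == dim(pouch))) stop("mask shapes differ")
  vox_ml <- prod(voxel_mm) / 1000
  central <- ceiling(dim(pouch)[3] / 2)
  sl <- pouch[, , central]
  if (!any(sl)) stop("pouch mask is empty in the central slice")
  rows <- range(which(apply(sl, 1, any)))
  cols <- range(which(apply(sl, 2, any)))
  structure(list(
    rbc_volume_ml = sum(rbc) * vox_ml,
    pouch_volume_ml = sum(pouch) * vox_ml,
    height_cm = diff(rows + c(-1, 0)) * voxel_mm[1] / 10,
    width_cm = diff(cols + c(-1, 0)) * voxel_mm[2] / 10,
    wh_ratio = (diff(cols + c(-1, 0)) * voxel_mm[2]) /
               (diff(rows + c(-1, 0)) * voxel_mm[1]),
    center = c(row = mean(rows), col = mean(cols), slice = central)),
    class = "geometry_summary")
}

#' Volume fraction exceeding a temperature threshold
#'
#' Fraction of masked voxels whose temperature exceeds `threshold_T`, per time
#' point. During warm-up these curves rise from 0 to 1 as the isotherm at
#' `threshold_T` sweeps from the surface to the core.
#'
#' @inheritParams mean_temperature
#' @param threshold_T Threshold temperature in degrees Celsius.
#' @return A list of class `volume_fraction_curve` with `threshold_T`,
#'   `times` (min) and `fractions` in `[0, 1]`.
#' @export
volume_fraction <- function(series, rbc_mask, threshold_T) {
  stopifnot(inherits(series, "temperature_series"))
  mask <- .mask_3d(rbc_mask, series$maps)
  fr <- apply(series$maps, 4, function(m) mean(m[mask] > threshold_T))
  structure(list(threshold_T = threshold_T, times = series$times,
                 fractions = fr),
            class = "volume_fraction_curve")
}

#' Tangent crossing times of a volume-fraction curve
#'
#' Interpolates the volume-fraction curve with a natural cubic spline, finds
#' the time at which it crosses one half (half maximum of the asymptote 1),
#' and extrapolates the tangent line at that point: the tangent's crossing of
#' 0 is the time the surface reaches the curve's threshold temperature, its
#' crossing of 1 the time the core does. The construction is insensitive to
#' noise and partial-volume effects at the curve's extremes.
#'
#' @param curve A [volume_fraction()] result.
#' @return Named numeric vector `c(t_surface_reach, t_core_reach)` in
#'   minutes, or `NULL` (with a message) when the curve never crosses 0.5
#'   inside the observation window.
#' @export
crossing_times <- function(curve) {
  stopifnot(inherits(curve, "volume_fraction_curve"))
  t <- curve$times; v <- curve$fractions
  if (max(v) <= 0.5 || min(v) >= 0.5) {
    message(sprintf(
      "threshold %.3g degC skipped: volume fraction never crosses 0.5 in the window",
      curve$threshold_T))
    return(NULL)
  }
  sp <- stats::splinefun(t, v, method = "natural")
  # bracket the first upward crossing of 0.5 between samples
  idx <- which(v[-length(v)] < 0.5 & v[-1] >= 0.5)[1]
  if (is.na(idx)) {  # noisy start above 0.5: search the full span
    root <- tryCatch(stats::uniroot(function(x) sp(x) - 0.5, range(t))$root,
                     error = function(e) NA_real_)
  } else {
    root <- stats::uniroot(function(x) sp(x) - 0.5, c(t[idx], t[idx + 1]))$root
  }
  if (is.na(root)) {
    message(sprintf("threshold %.3g degC skipped: no half-maximum crossing found",
                    curve$threshold_T))
    return(NULL)
  }
  slope <- sp(root, deriv = 1)
  if (slope <= 0) stop("zero or negative tangent slope at half maximum")
  c(t_surface_reach = root - 0.5 / slope,
    t_core_reach = root + 0.5 / slope)
}

#' Surface and core temperature time courses by the tangent method
#'
#' Sweeps integer temperature thresholds from `ceiling(t_storage) + 1` to
#' `floor(t_ambient) - 1`; each admissible threshold `T` contributes one
#' surface point (the tangent time when the RBC volume starts to exceed `T`,
#' so `T` is the momentary surface temperature) and one core point (the
#' tangent time when all of the volume exceeds `T`, so `T` is the momentary
#' core temperature). Thresholds whose half-maximum crossing falls outside the
#' observation window are skipped and reported. Points with negative tangent
#' times (thresholds the surface exceeds essentially at onset) are dropped.
#'
#' @inheritParams mean_temperature
#' @param t_storage,t_ambient Storage/ambient temperature in degrees Celsius;
#'   default from the series.
#' @return An object of class `warmup_curves`: `times`, `t_mean` (degC per
#'   time point), and data frames `surface` and `core` with columns
#'   `T_celsius`, `t_min`, plus `skipped` (thresholds not admissible).
#' @export
surface_core_curves <- function(series, rbc_mask,
                                t_storage = series$t_storage,
                                t_ambient = series$t_ambient) {
  stopifnot(inherits(series, "temperature_series"))
  if (length(series$times) < 5) stop("at least 5 time points are required")
  lo <- ceiling(t_storage) + 1; hi <- floor(t_ambient) - 1
  thresholds <- if (lo > hi) numeric(0) else seq(lo, hi)
  if (length(thresholds) < 2)
    stop("fewer than 2 admissible integer thresholds between storage and ambient")
  surf <- core <- list(); skipped <- numeric()
  for (th in thresholds) {
    cr <- suppressMessages(
      crossing_times(volume_fraction(series, rbc_mask, th)))
    if (is.null(cr)) { skipped <- c(skipped, th); next }
    if (cr[["t_surface_reach"]] >= 0)
      surf[[length(surf) + 1]] <- c(th, cr[["t_surface_reach"]])
    core[[length(core) + 1]] <- c(th, cr[["t_core_reach"]])
  }
  if (length(surf) < 2 || length(core) < 2)
    stop("fewer than 2 admissible thresholds yielded crossing times")
  as_df <- function(lst) {
    m <- do.call(rbind, lst)
    df <- data.frame(T_celsius = m[, 1], t_min = m[, 2])
    df[order(df$t_min), , drop = FALSE]
  }
  structure(list(times = series$times,
                 t_mean = mean_temperature(series, rbc_mask),
                 surface = as_df(surf), core = as_df(core),
                 t_storage = t_storage, t_ambient = t_ambient,
                 skipped = skipped),
            class = "warmup_curves")
}

#' @export
print.warmup_curves <- function(x, ...) {
  cat(sprintf(
    "Warm-up curves: %d mean points, %d surface points, %d core points",
    length(x$t_mean), nrow(x$surface), nrow(x$core)))
  if (length(x$skipped))
    cat(sprintf(" (%d thresholds skipped)", length(x$skipped)))
  cat("\n")
  invisible(x)
}

#' Fit the warm-up models to extracted curves
#'
#' Transforms the mean, surface and core temperature time courses of a
#' [surface_core_curves()] result to relative temperature differences and
#' fits the lumped-capacitance model (mean) and the shifted-exponential
#' models (surface, core).
#'
#' @param curves A `warmup_curves` object.
#' @return A [warmup_fit()] object.
#' @export
fit_warmup_curves <- function(curves) {
  stopifnot(inherits(curves, "warmup_curves"))
  th_of <- function(T) relative_difference(T, curves$t_ambient, curves$t_storage)
  fm <- fit_exponential(curves$times, th_of(curves$t_mean))
  fs <- fit_shifted_exponential(curves$surface$t_min,
                                th_of(curves$surface$T_celsius), "surface")
  fc <- fit_shifted_exponential(curves$core$t_min,
                                th_of(curves$core$T_celsius), "core")
  warmup_fit(tau_mean = fm$tau, tau_surface = fs$tau, tau_core = fc$tau,
             delta_surface = fs$delta, delta_core = fc$delta,
             r2_mean = fm$r2, r2_surface = fs$r2, r2_core = fc$r2,
             sd_tau_mean = fm$sd_tau, sd_tau_surface = fs$sd_tau,
             sd_tau_core = fc$sd_tau, sd_delta_surface = fs$sd_delta,
             sd_delta_core = fc$sd_delta)
}

#' Thermal core position
#'
#' Voxel with the minimal time-averaged temperature inside the mask — the
#' last region of the unit to warm up. Ties are broken by distance to the
#' mask centroid, then by lexicographic voxel index.
#'
#' @inheritParams mean_temperature
#' @return Voxel coordinate `c(row, col, slice)` (1-based).
#' @export
thermal_core_position <- function(series, rbc_mask) {
  stopifnot(inherits(series, "temperature_series"))
  mask <- .mask_3d(rbc_mask, series$maps)
  tavg <- apply(series$maps, 1:3, mean)
  idx <- which(mask, arr.ind = TRUE)
  vals <- tavg[mask]
  cand <- which(vals <= min(vals) + 1e-12)
  if (length(cand) > 1) {
    centroid <- colMeans(idx)
    d2 <- rowSums((idx[cand, , drop = FALSE] -
                     matrix(centroid, length(cand), 3, byrow = TRUE))^2)
    cand <- cand[d2 <= min(d2) + 1e-12]
  }
  pos <- idx[min(cand), ]
  c(row = unname(pos[1]), col = unname(pos[2]), slice = unname(pos[3]))
}
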