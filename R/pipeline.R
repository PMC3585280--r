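#' Run the full analysis for one unit
#'
#' End-to-end pipeline on a synthetic unit: simulate the diffusive warm-up of
#' the pouch phantom, generate a PRF calibration series and fit the thermal
#' coefficient, encode the temperature fields as drifting, noisy
#' phase-difference images, decode them back to temperature maps (median
#' drift correction + PRF conversion), extract mean/surface/core time courses
#' by the volume-fraction tangent method, fit the warm-up models and derive
#' the cold-chain constants. All randomness flows from `seed`.
#'
#' @param spec A [pouch_phantom_spec()]; its `seed` is used unless `seed` is
#'   given.
#' @param acq An [acquisition_config()].
#' @param alpha_true True PRF coefficient used by the generator.
#' @param phase_noise_sd Phase noise in radians (also used, scaled, for the
#'   calibration series).
#' @param drift Scanner drift passed to [encode_phases()]; default a slow
#'   linear drift of 0.02 rad per time point.
#' @param seed Integer seed overriding `spec$seed`.
#' @param out_dir Optional directory; when given, the fit report (JSON) and
#'   curve tables (CSV) are written there.
#' @return A list of class `unit_report`: `fit` ([warmup_fit()]), `derived`
#'   ([derived_constants()]), `calibration`, `geometry`, `curves`,
#'   `core_position`, `series` attributes (`biot`, `energy_balance_error`)
#'   and the `seed` used.
#' @export
run_unit <- function(spec = pouch_phantom_spec(),
                     acq = acquisition_config(),
                     alpha_true = 1.05e-8,
                     phase_noise_sd = 0.01,
                     drift = function(t) 0.02 * t / spec$sample_interval_min,
                     seed = NULL,
                     out_dir = NULL) {
  stopifnot(inherits(spec, "pouch_phantom_spec"))
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  stage <- function(what, expr) tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))

  phantom <- stage("phantom", make_pouch_phantom(spec))
  series_true <- stage("simulate", simulate_warmup(spec, phantom))
  cal_series <- stage("calibrate", generate_calibration_series(
    alpha_true, acq, noise_sd = phase_noise_sd, seed = spec$seed + 1L))
  calib <- stage("calibrate", fit_prf_coefficient(
    cal_series$temperatures, cal_series$phase_diffs, acq))
  phases <- stage("encode", encode_phases(
    series_true, phantom, calib, acq, drift = drift,
    noise_sd = phase_noise_sd, seed = spec$seed + 2L))
  series <- stage("convert", decode_phases(phases, calib, acq))
  curves <- stage("extract", surface_core_curves(series, phantom$rbc_mask))
  fit <- stage("fit", fit_warmup_curves(curves))
  derived <- stage("derive", derived_constants(fit))
  geometry <- stage("geometry", geometry_summary(
    phantom$rbc_mask, phantom$pouch_mask, spec$voxel_mm))
  core_pos <- stage("core", thermal_core_position(series, phantom$rbc_mask))

  report <- structure(list(
    fit = fit, derived = derived, calibration = calib, geometry = geometry,
    curves = curves, core_position = core_pos,
    biot = attr(series_true, "biot"),
    energy_balance_error = attr(series_true, "energy_balance_error"),
    t_storage = spec$t_storage, t_ambient = spec$t_ambient,
    seed = spec$seed), class = "unit_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fit_report(report, file.path(out_dir, "fit_report.json"))
    write_curves_csv(curves, file.path(out_dir, "warmup_curves.csv"))
  }
  report
}

#' @export
print.unit_report <- function(x, ...) {
  cat("Unit analysis report (seed", x$seed, ")\n")
  print(x$fit)
  cat(sprintf("  t_spread = %.1f min, theta_spread_max = %.3f, ratios %.2f / %.2f\n",
              x$derived$t_spread, x$derived$theta_spread_max,
              x$derived$ratio_sm, x$derived$ratio_sc))
  cat(sprintf("  alpha = %.3e /degC, Biot = %.2f\n",
              x$calibration$alpha, x$biot))
  invisible(x)
}

#' Run the pipeline over a cohort of units
#'
#' Applies [run_unit()] to each spec, skipping (and reporting) units whose
#' analysis fails, and summarises the surviving fits with [cohort_summary()].
#'
#' @param specs List of at least 3 [pouch_phantom_spec()] objects.
#' @param ... Passed to [run_unit()].
#' @return A list of class `cohort_report` with `reports`, `table`
#'   ([cohort_table()]), `summary` ([cohort_summary()]) and `skipped`
#'   (named failure messages).
#' @export
run_cohort <- function(specs, ...) {
  if (length(specs) < 3) stop("at least 3 unit configurations are required")
  reports <- list(); skipped <- character()
  for (i in seq_along(specs)) {
    res <- tryCatch(run_unit(specs[[i]], ...), error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[as.character(i)]] <- conditionMessage(res)
      message(sprintf("unit %d skipped: %s", i, conditionMessage(res)))
    } else reports[[length(reports) + 1]] <- res
  }
  if (length(reports) < 3)
    stop("fewer than 3 units analysed successfully")
  tab <- cohort_table(lapply(reports, `[[`, "fit"),
                      lapply(reports, `[[`, "geometry"),
                      vapply(reports, `[[`, numeric(1), "t_storage"),
                      vapply(reports, `[[`, numeric(1), "t_ambient"))
  structure(list(reports = reports, table = tab,
                 summary = cohort_summary(tab), skipped = skipped),
            class = "cohort_report")
}

#' Serialize a unit report as flat JSON
#'
#' Writes the fitted and derived constants with the flat key layout
#' `tau_mean_min`, `tau_surface_min`, `tau_core_min`, `delta_surface`,
#' `delta_core`, `r2_*`, `sd_*`, `t_spread_min`, `theta_spread_max`,
#' `ratio_sm`, `ratio_sc`, plus calibration and provenance fields.
#'
#' @param report A `unit_report` (or a bare [warmup_fit()]).
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_fit_report <- function(report, path) {
  fit <- if (inherits(report, "warmup_fit")) report else report$fit
  derived <- if (inherits(report, "warmup_fit")) derived_constants(report)
             else report$derived
  out <- list(
    tau_mean_min = fit$tau_mean, tau_surface_min = fit$tau_surface,
    tau_core_min = fit$tau_core, delta_surface = fit$delta_surface,
    delta_core = fit$delta_core,
    r2_mean = fit$r2_mean, r2_surface = fit$r2_surface, r2_core = fit$r2_core,
    sd_tau_mean_min = fit$sd_tau_mean, sd_tau_surface_min = fit$sd_tau_surface,
    sd_tau_core_min = fit$sd_tau_core,
    sd_delta_surface = fit$sd_delta_surface,
    sd_delta_core = fit$sd_delta_core,
    t_spread_min = derived$t_spread,
    theta_spread_max = derived$theta_spread_max,
    ratio_sm = derived$ratio_sm, ratio_sc = derived$ratio_sc)
  if (inherits(report, "unit_report")) {
    out$alpha_per_degC <- report$calibration$alpha
    out$t_storage_degC <- report$t_storage
    out$t_ambient_degC <- report$t_ambient
    out$seed <- report$seed
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a flat JSON fit report
#'
#' @param path JSON path written by [write_fit_report()].
#' @return A list with a [warmup_fit()] under `fit` and the remaining keys.
#' @export
read_fit_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- warmup_fit(x$tau_mean_min, x$tau_surface_min, x$tau_core_min,
                    x$delta_surface, x$delta_core,
                    r2_mean = x$r2_mean, r2_surface = x$r2_surface,
                    r2_core = x$r2_core,
                    sd_tau_mean = x$sd_tau_mean_min,
                    sd_tau_surface = x$sd_tau_surface_min,
                    sd_tau_core = x$sd_tau_core_min,
                    sd_delta_surface = x$sd_delta_surface,
                    sd_delta_core = x$sd_delta_core)
  list(fit = fit, extra = x[setdiff(names(x), c(
    "tau_mean_min", "tau_surface_min", "tau_core_min", "delta_surface",
    "delta_core", "r2_mean", "r2_surface", "r2_core", "sd_tau_mean_min",
    "sd_tau_surface_min", "sd_tau_core_min", "sd_delta_surface",
    "sd_delta_core"))])
}

#' Write warm-up curves as tidy CSV
#'
#' Long format with columns `kind` (`mean`, `surface`, `core`), `T_celsius`
#' and `t_min`.
#'
#' @param curves A `warmup_curves` object.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  stopifnot(inherits(curves, "warmup_curves"))
  df <- rbind(
    data.frame(kind = "mean", T_celsius = curves$t_mean,
               t_min = curves$times),
    data.frame(kind = "surface", T_celsius = curves$surface$T_celsius,
               t_min = curves$surface$t_min),
    data.frame(kind = "core", T_celsius = curves$core$T_celsius,
               t_min = curves$core$t_min))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read warm-up curves from tidy CSV
#'
#' Reconstructs a `warmup_curves` object written by [write_curves_csv()].
#' Storage and ambient temperatures are required because the CSV stores only
#' absolute temperatures.
#'
#' @param path CSV path.
#' @param t_storage,t_ambient Temperatures in degrees Celsius.
#' @return A `warmup_curves` object.
#' @export
read_curves_csv <- function(path, t_storage, t_ambient) {
  df <- utils::read.csv(path)
  m <- df[df$kind == "mean", ]
  structure(list(times = m$t_min, t_mean = m$T_celsius,
                 surface = df[df$kind == "surface", c("T_celsius", "t_min")],
                 core = df[df$kind == "core", c("T_celsius", "t_min")],
                 t_storage = t_storage, t_ambient = t_ambient,
                 skipped = numeric()),
            class = "warmup_curves")
}

#' Write / read a temperature series as NIfTI plus JSON sidecar
#'
#' The 4-D temperature stack is stored as `series.nii.gz` and the acquisition
#' context (`times`, `t_storage`, `t_ambient`, `voxel_mm`) as
#' `series.json` in `dir`.
#'
#' @param series A [temperature_series()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_temperature_series <- function(series, dir) {
  stopifnot(inherits(series, "temperature_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(RNifti::asNifti(series$maps,
                                     pixdim = c(series$voxel_mm, 1)),
                     file.path(dir, "series.nii.gz"))
  jsonlite::write_json(list(times_min = series$times,
                            t_storage_degC = series$t_storage,
                            t_ambient_degC = series$t_ambient,
                            voxel_mm = series$voxel_mm),
                       file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_temperature_series
#' @export
read_temperature_series <- function(dir) {
  maps <- as.array(RNifti::readNifti(file.path(dir, "series.nii.gz")))
  meta <- jsonlite::read_json(file.path(dir, "series.json"),
                              simplifyVector = TRUE)
  temperature_series(maps, meta$times_min, meta$t_storage_degC,
                     meta$t_ambient_degC, voxel_mm = meta$voxel_mm)
}
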