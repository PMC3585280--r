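#' MR acquisition configuration
#'
#' Holds the acquisition parameters entering the PRF temperature equation and
#' the sampling protocol of the warm-up experiment. Defaults correspond to a
#' 1.5 T gradient-echo protocol with TE = 20 ms, 1.1 x 1.1 x 7.5 mm voxels and
#' 20 time points at 3-min pause time.
#'
#' @param b0 Main magnetic field strength in tesla.
#' @param te Echo time in seconds.
#' @param gamma Gyromagnetic ratio of 1H in Hz per tesla (default 42.577e6).
#' @param voxel_mm Voxel dimensions in mm, `c(row, col, slice)`.
#' @param pause_time Sampling interval in minutes.
#' @param n_timepoints Number of acquired time points.
#' @param phase_sign `+1` if phase increases with temperature (default),
#'   `-1` for scanners with the opposite phase convention.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(b0 = 1.5, te = 0.02, gamma = 42.577e6,
                               voxel_mm = c(1.1, 1.1, 7.5),
                               pause_time = 3, n_timepoints = 20,
                               phase_sign = 1) {
  stopifnot(b0 > 0, te > 0, gamma > 0, all(voxel_mm > 0),
            pause_time > 0, n_timepoints > 0, phase_sign %in% c(-1, 1))
  structure(list(b0 = b0, te = te, gamma = gamma, voxel_mm = voxel_mm,
                 pause_time = pause_time, n_timepoints = n_timepoints,
                 phase_sign = phase_sign),
            class = "acquisition_config")
}

# phase accrued per degree Celsius: dphi/dT = 2*pi*alpha*gamma*B0*TE
.phase_per_degree <- function(alpha, acq) {
  acq$phase_sign * 2 * pi * alpha * acq$gamma * acq$b0 * acq$te
}

#' Fit the PRF thermal coefficient from a calibration series
#'
#' Ordinary least-squares fit of drift-corrected phase differences versus
#' temperature; the slope is converted to the PRF thermal coefficient
#' \eqn{\alpha = (1 / 2\pi\gamma B_0 TE) \cdot d\phi/dT} (fractional
#' resonance-frequency shift per degree Celsius, ~1e-8 for water-like media).
#'
#' @param temperatures Calibration temperatures in degrees Celsius (at least
#'   two distinct values; the calibration protocol spans roughly 1-18 degC).
#' @param phase_diffs Drift-corrected phase differences in radians, same
#'   length as `temperatures`.
#' @param acq An [acquisition_config()].
#' @return An object of class `prf_calibration` with fields `alpha` (per
#'   degC), `slope_dphi_dT` (rad per degC), `pearson_r` and `residual_sd`
#'   (rad).
#' @export
fit_prf_coefficient <- function(temperatures, phase_diffs, acq) {
  stopifnot(inherits(acq, "acquisition_config"))
  if (length(temperatures) != length(phase_diffs))
    stop("temperatures and phase_diffs differ in length")
  if (length(unique(temperatures)) < 2)
    stop("at least two distinct calibration temperatures are required")
  fit <- stats::lm(phase_diffs ~ temperatures)
  slope <- stats::coef(fit)[[2]]
  r <- if (stats::sd(phase_diffs) == 0) 0 else
    stats::cor(temperatures, phase_diffs)
  structure(list(
    alpha = slope / (acq$phase_sign * 2 * pi * acq$gamma * acq$b0 * acq$te),
    slope_dphi_dT = slope,
    pearson_r = r,
    residual_sd = stats::sd(stats::residuals(fit))),
    class = "prf_calibration")
}

#' @export
print.prf_calibration <- function(x, ...) {
  cat(sprintf("PRF calibration: alpha = %.4g / degC (dphi/dT = %.4g rad/degC, r = %.4f)\n",
              x$alpha, x$slope_dphi_dT, x$pearson_r))
  invisible(x)
}

#' Correct scanner phase drift using reference phantoms
#'
#' Subtracts the median phase over all reference-phantom voxels from every
#' voxel of the phase-difference map. Because the reference phantoms sit at
#' ambient temperature throughout the experiment, their phase carries only the
#' non-temperature-related scanner drift, which is shared with the sample; the
#' median makes the estimate robust to single corrupted reference voxels.
#'
#' @param phase_map Array of phase differences in radians (any shape).
#' @param reference_masks A logical array of the same shape, or a list of
#'   such arrays (one per phantom), marking reference-phantom voxels.
#' @return The corrected array, with the subtracted drift estimate attached
#'   as attribute `"drift"`.
#' @export
drift_correct <- function(phase_map, reference_masks) {
  if (!is.list(reference_masks)) reference_masks <- list(reference_masks)
  ref <- Reduce(`|`, reference_masks)
  if (!any(ref)) stop("reference masks are empty")
  if (!all(dim(ref) == dim(phase_map)))
    stop("reference mask shape does not match phase map")
  drift <- stats::median(phase_map[ref])
  out <- phase_map - drift
  attr(out, "drift") <- drift
  out
}

#' Convert corrected phase differences to temperature
#'
#' Voxelwise affine PRF conversion
#' \eqn{T = T_{storage} + \phi / (2\pi \alpha \gamma B_0 TE)}. Inputs are
#' assumed to be pre-unwrapped phase-difference maps; values outside
#' \eqn{(-\pi, \pi]} trigger a warning (at TE = 20 ms the <= 20 degC range
#' stays well within one phase cycle).
#'
#' @param phase_map Array of drift-corrected phase differences in radians.
#' @param calib A `prf_calibration` with non-zero `alpha`.
#' @param t_storage Storage temperature in degrees Celsius (temperature at
#'   the onset of the phase-difference series).
#' @param acq An [acquisition_config()].
#' @return Temperature array in degrees Celsius.
#' @seealso [temperature_to_phase()] for the inverse used by the simulator.
#' @export
phase_to_temperature <- function(phase_map, calib, t_storage, acq) {
  stopifnot(inherits(calib, "prf_calibration"),
            inherits(acq, "acquisition_config"))
  if (calib$alpha == 0) stop("calibration alpha is zero")
  if (any(phase_map > pi | phase_map <= -pi))
    warning("phase values outside (-pi, pi]: input may be wrapped")
  t_storage + phase_map / .phase_per_degree(calib$alpha, acq)
}

#' @rdname phase_to_temperature
#' @param temperature_map Temperature array in degrees Celsius.
#' @export
temperature_to_phase <- function(temperature_map, calib, t_storage, acq) {
  stopifnot(inherits(calib, "prf_calibration"),
            inherits(acq, "acquisition_config"))
  if (calib$alpha == 0) stop("calibration alpha is zero")
  (temperature_map - t_storage) * .phase_per_degree(calib$alpha, acq)
}
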