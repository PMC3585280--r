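#' Pouch phantom specification
#'
#' Geometry and thermal parameters driving the synthetic warm-up generator.
#' Defaults emulate a leukoreduced RBC unit in SAGM: pouch height 13.1 cm,
#' width (thickness) 3.4 cm and depth 6.44 cm with an 11.15% SAGM supernatant
#' layer, giving a pouch volume near 287 ml and an RBC volume near 255 ml.
#' Thermal properties are water-like (diffusivity 0.143 mm^2/s, volumetric
#' heat capacity 4.0e6 J/(m^3 degC), hence conductivity
#' k = kappa * rho_c = 0.572 W/(m degC)); the convective surface coefficient
#' default (13.86 W/(m^2 degC)) is the output of [calibrate_h_conv()] on this
#' geometry, placing the fitted mean-temperature time constant near 55.3 min.
#'
#' @param grid_dim Voxel grid `c(rows, cols, slices)`; rows are vertical.
#' @param voxel_mm Voxel dimensions in mm, `c(row, col, slice)`.
#' @param pouch_height_cm,pouch_width_cm,pouch_depth_cm Pouch extents in cm
#'   (height along rows, width along columns, depth across slices).
#' @param corner_radius_cm Corner rounding of the pouch cross-section in cm.
#' @param sagm_layer_fraction Fraction of the pouch height occupied by the
#'   SAGM supernatant layer at the top (excluded from the RBC mask).
#' @param kappa_mm2_s Thermal diffusivity in mm^2/s.
#' @param rho_c Volumetric heat capacity in J/(m^3 degC).
#' @param h_conv Convective surface coefficient in W/(m^2 degC).
#' @param t_storage,t_ambient Storage/ambient temperature in degrees Celsius.
#' @param duration_min Simulated warm-up duration in minutes.
#' @param sample_interval_min Sampling interval in minutes.
#' @param seed Integer seed recorded with generated data.
#' @return An object of class `pouch_phantom_spec`.
#' @export
pouch_phantom_spec <- function(grid_dim = c(72, 24, 7),
                               voxel_mm = c(2, 2, 9.2),
                               pouch_height_cm = 13.1,
                               pouch_width_cm = 3.4,
                               pouch_depth_cm = 6.44,
                               corner_radius_cm = 0.8,
                               sagm_layer_fraction = 0.1115,
                               kappa_mm2_s = 0.143,
                               rho_c = 4.0e6,
                               h_conv = 13.86,
                               t_storage = 3.6,
                               t_ambient = 21.25,
                               duration_min = 69,
                               sample_interval_min = 3,
                               seed = 1L) {
  stopifnot(all(grid_dim >= 1), all(voxel_mm > 0),
            pouch_height_cm > 0, pouch_width_cm > 0, pouch_depth_cm > 0,
            corner_radius_cm >= 0, sagm_layer_fraction >= 0,
            sagm_layer_fraction < 1, kappa_mm2_s > 0, rho_c > 0, h_conv > 0,
            duration_min > 0, sample_interval_min > 0)
  structure(list(grid_dim = as.integer(grid_dim), voxel_mm = voxel_mm,
                 pouch_height_cm = pouch_height_cm,
                 pouch_width_cm = pouch_width_cm,
                 pouch_depth_cm = pouch_depth_cm,
                 corner_radius_cm = corner_radius_cm,
                 sagm_layer_fraction = sagm_layer_fraction,
                 kappa_mm2_s = kappa_mm2_s, rho_c = rho_c, h_conv = h_conv,
                 conductivity = kappa_mm2_s * 1e-6 * rho_c,
                 t_storage = t_storage, t_ambient = t_ambient,
                 duration_min = duration_min,
                 sample_interval_min = sample_interval_min,
                 seed = as.integer(seed)),
            class = "pouch_phantom_spec")
}

#' Build phantom masks from a pouch specification
#'
#' Voxelises the pouch as a rounded-rectangle slab centred in the grid, with
#' the SAGM layer occupying the top `sagm_layer_fraction` of the pouch height
#' (excluded from the RBC mask) and two reference-phantom blobs placed in the
#' free columns beside the pouch. Masks are mutually disjoint.
#'
#' @param spec A [pouch_phantom_spec()].
#' @return A list with logical arrays `rbc_mask`, `sagm_mask`, `pouch_mask`
#'   (= RBC | SAGM) and `ref_masks` (list of two).
#' @export
make_pouch_phantom <- function(spec) {
  stopifnot(inherits(spec, "pouch_phantom_spec"))
  gd <- spec$grid_dim; vm <- spec$voxel_mm
  h <- spec$pouch_height_cm * 10; w <- spec$pouch_width_cm * 10
  d <- spec$pouch_depth_cm * 10; r <- spec$corner_radius_cm * 10
  tol <- 1e-9
  if (h > (gd[1] - 4) * vm[1] + tol || w > (gd[2] - 4) * vm[2] + tol ||
      d > gd[3] * vm[3] + tol)
    stop("pouch exceeds the grid (a 2-voxel margin is required in-plane)")
  # voxelise to the nearest whole-voxel extent, centred in the grid, so the
  # discrete pouch matches the requested dimensions to within half a voxel
  n_ext <- pmin(round(c(h, w, d) / vm), gd)
  sel <- lapply(1:3, function(a)
    seq(floor((gd[a] - n_ext[a]) / 2) + 1, length.out = n_ext[a]))
  # rounded rectangle in the (row, col) plane: voxel centres within the
  # corner radius of the shrunken rectangle
  yc <- (sel[[1]] - mean(sel[[1]])) * vm[1]
  xc <- (sel[[2]] - mean(sel[[2]])) * vm[2]
  hh <- n_ext[1] * vm[1] / 2; ww <- n_ext[2] * vm[2] / 2
  inplane <- outer(pmax(abs(yc) - (hh - r), 0)^2,
                   pmax(abs(xc) - (ww - r), 0)^2, `+`) <= r^2
  pouch <- array(FALSE, gd)
  for (k in sel[[3]]) pouch[sel[[1]], sel[[2]], k] <- inplane
  if (!any(pouch)) stop("pouch mask is empty; check geometry")
  # SAGM layer: top rows of the pouch (small row index = top)
  rows_in <- which(apply(pouch, 1, any))
  n_sagm <- round(spec$sagm_layer_fraction * length(rows_in))
  sagm <- array(FALSE, gd)
  if (n_sagm > 0) {
    sagm_rows <- rows_in[seq_len(n_sagm)]
    sagm[sagm_rows, , ] <- pouch[sagm_rows, , ]
  }
  rbc <- pouch & !sagm
  # two reference phantoms in the free columns, clear of the pouch
  cols_in <- which(apply(pouch, 2, any))
  mid_r <- round(gd[1] / 2); mid_z <- ceiling(gd[3] / 2)
  blob <- function(cols) {
    m <- array(FALSE, gd)
    m[(mid_r - 2):(mid_r + 2), cols,
      max(1, mid_z - 1):min(gd[3], mid_z + 1)] <- TRUE
    m
  }
  ref1 <- blob(seq_len(max(1, min(cols_in) - 2)))
  ref2 <- blob(seq(min(gd[2], max(cols_in) + 2), gd[2]))
  if (any(ref1 & pouch) || any(ref2 & pouch))
    stop("reference phantoms overlap the pouch; widen the grid")
  list(rbc_mask = rbc, sagm_mask = sagm, pouch_mask = pouch,
       ref_masks = list(ref1, ref2))
}

# shift a 3-D array by one voxel along an axis, padding with `fill`
.shift3 <- function(arr, axis, by, fill) {
  d <- dim(arr); out <- array(fill, d)
  idx_src <- idx_dst <- lapply(d, seq_len)
  if (by > 0) { idx_dst[[axis]] <- 2:d[axis]; idx_src[[axis]] <- 1:(d[axis] - 1) }
  else        { idx_dst[[axis]] <- 1:(d[axis] - 1); idx_src[[axis]] <- 2:d[axis] }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Simulate diffusive warm-up of the pouch phantom
#'
#' Solves the heat equation \eqn{\partial T/\partial t = \kappa \nabla^2 T} on
#' the pouch mask with a convective (Robin) surface boundary
#' \eqn{-k \, \partial T/\partial n = h_{conv} (T - T_{ambient})} and uniform
#' initial condition `t_storage`, by an explicit finite-difference scheme with
#' automatic sub-stepping to satisfy the stability limit. Axes of length 1
#' are treated as insulated (enabling 1-D slab configurations). Voxels outside
#' the pouch are held at ambient temperature for display purposes; they do not
#' exchange heat by conduction.
#'
#' @param spec A [pouch_phantom_spec()].
#' @param phantom Optional phantom from [make_pouch_phantom()]; built from
#'   `spec` when missing. Any list with a `pouch_mask` works, so arbitrary
#'   body shapes (slabs, boxes) can be simulated.
#' @return A [temperature_series()] sampled every `sample_interval_min`, with
#'   attributes `biot` (Biot number \eqn{h L_c / k}, \eqn{L_c = V/A}),
#'   `surface_area_m2`, `volume_m3`, `n_substeps` and `energy_balance_error`
#'   (largest per-step relative mismatch between the enthalpy change and the
#'   boundary heat influx).
#' @export
simulate_warmup <- function(spec, phantom = NULL) {
  stopifnot(inherits(spec, "pouch_phantom_spec"))
  if (is.null(phantom)) phantom <- make_pouch_phantom(spec)
  mask <- phantom$pouch_mask
  gd <- dim(mask); dm <- spec$voxel_mm * 1e-3          # voxel size in m
  kappa <- spec$kappa_mm2_s * 1e-6                     # m^2/s
  k_cond <- spec$conductivity; h <- spec$h_conv; rho_c <- spec$rho_c
  axes <- which(gd > 1)
  # per-axis boundary-face conductance: conduction from the voxel centre to
  # the face in series with surface convection (finite-volume Robin flux)
  g_face <- 1 / (1 / h + dm / (2 * k_cond))
  # neighbour-inside indicators and per-voxel convective rate (1/s per degC)
  nb_in <- list(); conv_rate <- array(0, gd)
  for (a in axes) for (s in c(-1, 1)) {
    nb <- .shift3(mask, a, s, FALSE)
    nb_in[[paste(a, s)]] <- nb
    conv_rate <- conv_rate + (!nb) * g_face[a] / (rho_c * dm[a])
  }
  face_area <- vapply(axes, function(a) prod(dm[-a]), numeric(1))
  names(face_area) <- axes
  area <- 0
  for (a in axes) for (s in c(-1, 1))
    area <- area + sum(mask & !nb_in[[paste(a, s)]]) * face_area[[as.character(a)]]
  vol <- sum(mask) * prod(dm)
  biot <- h * (vol / area) / k_cond

  # stability: rate of the most constrained voxel (all faces counted)
  rate <- sum(2 * kappa / dm[axes]^2) +
    sum(2 * g_face[axes] / (rho_c * dm[axes]))
  dt_samp <- spec$sample_interval_min * 60
  n_sub <- ceiling(dt_samp * rate / 0.9)
  dt <- dt_samp / n_sub
  if (!is.finite(dt) || dt <= 0)
    stop(sprintf("unstable configuration: %d sub-steps required", n_sub))

  times <- seq(0, spec$duration_min, by = spec$sample_interval_min)
  Tarr <- array(spec$t_ambient, gd)
  Tarr[mask] <- spec$t_storage
  maps <- array(NA_real_, c(gd, length(times)))
  maps[, , , 1] <- Tarr
  max_bal_err <- 0
  for (it in 2:length(times)) {
    for (sub in seq_len(n_sub)) {
      dT <- array(0, gd)
      for (a in axes) for (s in c(-1, 1)) {
        nb <- nb_in[[paste(a, s)]]
        Tn <- .shift3(Tarr, a, s, spec$t_ambient)
        # conductive exchange with inside neighbours; boundary faces are
        # handled below through conv_rate
        dT <- dT + ifelse(nb, kappa / dm[a]^2 * (Tn - Tarr), 0)
      }
      dT <- dT + conv_rate * (spec$t_ambient - Tarr)
      step <- dt * dT
      influx <- rho_c * dt *
        sum((conv_rate * (spec$t_ambient - Tarr))[mask]) * prod(dm)
      denth <- rho_c * sum(step[mask]) * prod(dm)
      if (abs(influx) > 1e-12)
        max_bal_err <- max(max_bal_err, abs(denth - influx) / abs(influx))
      Tarr[mask] <- Tarr[mask] + step[mask]
      if (any(!is.finite(Tarr[mask])))
        stop(sprintf("simulation diverged; %d sub-steps were insufficient", n_sub))
    }
    maps[, , , it] <- Tarr
  }
  out <- temperature_series(maps, times, spec$t_storage, spec$t_ambient,
                            voxel_mm = spec$voxel_mm)
  attr(out, "biot") <- biot
  attr(out, "surface_area_m2") <- area
  attr(out, "volume_m3") <- vol
  attr(out, "n_substeps") <- n_sub
  attr(out, "energy_balance_error") <- max_bal_err
  out
}

#' Calibrate the convective surface coefficient
#'
#' Secant iteration on `h_conv` such that the lumped-capacitance fit to the
#' simulated mean RBC temperature returns a target time constant. Used once to
#' fix the default `h_conv` of [pouch_phantom_spec()].
#'
#' @param spec A [pouch_phantom_spec()] (its `h_conv` is the starting value).
#' @param target_tau_mean Target fitted mean time constant in minutes.
#' @param tol Convergence tolerance on the fitted time constant, minutes.
#' @param max_iter Maximum secant iterations.
#' @return A list with `h_conv`, `tau_mean` achieved and `iterations`.
#' @export
calibrate_h_conv <- function(spec, target_tau_mean = 55.3, tol = 0.1,
                             max_iter = 12) {
  tau_of <- function(h) {
    sp <- spec; sp$h_conv <- h
    phantom <- make_pouch_phantom(sp)
    series <- simulate_warmup(sp, phantom)
    th <- relative_difference(mean_temperature(series, phantom$rbc_mask),
                              sp$t_ambient, sp$t_storage)
    fit_exponential(series$times, th)$tau
  }
  h0 <- spec$h_conv; h1 <- spec$h_conv * 1.2
  f0 <- tau_of(h0) - target_tau_mean; f1 <- tau_of(h1) - target_tau_mean
  for (i in seq_len(max_iter)) {
    if (abs(f1) < tol) break
    h2 <- h1 - f1 * (h1 - h0) / (f1 - f0)
    h2 <- max(h2, 0.1 * h1)
    h0 <- h1; f0 <- f1; h1 <- h2; f1 <- tau_of(h1) - target_tau_mean
  }
  list(h_conv = h1, tau_mean = f1 + target_tau_mean, iterations = i)
}

# evaluate a drift model (numeric scalar/vector or function of time) at times
.drift_at <- function(drift, times) {
  if (is.null(drift)) return(rep(0, length(times)))
  if (is.function(drift)) return(vapply(times, drift, numeric(1)))
  if (length(drift) == 1) return(rep(drift, length(times)))
  if (length(drift) != length(times))
    stop("drift vector length does not match the number of time points")
  drift
}

#' Encode a temperature series as PRF phase-difference images
#'
#' Inverts the PRF temperature equation to produce synthetic phase-difference
#' maps: sample voxels get
#' \eqn{\phi = 2\pi \alpha \gamma B_0 TE (T - T_{storage})}, reference-phantom
#' voxels (held at ambient temperature throughout, so no thermal phase
#' accrues) get zero thermal phase, and the scanner drift plus i.i.d. Gaussian
#' phase noise is added everywhere. The identical drift in sample and
#' reference regions is what makes median-based [drift_correct()] exact.
#'
#' @param series A [temperature_series()].
#' @param phantom Phantom masks from [make_pouch_phantom()].
#' @param calib A `prf_calibration`.
#' @param acq An [acquisition_config()].
#' @param drift Scanner drift in radians: scalar, vector (per time point) or
#'   function of time in minutes. `NULL` for none.
#' @param noise_sd Standard deviation of the additive phase noise, radians.
#' @param seed Integer seed for the noise generator.
#' @return A list of class `phase_image_series`: `phases` (4-D array, rad),
#'   `times`, `masks`, `t_storage`, `t_ambient`, `noise_sd`, `seed`, and the
#'   per-time-point `drift` actually applied.
#' @export
encode_phases <- function(series, phantom, calib, acq, drift = NULL,
                          noise_sd = 0, seed = 1L) {
  stopifnot(inherits(series, "temperature_series"),
            inherits(calib, "prf_calibration"),
            inherits(acq, "acquisition_config"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  d <- dim(series$maps)
  drift_t <- .drift_at(drift, series$times)
  sample_mask <- phantom$pouch_mask
  phases <- array(0, d)
  for (it in seq_len(d[4])) {
    ph <- array(0, d[1:3])
    ph[sample_mask] <- temperature_to_phase(
      series$maps[, , , it][sample_mask], calib, series$t_storage, acq)
    phases[, , , it] <- ph + drift_t[it]
  }
  if (noise_sd > 0) {
    set.seed(seed)
    phases <- phases + array(stats::rnorm(length(phases), 0, noise_sd), d)
  }
  structure(list(phases = phases, times = series$times,
                 masks = phantom, t_storage = series$t_storage,
                 t_ambient = series$t_ambient, voxel_mm = series$voxel_mm,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 drift = drift_t),
            class = "phase_image_series")
}

#' Decode a phase-image series to temperature maps
#'
#' Applies [drift_correct()] (median over the reference phantoms) and
#' [phase_to_temperature()] to every time point of a synthetic or measured
#' phase-difference series.
#'
#' @param phase_series A `phase_image_series`.
#' @param calib A `prf_calibration`.
#' @param acq An [acquisition_config()].
#' @return A [temperature_series()].
#' @export
decode_phases <- function(phase_series, calib, acq) {
  stopifnot(inherits(phase_series, "phase_image_series"))
  d <- dim(phase_series$phases)
  maps <- array(NA_real_, d)
  for (it in seq_len(d[4])) {
    corr <- drift_correct(phase_series$phases[, , , it],
                          phase_series$masks$ref_masks)
    maps[, , , it] <- phase_to_temperature(corr, calib,
                                           phase_series$t_storage, acq)
  }
  temperature_series(maps, phase_series$times, phase_series$t_storage,
                     phase_series$t_ambient, voxel_mm = phase_series$voxel_mm)
}

#' Generate model-based relative-temperature curves
#'
#' Closed-form \eqn{\theta_{mean}}, \eqn{\theta_{surface}} and
#' \eqn{\theta_{core}} curves with optional i.i.d. Gaussian noise; the fast
#' route for fitting and recovery experiments.
#'
#' @param tau_mean,tau_surface,tau_core Time constants in minutes.
#' @param delta_surface,delta_core Dimensionless shifts.
#' @param times Times in minutes (default 24 points, 3-min sampling over
#'   0-69 min).
#' @param noise_sd Standard deviation of the additive noise on theta.
#' @param seed Integer seed; distinct seeds give distinct noise.
#' @return A data frame with columns `t_min`, `theta_mean`, `theta_surface`,
#'   `theta_core`.
#' @export
generate_model_curves <- function(tau_mean = 55.3, tau_surface = 41.4,
                                  tau_core = 76.8, delta_surface = 0.07,
                                  delta_core = 0.04,
                                  times = seq(0, 69, by = 3),
                                  noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  n <- length(times)
  noise <- matrix(0, n, 3)
  if (noise_sd > 0) {
    set.seed(seed)
    noise <- matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3)
  }
  data.frame(
    t_min = times,
    theta_mean = theta_mean_model(times, tau_mean) + noise[, 1],
    theta_surface = theta_shifted_model(times, tau_surface, delta_surface,
                                        "surface") + noise[, 2],
    theta_core = theta_shifted_model(times, tau_core, delta_core,
                                     "core") + noise[, 3])
}

#' Generate a PRF calibration series
#'
#' Synthetic calibration experiment: phase differences accrued between the
#' first (reference) temperature and each calibration temperature,
#' \eqn{\phi = 2\pi \gamma B_0 TE \, \alpha (T - T_1)}, plus Gaussian noise.
#'
#' @param alpha_true True PRF thermal coefficient per degree Celsius.
#' @param acq An [acquisition_config()].
#' @param temperatures Calibration temperatures in degrees Celsius (default
#'   12 steps over 1-18 degC).
#' @param noise_sd Phase noise standard deviation in radians.
#' @param seed Integer seed.
#' @return A list with `temperatures` and `phase_diffs`.
#' @export
generate_calibration_series <- function(alpha_true = 1.05e-8,
                                        acq = acquisition_config(),
                                        temperatures = seq(1, 18,
                                                           length.out = 12),
                                        noise_sd = 0, seed = 1L) {
  if (length(temperatures) < 2)
    stop("at least two calibration temperatures are required")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  phases <- .phase_per_degree(alpha_true, acq) *
    (temperatures - temperatures[1])
  if (noise_sd > 0) {
    set.seed(seed)
    phases <- phases + stats::rnorm(length(phases), 0, noise_sd)
  }
  list(temperatures = temperatures, phase_diffs = phases)
}
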