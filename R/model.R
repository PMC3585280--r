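#' Relative temperature difference
#'
#' Converts an absolute temperature to the dimensionless relative temperature
#' difference \eqn{\theta = (T_{ambient} - T) / (T_{ambient} - T_{storage})}.
#' \eqn{\theta = 1} at storage temperature (onset of warm-up) and
#' \eqn{\theta = 0} at full equilibration with ambient temperature.
#'
#' @param temperature Temperature in degrees Celsius (vectorised).
#' @param t_ambient Ambient temperature in degrees Celsius.
#' @param t_storage Storage temperature in degrees Celsius.
#' @return Dimensionless relative temperature difference(s).
#' @seealso [temperature_from_theta()] for the inverse.
#' @export
#' @examples
#' relative_difference(10, t_ambient = 20, t_storage = 1)  # 9/19
relative_difference <- function(temperature, t_ambient, t_storage) {
  if (!is.finite(t_ambient) || !is.finite(t_storage))
    stop("ambient and storage temperatures must be finite")
  if (t_ambient == t_storage)
    stop("degenerate temperature scale: t_ambient equals t_storage")
  (t_ambient - temperature) / (t_ambient - t_storage)
}

#' @rdname relative_difference
#' @param theta Dimensionless relative temperature difference(s).
#' @export
temperature_from_theta <- function(theta, t_ambient, t_storage) {
  if (t_ambient == t_storage)
    stop("degenerate temperature scale: t_ambient equals t_storage")
  t_ambient - theta * (t_ambient - t_storage)
}

#' Lumped-capacitance warm-up model for the mean temperature
#'
#' Relative mean temperature difference under the lumped-capacitance model of
#' heat transfer: \eqn{\theta_{mean}(t) = \exp(-t/\tau)}. Valid when the
#' surface resistance to heat transfer dominates the internal resistance.
#'
#' @param t Time in minutes since exposure to ambient temperature (vectorised).
#' @param tau Time constant in minutes, `> 0`.
#' @return Dimensionless \eqn{\theta_{mean}(t)}.
#' @export
theta_mean_model <- function(t, tau) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive and finite")
  exp(-t / tau)
}

#' Shifted-exponential warm-up model for surface and core temperatures
#'
#' Surface and core relative temperature differences follow time-shifted
#' exponential decays: \eqn{\theta_{surface}(t) = \exp(-(t/\tau + \Delta))}
#' and \eqn{\theta_{core}(t) = \exp(-(t/\tau - \Delta))}. The shift
#' \eqn{\Delta} (in units of the time constant) expresses how much earlier
#' (surface) or later (core) the decay starts relative to the instantaneous
#' decay of the mean temperature. Near `t = 0` the core value may exceed 1;
#' this model artifact is retained, not clamped, so that the time-elimination
#' identities hold exactly.
#'
#' @inheritParams theta_mean_model
#' @param delta Dimensionless relative time shift, `>= 0`.
#' @param side `"surface"` or `"core"`.
#' @return Dimensionless \eqn{\theta(t)}.
#' @export
theta_shifted_model <- function(t, tau, delta, side = c("surface", "core")) {
  side <- match.arg(side)
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive and finite")
  if (!is.finite(delta) || delta < 0) stop("delta must be non-negative")
  sgn <- if (side == "surface") +1 else -1
  exp(-(t / tau + sgn * delta))
}

# log-linear initial estimate of tau; falls back to the time span when fewer
# than two positive thetas are available
.init_tau <- function(times, thetas) {
  ok <- thetas > 0 & is.finite(thetas)
  if (sum(ok) >= 2) {
    sl <- stats::coef(stats::lm(log(thetas[ok]) ~ times[ok]))[[2]]
    if (is.finite(sl) && sl < 0) return(-1 / sl)
  }
  max(diff(range(times)), 1)
}

.check_fit_input <- function(times, thetas, min_n) {
  if (length(times) != length(thetas)) stop("times and thetas differ in length")
  if (length(times) < min_n)
    stop(sprintf("at least %d points are required", min_n))
  if (any(!is.finite(times)) || any(!is.finite(thetas)))
    stop("non-finite values in input")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
}

.r_squared <- function(observed, fitted) {
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  1 - ss_res / ss_tot
}

#' Fit the lumped-capacitance exponential decay
#'
#' Nonlinear least-squares fit of \eqn{\theta(t) = \exp(-t/\tau)} by a
#' Levenberg-Marquardt optimiser, with \eqn{\tau} initialised from the
#' log-linear slope of \eqn{\ln\theta} versus \eqn{t}.
#'
#' @param times Strictly increasing times in minutes (at least 3).
#' @param thetas Relative temperature differences at `times`.
#' @return A list with `tau` (minutes), `r2` (coefficient of determination,
#'   \eqn{1 - SS_{res}/SS_{tot}}) and `sd_tau` (standard error of `tau`).
#' @export
fit_exponential <- function(times, thetas) {
  .check_fit_input(times, thetas, 3L)
  dat <- data.frame(t = times, th = thetas)
  fit <- tryCatch(
    minpack.lm::nlsLM(th ~ exp(-t / tau), data = dat,
                      start = list(tau = .init_tau(times, thetas)),
                      lower = 1e-6, upper = 1e4,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("exponential fit failed to converge: ",
                             conditionMessage(e)))
  tau <- stats::coef(fit)[["tau"]]
  list(tau = tau,
       r2 = .r_squared(dat$th, stats::fitted(fit)),
       sd_tau = summary(fit)$coefficients["tau", "Std. Error"])
}

#' Fit the shifted-exponential decay
#'
#' Joint nonlinear least-squares estimate of \eqn{(\tau, \Delta)} for the
#' surface or core model, \eqn{\tau} initialised from the log-linear slope and
#' \eqn{\Delta} at 0, with \eqn{\Delta} constrained to `[0, 1]`. A boundary
#' hit at \eqn{\Delta = 0} is reported via the `delta_at_boundary` flag.
#'
#' @inheritParams fit_exponential
#' @param side `"surface"` or `"core"`.
#' @return A list with `tau`, `delta`, `r2`, `sd_tau`, `sd_delta`,
#'   `covariance` (2x2 matrix) and `delta_at_boundary`.
#' @export
fit_shifted_exponential <- function(times, thetas, side = c("surface", "core")) {
  side <- match.arg(side)
  .check_fit_input(times, thetas, 4L)
  # side enters through the fixed sign column s
  dat <- data.frame(t = times, th = thetas,
                    s = if (side == "surface") +1 else -1)
  fit <- tryCatch(
    minpack.lm::nlsLM(th ~ exp(-(t / tau + s * delta)), data = dat,
                      start = list(tau = .init_tau(times, thetas), delta = 0),
                      lower = c(1e-6, 0), upper = c(1e4, 1),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("shifted-exponential fit failed to converge: ",
                             conditionMessage(e)))
  co <- stats::coef(fit)
  sm <- summary(fit)
  list(tau = co[["tau"]], delta = co[["delta"]],
       r2 = .r_squared(dat$th, stats::fitted(fit)),
       sd_tau = sm$coefficients["tau", "Std. Error"],
       sd_delta = sm$coefficients["delta", "Std. Error"],
       covariance = stats::vcov(fit),
       delta_at_boundary = co[["delta"]] <= 1e-10)
}

#' Construct a warm-up fit object
#'
#' Bundles the three fitted decays (mean, surface, core) into a single
#' `warmup_fit` object holding time constants (minutes), shifts
#' (dimensionless), coefficients of determination and parameter standard
#' errors. For physically sensible warm-ups
#' \eqn{\tau_{surface} < \tau_{mean} < \tau_{core}}; a violation triggers a
#' warning, not an error.
#'
#' @param tau_mean,tau_surface,tau_core Time constants in minutes.
#' @param delta_surface,delta_core Dimensionless shifts, `>= 0`.
#' @param r2_mean,r2_surface,r2_core Coefficients of determination.
#' @param sd_tau_mean,sd_tau_surface,sd_tau_core,sd_delta_surface,sd_delta_core
#'   Parameter standard errors (same units as the parameter); default 0.
#' @return An object of class `warmup_fit`.
#' @export
warmup_fit <- function(tau_mean, tau_surface, tau_core,
                       delta_surface, delta_core,
                       r2_mean = NA_real_, r2_surface = NA_real_,
                       r2_core = NA_real_,
                       sd_tau_mean = 0, sd_tau_surface = 0, sd_tau_core = 0,
                       sd_delta_surface = 0, sd_delta_core = 0) {
  taus <- c(tau_mean, tau_surface, tau_core)
  if (any(!is.finite(taus)) || any(taus <= 0))
    stop("all time constants must be positive and finite")
  if (delta_surface < 0 || delta_core < 0)
    stop("shifts must be non-negative")
  if (!(tau_surface < tau_mean && tau_mean < tau_core))
    warning("time constants violate tau_surface < tau_mean < tau_core; ",
            "fit may not be physically sensible")
  structure(list(
    tau_mean = tau_mean, tau_surface = tau_surface, tau_core = tau_core,
    delta_surface = delta_surface, delta_core = delta_core,
    r2_mean = r2_mean, r2_surface = r2_surface, r2_core = r2_core,
    sd_tau_mean = sd_tau_mean, sd_tau_surface = sd_tau_surface,
    sd_tau_core = sd_tau_core, sd_delta_surface = sd_delta_surface,
    sd_delta_core = sd_delta_core), class = "warmup_fit")
}

#' @export
print.warmup_fit <- function(x, ...) {
  cat("RBC warm-up fit (shifted-exponential family)\n")
  cat(sprintf("  tau_mean    = %6.1f min  (R2 = %s)\n", x$tau_mean,
              format(x$r2_mean, digits = 4)))
  cat(sprintf("  tau_surface = %6.1f min  delta_surface = %.3f  (R2 = %s)\n",
              x$tau_surface, x$delta_surface, format(x$r2_surface, digits = 4)))
  cat(sprintf("  tau_core    = %6.1f min  delta_core    = %.3f  (R2 = %s)\n",
              x$tau_core, x$delta_core, format(x$r2_core, digits = 4)))
  invisible(x)
}

#' Cohort-mean warm-up constants for leukoreduced RBC units
#'
#' Reference `warmup_fit` built from cohort-mean warm-up constants reported
#' for 47 leukoreduced RBC units in SAGM (MacoPharma collection systems)
#' warming from 1-6 degC storage toward 21.25 degC ambient temperature:
#' \eqn{\tau_{mean} = 55.3} min, \eqn{\tau_{surface} = 41.4} min,
#' \eqn{\tau_{core} = 76.8} min, \eqn{\Delta_{surface} = 0.07},
#' \eqn{\Delta_{core} = 0.04}. These drive the cold-chain calculators when no
#' unit-specific fit is available.
#'
#' @return A `warmup_fit` object.
#' @export
cohort_reference_fit <- function() {
  warmup_fit(tau_mean = 55.3, tau_surface = 41.4, tau_core = 76.8,
             delta_surface = 0.07, delta_core = 0.04,
             r2_mean = 0.999, r2_surface = 0.996, r2_core = 0.998,
             sd_tau_mean = 3.7, sd_tau_surface = 2.9, sd_tau_core = 7.1,
             sd_delta_surface = 0.02, sd_delta_core = 0.01)
}

# evaluate one of the three model curves from a warmup_fit
.theta_curve <- function(t, fit, which = c("mean", "surface", "core")) {
  which <- match.arg(which)
  switch(which,
         mean = theta_mean_model(t, fit$tau_mean),
         surface = theta_shifted_model(t, fit$tau_surface, fit$delta_surface,
                                       "surface"),
         core = theta_shifted_model(t, fit$tau_core, fit$delta_core, "core"))
}

#' Time of maximal relative temperature spread
#'
#' The relative temperature spread \eqn{\theta_{spread}(t) = \theta_{core}(t)
#' - \theta_{surface}(t)} attains its interior maximum at
#' \deqn{t^\ast = \frac{\ln(\tau_s/\tau_c) + \Delta_s + \Delta_c}
#'                     {1/\tau_c - 1/\tau_s},}
#' the unique root of \eqn{d\theta_{spread}/dt = 0}, which requires
#' \eqn{\tau_{surface} < \tau_{core}}.
#'
#' @param fit A [warmup_fit()] object.
#' @return Time of maximal spread in minutes.
#' @export
t_spread <- function(fit) {
  stopifnot(inherits(fit, "warmup_fit"))
  if (fit$tau_surface >= fit$tau_core)
    stop("no interior maximum: tau_surface must be smaller than tau_core")
  (log(fit$tau_surface / fit$tau_core) + fit$delta_surface + fit$delta_core) /
    (1 / fit$tau_core - 1 / fit$tau_surface)
}

#' Relative temperature spread at a given time
#'
#' \eqn{\theta_{spread}(t) = \theta_{core}(t) - \theta_{surface}(t)}, the
#' core-to-surface spread expressed as a fraction of the ambient-to-storage
#' temperature difference.
#'
#' @param t Time in minutes (vectorised).
#' @param fit A [warmup_fit()] object.
#' @return Dimensionless spread.
#' @export
theta_spread <- function(t, fit) {
  stopifnot(inherits(fit, "warmup_fit"))
  .theta_curve(t, fit, "core") - .theta_curve(t, fit, "surface")
}

#' Derived warm-up constants
#'
#' Computes the quantities derived from a warm-up fit: the time of maximal
#' spread, the maximal spread itself, and the time-constant quotients
#' \eqn{\tau_{surface}/\tau_{mean}} and \eqn{\tau_{surface}/\tau_{core}} that
#' govern the surface-to-mean and surface-to-core predictions.
#'
#' @param fit A [warmup_fit()] object.
#' @return A list with `t_spread` (min), `theta_spread_max`, `ratio_sm`
#'   and `ratio_sc` (all others dimensionless).
#' @export
derived_constants <- function(fit) {
  ts <- t_spread(fit)
  list(t_spread = ts,
       theta_spread_max = theta_spread(ts, fit),
       ratio_sm = fit$tau_surface / fit$tau_mean,
       ratio_sc = fit$tau_surface / fit$tau_core)
}

#' Predict mean and core temperature state from the surface state
#'
#' Eliminating time between the surface and mean (or core) decays yields
#' \deqn{\theta_{mean} = (\theta_s e^{\Delta_s})^{\tau_s/\tau_m}, \qquad
#'       \theta_{core} = e^{\Delta_c} (\theta_s e^{\Delta_s})^{\tau_s/\tau_c}.}
#' Only quotients of time constants appear, which makes the prediction largely
#' independent of pouch geometry. Near onset (\eqn{\theta_s = e^{-\Delta_s}})
#' the core prediction equals \eqn{e^{\Delta_c} > 1}, a documented model
#' artifact that is not clamped here.
#'
#' @param theta_surface Relative surface temperature difference in `(0, 1]`.
#' @param fit A [warmup_fit()] object.
#' @return Predicted relative mean (resp. core) temperature difference.
#' @export
predict_mean_from_surface <- function(theta_surface, fit) {
  stopifnot(inherits(fit, "warmup_fit"))
  if (any(theta_surface <= 0)) stop("theta_surface must be positive")
  (theta_surface * exp(fit$delta_surface))^(fit$tau_surface / fit$tau_mean)
}

#' @rdname predict_mean_from_surface
#' @export
predict_core_from_surface <- function(theta_surface, fit) {
  stopifnot(inherits(fit, "warmup_fit"))
  if (any(theta_surface <= 0)) stop("theta_surface must be positive")
  exp(fit$delta_core) *
    (theta_surface * exp(fit$delta_surface))^(fit$tau_surface / fit$tau_core)
}

#' Time for a temperature curve to reach a threshold
#'
#' Inverts the chosen warm-up model for the time at which the mean, surface or
#' core temperature reaches `t_thresh`. With
#' \eqn{\theta^\ast = (T_{ambient} - T_{thresh})/(T_{ambient} - T_{storage})}:
#' mean \eqn{t = -\tau_m \ln\theta^\ast}; surface
#' \eqn{t = \tau_s(-\Delta_s - \ln\theta^\ast)} clipped at 0 (the surface may
#' already exceed low thresholds at onset); core
#' \eqn{t = \tau_c(\Delta_c - \ln\theta^\ast)}.
#'
#' @param t_thresh Threshold temperature in degrees Celsius, strictly between
#'   storage and ambient.
#' @param t_storage,t_ambient Storage and ambient temperatures in degrees
#'   Celsius.
#' @param fit A [warmup_fit()] object.
#' @param which `"mean"`, `"surface"` or `"core"`.
#' @return Time in minutes.
#' @export
#' @examples
#' time_to_threshold(10, 1, 20, cohort_reference_fit(), "core")  # ~52 min
time_to_threshold <- function(t_thresh, t_storage, t_ambient, fit,
                              which = c("mean", "surface", "core")) {
  which <- match.arg(which)
  stopifnot(inherits(fit, "warmup_fit"))
  lo <- min(t_storage, t_ambient); hi <- max(t_storage, t_ambient)
  if (t_thresh <= lo || t_thresh >= hi)
    stop("threshold must lie strictly between storage and ambient temperature")
  theta_star <- relative_difference(t_thresh, t_ambient, t_storage)
  switch(which,
         mean = -fit$tau_mean * log(theta_star),
         surface = max(0, fit$tau_surface *
                            (-fit$delta_surface - log(theta_star))),
         core = fit$tau_core * (fit$delta_core - log(theta_star)))
}

#' Limiting ambient temperature for a hold time
#'
#' Largest ambient temperature such that the chosen temperature curve stays
#' below `t_thresh` for `t_hold` minutes outside refrigerated storage. With
#' \eqn{\theta^\ast = \theta(t_{hold})} the limit solves
#' \eqn{\theta^\ast = (T_{ambient} - T_{thresh})/(T_{ambient} - T_{storage})},
#' i.e. \eqn{T_{ambient} = (T_{thresh} - \theta^\ast T_{storage})
#' / (1 - \theta^\ast)}. This is the calculator behind the 30-minute rule:
#' for core temperature to stay below 10 degC after 30 min it bounds the
#' allowable room temperature given the storage temperature.
#'
#' @param t_storage Storage temperature in degrees Celsius.
#' @param t_hold Hold time outside storage in minutes, `> 0`.
#' @param t_thresh Temperature limit in degrees Celsius.
#' @param fit A [warmup_fit()] object.
#' @param which Which curve to bound; the regulatory limit concerns `"core"`.
#' @return Limiting ambient temperature in degrees Celsius (unrounded).
#' @export
#' @examples
#' limit_ambient(1, 30, 10, cohort_reference_fit())  # ~31.4 -> 31 degC
limit_ambient <- function(t_storage, t_hold, t_thresh, fit,
                          which = c("core", "mean", "surface")) {
  which <- match.arg(which)
  stopifnot(inherits(fit, "warmup_fit"))
  if (t_hold <= 0) stop("t_hold must be positive")
  theta_star <- .theta_curve(t_hold, fit, which)
  if (theta_star >= 1)
    stop("curve has not started to decay at t_hold (theta >= 1); ",
         "no finite ambient limit exists")
  (t_thresh - theta_star * t_storage) / (1 - theta_star)
}

#' First-order uncertainty bands for the model curves
#'
#' Gaussian propagation of the fitted-parameter standard deviations onto the
#' model curves. For the shifted models
#' \eqn{\sigma_\theta^2 = (\theta t/\tau^2)^2 \sigma_\tau^2 +
#' \theta^2 \sigma_\Delta^2}; for the mean curve the \eqn{\Delta} term is
#' absent. Parameter covariances are neglected (the cohort summary reports
#' independent SDs).
#'
#' @param fit A [warmup_fit()] object carrying `sd_*` entries.
#' @param t_grid Times in minutes at which to evaluate the bands.
#' @return A data frame with columns `t_min`, `sigma_mean`, `sigma_surface`,
#'   `sigma_core`.
#' @export
propagate_uncertainty <- function(fit, t_grid) {
  stopifnot(inherits(fit, "warmup_fit"))
  sds <- unlist(fit[grep("^sd_", names(fit))])
  if (any(sds < 0)) stop("standard deviations must be non-negative")
  band <- function(which, tau, sd_tau, sd_delta = 0) {
    th <- .theta_curve(t_grid, fit, which)
    sqrt((th * t_grid / tau^2)^2 * sd_tau^2 + th^2 * sd_delta^2)
  }
  data.frame(
    t_min = t_grid,
    sigma_mean = band("mean", fit$tau_mean, fit$sd_tau_mean),
    sigma_surface = band("surface", fit$tau_surface, fit$sd_tau_surface,
                         fit$sd_delta_surface),
    sigma_core = band("core", fit$tau_core, fit$sd_tau_core,
                      fit$sd_delta_core))
}
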