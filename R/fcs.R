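#' Confocal detection-volume geometry for FCS
#'
#' @param r0 Lateral (x-y) focal radius (m), > 0.
#' @param z0 Axial (z) focal radius (m), > 0; must not be smaller than `r0`
#'   (the structure ratio `r0^2/z0^2` lies in (0, 1]).
#' @return An object of class `instrument_geometry`.
#' @export
instrument_geometry <- function(r0, z0) {
  check_scalar(r0, "r0", min = 0, strict_min = TRUE)
  check_scalar(z0, "z0", min = 0, strict_min = TRUE)
  kappa <- r0^2 / z0^2
  if (kappa > 1)
    stop("structure ratio r0^2/z0^2 must be <= 1 (z0 >= r0)", call. = FALSE)
  structure(list(r0 = r0, z0 = z0, kappa = kappa),
            class = "instrument_geometry")
}

#' Calibration constants for Stokes--Einstein radius conversion
#'
#' The diffusion time of a sample is converted to a hydrodynamic radius by
#' linear scaling from a calibration measurement of a reference species with
#' known diffusion coefficient, via the Stokes--Einstein relation. Room
#' temperature and the viscosity of water are the defaults; the reference
#' diffusion coefficient and diffusion time are instrument-specific and
#' required.
#'
#' @param d_ref Reference diffusion coefficient (m^2/s), > 0.
#' @param taud_ref Reference diffusion time (s), > 0.
#' @param temperature Temperature (K), default 295.15.
#' @param viscosity Buffer viscosity (Pa s), default 1.0e-3.
#' @return An object of class `fcs_calibration`.
#' @export
fcs_calibration <- function(d_ref, taud_ref, temperature = 295.15,
                            viscosity = 1.0e-3) {
  check_scalar(d_ref, "d_ref", min = 0, strict_min = TRUE)
  check_scalar(taud_ref, "taud_ref", min = 0, strict_min = TRUE)
  check_scalar(temperature, "temperature", min = 0, strict_min = TRUE)
  check_scalar(viscosity, "viscosity", min = 0, strict_min = TRUE)
  structure(list(d_ref = d_ref, taud_ref = taud_ref,
                 temperature = temperature, viscosity = viscosity),
            class = "fcs_calibration")
}

#' Construct an FCS autocorrelation trace
#'
#' @param lags Strictly increasing, positive lag times (s).
#' @param g_values Autocorrelation amplitudes G(t) (dimensionless, finite).
#' @param sd Optional per-point uncertainties (used as weights in fitting).
#' @return An object of class `autocorrelation_trace`.
#' @export
autocorrelation_trace <- function(lags, g_values, sd = NULL) {
  if (!is.numeric(lags) || any(!is.finite(lags)) || any(lags <= 0))
    stop("lags must be finite and > 0", call. = FALSE)
  if (any(diff(lags) <= 0))
    stop("lags must be strictly increasing", call. = FALSE)
  if (!is.numeric(g_values) || length(g_values) != length(lags) ||
      any(!is.finite(g_values)))
    stop("g_values must be finite and match lags in length", call. = FALSE)
  if (!is.null(sd)) {
    if (length(sd) != length(lags) || any(!is.finite(sd)) || any(sd <= 0))
      stop("sd must be positive, finite, and match lags in length",
           call. = FALSE)
  }
  structure(list(lags = as.numeric(lags), g_values = as.numeric(g_values),
                 sd = sd),
            class = "autocorrelation_trace")
}

#' Read an FCS trace from delimited text
#'
#' Expects a header and two columns, lag time in seconds (`lag_s`) and the
#' autocorrelation amplitude (`g`); comma or tab separated (auto-detected).
#'
#' @param path Path to the trace file.
#' @return An [autocorrelation_trace()].
#' @export
read_fcs_trace <- function(path) {
  l1 <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", l1, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (ncol(df) < 2L)
    stop(sprintf("parse error in '%s': need lag and g columns", path),
         call. = FALSE)
  autocorrelation_trace(df[[1]], df[[2]])
}

#' Single-component 3D-diffusion autocorrelation model
#'
#' The standard single-component model for free 3D diffusion through a
#' Gaussian confocal volume:
#' \deqn{G(t) = 1 + \frac{1}{N}\,\frac{1}{1 + t/\tau_D}\,
#'   \left(1 + \frac{t}{\tau_D}\,\frac{r_0^2}{z_0^2}\right)^{-1/2},}
#' where `N` is the mean number of fluorophores in the detection volume and
#' `tauD` the characteristic diffusion time. Vectorized over `lag`.
#'
#' @param lag Lag time(s) (s), >= 0.
#' @param n_particles N, > 0.
#' @param taud Diffusion time (s), > 0.
#' @param geometry An [instrument_geometry()].
#' @return G(lag), dimensionless.
#' @examples
#' geom <- instrument_geometry(r0 = 2e-7, z0 = 1e-6)
#' model_autocorrelation(0, n_particles = 5, taud = 1e-4, geom)  # 1 + 1/5
#' @export
model_autocorrelation <- function(lag, n_particles, taud, geometry) {
  check_scalar(n_particles, "n_particles", min = 0, strict_min = TRUE)
  check_scalar(taud, "taud", min = 0, strict_min = TRUE)
  if (any(lag < 0)) stop("lag must be >= 0", call. = FALSE)
  x <- lag / taud
  1 + (1 / n_particles) / (1 + x) / sqrt(1 + x * geometry$kappa)
}

#' Fit the single-component model to an autocorrelation trace
#'
#' Weighted trust-region least squares (Levenberg--Marquardt) over
#' `(N, tauD)` with bounds `N` in (1e-3, 1e6) and `tauD` in (1e-7 s, 10 s).
#' Initial guesses: `N = 1/(G(first lag) - 1)` and `tauD` at the lag where
#' the decay `G - 1` falls to half its initial amplitude. A trace whose
#' amplitude `max(G) - 1` does not exceed the noise floor (estimated from
#' the long-lag tail) returns a non-converged fit with a diagnostic rather
#' than an error.
#'
#' @param trace An [autocorrelation_trace()] with at least 5 points.
#' @param geometry An [instrument_geometry()].
#' @return An object of class `fcs_fit`: list with `n_particles`, `taud`,
#'   `residual_norm`, `converged`, `message`.
#' @export
fit_autocorrelation <- function(trace, geometry) {
  if (!inherits(trace, "autocorrelation_trace"))
    stop("trace must be an autocorrelation_trace", call. = FALSE)
  if (length(trace$lags) < 5L)
    stop("trace must have at least 5 points", call. = FALSE)
  g <- trace$g_values
  lags <- trace$lags
  amp <- max(g) - 1
  ntail <- max(3L, ceiling(length(g) * 0.2))
  noise <- stats::sd(utils::tail(g, ntail))
  if (!is.finite(amp) || amp <= max(5 * noise, 1e-9))
    return(structure(list(n_particles = NA_real_, taud = NA_real_,
                          residual_norm = NA_real_, converged = FALSE,
                          message = "flat trace: amplitude below noise floor"),
                     class = "fcs_fit"))
  n0 <- min(max(1 / amp, 1e-3), 1e6)
  half <- which(g - 1 <= amp / 2)
  taud0 <- if (length(half)) lags[half[1]] else lags[ceiling(length(lags) / 2)]
  taud0 <- min(max(taud0, 1e-7), 10)
  w <- if (is.null(trace$sd)) rep(1, length(g)) else 1 / trace$sd^2
  fit <- tryCatch(
    minpack.lm::nlsLM(
      g ~ model_autocorrelation(lags, N, tauD, geometry),
      start = list(N = n0, tauD = taud0),
      lower = c(1e-3, 1e-7), upper = c(1e6, 10),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error"))
    return(structure(list(n_particles = NA_real_, taud = NA_real_,
                          residual_norm = NA_real_, converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "fcs_fit"))
  est <- stats::coef(fit)
  at_bound <- est[["N"]] <= 1e-3 * (1 + 1e-6) ||
    est[["N"]] >= 1e6 * (1 - 1e-6) ||
    est[["tauD"]] <= 1e-7 * (1 + 1e-6) || est[["tauD"]] >= 10 * (1 - 1e-6)
  structure(
    list(n_particles = unname(est[["N"]]), taud = unname(est[["tauD"]]),
         residual_norm = sqrt(sum(stats::resid(fit)^2)),
         converged = !at_bound,
         message = if (at_bound) "estimate at parameter bound" else "ok"),
    class = "fcs_fit"
  )
}

#' @export
print.fcs_fit <- function(x, ...) {
  if (isTRUE(x$converged))
    cat(sprintf("fcs_fit: N = %.4g, tauD = %.4g s (residual norm %.3g)\n",
                x$n_particles, x$taud, x$residual_norm))
  else cat("fcs_fit: not converged -", x$message, "\n")
  invisible(x)
}

#' Convert a diffusion time to a hydrodynamic radius
#'
#' Stokes--Einstein conversion scaled linearly from the calibration point:
#' \deqn{R_h = \frac{k_B T\, \tau_{D,sample}}{6 \pi \eta\, D_{ref}\,
#'   \tau_{D,ref}},}
#' equivalent to `Rh = kB*T / (6*pi*eta*D_sample)` with
#' `D_sample = D_ref * taud_ref / taud_sample` (both diffusion times refer
#' to the same focal volume, `tauD = r0^2 / (4 D)`). Vectorized over
#' `taud_sample`.
#'
#' @param taud_sample Sample diffusion time(s) (s), > 0.
#' @param cal An [fcs_calibration()].
#' @return Hydrodynamic radius (m).
#' @export
diffusion_time_to_radius <- function(taud_sample, cal) {
  if (!inherits(cal, "fcs_calibration"))
    stop("cal must be an fcs_calibration", call. = FALSE)
  if (any(!is.finite(taud_sample)) || any(taud_sample <= 0))
    stop("taud_sample must be finite and > 0", call. = FALSE)
  .kB * cal$temperature * taud_sample /
    (6 * pi * cal$viscosity * cal$d_ref * cal$taud_ref)
}

#' Fit a batch of traces and report hydrodynamic radii
#'
#' Fits each trace with [fit_autocorrelation()] and converts converged
#' diffusion times to radii; failed fits are reported as `NA` with their
#' diagnostic, preserving input order. The per-sample protocol of repeated
#' short acquisitions makes the spread across this series the readout of
#' sample polydispersity.
#'
#' @param traces List of [autocorrelation_trace()] objects.
#' @param geometry An [instrument_geometry()].
#' @param cal An [fcs_calibration()].
#' @return A data frame with one row per trace: `n_particles`, `taud_s`,
#'   `radius_m`, `converged`, `message`.
#' @export
radius_series <- function(traces, geometry, cal) {
  if (inherits(traces, "autocorrelation_trace")) traces <- list(traces)
  if (!is.list(traces) || length(traces) < 1L)
    stop("traces must be a non-empty list of autocorrelation traces",
         call. = FALSE)
  fits <- lapply(traces, fit_autocorrelation, geometry = geometry)
  data.frame(
    n_particles = vapply(fits, `[[`, numeric(1), "n_particles"),
    taud_s = vapply(fits, `[[`, numeric(1), "taud"),
    radius_m = vapply(fits, function(f)
      if (isTRUE(f$converged)) diffusion_time_to_radius(f$taud, cal)
      else NA_real_, numeric(1)),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    message = vapply(fits, `[[`, character(1), "message")
  )
}

#' Summarize a radius series
#'
#' Median and mean radius with interquartile range over the converged fits
#' of a [radius_series()]; both location summaries are reported because
#' either may be used as the per-sample size estimate.
#'
#' @param series Data frame from [radius_series()].
#' @return One-row data frame: `n_traces`, `n_converged`, `median_radius_m`,
#'   `mean_radius_m`, `iqr_radius_m`.
#' @export
summarize_radius_series <- function(series) {
  r <- series$radius_m[series$converged & is.finite(series$radius_m)]
  data.frame(
    n_traces = nrow(series),
    n_converged = length(r),
    median_radius_m = if (length(r)) stats::median(r) else NA_real_,
    mean_radius_m = if (length(r)) mean(r) else NA_real_,
    iqr_radius_m = if (length(r)) stats::IQR(r) else NA_real_
  )
}
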