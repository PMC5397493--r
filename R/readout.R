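#' Exact population vector
#'
#' The second spatial Fourier coefficient of the activity profile,
#' \eqn{ER = \frac{1}{N}\sum_j e^{-2i\theta_j} m_j}: a complex number whose
#' argument encodes the orientation of the activity bump (through
#' \eqn{-\arg/2}) and whose magnitude measures its spatial modulation.
#'
#' @param m rate vector.
#' @param theta matching preferred-angle vector (radians).
#' @return A complex scalar.
#' @examples
#' th <- preferred_angles(200)
#' exact_pv(1 + cos(2 * (th - 0.7)), th)   # magnitude 0.5, encodes 0.7
#' @export
exact_pv <- function(m, theta) {
  stopifnot(length(m) == length(theta))
  mean(exp(-2i * theta) * m)
}

#' Poisson spike counts from rates
#'
#' Independent Poisson counts with mean \eqn{m_j \, dt} per unit per step:
#' the discrete spiking observed by a readout that samples a rate unit over
#' one integration step.
#'
#' @param m nonnegative rate vector (Hz).
#' @param dt time step (s).
#' @return Integer vector of counts.
#' @export
sample_spikes <- function(m, dt) {
  if (any(m < 0)) stop("rates must be nonnegative")
  stats::rpois(length(m), m * dt)
}

#' One Euler step of the sparse population-vector readout
#'
#' Leaky integration \eqn{\tau_{rd} \dot R = -R + \frac{1}{N_{read}}
#' \sum_j e^{-2i\theta_j}\, \chi_j(t)} where spikes enter as unit-area
#' impulses (counts divided by \code{dt}), so the fixed point is independent
#' of the step size and \eqn{E[R]} equals the population vector of the
#' sampled units' rates.
#'
#' @param R current complex readout value.
#' @param counts spike counts of the sampled units at this step.
#' @param theta preferred angles of the sampled units.
#' @param tau_rd readout time constant (s).
#' @param dt time step (s).
#' @return Updated complex readout value.
#' @export
sparse_pv_step <- function(R, counts, theta, tau_rd, dt) {
  stopifnot(length(counts) == length(theta))
  impulse <- mean(exp(-2i * theta) * counts) / dt
  R + (dt / tau_rd) * (-R + impulse)
}

#' Detected orientation from a population vector
#'
#' Inverts the encoding: \eqn{\hat\theta = (-\arg(pv)/2) \bmod \pi}.
#' Zero-magnitude population vectors have no defined angle and yield
#' \code{NA} (downstream error averages exclude and count them).
#'
#' @param pv complex population vector (vectorized).
#' @return Orientation(s) in [0, pi), radians; \code{NA} where |pv| = 0.
#' @export
detect_angle <- function(pv) {
  out <- (-Arg(pv) / 2) %% pi
  out[Mod(pv) == 0] <- NA_real_
  out
}

#' Circular orientation error
#'
#' Orientations live on a circle of period pi; the error between two of
#' them is \eqn{\min(|\Delta|, \pi - |\Delta|)}, at most pi/2 (orthogonal
#' orientations).
#'
#' @param theta_hat,theta_true orientations in [0, pi) (vectorized).
#' @return Error(s) in radians, in [0, pi/2].
#' @export
angular_error <- function(theta_hat, theta_true) {
  d <- abs(theta_hat - theta_true) %% pi
  pmin(d, pi - d)
}

#' Readout trace container
#'
#' @param times sample times (s), a uniform grid.
#' @param pv complex population-vector samples at those times.
#' @return Object of class \code{readout_trace}.
#' @export
readout_trace <- function(times, pv) {
  stopifnot(length(times) == length(pv))
  structure(list(times = times, pv = pv), class = "readout_trace")
}

#' Stimulus-detection error of a readout trace at a fixed lag
#'
#' For every stimulus window \eqn{[t_k, t_k + T)} the decoded orientation of
#' the (lagged) population vector is compared with the true stimulus
#' orientation and the circular error averaged over all in-window samples:
#' the discrete form of \eqn{\frac{1}{T N_{stim}} \sum_k
#' \int_{t_k}^{t_k+T} e(\hat\theta(R(t + lag)), \theta_k)\, dt}.
#' The lag absorbs the readout's integration latency. Samples with an
#' undefined angle (|pv| = 0) are excluded; their count is attached as the
#' \code{n_undefined} attribute.
#'
#' @param trace a [readout_trace()] (the trace must cover every lagged
#'   window).
#' @param schedule a [sample_schedule()] whose onsets are on the trace
#'   clock.
#' @param lag readout delay (s); rounded to the nearest trace sample.
#' @return Mean error (radians) with attribute \code{n_undefined}.
#' @export
detection_error <- function(trace, schedule, lag = 0) {
  w <- stim_window_samples(trace, schedule, max_lag = lag)
  dt <- w$dt
  lag_steps <- as.integer(round(lag / dt))
  th_hat <- detect_angle(trace$pv[w$idx + lag_steps])
  err <- angular_error(th_hat, w$theta)
  n_undef <- sum(is.na(err))
  out <- mean(err, na.rm = TRUE)
  attr(out, "n_undefined") <- n_undef
  out
}

# indices of all in-window trace samples plus matching true orientations;
# windows that a lag of max_lag would push past the trace end are dropped
stim_window_samples <- function(trace, schedule, max_lag = 0) {
  ev <- schedule$events
  if (nrow(ev) == 0L) stop("schedule has no events")
  n <- length(trace$times)
  if (n < 2L) stop("trace too short")
  dt <- trace$times[2L] - trace$times[1L]
  t0 <- trace$times[1L]
  T <- schedule$protocol$T
  usable <- ev$onset_s >= t0 & (ev$onset_s + T + max_lag) <= trace$times[n] + dt / 2
  ev <- ev[usable, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no stimulus window fits inside the trace")
  first <- as.integer(ceiling((ev$onset_s - t0) / dt - 1e-9)) + 1L
  len <- as.integer(round(T / dt))
  idx <- rep(first, each = len) + rep.int(seq_len(len) - 1L, nrow(ev))
  list(idx = idx, theta = rep(ev$theta_rad, each = len), dt = dt,
       n_events = nrow(ev))
}

#' Lag-optimized detection error
#'
#' Evaluates [detection_error()] on a grid of lags and returns the full
#' error curve together with the minimizing lag (smallest lag on ties).
#' All lags are scored on the same set of stimulus windows (those that fit
#' inside the trace even at the largest lag), so the curve is comparable
#' across the grid.
#'
#' @param trace a [readout_trace()].
#' @param schedule a [sample_schedule()] on the trace clock.
#' @param lag_grid lags to scan (s); default 0 to 0.2 s in 2 ms steps.
#' @return Object of class \code{error_curve}: list with \code{lags},
#'   \code{err} (radians), \code{err_deg}, \code{optimal_lag},
#'   \code{min_err} (radians), \code{min_err_deg}, \code{n_events} and
#'   \code{n_undefined}.
#' @export
optimal_lag <- function(trace, schedule,
                        lag_grid = seq(0, 0.2, by = 0.002)) {
  stopifnot(length(lag_grid) >= 1L)
  w <- stim_window_samples(trace, schedule, max_lag = max(lag_grid))
  dt <- w$dt
  th_all <- detect_angle(trace$pv)
  err <- numeric(length(lag_grid))
  n_undef <- integer(length(lag_grid))
  for (i in seq_along(lag_grid)) {
    idx <- w$idx + as.integer(round(lag_grid[i] / dt))
    e <- angular_error(th_all[idx], w$theta)
    n_undef[i] <- sum(is.na(e))
    err[i] <- mean(e, na.rm = TRUE)
  }
  best <- which.min(err)   # first index on ties = smallest lag
  structure(list(lags = lag_grid, err = err, err_deg = err * 180 / pi,
                 optimal_lag = lag_grid[best], min_err = err[best],
                 min_err_deg = err[best] * 180 / pi,
                 n_events = w$n_events, n_undefined = n_undef),
            class = "error_curve")
}

#' @export
print.error_curve <- function(x, ...) {
  cat(sprintf(
    "Detection-error curve over %d lags: min %.2f deg at lag %.3f s (%d stimuli)\n",
    length(x$lags), x$min_err_deg, x$optimal_lag, x$n_events))
  invisible(x)
}

#' Write a readout trace or error curve to CSV
#'
#' @param x a [readout_trace()] or [optimal_lag()] result.
#' @param path CSV path.
#' @export
write_readout_csv <- function(x, path) {
  df <- if (inherits(x, "readout_trace")) {
    data.frame(time_s = x$times, pv_re = Re(x$pv), pv_im = Im(x$pv))
  } else if (inherits(x, "error_curve")) {
    data.frame(lag_s = x$lags, err_deg = x$err_deg)
  } else stop("x must be a readout_trace or error_curve")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
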