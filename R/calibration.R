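#' Time- and population-averaged firing rate
#'
#' The discrete form of \eqn{\langle m \rangle = \frac{1}{T N}\int_0^T
#' \sum_i m_i(t)\,dt}, computed over the recorded frames after discarding
#' \code{burn_in} seconds.
#'
#' @param sim a [simulate_ring()] result (or any list with \code{t_rec}
#'   and an N x frames matrix \code{m}).
#' @param burn_in seconds discarded from the start.
#' @return Mean rate (Hz).
#' @export
mean_rate <- function(sim, burn_in = 0) {
  keep <- sim$t_rec >= burn_in
  if (!any(keep)) stop("no frames after burn_in")
  mean(sim$m[, keep, drop = FALSE])
}

#' Calibrate the baseline depolarization for a given release probability
#'
#' Transitions between cortical functional states are emulated by changing
#' the release probability \code{U} together with the baseline
#' depolarization \code{I0} so that the stimulus-free mean firing rate stays
#' at a fixed target (default 0.5 Hz). This function finds that \code{I0} by
#' bisection: the mean rate is evaluated by a full stochastic simulation
#' with *common random numbers* (the identical noise seed at every iterate),
#' which makes the objective effectively deterministic in \code{I0}, and the
#' bracket is narrowed until the achieved mean is within half the stated
#' tolerance of the target (the inner margin leaves room for the
#' independent-seed validation run that follows). The returned
#' \code{mean_rate} is from that validation run.
#'
#' @param U release probability for this functional state.
#' @param params a [model_params()] object (its U and I0 fields are ignored).
#' @param target stimulus-free mean rate to hold (Hz).
#' @param tolerance accepted |mean - target| (Hz).
#' @param sim_duration simulated seconds per evaluation (after burn-in).
#' @param burn_in discarded initial transient (s).
#' @param bracket initial I0 search interval.
#' @param max_iter bisection iteration cap.
#' @param seed common-random-number seed for the calibration evaluations;
#'   the validation run uses an independently derived seed.
#' @return Object of class \code{calibration_result}: list with U, I0,
#'   mean_rate (validation), target, tolerance, sim_duration, seed,
#'   converged flag and the bisection \code{history} data.frame.
#' @export
calibrate_I0 <- function(U, params, target = 0.5, tolerance = 0.05,
                         sim_duration = 200, burn_in = 10,
                         bracket = c(-20, 20), max_iter = 40L,
                         seed = params$seed) {
  stopifnot(target > 0, tolerance > 0, sim_duration > 0)
  inner_tol <- tolerance / 2

  eval_mean <- function(I0, s) {
    p <- params
    p$U <- U
    p$I0 <- I0
    sim <- simulate_ring(p, duration = burn_in + sim_duration,
                         record_stride = 1000L, noise_seed = s,
                         record_trace = FALSE, burn_in = burn_in)
    sim$mean_rate
  }

  lo <- bracket[1]
  hi <- bracket[2]
  f_lo <- eval_mean(lo, seed)
  f_hi <- eval_mean(hi, seed)
  hist <- data.frame(I0 = c(lo, hi), mean_rate = c(f_lo, f_hi))
  if (f_lo > target || f_hi < target)
    stop(sprintf(
      "no bracket: mean rate is %.3f at I0 = %g and %.3f at I0 = %g",
      f_lo, lo, f_hi, hi))

  converged <- FALSE
  mid <- f_mid <- NA_real_
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- eval_mean(mid, seed)
    hist <- rbind(hist, data.frame(I0 = mid, mean_rate = f_mid))
    if (abs(f_mid - target) <= inner_tol) {
      converged <- TRUE
      break
    }
    if (f_mid < target) lo <- mid else hi <- mid
  }
  if (!converged)
    warning(sprintf("calibration for U = %g did not converge in %d iterations",
                    U, max_iter))

  val_seed <- derive_seed(seed, "validation", U)
  val_mean <- eval_mean(mid, val_seed)

  structure(list(U = U, I0 = mid, mean_rate = val_mean, target = target,
                 tolerance = tolerance, sim_duration = sim_duration,
                 burn_in = burn_in, seed = seed, validation_seed = val_seed,
                 converged = converged, history = hist),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "Calibration: U = %g -> I0 = %.5f (validated mean rate %.4f Hz, target %g +/- %g)\n",
    x$U, x$I0, x$mean_rate, x$target, x$tolerance))
  invisible(x)
}

#' Calibrate a grid of release probabilities
#'
#' Runs [calibrate_I0()] for every U in \code{U_grid} with per-U seeds
#' derived from \code{master_seed}, and returns the calibration table used
#' by the downstream state sweep.
#'
#' @param U_grid release probabilities (default 0.05 to 0.9 in steps
#'   of 0.05).
#' @param params a [model_params()] object.
#' @param master_seed integer; per-U seeds are derived from it.
#' @inheritParams calibrate_I0
#' @param ... passed on to [calibrate_I0()].
#' @return data.frame with one row per U: U, I0, mean_rate, tolerance,
#'   sim_duration, seed, converged.
#' @export
calibrate_grid <- function(U_grid = seq(0.05, 0.9, by = 0.05), params,
                           target = 0.5, tolerance = 0.05,
                           master_seed = params$seed, ...) {
  rows <- lapply(U_grid, function(u) {
    cal <- calibrate_I0(u, params, target = target, tolerance = tolerance,
                        seed = derive_seed(master_seed, "calibrate", u), ...)
    data.frame(U = u, I0 = cal$I0, mean_rate = cal$mean_rate,
               tolerance = cal$tolerance, sim_duration = cal$sim_duration,
               seed = cal$seed, converged = cal$converged)
  })
  do.call(rbind, rows)
}

#' Write / read a calibration table
#'
#' Plain CSV, one row per U, consumed verbatim by the sweep functions.
#'
#' @param calibration data.frame from [calibrate_grid()].
#' @param path CSV file path.
#' @export
write_calibration <- function(calibration, path) {
  utils::write.csv(calibration, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  utils::read.csv(path)
}
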