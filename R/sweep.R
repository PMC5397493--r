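#' Spatial bump-modulation index
#'
#' Quantifies how strongly activity is concentrated in a bump:
#' \eqn{M(t) = |ER(t)| / \bar m(t)} where \eqn{\bar m(t)} is the
#' population-mean rate at that frame. Uniform activity gives M = 0; a
#' pure cosine profile \eqn{a(1 + \cos(2(\theta - \theta_0)))} gives
#' M = 0.5; a single active unit gives M = 1 (up to the discrete-ring
#' limit). Computed on the recorded (strided) frames after burn-in.
#'
#' @param sim a [simulate_ring()] result.
#' @param burn_in seconds discarded from the start.
#' @return Object of class \code{bump_metrics}: list with \code{times},
#'   \code{M} and \code{summary} (time-averaged M).
#' @export
bump_modulation <- function(sim, burn_in = 0) {
  keep <- sim$t_rec >= burn_in
  if (!any(keep)) stop("no frames after burn_in")
  m <- sim$m[, keep, drop = FALSE]
  mbar <- colMeans(m)
  if (any(mbar == 0)) stop("all-zero activity frame: modulation undefined")
  theta <- preferred_angles(nrow(m))
  er <- as.vector(Mod(crossprod(exp(-2i * theta), m))) / nrow(m)
  structure(list(times = sim$t_rec[keep], M = er / mbar,
                 summary = mean(er / mbar)),
            class = "bump_metrics")
}

#' Bump-onset release probability
#'
#' Given time-averaged modulation indices \code{M} on an ascending grid of
#' release probabilities, returns the smallest grid U whose M exceeds a
#' threshold. By default the threshold is data-driven: midway between the
#' low-U plateau (the curve's minimum) and the high-U saturation (its
#' maximum) — the half-rise point of the M(U) curve.
#'
#' @param U_grid ascending release probabilities.
#' @param M matching time-averaged modulation indices.
#' @param threshold optional explicit threshold; default half-rise.
#' @return The onset U, with attribute \code{threshold}; \code{NA} (with a
#'   message attribute) if the curve never crosses.
#' @export
bump_onset <- function(U_grid, M, threshold = NULL) {
  stopifnot(length(U_grid) == length(M), !is.unsorted(U_grid))
  if (is.null(threshold)) threshold <- (min(M) + max(M)) / 2
  above <- which(M > threshold)
  if (length(above) == 0L) {
    out <- NA_real_
    attr(out, "message") <- "no onset in grid"
  } else {
    out <- U_grid[above[1L]]
  }
  attr(out, "threshold") <- threshold
  out
}

#' Sweep configuration
#'
#' Grids and protocol constants for a functional-state sweep: release
#' probabilities \code{U_grid}, readout sizes \code{N_read_grid}, stimulus
#' amplitudes \code{C_grid}, stimulus duration \code{T} and rate
#' \code{Freq}, per-condition simulated time \code{T_sim} (after a
#' \code{burn_in}), the lag grid, and a master seed from which every
#' per-condition stream is derived deterministically.
#'
#' @param U_grid release probabilities.
#' @param N_read_grid numbers of readout units.
#' @param C_grid stimulus amplitudes.
#' @param T stimulus duration (s).
#' @param Freq stimulus rate (Hz).
#' @param T_sim per-condition simulated time after burn-in (s).
#' @param burn_in discarded transient (s).
#' @param lag_grid readout lags scanned (s).
#' @param tau_rd readout time constant (s).
#' @param master_seed integer master seed.
#' @return Object of class \code{sweep_config}.
#' @export
sweep_config <- function(U_grid = seq(0.05, 0.9, by = 0.05),
                         N_read_grid = c(20L, 80L),
                         C_grid = c(5, 10, 20, 40),
                         T = 0.05, Freq = 4, T_sim = 200, burn_in = 10,
                         lag_grid = seq(0, 0.2, by = 0.002),
                         tau_rd = 0.02, master_seed = 1L) {
  stopifnot(length(U_grid) > 0, length(N_read_grid) > 0, length(C_grid) > 0)
  structure(list(U_grid = U_grid, N_read_grid = as.integer(N_read_grid),
                 C_grid = C_grid, T = T, Freq = Freq, T_sim = T_sim,
                 burn_in = burn_in, lag_grid = lag_grid, tau_rd = tau_rd,
                 master_seed = as.integer(master_seed)),
            class = "sweep_config")
}

#' Run one sweep condition
#'
#' Simulates the calibrated network under the stimulus protocol for one
#' (U, C) pair, integrates a sparse readout for every requested
#' \code{N_read} (all from the same network trajectory — readout sampling
#' uses its own RNG stream) plus the exact readout, and scores each with
#' the lag-optimized detection error. Per-concern seeds (schedule, noise,
#' unit sampling, spikes) are derived from the master seed and the
#' condition tuple, so every row is regenerable bit-for-bit.
#'
#' @param U release probability.
#' @param I0 calibrated baseline depolarization for this U.
#' @param N_read vector of sparse-readout sizes.
#' @param C stimulus amplitude.
#' @param config a [sweep_config()] object.
#' @param params a [model_params()] object (network constants).
#' @return data.frame with one row per readout (sparse rows plus one
#'   \code{readout = "exact"} row): U, I0, N_read, C, min_err_deg,
#'   optimal_lag_s, bump_index, n_stimuli, n_undefined, seed.
#' @export
run_condition <- function(U, I0, N_read, C, config, params = model_params()) {
  ms <- config$master_seed
  seed_sched <- derive_seed(ms, "schedule", U, C)
  seed_noise <- derive_seed(ms, "noise", U, C)
  seed_spike <- derive_seed(ms, "spikes", U, C)
  seed_sample <- derive_seed(ms, "sampling", U, C)

  p <- params
  p$U <- U
  p$I0 <- I0
  proto <- stimulus_protocol(C = C, T = config$T, Freq = config$Freq,
                             T_sim = config$T_sim, seed = seed_sched)
  sched <- shift_schedule(sample_schedule(proto), config$burn_in)

  set.seed(seed_sample)
  sets <- lapply(N_read, function(nr) sort(sample.int(p$N, nr)))

  sim <- simulate_ring(p, schedule = sched,
                       duration = config$burn_in + config$T_sim,
                       record_stride = 25L, readout = sets,
                       tau_rd = config$tau_rd, noise_seed = seed_noise,
                       spike_seed = seed_spike, burn_in = config$burn_in)

  bump <- bump_modulation(sim, burn_in = config$burn_in)$summary

  score <- function(pv) {
    tr <- readout_trace(sim$trace$times, pv)
    optimal_lag(tr, sched, config$lag_grid)
  }
  rows <- lapply(seq_along(N_read), function(i) {
    ec <- score(sim$trace$R[[i]])
    data.frame(U = U, I0 = I0, readout = "sparse", N_read = N_read[i],
               C = C, min_err_deg = ec$min_err_deg,
               optimal_lag_s = ec$optimal_lag, bump_index = bump,
               n_stimuli = ec$n_events,
               n_undefined = ec$n_undefined[which.min(ec$err)],
               seed = seed_noise)
  })
  ec <- score(sim$trace$ER)
  rows <- c(rows, list(
    data.frame(U = U, I0 = I0, readout = "exact", N_read = p$N, C = C,
               min_err_deg = ec$min_err_deg, optimal_lag_s = ec$optimal_lag,
               bump_index = bump, n_stimuli = ec$n_events,
               n_undefined = ec$n_undefined[which.min(ec$err)],
               seed = seed_noise)))
  do.call(rbind, rows)
}

#' Run a full functional-state sweep
#'
#' For every (U, C) pair of the configured grids, simulates the calibrated
#' network and scores sparse readouts at every \code{N_read} plus the exact
#' readout. A failing condition is recorded (with its error message) and
#' skipped rather than aborting the sweep.
#'
#' @param config a [sweep_config()] object.
#' @param calibration calibration table from [calibrate_grid()] (must cover
#'   every U in the config's grid).
#' @param params a [model_params()] object.
#' @param verbose print one line per condition.
#' @return data.frame of all condition rows; failed conditions appear in
#'   the \code{failures} attribute.
#' @export
run_sweep <- function(config, calibration, params = model_params(),
                      verbose = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  missing_u <- setdiff(round(config$U_grid, 10), round(calibration$U, 10))
  if (length(missing_u) > 0)
    stop("no calibration for U = ", paste(missing_u, collapse = ", "))
  rows <- list()
  failures <- list()
  for (C in config$C_grid) {
    for (U in config$U_grid) {
      I0 <- calibration$I0[match(round(U, 10), round(calibration$U, 10))]
      res <- tryCatch(
        run_condition(U, I0, config$N_read_grid, C, config, params),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(U = U, C = C, message = conditionMessage(res))
        next
      }
      if (verbose)
        message(sprintf("[sweep] U = %.2f C = %g: sparse err %s deg",
                        U, C,
                        paste(sprintf("%.1f",
                          res$min_err_deg[res$readout == "sparse"]),
                          collapse = "/")))
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "failures") <- if (length(failures)) do.call(rbind, failures)
  out
}

#' Optimal release probability of an error curve
#'
#' Argmin of the detection error over U for one (readout, N_read, C)
#' condition; ties go to the smallest U. Also flags whether the minimum is
#' interior to the grid (not at either endpoint).
#'
#' @param results sweep rows for a single condition (>= 3 distinct U).
#' @return list with \code{U_opt}, \code{min_err_deg} and \code{interior}.
#' @export
find_optimal_U <- function(results) {
  results <- results[order(results$U), ]
  if (nrow(results) < 3L) stop("need at least 3 grid points")
  best <- which.min(results$min_err_deg)
  list(U_opt = results$U[best],
       min_err_deg = results$min_err_deg[best],
       interior = best > 1L && best < nrow(results))
}
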