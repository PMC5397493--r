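#' Softplus gain function
#'
#' The network's rate gain \eqn{g(y) = \log(1 + e^y)}, evaluated
#' overflow-safely: for large positive \code{y} it returns
#' \eqn{y + \log(1 + e^{-y})}, which is exact to machine precision.
#' Strictly positive everywhere, so unit rates never reach zero.
#'
#' @param y input current (any finite real, vectorized).
#' @return Nonnegative rate(s), same length as \code{y}.
#' @examples
#' gain(0)        # log(2)
#' gain(c(-50, 50))
#' @export
gain <- function(y) {
  out <- ifelse(y > 0, y + log1p(exp(-y)), log1p(exp(y)))
  out
}

#' Inverse of the softplus gain
#'
#' @param r target rate (> 0).
#' @return The input \code{y} with \code{gain(y) == r}:
#'   \eqn{\log(e^r - 1)}, computed stably for small and large \code{r}.
#' @export
gain_inv <- function(r) {
  if (any(r <= 0)) stop("gain_inv requires r > 0")
  # log(exp(r) - 1) = r + log(1 - exp(-r))
  r + log(-expm1(-r))
}

#' Build the ring connectivity matrix
#'
#' \eqn{W_{ij} = J_0 + J_1 \cos(2(\theta_i - \theta_j))} with preferred
#' orientations \eqn{\theta_i = i\pi/N}: uniform inhibition plus stronger
#' coupling between units with similar preferred orientation. The matrix is
#' symmetric and circulant; the cosine part sums to zero around the ring, so
#' every row sums to \code{N * J0}.
#'
#' @param params a [model_params()] object.
#' @return Object of class \code{ring_connectivity}: list with the
#'   \code{N x N} matrix \code{W} and the angle vector \code{theta}.
#' @export
build_connectivity <- function(params) {
  stopifnot(inherits(params, "ring_params"))
  theta <- preferred_angles(params$N)
  W <- params$J0 + params$J1 * cos(2 * outer(theta, theta, "-"))
  structure(list(W = W, theta = theta), class = "ring_connectivity")
}

#' Construct a network state
#'
#' Default initial conditions: full synaptic resources (\code{x = 1}), no
#' noise current, and rates at the uncoupled fixed point \code{gain(I0)}.
#'
#' @param params a [model_params()] object.
#' @param m,x,I_noise optional length-N vectors overriding the defaults.
#' @param t initial time (s).
#' @return Object of class \code{ring_state}.
#' @export
network_state <- function(params, m = NULL, x = NULL, I_noise = NULL, t = 0) {
  N <- params$N
  st <- list(
    t = t,
    m = if (is.null(m)) rep(gain(params$I0), N) else m,
    x = if (is.null(x)) rep(1, N) else x,
    I_noise = if (is.null(I_noise)) rep(0, N) else I_noise)
  stopifnot(length(st$m) == N, length(st$x) == N, length(st$I_noise) == N)
  class(st) <- "ring_state"
  st
}

#' One Euler--Maruyama step of the noise current
#'
#' Advances the Ornstein--Uhlenbeck noise
#' \eqn{\tau_n \, dI = -I\,dt + \sigma\sqrt{2\tau_n}\, dW} by one step
#' \code{dt}. Each component is independent; the stationary standard
#' deviation converges to \code{sigma} and the autocorrelation time to
#' \code{tau_n}.
#'
#' @param I_noise current noise vector.
#' @param params a [model_params()] object.
#' @param increments standard-normal vector of the same length (drawn with
#'   \code{rnorm} if omitted).
#' @return Updated noise vector.
#' @export
noise_step <- function(I_noise, params, increments = NULL) {
  if (is.null(increments)) increments <- stats::rnorm(length(I_noise))
  stopifnot(length(increments) == length(I_noise))
  I_noise - (params$dt / params$tau_n) * I_noise +
    params$sigma * sqrt(2 * params$dt / params$tau_n) * increments
}

#' One Euler--Maruyama step of the full network
#'
#' Advances rates and synaptic resources by one step of
#' \deqn{\tau \dot m_i = -m_i + g\Big(\frac{1}{N}\sum_j W_{ij} U x_j m_j
#'   + I^{inp}_i + I^{noise}_i + I_0\Big), \qquad
#'   \dot x_i = \frac{1 - x_i}{\tau_{rec}} - U x_i m_i,}
#' with the noise advanced by [noise_step()]. The drive uses the state at the
#' current time; all three variables update simultaneously. If any rate
#' becomes nonpositive or any resource leaves (0, 1] an error is raised
#' rather than clamping — this indicates \code{dt} is too large.
#'
#' @param state a [network_state()] object.
#' @param conn a [build_connectivity()] object.
#' @param params a [model_params()] object.
#' @param I_inp external input vector (length N), e.g. from [input_current()].
#' @param increments optional standard-normal increments for the noise.
#' @return The state advanced by \code{dt}.
#' @export
network_step <- function(state, conn, params, I_inp = rep(0, params$N),
                         increments = NULL) {
  stopifnot(length(I_inp) == params$N)
  drive <- as.vector(conn$W %*% (params$U * state$x * state$m)) / params$N
  y <- drive + I_inp + state$I_noise + params$I0
  m_new <- state$m + (params$dt / params$tau) * (gain(y) - state$m)
  x_new <- state$x + params$dt *
    ((1 - state$x) / params$tau_rec - params$U * state$x * state$m)
  if (any(m_new <= 0) || any(x_new <= 0) || any(x_new > 1 + 1e-12)) {
    stop(sprintf(
      "state invariant violated at t = %g (m or x out of range); dt too large?",
      state$t + params$dt))
  }
  network_state(params, m = m_new, x = x_new,
                I_noise = noise_step(state$I_noise, params, increments),
                t = state$t + params$dt)
}

#' Simulate the ring network
#'
#' Integrates the network by the Euler--Maruyama method (compiled core) for
#' \code{duration} seconds, optionally driven by a stimulus schedule and
#' optionally accumulating one or more sparse population-vector readouts
#' on the fly. Rates and resources are recorded every \code{record_stride}
#' steps; the exact population vector \code{ER(t)} (and each sparse readout
#' \code{R(t)}) is recorded at every step when \code{record_trace = TRUE}.
#'
#' Reproducibility: the noise stream is seeded from \code{noise_seed} via
#' \code{set.seed}; spike sampling for sparse readouts uses an independent
#' stream seeded by \code{spike_seed}, so readout configuration never
#' perturbs the network trajectory.
#'
#' @param params a [model_params()] object.
#' @param schedule optional [sample_schedule()] object; its event times are
#'   interpreted on the simulation clock.
#' @param duration simulated time (s), > 0 (0 returns the initial state).
#' @param record_stride record m and x every this many steps (default 25,
#'   i.e. every 0.05 s at dt = 0.002 s).
#' @param readout optional list of integer vectors of 1-based unit indices;
#'   one sparse readout trace is integrated per vector.
#' @param tau_rd readout integration time constant (s).
#' @param init optional [network_state()] to start from.
#' @param noise_seed seed for the noise stream (default \code{params$seed}).
#' @param spike_seed seed for the spike-sampling stream.
#' @param record_trace record per-step ER (and R) traces.
#' @param burn_in time (s) excluded from the running mean-rate accumulator
#'   (recorded trajectories are not truncated).
#' @return Object of class \code{ring_sim}: list with \code{t_rec},
#'   \code{m} and \code{x} (N x n_rec matrices), \code{trace}
#'   (list: \code{times}, complex \code{ER}, list of complex \code{R}),
#'   \code{mean_rate} (time/population mean over [burn_in, duration]),
#'   \code{final} state, and the inputs used.
#' @export
simulate_ring <- function(params, schedule = NULL, duration,
                          record_stride = 25L, readout = NULL,
                          tau_rd = 0.02, init = NULL,
                          noise_seed = params$seed, spike_seed = 1L,
                          record_trace = TRUE, burn_in = 0) {
  stopifnot(inherits(params, "ring_params"), duration >= 0,
            record_stride >= 1L)
  if (is.null(init)) init <- network_state(params)
  n_steps <- as.integer(round(duration / params$dt))
  if (!is.null(readout)) {
    lapply(readout, function(idx) {
      if (anyDuplicated(idx) || any(idx < 1L) || any(idx > params$N))
        stop("readout indices must be distinct and in 1..N")
    })
  }
  ev_t <- if (is.null(schedule)) numeric(0) else schedule$events$onset_s
  ev_a <- if (is.null(schedule)) numeric(0) else schedule$events$theta_rad
  stim_C <- if (is.null(schedule)) 0 else schedule$protocol$C
  stim_T <- if (is.null(schedule)) 1 else schedule$protocol$T
  idx0 <- lapply(if (is.null(readout)) list() else readout,
                 function(i) as.integer(i) - 1L)

  set.seed(noise_seed)
  raw <- cpp_simulate(params$N, params$J0, params$J1, params$tau,
                      params$tau_rec, params$tau_n, params$sigma,
                      params$U, params$I0, params$dt,
                      init$m, init$x, init$I_noise,
                      n_steps, as.integer(record_stride),
                      as.integer(round(burn_in / params$dt)),
                      ev_t, ev_a, stim_C, stim_T,
                      idx0, tau_rd, as.numeric(spike_seed), record_trace)

  trace <- NULL
  if (record_trace && n_steps > 0) {
    trace <- list(
      times = (seq_len(n_steps) - 1L) * params$dt,
      ER = complex(real = raw$er_re, imaginary = raw$er_im),
      R = lapply(raw$readout, function(r)
        complex(real = r$re, imaginary = r$im)))
  }
  structure(list(
    t_rec = raw$t_rec, m = raw$m_rec, x = raw$x_rec,
    trace = trace,
    mean_rate = raw$mean_rate,
    final = network_state(params, m = raw$final_m, x = raw$final_x,
                          I_noise = raw$final_noise, t = n_steps * params$dt),
    params = params, schedule = schedule, readout = readout,
    tau_rd = tau_rd, duration = duration, burn_in = burn_in,
    noise_seed = noise_seed, spike_seed = spike_seed),
    class = "ring_sim")
}

#' @export
print.ring_sim <- function(x, ...) {
  cat(sprintf(
    "Ring simulation: %g s at dt = %g s (U = %g, I0 = %.4g), %d recorded frames\n",
    x$duration, x$params$dt, x$params$U, x$params$I0, length(x$t_rec)))
  if (!is.null(x$schedule))
    cat(sprintf("  %d stimuli (C = %g, T = %g s)\n",
                nrow(x$schedule$events), x$schedule$protocol$C,
                x$schedule$protocol$T))
  if (!is.null(x$readout))
    cat(sprintf("  sparse readouts: N_read = %s\n",
                paste(lengths(x$readout), collapse = ", ")))
  invisible(x)
}

#' Write / read a recorded trajectory
#'
#' Columnar gzipped CSV (one row per recorded frame, columns t, m_1..m_N,
#' x_1..x_N) plus a JSON sidecar recording the full parameter set and seeds,
#' so a run can be identified and replayed exactly.
#'
#' @param sim a [simulate_ring()] result.
#' @param path base path; \code{<path>.csv.gz} and \code{<path>.json} are
#'   written.
#' @return Invisibly, the two file paths.
#' @export
write_trajectory <- function(sim, path) {
  df <- data.frame(t = sim$t_rec, t(sim$m), t(sim$x), check.names = FALSE)
  names(df) <- c("t", paste0("m_", seq_len(nrow(sim$m))),
                 paste0("x_", seq_len(nrow(sim$x))))
  csv <- paste0(path, ".csv.gz")
  con <- gzfile(csv, "w")
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  side <- paste0(path, ".json")
  jsonlite::write_json(list(
    params = unclass(sim$params), duration = sim$duration,
    burn_in = sim$burn_in, noise_seed = sim$noise_seed,
    spike_seed = sim$spike_seed, tau_rd = sim$tau_rd,
    n_stimuli = if (is.null(sim$schedule)) 0L else nrow(sim$schedule$events)),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, side))
}
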