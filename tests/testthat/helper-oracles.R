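# Independent oracles used by the tests.

# Event-by-event refractory-Poisson sampler: draws exponential waits one at a
# time and applies the acceptance rule directly. Independent of the package's
# vectorized implementation.
oracle_schedule_count <- function(Freq, T, T_sim, seed) {
  set.seed(seed)
  t <- 0
  last <- -Inf
  n <- 0L
  repeat {
    t <- t + stats::rexp(1L, Freq)
    if (t + T > T_sim) break
    if (t - last >= T) {
      n <- n + 1L
      last <- t
    }
  }
  n
}

# exponential autocorrelation time from a sample series: interpolated lag at
# which the empirical ACF crosses 1/e
acf_decay_time <- function(series, dt, max_lag) {
  a <- stats::acf(series, lag.max = max_lag, plot = FALSE)$acf[, 1, 1]
  below <- which(a < exp(-1))[1L]
  stopifnot(!is.na(below), below > 1L)
  frac <- (a[below - 1L] - exp(-1)) / (a[below - 1L] - a[below])
  (below - 2L + frac) * dt
}

# small-n ring simulation by repeated R-level network_step (full-matrix
# route), as an independent check on the compiled O(N) core
r_reference_trajectory <- function(params, n_steps, I_inp_fun = NULL,
                                   init = NULL) {
  conn <- build_connectivity(params)
  st <- if (is.null(init)) network_state(params) else init
  out <- matrix(NA_real_, params$N, n_steps + 1L)
  out[, 1L] <- st$m
  for (s in seq_len(n_steps)) {
    I_inp <- if (is.null(I_inp_fun)) rep(0, params$N) else I_inp_fun(st$t)
    st <- network_step(st, conn, params, I_inp,
                       increments = rep(0, params$N))
    out[, s + 1L] <- st$m
  }
  list(m = out, final = st)
}

# build a stimulus_schedule from explicit events (bypassing sampling)
manual_schedule <- function(onsets, thetas, C, T, T_sim, Freq = 4) {
  proto <- stimulus_protocol(C = C, T = T, Freq = Freq, T_sim = T_sim,
                             seed = 1L)
  structure(list(events = data.frame(onset_s = onsets, theta_rad = thetas),
                 protocol = proto), class = "stimulus_schedule")
}
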