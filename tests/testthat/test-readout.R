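test_that("exact population vector obeys Fourier orthogonality on the ring", {
  th <- preferred_angles(200)
  expect_lt(Mod(exact_pv(rep(2, 200), th)), 1e-13)
  m <- rep(0, 200); m[37] <- 5
  expect_equal(exact_pv(m, th), (5 / 200) * exp(-2i * th[37]),
               tolerance = 1e-12)
  pv <- exact_pv(1.5 + 0.8 * cos(2 * (th - 0.7)), th)
  expect_equal(Mod(pv), 0.4, tolerance = 1e-10)
  expect_equal(Arg(pv), -2 * 0.7, tolerance = 1e-10)
})

test_that("spike sampling is Poisson with mean m*dt and reproducible", {
  expect_equal(sample_spikes(rep(0, 50), 0.002), rep(0L, 50))
  set.seed(21)
  counts <- sample_spikes(rep(100, 1e5), 0.002)
  se <- sqrt(0.2 / 1e5)
  expect_lt(abs(mean(counts) - 0.2), 3 * se)
  set.seed(8); a <- sample_spikes(rep(40, 100), 0.002)
  set.seed(8); b <- sample_spikes(rep(40, 100), 0.002)
  expect_identical(a, b)
  expect_error(sample_spikes(-1, 0.002), "nonnegative")
})

test_that("silent readout decays exponentially to zero", {
  R <- 1 + 1i
  dt <- 0.002; tau_rd <- 0.02
  for (k in 1:100) R <- sparse_pv_step(R, rep(0, 10), rep(0, 10), tau_rd, dt)
  expect_equal(Mod(R), Mod(1 + 1i) * (1 - dt / tau_rd)^100, tolerance = 1e-10)
  expect_lt(Mod(R), Mod(1 + 1i) * exp(-100 * dt / tau_rd) * 1.2)
})

test_that("time-averaged sparse readout is unbiased for the population vector", {
  th <- preferred_angles(40)
  m <- 30 + 15 * cos(2 * (th - 1.1))   # stationary rates, high enough to spike
  target <- exact_pv(m, th)
  dt <- 0.002; tau_rd <- 0.02
  set.seed(31)
  n_steps <- 4000L   # 8 s = 400 tau_rd
  vals <- complex(n_steps)
  R <- 0 + 0i
  for (k in seq_len(n_steps)) {
    R <- sparse_pv_step(R, sample_spikes(m, dt), th, tau_rd, dt)
    vals[k] <- R
  }
  vals <- vals[-(1:500)]
  # SE of the mean from batch means (batches >> tau_rd decorrelate)
  nb <- 20L
  bm <- tapply(vals, rep(seq_len(nb), each = length(vals) / nb), mean)
  se_re <- sd(Re(bm)) / sqrt(nb)
  se_im <- sd(Im(bm)) / sqrt(nb)
  expect_lt(abs(mean(Re(vals)) - Re(target)), 3 * se_re)
  expect_lt(abs(mean(Im(vals)) - Im(target)), 3 * se_im)
})

test_that("readout variance scales as 1/N_read", {
  th <- preferred_angles(200)
  m <- rep(50, 200)
  dt <- 0.002; tau_rd <- 0.02
  run_var <- function(idx, seed) {
    set.seed(seed)
    R <- 0 + 0i
    vals <- complex(6000L)
    for (k in 1:6000) {
      R <- sparse_pv_step(R, sample_spikes(m[idx], dt), th[idx], tau_rd, dt)
      vals[k] <- R
    }
    vals <- vals[-(1:500)]
    var(Re(vals)) + var(Im(vals))
  }
  v20 <- run_var(seq(1, 200, by = 10), 41)  # 20 units
  v80 <- run_var(seq(1, 200, length.out = 80), 42)
  expect_equal(v20 / v80, 4, tolerance = 0.25)
})

test_that("angle detection inverts the encoding on the orientation circle", {
  expect_equal(detect_angle(exp(-2i * 1.0)), 1.0, tolerance = 1e-12)
  # theta = 0 and theta = pi are the same orientation (period-pi circle)
  expect_equal(angular_error(detect_angle(exp(-2i * 0)),
                             detect_angle(exp(-2i * pi))), 0,
               tolerance = 1e-12)
  set.seed(4)
  th <- runif(1000, 0, pi)
  expect_equal(detect_angle(exp(-2i * th)), th, tolerance = 1e-9)
  pv <- complex(real = rnorm(500), imaginary = rnorm(500))
  out <- detect_angle(pv)
  expect_true(all(out >= 0 & out < pi))
  expect_true(is.na(detect_angle(0 + 0i)))
})

test_that("angular error is the wrapped orientation distance", {
  expect_equal(angular_error(0.3, 0.3), 0)
  expect_equal(angular_error(0.01, pi - 0.01), 0.02, tolerance = 1e-12)
  expect_equal(angular_error(0, pi / 2), pi / 2)
  set.seed(5)
  a <- runif(1000, 0, pi); b <- runif(1000, 0, pi)
  e <- angular_error(a, b)
  expect_true(all(e >= 0 & e <= pi / 2 + 1e-12))
})

test_that("detection error scores lagged windows against true orientations", {
  dt <- 0.002
  times <- seq(0, 10 - dt, by = dt)
  thetas <- c(0.5, 1.4, 2.8, 0.2)
  sched <- manual_schedule(c(1, 3, 5, 7), thetas, C = 20, T = 0.05,
                           T_sim = 10)
  # perfect decoder: pv encodes the true angle inside each window
  pv <- rep(exp(-2i * 0.1), length(times))   # arbitrary outside windows
  for (k in 1:4) {
    inside <- times >= sched$events$onset_s[k] &
      times < sched$events$onset_s[k] + 0.05
    pv[inside] <- exp(-2i * thetas[k])
  }
  tr <- readout_trace(times, pv)
  expect_equal(as.numeric(detection_error(tr, sched, lag = 0)), 0,
               tolerance = 1e-12)
  # decoder at a constant orientation offset scores that offset
  off <- readout_trace(times, exp(-2i * 0.75) + 0 * times)
  err <- detection_error(off, manual_schedule(1, 0.5, C = 20, T = 0.05,
                                              T_sim = 10))
  expect_equal(as.numeric(err), 0.25, tolerance = 1e-12)
  # uniform-random decoder scores 45 degrees
  set.seed(9)
  tru <- readout_trace(times, exp(-2i * runif(length(times), 0, pi)))
  sched_many <- manual_schedule(seq(0.5, 9, by = 0.5),
                                runif(18, 0, pi), C = 20, T = 0.05,
                                T_sim = 10)
  e <- as.numeric(detection_error(tru, sched_many))
  n <- 18 * 25
  se <- (pi / 2) / sqrt(12 * n)
  expect_equal(e, pi / 4, tolerance = 4 * se / (pi / 4))
  expect_error(detection_error(tr, manual_schedule(numeric(0), numeric(0),
                                                   C = 20, T = 0.05,
                                                   T_sim = 10)),
               "no events")
})

test_that("optimal lag recovers a constructed readout delay", {
  dt <- 0.002
  times <- seq(0, 20 - dt, by = dt)
  set.seed(10)
  onsets <- seq(1, 18, by = 1)
  thetas <- runif(length(onsets), 0, pi)
  sched <- manual_schedule(onsets, thetas, C = 20, T = 0.05, T_sim = 20)
  L <- 0.04
  pv <- exp(-2i * 0.123) + 0 * times   # background angle
  for (k in seq_along(onsets)) {
    inside <- times >= onsets[k] + L & times < onsets[k] + L + 0.05
    pv[inside] <- exp(-2i * thetas[k])
  }
  ec <- optimal_lag(readout_trace(times, pv), sched,
                    lag_grid = seq(0, 0.2, by = 0.002))
  expect_equal(ec$optimal_lag, L)
  expect_equal(ec$min_err, 0, tolerance = 1e-12)
  expect_true(all(ec$err >= ec$min_err))
  # flat curve ties break to the smallest lag
  flat <- optimal_lag(readout_trace(times, exp(-2i * 0.5) + 0 * times),
                      sched, lag_grid = c(0, 0.01, 0.02))
  expect_equal(flat$optimal_lag, 0)
})
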