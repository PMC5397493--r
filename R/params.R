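#' Model parameters for the depressing ring network
#'
#' Bundles all constants of the rate model of an orientation hypercolumn:
#' a ring of \code{N} units with preferred orientations \eqn{\theta_i = i\pi/N},
#' cosine-profiled connectivity \eqn{W_{ij} = J_0 + J_1\cos(2(\theta_i-\theta_j))},
#' short-term synaptic depression with baseline release probability \code{U}
#' and recovery time \code{tau_rec}, Ornstein--Uhlenbeck input noise
#' (stationary sd \code{sigma}, correlation time \code{tau_n}) and a uniform
#' depolarization \code{I0}. Defaults are the reference parameter set used
#' throughout: J0 = -12, J1 = 30, tau = 0.01 s, tau_rec = 0.8 s,
#' tau_n = 0.1 s, sigma = 2, N = 200, dt = 0.002 s.
#'
#' @param N number of ring units (>= 2).
#' @param J0 uniform (inhibitory, negative) coupling.
#' @param J1 orientation-modulated coupling (positive).
#' @param tau rate time constant (s).
#' @param tau_rec synaptic resource recovery time constant (s).
#' @param tau_n noise correlation time (s).
#' @param sigma stationary standard deviation of the noise current.
#' @param U baseline neurotransmitter release probability, in (0, 1].
#' @param I0 baseline depolarization (input units).
#' @param dt Euler--Maruyama integration step (s); must satisfy dt < tau.
#' @param seed integer RNG seed for the noise stream.
#' @return An object of class \code{ring_params} (a named list).
#' @examples
#' p <- model_params(U = 0.2, I0 = 0.5)
#' p$N
#' @export
model_params <- function(N = 200L, J0 = -12, J1 = 30, tau = 0.01,
                         tau_rec = 0.8, tau_n = 0.1, sigma = 2,
                         U = 0.5, I0 = 0, dt = 0.002, seed = 1L) {
  N <- as.integer(N)
  if (is.na(N) || N < 2L) stop("N must be an integer >= 2")
  for (nm in c("tau", "tau_rec", "tau_n", "dt")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("%s must be a positive scalar", nm))
  }
  if (!is.numeric(U) || U <= 0 || U > 1) stop("U must lie in (0, 1]")
  if (sigma < 0) stop("sigma must be nonnegative")
  if (dt >= tau)
    stop("dt must be smaller than tau (explicit-Euler stability)")
  p <- list(N = N, J0 = J0, J1 = J1, tau = tau, tau_rec = tau_rec,
            tau_n = tau_n, sigma = sigma, U = U, I0 = I0, dt = dt,
            seed = as.integer(seed))
  class(p) <- "ring_params"
  p
}

#' @export
print.ring_params <- function(x, ...) {
  cat("Ring network parameters\n")
  cat(sprintf("  N = %d units, J0 = %g, J1 = %g\n", x$N, x$J0, x$J1))
  cat(sprintf("  tau = %g s, tau_rec = %g s, tau_n = %g s, sigma = %g\n",
              x$tau, x$tau_rec, x$tau_n, x$sigma))
  cat(sprintf("  U = %g, I0 = %g, dt = %g s, seed = %d\n",
              x$U, x$I0, x$dt, x$seed))
  invisible(x)
}

#' Preferred orientations of the ring units
#'
#' @param N number of units.
#' @return Numeric vector \eqn{\theta_i = i\pi/N}, i = 0, ..., N-1 (radians).
#' @export
preferred_angles <- function(N) {
  (seq_len(N) - 1L) * pi / N
}

#' Read and write model configuration files
#'
#' A flat key--value configuration (JSON or YAML, chosen by file extension)
#' with keys named as the standard symbols: J0, J1, tau, tau_rec, tau_n,
#' sigma, N, C, T, Freq, T_sim, plus U, I0, dt and seed. Keys beyond those
#' consumed by [model_params()] (the stimulus-protocol constants C, T, Freq,
#' T_sim) are preserved and returned in the \code{extra} attribute.
#'
#' @param path file path ending in .json, .yaml or .yml.
#' @return For \code{read_config}, a \code{ring_params} object with attribute
#'   \code{extra} holding any non-network keys.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else stop("config must be a .json, .yaml or .yml file")
  known <- names(formals(model_params))
  args <- vals[intersect(names(vals), known)]
  p <- do.call(model_params, args)
  attr(p, "extra") <- vals[setdiff(names(vals), known)]
  p
}

#' @rdname read_config
#' @param params a \code{ring_params} object.
#' @param extra named list of additional keys to store (e.g. C, T, Freq, T_sim).
#' @export
write_config <- function(params, path, extra = list()) {
  vals <- c(unclass(params), extra)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(vals, path)
  } else stop("config must be a .json, .yaml or .yml file")
  invisible(path)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic per-concern / per-condition seed derivation (Lehmer-style
#' modular hash over the master seed and any number of numeric or string
#' tokens; all arithmetic exact in doubles, result < 2^31 - 1). Used
#' throughout so that independent concerns (noise, schedule, unit sampling,
#' spikes) and sweep conditions get independent but reproducible streams.
#'
#' @param master integer master seed.
#' @param ... numeric or character tokens identifying the concern/condition.
#' @return An integer seed in [1, 2^31 - 1].
#' @examples
#' derive_seed(1, "noise", 0.25)
#' @export
derive_seed <- function(master, ...) {
  toks <- c(as.numeric(master), vapply(list(...), function(v) {
    if (is.character(v)) sum(utf8ToInt(v) * seq_along(utf8ToInt(v)))
    else round(as.numeric(v) * 1e6) %% 2147483647
  }, numeric(1)))
  h <- 17
  for (tok in toks) h <- (h * 48271 + abs(tok)) %% 2147483647
  as.integer(h + 1)
}
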