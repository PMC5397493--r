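#' Stimulus protocol
#'
#' Constants of the oriented-stimulus presentation protocol: brief oriented
#' stimuli of amplitude \code{C} and duration \code{T} arrive as a Poisson
#' process of rate \code{Freq} thinned by a refractory period \code{T} (so
#' windows never overlap), with orientations drawn uniformly on [0, pi).
#'
#' @param C stimulus amplitude (input units), >= 0.
#' @param T stimulus duration (s), > 0.
#' @param Freq Poisson event rate before refractory thinning (Hz).
#' @param T_sim scheduling horizon (s); every window fits inside it.
#' @param seed integer seed for the schedule stream.
#' @return Object of class \code{stimulus_protocol}.
#' @export
stimulus_protocol <- function(C = 20, T = 0.05, Freq = 4, T_sim = 200,
                              seed = 1L) {
  stopifnot(C >= 0, T > 0, Freq >= 0, T_sim > 0)
  if (Freq * T >= 1)
    stop("infeasible protocol: Freq * T must be < 1 (refractory feasibility)")
  structure(list(C = C, T = T, Freq = Freq, T_sim = T_sim,
                 seed = as.integer(seed)),
            class = "stimulus_protocol")
}

#' Sample a refractory-Poisson stimulus schedule
#'
#' Candidate onset times are a homogeneous Poisson stream of rate
#' \code{Freq}; candidates are thinned sequentially, accepting an event only
#' if it falls at least \code{T} after the previously accepted one, which
#' removes window overlaps. The realized event rate is therefore slightly
#' below \code{Freq} (approximately \code{Freq / (1 + Freq * T)}).
#' Orientations are i.i.d. uniform on [0, pi). Events whose window would
#' extend past \code{T_sim} are dropped. Fully reproducible from the
#' protocol seed.
#'
#' @param protocol a [stimulus_protocol()] object.
#' @return Object of class \code{stimulus_schedule}: list with
#'   \code{events} (data.frame: onset_s, theta_rad) and \code{protocol}.
#' @export
sample_schedule <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  set.seed(protocol$seed)
  onsets <- numeric(0)
  if (protocol$Freq > 0) {
    cand <- numeric(0)
    last <- 0
    repeat {
      n_draw <- max(32L, ceiling(protocol$Freq *
                                   (protocol$T_sim - last) * 1.25) + 16L)
      cand <- c(cand, last + cumsum(stats::rexp(n_draw, protocol$Freq)))
      last <- cand[length(cand)]
      if (last > protocol$T_sim) break
    }
    cand <- cand[cand + protocol$T <= protocol$T_sim]
    keep <- logical(length(cand))
    prev <- -Inf
    for (k in seq_along(cand)) {
      if (cand[k] - prev >= protocol$T) {
        keep[k] <- TRUE
        prev <- cand[k]
      }
    }
    onsets <- cand[keep]
  }
  theta <- stats::runif(length(onsets), 0, pi)
  structure(list(
    events = data.frame(onset_s = onsets, theta_rad = theta),
    protocol = protocol), class = "stimulus_schedule")
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf(
    "Stimulus schedule: %d events over %g s (C = %g, T = %g s, Freq = %g Hz)\n",
    nrow(x$events), x$protocol$T_sim, x$protocol$C, x$protocol$T,
    x$protocol$Freq))
  invisible(x)
}

#' Per-unit stimulus input current at a time point
#'
#' \eqn{I_i(t) = C \sum_k \mathrm{rect}((t - t_k)/T)\cos(2(\theta_k - \theta_i))}
#' with the rectangular window taken half-open, \eqn{[t_k, t_k + T)}, so
#' windows tile cleanly on the discrete time grid. Because accepted events
#' are separated by at least \code{T}, at most one term is active.
#'
#' @param schedule a [sample_schedule()] object.
#' @param theta unit preferred angles (radians).
#' @param t time (s).
#' @return Input vector of \code{length(theta)}.
#' @export
input_current <- function(schedule, theta, t) {
  ev <- schedule$events
  act <- which(t >= ev$onset_s & t < ev$onset_s + schedule$protocol$T)
  if (length(act) == 0L) return(rep(0, length(theta)))
  schedule$protocol$C * cos(2 * (ev$theta_rad[act[1L]] - theta))
}

#' Shift all event onsets by a constant
#'
#' Used to place a schedule after a burn-in period on the simulation clock.
#'
#' @param schedule a [sample_schedule()] object.
#' @param offset time shift (s).
#' @return The shifted schedule (protocol unchanged).
#' @export
shift_schedule <- function(schedule, offset) {
  schedule$events$onset_s <- schedule$events$onset_s + offset
  schedule
}

#' Write / read a stimulus schedule
#'
#' Two-column tab-separated table (onset_s, theta_rad) plus a JSON header
#' with the protocol constants, so runs can be replayed exactly.
#'
#' @param schedule a [sample_schedule()] object.
#' @param path base path; \code{<path>.tsv} and \code{<path>.json} written.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(schedule$events, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(schedule$protocol), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  ev <- utils::read.table(paste0(path, ".tsv"), header = TRUE, sep = "\t")
  pr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(events = ev,
                 protocol = do.call(stimulus_protocol, pr)),
            class = "stimulus_schedule")
}
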