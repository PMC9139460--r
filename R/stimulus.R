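#' Timed stimulus protocol
#'
#' A stimulus protocol is a list of rectangular current pulses delivered to a
#' memory unit or population, optionally corrupted by seeded additive Gaussian
#' noise. It is the sole input format of every simulator in the package: the
#' single-unit feedback models receive it as `I(t)`, the mean-field population
#' as the external current `i(t)` (scaled by the input gain `j_eo`).
#'
#' @param pulses a data frame (or list coercible to one) with columns
#'   `onset`, `duration` and `amplitude`. Onsets are in ms and must be
#'   non-negative; durations are in ms and must be positive; amplitudes are in
#'   the model's input units. Overlapping pulses sum. May have zero rows.
#' @param total_duration total simulated time in ms (> 0). No pulse may
#'   extend past it.
#' @param noise `NULL` for a noiseless protocol, or a list with elements
#'   `sd` (standard deviation of the per-time-step Gaussian noise, in input
#'   units) and `seed` (integer seed making the noise reproducible).
#'
#' @return An object of class `stimulus_protocol`.
#' @examples
#' stim <- stimulus_protocol(pulses = data.frame(onset = 0, duration = 200,
#'                                               amplitude = 1),
#'                           total_duration = 1000)
#' @export
stimulus_protocol <- function(pulses = data.frame(onset = numeric(),
                                                  duration = numeric(),
                                                  amplitude = numeric()),
                              total_duration,
                              noise = NULL) {
  pulses <- as.data.frame(pulses)
  required <- c("onset", "duration", "amplitude")
  if (!all(required %in% names(pulses)))
    stop("`pulses` must have columns onset, duration, amplitude")
  if (!is.numeric(total_duration) || length(total_duration) != 1L ||
      !is.finite(total_duration) || total_duration <= 0)
    stop("`total_duration` must be a single positive number (ms)")
  if (nrow(pulses) > 0) {
    if (any(pulses$onset < 0)) stop("pulse onsets must be >= 0")
    if (any(pulses$duration <= 0)) stop("pulse durations must be > 0")
    if (any(pulses$onset + pulses$duration > total_duration + 1e-9))
      stop("pulses may not extend past `total_duration`")
    if (any(!is.finite(pulses$amplitude)))
      stop("pulse amplitudes must be finite")
  }
  if (!is.null(noise)) {
    if (!is.list(noise) || is.null(noise$sd) || is.null(noise$seed))
      stop("`noise` must be NULL or list(sd =, seed =)")
    if (noise$sd < 0) stop("noise sd must be >= 0")
  }
  structure(list(pulses = pulses, total_duration = total_duration,
                 noise = noise),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("<stimulus_protocol> ", nrow(x$pulses), " pulse(s), ",
      x$total_duration, " ms total",
      if (!is.null(x$noise)) sprintf(", noise sd=%g seed=%d", x$noise$sd,
                                     as.integer(x$noise$seed)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Evaluate a stimulus protocol on a time grid
#'
#' Returns the input current at each time point: the sum of all pulses active
#' at that instant (a pulse is active on `[onset, onset + duration)`), plus
#' one Gaussian noise draw per time step when the protocol carries a noise
#' spec. The noise stream is generated under the protocol's own seed in a
#' local RNG scope, so evaluating a protocol never disturbs the caller's
#' random-number state and identical protocols give identical currents.
#'
#' @param stim a [stimulus_protocol()].
#' @param times numeric vector of times (ms).
#' @return numeric vector of input currents, one per time point.
#' @export
stimulus_current <- function(stim, times) {
  stopifnot(inherits(stim, "stimulus_protocol"))
  current <- numeric(length(times))
  p <- stim$pulses
  if (nrow(p) > 0) {
    for (k in seq_len(nrow(p))) {
      on <- times >= p$onset[k] & times < p$onset[k] + p$duration[k]
      current[on] <- current[on] + p$amplitude[k]
    }
  }
  if (!is.null(stim$noise) && stim$noise$sd > 0) {
    current <- current + withr::with_seed(
      as.integer(stim$noise$seed),
      stats::rnorm(length(times), mean = 0, sd = stim$noise$sd))
  }
  current
}
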