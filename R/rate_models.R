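#' Parameters of the single-unit feedback memory models
#'
#' A cortical memory unit is inherently leaky: without feedback its firing
#' rate relaxes back to rest with intrinsic time constant `tau`. The three
#' single-unit models in this package fight that leak in different ways.
#' Positive feedback of strength `w_pos` re-injects the unit's own rate and
#' exactly cancels the leak when `w_pos = 1`. Negative-derivative feedback of
#' strength `w_der` opposes *changes* in rate, slowing any residual drift
#' caused by a mistuned `w_pos`. The hybrid unit combines both.
#'
#' @param tau intrinsic membrane/firing-rate time constant in ms (> 0).
#' @param w_pos dimensionless positive-feedback synaptic strength (>= 0).
#' @param w_der negative-derivative-feedback synaptic strength (>= 0). After
#'   the hybrid model's derivative terms are collected it adds to `tau`, so
#'   it acts as a time-like coefficient in ms even though it originates as a
#'   synaptic strength.
#' @return An object of class `feedback_params`.
#' @seealso [simulate_positive_feedback()], [simulate_derivative_feedback()],
#'   [simulate_hpnf()]
#' @export
feedback_params <- function(tau = 20, w_pos = 1, w_der = 0) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("`tau` must be a single positive number (ms)")
  for (nm in c("w_pos", "w_der")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("`", nm, "` must be a single finite number >= 0")
  }
  structure(list(tau = tau, w_pos = w_pos, w_der = w_der),
            class = "feedback_params")
}

#' @export
print.feedback_params <- function(x, ...) {
  cat(sprintf("<feedback_params> tau=%g ms, w_pos=%g, w_der=%g\n",
              x$tau, x$w_pos, x$w_der))
  invisible(x)
}

# Shared forward-Euler recursion for all the linear single-unit models:
#   denom * dr/dt = -leak * r + I(t)
# Returns the rate vector on the same grid as `current`. Integration halts at
# the first non-finite value (exponential blow-up with supercritical
# feedback); the remainder is filled with NA and the caller flags overflow.
euler_linear <- function(denom, leak, current, dt, r0) {
  n <- length(current)
  r <- numeric(n)
  r[1] <- r0
  step <- dt / denom
  for (k in seq_len(n - 1L)) {
    r[k + 1L] <- r[k] + step * (-leak * r[k] + current[k])
    if (!is.finite(r[k + 1L])) {
      if (k + 1L < n) r[(k + 2L):n] <- NA_real_
      break
    }
  }
  r
}

rate_trace <- function(times, rates, dt) {
  status <- if (anyNA(rates) || any(!is.finite(rates[!is.na(rates)])))
    "overflow" else "ok"
  structure(data.frame(time = times, rate = rates),
            dt = dt, status = status,
            class = c("rate_trace", "data.frame"))
}

#' @export
print.rate_trace <- function(x, ...) {
  cat(sprintf("<rate_trace> %d points, dt=%g ms, status=%s\n",
              nrow(x), attr(x, "dt"), attr(x, "status")))
  if (attr(x, "status") == "overflow")
    cat("  (rate diverged; trailing values are NA)\n")
  invisible(x)
}

#' Trace status flag
#'
#' Returns `"ok"` for a finite trace or `"overflow"` when the simulated rate
#' diverged (e.g. supercritical positive feedback, `w_pos > 1`, run over a
#' long horizon). Divergence is reported through this flag rather than an
#' error so that parameter sweeps across the critical point do not abort.
#'
#' @param trace a `rate_trace` as returned by the single-unit simulators.
#' @return `"ok"` or `"overflow"`.
#' @export
trace_status <- function(trace) attr(trace, "status") %||% "ok"

`%||%` <- function(a, b) if (is.null(a)) b else a

check_dt <- function(dt, tau) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a single positive number (ms)")
  if (dt > tau / 10)
    stop("`dt` must be <= tau/10 for a stable explicit integration (dt = ",
         dt, ", tau = ", tau, ")")
}

#' Simulate the positive-feedback memory unit
#'
#' Integrates the leaky rate unit with recurrent positive feedback,
#' \deqn{\tau \, dr/dt = -(1 - W_{pos})\, r + I(t),}
#' by forward Euler on a uniform grid. With `w_pos = 1` the feedback current
#' exactly replaces the membrane leak and the post-stimulus rate is held
#' indefinitely; with `w_pos < 1` activity decays to rest on time scale
#' `tau / (1 - w_pos)`, and with `w_pos > 1` it grows exponentially.
#'
#' @param params a [feedback_params()]; only `tau` and `w_pos` are used.
#' @param stim a [stimulus_protocol()] supplying `I(t)`.
#' @param dt Euler time step in ms; must satisfy `dt <= tau/10`.
#' @param r0 initial rate (default 0, the resting state).
#' @return A `rate_trace` data frame with columns `time` and `rate`; check
#'   [trace_status()] for overflow.
#' @examples
#' p <- feedback_params(tau = 20, w_pos = 1)
#' s <- stimulus_protocol(data.frame(onset = 50, duration = 100,
#'                                   amplitude = 2), total_duration = 1000)
#' tr <- simulate_positive_feedback(p, s, dt = 0.1)
#' tail(tr$rate, 1)  # held at the offset value
#' @export
simulate_positive_feedback <- function(params, stim, dt = 0.1, r0 = 0) {
  stopifnot(inherits(params, "feedback_params"),
            inherits(stim, "stimulus_protocol"))
  check_dt(dt, params$tau)
  times <- seq(0, stim$total_duration, by = dt)
  current <- stimulus_current(stim, times)
  rates <- euler_linear(params$tau, 1 - params$w_pos, current, dt, r0)
  tr <- rate_trace(times, rates, dt)
  if (trace_status(tr) == "overflow")
    warning("rate diverged (overflow); see trace_status()")
  tr
}

#' Simulate the negative-derivative feedback pair
#'
#' Integrates the two-pathway model in which a common transient input drives
#' an excitatory and an inhibitory trace with different feedback strengths,
#' \deqn{\tau \, dr_E/dt = -W_{pos}\, r_E + I(t), \qquad
#'       \tau \, dr_I/dt = -W_{der}\, r_I + I(t),}
#' and returns both traces together with their pointwise difference
#' `r_E - r_I`. Because the inhibitory pathway is the faster of the two
#' (`w_der > w_pos`), the difference approximates the (negated) derivative of
#' the stored signal: it is the circuit realisation of derivative feedback.
#'
#' @inheritParams simulate_positive_feedback
#' @param r0 length-2 numeric: initial `r_E` and `r_I` (default both 0).
#' @return A list with elements `r_e`, `r_i`, `difference`, each a
#'   `rate_trace` on the same grid.
#' @export
simulate_derivative_feedback <- function(params, stim, dt = 0.1,
                                         r0 = c(0, 0)) {
  stopifnot(inherits(params, "feedback_params"),
            inherits(stim, "stimulus_protocol"), length(r0) == 2L)
  check_dt(dt, params$tau)
  times <- seq(0, stim$total_duration, by = dt)
  current <- stimulus_current(stim, times)
  re <- euler_linear(params$tau, params$w_pos, current, dt, r0[1])
  ri <- euler_linear(params$tau, params$w_der, current, dt, r0[2])
  out <- list(r_e = rate_trace(times, re, dt),
              r_i = rate_trace(times, ri, dt),
              difference = rate_trace(times, re - ri, dt))
  if (any(vapply(out, trace_status, "") == "overflow"))
    warning("rate diverged (overflow); see trace_status()")
  out
}

#' Simulate the hybrid positive and negative-derivative feedback (HPNF) unit
#'
#' The hybrid unit feeds back both the rate and its derivative,
#' \deqn{\tau \, dr/dt = -r + W_{pos} r - W_{der}\, dr/dt + I(t).}
#' Collecting the derivative terms gives the equivalent explicit form that is
#' integrated here,
#' \deqn{(\tau + W_{der})\, dr/dt = -(1 - W_{pos})\, r + I(t),}
#' so for subcritical positive feedback (`w_pos < 1`) the effective decay
#' time constant is `(tau + w_der) / (1 - w_pos)`: derivative feedback
#' multiplies the tolerance of the unit to a mistuned `w_pos`, which is what
#' makes the hybrid unit robust. With `w_der = 0` the model reduces exactly
#' (including the discretisation) to [simulate_positive_feedback()].
#'
#' @inheritParams simulate_positive_feedback
#' @param params a [feedback_params()]; `tau + w_der` must be positive.
#' @return A `rate_trace`.
#' @export
simulate_hpnf <- function(params, stim, dt = 0.1, r0 = 0) {
  stopifnot(inherits(params, "feedback_params"),
            inherits(stim, "stimulus_protocol"))
  denom <- params$tau + params$w_der
  if (denom <= 0) stop("tau + w_der must be > 0")
  check_dt(dt, params$tau)
  times <- seq(0, stim$total_duration, by = dt)
  current <- stimulus_current(stim, times)
  rates <- euler_linear(denom, 1 - params$w_pos, current, dt, r0)
  tr <- rate_trace(times, rates, dt)
  if (trace_status(tr) == "overflow")
    warning("rate diverged (overflow); see trace_status()")
  tr
}
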