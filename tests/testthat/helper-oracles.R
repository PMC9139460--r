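# Independent oracles used across the suite.

# Continuous-time input of a stimulus protocol (analytic, not gridded).
pulse_current_fun <- function(stim) {
  p <- stim$pulses
  function(t) {
    if (!nrow(p)) return(0)
    sum(p$amplitude[t >= p$onset & t < p$onset + p$duration])
  }
}

# High-order reference for the linear single-unit models:
#   denom * dr/dt = -leak * r + I(t), solved by deSolve's fixed-step RK4.
unit_rk4_oracle <- function(denom, leak, stim, times, r0 = 0) {
  I_fun <- pulse_current_fun(stim)
  sol <- deSolve::ode(y = c(r = r0), times = times,
                      func = function(t, y, parms)
                        list((-leak * y[[1]] + I_fun(t)) / denom),
                      parms = NULL, method = "rk4")
  unname(sol[, "r"])
}

# RK4 reference for the six-variable mean-field population (written out
# independently of the package's stepping code).
population_rk4_oracle <- function(stim, p, nr, times,
                                  init = c(r_e = 0, r_i = 0, s_EE = 0,
                                           s_EI = 0, s_IE = 0, s_II = 0)) {
  I_fun <- pulse_current_fun(stim)
  f <- function(x) {
    d <- x - nr$x_theta
    if (d <= 0) 0 else nr$m_max * d^2 / (nr$x_half^2 + d^2)
  }
  deriv <- function(t, y, parms) {
    x_e <- p$j_intra[["EE"]] * y[["s_EE"]] -
      p$j_intra[["EI"]] * y[["s_EI"]] + p$j_eo * I_fun(t)
    x_i <- p$j_intra[["IE"]] * y[["s_IE"]] -
      p$j_intra[["II"]] * y[["s_II"]]
    list(c((-y[["r_e"]] + f(x_e)) / p$tau_e,
           (-y[["r_i"]] + f(x_i)) / p$tau_i,
           (-y[["s_EE"]] + y[["r_e"]]) / p$tau_syn[["EE"]],
           (-y[["s_EI"]] + y[["r_i"]]) / p$tau_syn[["EI"]],
           (-y[["s_IE"]] + y[["r_e"]]) / p$tau_syn[["IE"]],
           (-y[["s_II"]] + y[["r_i"]]) / p$tau_syn[["II"]]))
  }
  deSolve::ode(y = init, times = times, func = deriv, parms = NULL,
               method = "rk4")
}

# Discrete-event bookkeeping oracle for SDN storage: tracks items with
# analytic exponential decay and predicts the eviction and forgetting
# sequence without touching the selector circuit.
fifo_oracle <- function(schedule, tau_eff, forget_frac) {
  items <- list()   # feature -> list(plateau, refresh, store)
  evicted <- character(0)
  forgotten <- character(0)
  for (k in seq_len(nrow(schedule))) {
    t <- schedule$t[k]; f <- schedule$feature_id[k]
    a <- schedule$amplitude[k]
    # forgetting that happened before this arrival
    for (nm in names(items)) {
      cross <- items[[nm]]$refresh + tau_eff * log(1 / forget_frac)
      if (cross <= t) {
        forgotten <- c(forgotten, nm)
        items[[nm]] <- NULL
      }
    }
    if (f %in% names(items)) {
      items[[f]]$plateau <- a
      items[[f]]$refresh <- t
    } else if (length(items) < 4L) {
      items[[f]] <- list(plateau = a, refresh = t, store = t)
    } else {
      rates <- vapply(items, function(it)
        it$plateau * exp(-(t - it$refresh) / tau_eff), 0)
      stores <- vapply(items, `[[`, 0, "store")
      victim <- names(items)[order(rates, stores)[1L]]
      evicted <- c(evicted, victim)
      items[[victim]] <- NULL
      items[[f]] <- list(plateau = a, refresh = t, store = t)
    }
  }
  list(evicted = evicted, forgotten = forgotten,
       held = names(items))
}

# Standard pulse protocol used throughout the unit-model tests.
pulse_stim <- function(amplitude = 2, onset = 0, duration = 100,
                       total = 1000) {
  stimulus_protocol(data.frame(onset = onset, duration = duration,
                               amplitude = amplitude),
                    total_duration = total)
}
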