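#' Naka-Rushton transfer parameters
#'
#' The steady-state response of a neural population to its net input current
#' is modelled by a thresholded Naka-Rushton function: zero below the input
#' threshold, then a saturating rise towards the maximal response. Defaults
#' are the values used throughout the package: maximal response 100, input
#' threshold 30, half-activation parameter 30.
#'
#' @param m_max maximal response, in rate units (> 0).
#' @param x_theta input threshold, in current units.
#' @param x_half half-activation parameter, in current units (> 0); the
#'   response reaches `m_max / 2` at `x_theta + x_half`.
#' @return An object of class `naka_rushton_params`.
#' @export
naka_rushton_params <- function(m_max = 100, x_theta = 30, x_half = 30) {
  if (!is.numeric(m_max) || m_max <= 0) stop("`m_max` must be > 0")
  if (!is.numeric(x_half) || x_half <= 0) stop("`x_half` must be > 0")
  structure(list(m_max = m_max, x_theta = x_theta, x_half = x_half),
            class = "naka_rushton_params")
}

#' Thresholded Naka-Rushton transfer function
#'
#' Maps net input current to steady-state firing rate,
#' \deqn{f(x) = M \frac{(x - x_\theta)^2}{x_0^2 + (x - x_\theta)^2}
#'              \, h(x - x_\theta),}
#' with `h` the Heaviside step under the convention `h(0) = 0`, so
#' `f(x_theta)` is exactly zero. The function is total, monotone
#' nondecreasing, zero at or below threshold and bounded above by `m_max`.
#'
#' @param x input current (vectorised).
#' @param p a [naka_rushton_params()].
#' @return firing rate(s), same length as `x`.
#' @examples
#' naka_rushton(30)  # 0: at threshold
#' naka_rushton(60)  # 50: one half-activation above threshold
#' @export
naka_rushton <- function(x, p = naka_rushton_params()) {
  stopifnot(inherits(p, "naka_rushton_params"))
  d <- x - p$x_theta
  out <- numeric(length(x))
  pos <- is.finite(d) & d > 0
  out[pos] <- p$m_max * d[pos]^2 / (p$x_half^2 + d[pos]^2)
  out[!is.finite(d)] <- NA_real_
  out
}

#' Mean-field population parameters
#'
#' Constants of the excitatory/inhibitory mean-field model that forms one
#' neural signal self-sustaining unit (NSSU). `rE` and `rI` are the mean
#' firing rates of the pyramidal-cell and interneuron groups; each of the
#' four pathways (E to E, I to E, E to I, I to I) has a synaptic state
#' variable that low-pass filters the presynaptic rate with its own time
#' constant. The E-to-E pathway is slow (100 ms, NMDA-dominated) while the
#' pathways onto and between interneurons are fast (10 ms); that kinetic
#' asymmetry is what turns balanced excitation and inhibition into
#' negative-derivative feedback at the population level.
#'
#' Synaptic variables are indexed target-first: `s["EI"]` sits on the
#' excitatory population and tracks the inhibitory rate. Coupling strengths
#' come in an intra-unit set (used within one NSSU) and a weaker inter-unit
#' set (used between NSSUs of a storage network).
#'
#' @param tau_e,tau_i intrinsic time constants of the excitatory and
#'   inhibitory populations, ms.
#' @param tau_syn named numeric, synaptic time constants in ms for pathways
#'   `EE`, `EI`, `IE`, `II` (target-first indexing).
#' @param j_intra,j_inter named numeric, synaptic strengths for the same four
#'   pathways, within one unit and between units respectively (>= 0).
#' @param j_eo external-input gain applied to the stimulus current `i(t)`;
#'   must lie in `[0, 6000]`.
#' @return An object of class `mean_field_params`.
#' @export
mean_field_params <- function(tau_e = 20, tau_i = 10,
                              tau_syn = c(EE = 100, EI = 25, IE = 10,
                                          II = 10),
                              j_intra = c(EE = 300, EI = 450, IE = 900,
                                          II = 900),
                              j_inter = c(EE = 150, EI = 300, IE = 600,
                                          II = 600),
                              j_eo = 3000) {
  path <- c("EE", "EI", "IE", "II")
  tau_syn <- tau_syn[path]; j_intra <- j_intra[path]; j_inter <- j_inter[path]
  if (anyNA(tau_syn) || anyNA(j_intra) || anyNA(j_inter))
    stop("`tau_syn`, `j_intra`, `j_inter` need entries EE, EI, IE, II")
  if (tau_e <= 0 || tau_i <= 0 || any(tau_syn <= 0))
    stop("all time constants must be > 0")
  if (any(j_intra < 0) || any(j_inter < 0))
    stop("synaptic strengths must be >= 0")
  if (!is.numeric(j_eo) || j_eo < 0 || j_eo > 6000)
    stop("`j_eo` must lie in [0, 6000]")
  structure(list(tau_e = tau_e, tau_i = tau_i, tau_syn = tau_syn,
                 j_intra = j_intra, j_inter = j_inter, j_eo = j_eo),
            class = "mean_field_params")
}

#' State of one mean-field population
#'
#' Six state variables: the two mean rates and the four synaptic variables.
#'
#' @param r_e,r_i excitatory and inhibitory mean rates (>= 0).
#' @param s named numeric of synaptic variables `EE`, `EI`, `IE`, `II`.
#' @return An object of class `population_state`.
#' @export
population_state <- function(r_e = 0, r_i = 0,
                             s = c(EE = 0, EI = 0, IE = 0, II = 0)) {
  s <- s[c("EE", "EI", "IE", "II")]
  if (anyNA(s)) stop("`s` needs entries EE, EI, IE, II")
  structure(list(r_e = r_e, r_i = r_i, s = s), class = "population_state")
}

check_finite_state <- function(state) {
  vals <- c(r_e = state$r_e, r_i = state$r_i, state$s)
  bad <- names(vals)[!is.finite(vals)]
  if (length(bad))
    stop("non-finite state variable(s): ", paste(bad, collapse = ", "))
}

#' Advance one mean-field population by one Euler step
#'
#' One forward-Euler step of the six coupled equations
#' \deqn{\tau_E \dot r_E = -r_E + f(J_{EE} s_{EE} - J_{EI} s_{EI}
#'   + J_{EO}\, i(t)),}
#' \deqn{\tau_I \dot r_I = -r_I + f(J_{IE} s_{IE} - J_{II} s_{II}),}
#' \deqn{\tau_{xy} \dot s_{xy} = -s_{xy} + r_y,}
#' with `f` the Naka-Rushton transfer. Intra-unit strengths are used (a
#' single isolated unit). Rates inherit the bounds of `f` at the fixed point
#' and, because `dt` is restricted to at most a fifth of the fastest time
#' constant, remain within `[0, m_max]` along the whole trajectory when
#' started there.
#'
#' @param state a [population_state()].
#' @param i_ext external stimulus current at this instant (before the
#'   `j_eo` gain).
#' @param p a [mean_field_params()].
#' @param nr a [naka_rushton_params()].
#' @param dt time step, ms; must satisfy `dt <= min(tau)/5`.
#' @return the updated `population_state`.
#' @export
step_population <- function(state, i_ext, p = mean_field_params(),
                            nr = naka_rushton_params(), dt = 0.1) {
  stopifnot(inherits(state, "population_state"),
            inherits(p, "mean_field_params"))
  tmin <- min(p$tau_e, p$tau_i, p$tau_syn)
  if (dt > tmin / 5)
    stop("`dt` must be <= min(tau)/5 = ", tmin / 5, " ms")
  check_finite_state(state)
  s <- state$s; j <- p$j_intra
  x_e <- j[["EE"]] * s[["EE"]] - j[["EI"]] * s[["EI"]] + p$j_eo * i_ext
  x_i <- j[["IE"]] * s[["IE"]] - j[["II"]] * s[["II"]]
  r_e <- state$r_e + dt / p$tau_e * (-state$r_e + naka_rushton(x_e, nr))
  r_i <- state$r_i + dt / p$tau_i * (-state$r_i + naka_rushton(x_i, nr))
  s_new <- s + dt / p$tau_syn *
    (-s + c(state$r_e, state$r_i, state$r_e, state$r_i))
  out <- population_state(r_e, r_i, s_new)
  check_finite_state(out)
  out
}

#' Simulate one mean-field population over a stimulus protocol
#'
#' Repeatedly applies [step_population()] over the protocol's horizon and
#' collects the trajectory. Deterministic: any stimulus noise is generated
#' under the protocol's own seed, so identical calls give identical
#' trajectories.
#'
#' @param init initial [population_state()] (default rest).
#' @param stim a [stimulus_protocol()]; amplitudes are in the `i(t)` units of
#'   the mean-field input (multiplied by `p$j_eo` inside the model).
#' @inheritParams step_population
#' @return a data frame of class `population_trace` with columns `time`,
#'   `r_e`, `r_i`, `s_EE`, `s_EI`, `s_IE`, `s_II`.
#' @export
simulate_population <- function(init = population_state(), stim,
                                p = mean_field_params(),
                                nr = naka_rushton_params(), dt = 0.1) {
  stopifnot(inherits(stim, "stimulus_protocol"))
  times <- seq(0, stim$total_duration, by = dt)
  current <- stimulus_current(stim, times)
  n <- length(times)
  out <- matrix(0, n, 6L,
                dimnames = list(NULL, c("r_e", "r_i", "s_EE", "s_EI",
                                        "s_IE", "s_II")))
  st <- init
  out[1L, ] <- c(st$r_e, st$r_i, st$s)
  for (k in seq_len(n - 1L)) {
    st <- step_population(st, current[k], p, nr, dt)
    out[k + 1L, ] <- c(st$r_e, st$r_i, st$s)
  }
  structure(data.frame(time = times, out), dt = dt,
            class = c("population_trace", "data.frame"))
}
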