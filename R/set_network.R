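#' Configuration of a SET storage network
#'
#' A SET is a bank of `n_units` parallel NSSUs (mean-field E/I populations)
#' that stores one memory item redundantly. One unit, the *basic unit*,
#' receives the external stimulus; the remaining *backup units* hold a copy
#' of its content through the inter-unit coupling. By default the fifth unit
#' is the basic one (for banks smaller than five, the last unit).
#'
#' @param n_units number of NSSUs, an integer in 2..12.
#' @param basic_index index of the basic unit (1..n_units); default the
#'   fifth unit, or the last one when `n_units < 5`.
#' @param stimulate `"basic"` (default) to feed the external current only to
#'   the basic unit, or `"all"` to feed every unit directly.
#' @return An object of class `set_config`.
#' @export
set_config <- function(n_units = 8, basic_index = NULL,
                       stimulate = c("basic", "all")) {
  if (!is.numeric(n_units) || length(n_units) != 1L ||
      n_units != round(n_units) || n_units < 2 || n_units > 12)
    stop("`n_units` must be an integer in 2..12")
  n_units <- as.integer(n_units)
  if (is.null(basic_index)) basic_index <- min(5L, n_units)
  if (basic_index < 1 || basic_index > n_units)
    stop("`basic_index` must lie in 1..n_units")
  structure(list(n_units = n_units, basic_index = as.integer(basic_index),
                 stimulate = match.arg(stimulate)),
            class = "set_config")
}

#' Build a coupled SET system
#'
#' Assembles the description of a SET: `n_units` mean-field populations,
#' each with 6 state variables, coupled all-to-all. Within a unit the four
#' pathways use the intra-unit strengths `p$j_intra`; every ordered pair of
#' distinct units is connected through the weaker inter-unit strengths
#' `p$j_inter` acting on the partner units' synaptic variables.
#'
#' @param cfg a [set_config()].
#' @param p a [mean_field_params()].
#' @param nr a [naka_rushton_params()].
#' @return An object of class `set_system` with `6 * n_units` state
#'   variables.
#' @export
build_set <- function(cfg = set_config(), p = mean_field_params(),
                      nr = naka_rushton_params()) {
  stopifnot(inherits(cfg, "set_config"), inherits(p, "mean_field_params"),
            inherits(nr, "naka_rushton_params"))
  structure(list(cfg = cfg, p = p, nr = nr,
                 n_state = 6L * cfg$n_units),
            class = "set_system")
}

#' @export
print.set_system <- function(x, ...) {
  cat(sprintf("<set_system> %d NSSUs (basic unit %d), %d state variables\n",
              x$cfg$n_units, x$cfg$basic_index, x$n_state))
  invisible(x)
}

#' Default storage protocol for SET experiments
#'
#' A single rectangular pulse of the given amplitude over the first 200 ms
#' of a 2000 ms run: the storage event followed by an unstimulated
#' maintenance period during which the network either sustains the stored
#' rate or lets it collapse.
#'
#' @param amplitude pulse amplitude in `i(t)` units (default 1).
#' @param onset,duration pulse timing, ms.
#' @param total_duration simulation horizon, ms.
#' @param noise optional noise spec, as in [stimulus_protocol()].
#' @return a [stimulus_protocol()].
#' @export
set_protocol <- function(amplitude = 1, onset = 0, duration = 200,
                         total_duration = 2000, noise = NULL) {
  stimulus_protocol(data.frame(onset = onset, duration = duration,
                               amplitude = amplitude),
                    total_duration = total_duration, noise = noise)
}

# Vectorised Euler integration of a SET. `gain` is an optional function
# (time_ms -> named multiplier vector over pathways EE, EI, IE, II) used by
# the perturbation protocol; it scales both the intra- and inter-unit
# strengths of the targeted pathway while active.
simulate_set_core <- function(sys, stim, dt, gain = NULL) {
  cfg <- sys$cfg; p <- sys$p; nr <- sys$nr
  n <- cfg$n_units
  times <- seq(0, stim$total_duration, by = dt)
  current <- stimulus_current(stim, times)
  drive <- matrix(0, length(times), n)
  if (cfg$stimulate == "basic") drive[, cfg$basic_index] <- current
  else drive[] <- current

  r_e <- numeric(n); r_i <- numeric(n)
  s_ee <- numeric(n); s_ei <- numeric(n); s_ie <- numeric(n)
  s_ii <- numeric(n)
  nt <- length(times)
  re_mat <- matrix(0, nt, n); ri_mat <- matrix(0, nt, n)
  ji <- p$j_intra; jx <- p$j_inter
  one <- rep(1, n)
  for (k in seq_len(nt - 1L)) {
    f_ee <- ji[["EE"]]; f_ei <- ji[["EI"]]; f_ie <- ji[["IE"]]
    f_ii <- ji[["II"]]
    g_ee <- jx[["EE"]]; g_ei <- jx[["EI"]]; g_ie <- jx[["IE"]]
    g_ii <- jx[["II"]]
    if (!is.null(gain)) {
      g <- gain(times[k])
      f_ee <- f_ee * g[["EE"]]; g_ee <- g_ee * g[["EE"]]
      f_ei <- f_ei * g[["EI"]]; g_ei <- g_ei * g[["EI"]]
      f_ie <- f_ie * g[["IE"]]; g_ie <- g_ie * g[["IE"]]
      f_ii <- f_ii * g[["II"]]; g_ii <- g_ii * g[["II"]]
    }
    x_e <- f_ee * s_ee + g_ee * (sum(s_ee) - s_ee) -
      f_ei * s_ei - g_ei * (sum(s_ei) - s_ei) + p$j_eo * drive[k, ]
    x_i <- f_ie * s_ie + g_ie * (sum(s_ie) - s_ie) -
      f_ii * s_ii - g_ii * (sum(s_ii) - s_ii)
    r_e_new <- r_e + dt / p$tau_e * (-r_e + naka_rushton(x_e, nr))
    r_i_new <- r_i + dt / p$tau_i * (-r_i + naka_rushton(x_i, nr))
    s_ee <- s_ee + dt / p$tau_syn[["EE"]] * (-s_ee + r_e)
    s_ei <- s_ei + dt / p$tau_syn[["EI"]] * (-s_ei + r_i)
    s_ie <- s_ie + dt / p$tau_syn[["IE"]] * (-s_ie + r_e)
    s_ii <- s_ii + dt / p$tau_syn[["II"]] * (-s_ii + r_i)
    r_e <- r_e_new; r_i <- r_i_new
    re_mat[k + 1L, ] <- r_e; ri_mat[k + 1L, ] <- r_i
  }
  list(times = times, r_e = re_mat, r_i = ri_mat,
       mean_rate = rowMeans(re_mat))
}

#' Simulate a SET over a stimulus protocol
#'
#' Integrates the coupled system by forward Euler and returns the mean
#' excitatory rate across NSSUs together with the per-unit rate traces.
#'
#' @param sys a [build_set()] system.
#' @param stim a [stimulus_protocol()]; it is delivered through the basic
#'   unit's external-input channel (or to all units, per the config).
#' @param dt time step, ms (must satisfy the mean-field step bound).
#' @return An object of class `set_trace`: a list with `times`, `mean_rate`,
#'   and matrices `r_e`, `r_i` (time by unit).
#' @export
simulate_set <- function(sys, stim, dt = 0.1) {
  stopifnot(inherits(sys, "set_system"), inherits(stim, "stimulus_protocol"))
  tmin <- min(sys$p$tau_e, sys$p$tau_i, sys$p$tau_syn)
  if (dt > tmin / 5) stop("`dt` must be <= min(tau)/5 = ", tmin / 5, " ms")
  out <- simulate_set_core(sys, stim, dt)
  structure(c(out, list(cfg = sys$cfg, dt = dt)), class = "set_trace")
}

#' Stability criterion for a stored-rate trace
#'
#' A SET run is classified *stable* when the mean excitatory rate has
#' reached a plateau by the end of the run: the relative change between the
#' mean rate over the final `tail_frac` of the run and over the window
#' immediately preceding it must be below `drift_tol`, and the plateau must
#' sit above a minimum activity floor (otherwise the network has simply
#' collapsed to rest, which holds no memory).
#'
#' @param trace a `set_trace` from [simulate_set()], or any list with
#'   elements `times` and `mean_rate`.
#' @param tail_frac fraction of the run used for each assessment window
#'   (default 0.1).
#' @param drift_tol relative drift tolerance (default 0.02).
#' @param floor minimum plateau rate, rate units (default 1).
#' @return An object of class `stability_report`: a list with `n_units`,
#'   `stable`, `plateau_rate` (mean rate over the final window) and
#'   `drift_metric` (relative change between the two windows).
#' @export
assess_stability <- function(trace, tail_frac = 0.1, drift_tol = 0.02,
                             floor = 1.0) {
  nt <- length(trace$times)
  w <- max(1L, floor(tail_frac * nt))
  last <- trace$mean_rate[(nt - w + 1L):nt]
  prev <- trace$mean_rate[(nt - 2L * w + 1L):(nt - w)]
  plateau <- mean(last)
  drift <- if (plateau > 0) abs(mean(last) - mean(prev)) / plateau else Inf
  structure(list(n_units = if (!is.null(trace$cfg)) trace$cfg$n_units
                 else NA_integer_,
                 stable = is.finite(drift) && drift < drift_tol &&
                   plateau > floor,
                 plateau_rate = plateau, drift_metric = drift),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> n_units=%s stable=%s plateau=%.3f drift=%.4g\n",
              x$n_units, x$stable, x$plateau_rate, x$drift_metric))
  invisible(x)
}

#' Sweep the NSSU count of a SET
#'
#' Runs the same storage protocol on SETs of different sizes and classifies
#' each run with [assess_stability()]. Used to find the smallest redundancy
#' level at which the stored mean rate settles to a steady plateau instead
#' of drifting or collapsing.
#'
#' @param counts integer vector of NSSU counts, each in 2..12.
#' @param protocol a [stimulus_protocol()] (default [set_protocol()]).
#' @param p,nr model parameters.
#' @param dt time step, ms.
#' @param tail_frac,drift_tol,floor stability criterion, see
#'   [assess_stability()].
#' @return A data frame with one row per count (`n_units`, `stable`,
#'   `plateau_rate`, `drift_metric`) and attribute `minimal_stable`, the
#'   smallest stable count (NA if none).
#' @export
sweep_nssu_counts <- function(counts = 2:12, protocol = set_protocol(),
                              p = mean_field_params(),
                              nr = naka_rushton_params(), dt = 0.1,
                              tail_frac = 0.1, drift_tol = 0.02,
                              floor = 1.0) {
  if (length(counts) == 0) stop("`counts` must be non-empty")
  reports <- lapply(counts, function(n) {
    sys <- build_set(set_config(n_units = n), p, nr)
    tr <- simulate_set(sys, protocol, dt)
    assess_stability(tr, tail_frac, drift_tol, floor)
  })
  out <- data.frame(n_units = as.integer(counts),
                    stable = vapply(reports, `[[`, TRUE, "stable"),
                    plateau_rate = vapply(reports, `[[`, 0, "plateau_rate"),
                    drift_metric = vapply(reports, `[[`, 0, "drift_metric"))
  stable_counts <- out$n_units[out$stable]
  attr(out, "minimal_stable") <- if (length(stable_counts))
    min(stable_counts) else NA_integer_
  out
}

#' Transient perturbation of a coupling pathway
#'
#' Describes a rectangular disturbance applied to one synaptic pathway: the
#' targeted strength (both its intra- and inter-unit values) is scaled by
#' `1 + magnitude` from `onset` for a window covering `window_fraction` of
#' the simulated horizon, then restored.
#'
#' @param target one of `"J_EE"`, `"J_EI"`, `"J_IE"`, `"J_II"`.
#' @param magnitude relative magnitude in `[0, 1]` (default 0.05, i.e. 5%).
#' @param window_fraction fraction of the horizon the disturbance lasts,
#'   in (0, 1) (default 0.02, i.e. 2%).
#' @param onset disturbance onset, ms; must fall after stimulus offset.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(target = c("J_EE", "J_EI", "J_IE", "J_II"),
                              magnitude = 0.05, window_fraction = 0.02,
                              onset = 600) {
  target <- match.arg(target)
  if (magnitude < 0 || magnitude > 1)
    stop("`magnitude` must lie in [0, 1]")
  if (window_fraction <= 0 || window_fraction >= 1)
    stop("`window_fraction` must lie in (0, 1)")
  structure(list(target = target, magnitude = magnitude,
                 window_fraction = window_fraction, onset = onset),
            class = "perturbation_spec")
}

#' Apply a perturbation to a SET and measure robustness
#'
#' Runs the storage protocol twice — once undisturbed, once with the
#' specified pathway transiently scaled — and measures how far the
#' disturbance pushes the mean rate off the undisturbed trajectory and
#' whether the network returns to it. The deviation is computed against the
#' twin unperturbed run rather than against a pre-onset snapshot so that an
#' identity perturbation scores exactly zero even when the underlying
#' trajectory is itself drifting. Recovery holds when the perturbed run's
#' final plateau agrees with the undisturbed one to within `drift_tol`
#' relative, with an absolute floor of one rate unit on the reference so
#' that trajectories near rest are compared on an absolute band.
#'
#' @param sys a [build_set()] system.
#' @param spec a [perturbation_spec()]; its onset must fall after the
#'   protocol's last stimulus offset and the window must fit the horizon.
#' @param protocol a [stimulus_protocol()].
#' @param dt time step, ms.
#' @param drift_tol relative tolerance of the recovery band (default 0.02).
#' @return A list of class `perturbation_report`: `target`, `deviation`
#'   (max absolute difference between the perturbed and unperturbed mean
#'   rates from onset onwards, rate units), `recovery` (logical),
#'   `plateau_pre` (mean rate just before onset), `plateau_end` (perturbed
#'   final plateau), `plateau_ref` (undisturbed final plateau).
#' @export
perturb_and_measure <- function(sys, spec, protocol = set_protocol(),
                                dt = 0.1, drift_tol = 0.02) {
  stopifnot(inherits(sys, "set_system"), inherits(spec, "perturbation_spec"))
  total <- protocol$total_duration
  offsets <- with(protocol$pulses, onset + duration)
  if (length(offsets) && spec$onset < max(offsets))
    stop("perturbation onset must fall after stimulus offset (storage)")
  win <- spec$window_fraction * total
  if (spec$onset + win > total)
    stop("perturbation window extends past the simulation horizon")

  pathway <- sub("J_", "", spec$target)
  gain <- function(t) {
    g <- c(EE = 1, EI = 1, IE = 1, II = 1)
    if (t >= spec$onset && t < spec$onset + win)
      g[[pathway]] <- 1 + spec$magnitude
    g
  }
  base <- simulate_set_core(sys, protocol, dt)
  pert <- simulate_set_core(sys, protocol, dt, gain = gain)

  pre_win <- pert$times >= spec$onset - 0.05 * total & pert$times < spec$onset
  plateau_pre <- mean(pert$mean_rate[pre_win])
  post <- pert$times >= spec$onset
  deviation <- max(abs(pert$mean_rate[post] - base$mean_rate[post]))
  nt <- length(pert$times); w <- max(1L, floor(0.1 * nt))
  tail_idx <- (nt - w + 1L):nt
  plateau_end <- mean(pert$mean_rate[tail_idx])
  plateau_ref <- mean(base$mean_rate[tail_idx])
  recovery <- abs(plateau_end - plateau_ref) <
    drift_tol * max(plateau_ref, 1)
  structure(list(target = spec$target, deviation = deviation,
                 recovery = recovery, plateau_pre = plateau_pre,
                 plateau_end = plateau_end, plateau_ref = plateau_ref),
            class = "perturbation_report")
}

#' @export
print.perturbation_report <- function(x, ...) {
  cat(sprintf(
    "<perturbation_report> %s: deviation=%.3f recovery=%s plateau %.2f -> %.2f (ref %.2f)\n",
    x$target, x$deviation, x$recovery, x$plateau_pre, x$plateau_end,
    x$plateau_ref))
  invisible(x)
}
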