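test_that("the transfer function is thresholded, saturating and monotone", {
  nr <- naka_rushton_params()
  expect_identical(naka_rushton(30, nr), 0)       # h(0) = 0 at threshold
  expect_identical(naka_rushton(c(-50, 0, 29.999), nr), c(0, 0, 0))
  expect_equal(naka_rushton(60, nr), 50)          # one x_half above theta
  x <- seq(-100, 5000, by = 0.5)
  fx <- naka_rushton(x, nr)
  expect_true(all(diff(fx) >= 0))
  expect_true(all(fx >= 0 & fx <= 100))
  expect_equal(naka_rushton(1e9, nr), 100, tolerance = 1e-6)
})

test_that("rest is a fixed point of the population dynamics", {
  st <- population_state()
  for (k in 1:50) st <- step_population(st, 0)
  expect_identical(c(st$r_e, st$r_i, unname(st$s)), rep(0, 6))
})

test_that("synaptic variables relax to the presynaptic rate with their own tau", {
  # freeze the excitatory rate at R and watch s_EE approach it
  R <- 40
  st <- population_state(r_e = R)
  dt <- 0.1
  ts <- seq(0, 400, by = dt)
  s_track <- numeric(length(ts))
  for (k in seq_along(ts)[-1]) {
    st2 <- step_population(st, 0, dt = dt)
    st2$r_e <- R                      # clamp the presynaptic rate
    st <- st2
    s_track[k] <- st$s[["EE"]]
  }
  expect_equal(s_track, R * (1 - exp(-ts / 100)), tolerance = 5e-3)
})

test_that("the synaptic subsystem is a first-order low-pass filter", {
  # sinusoidal presynaptic rate; steady-state attenuation must match
  # 1/sqrt(1 + (omega*tau)^2)
  dt <- 0.1; period <- 200; tau_ee <- 100
  ts <- seq(0, 5 * period, by = dt)
  omega <- 2 * pi / period
  st <- population_state()
  s_track <- numeric(length(ts))
  for (k in seq_along(ts)[-1]) {
    st$r_e <- sin(omega * ts[k - 1])  # impose the drive
    st <- step_population(st, 0, dt = dt)
    s_track[k] <- st$s[["EE"]]
  }
  last <- ts >= 4 * period
  gain <- (max(s_track[last]) - min(s_track[last])) / 2
  expect_equal(gain, 1 / sqrt(1 + (omega * tau_ee)^2), tolerance = 0.02)
})

test_that("rates stay within [0, M] under strong drive", {
  st <- population_state()
  lo <- Inf; hi <- -Inf
  for (k in 1:4000) {
    st <- step_population(st, 10, dt = 0.1)   # j_eo * 10 = 30000
    lo <- min(lo, st$r_e, st$r_i)
    hi <- max(hi, st$r_e, st$r_i)
  }
  expect_gte(lo, 0)
  expect_lte(hi, 100)
  expect_gt(hi, 50)  # the drive really engaged the network
})

test_that("population trajectories are deterministic and stimulus-responsive", {
  stim <- stimulus_protocol(data.frame(onset = 50, duration = 100,
                                       amplitude = 1),
                            total_duration = 400,
                            noise = list(sd = 0.01, seed = 7))
  tr1 <- simulate_population(population_state(), stim)
  tr2 <- simulate_population(population_state(), stim)
  expect_identical(tr1, tr2)
  expect_gt(tr1$r_e[tr1$time == 150], 0)  # active at stimulus offset
  # flat zero without stimulus
  quiet <- simulate_population(population_state(),
                               stimulus_protocol(total_duration = 100))
  expect_identical(max(abs(quiet$r_e)), 0)
})

test_that("NaN states are reported with the offending variable named", {
  st <- population_state()
  st$s[["EI"]] <- NaN
  expect_error(step_population(st, 0), "s_?EI|EI")
})
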