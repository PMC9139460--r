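test_that("the leaky unit without feedback follows the closed-form decay", {
  p <- feedback_params(tau = 20, w_pos = 0)
  stim <- stimulus_protocol(total_duration = 200)
  tr <- simulate_positive_feedback(p, stim, dt = 0.01, r0 = 5)
  expect_equal(tr$rate, 5 * exp(-tr$time / 20), tolerance = 5e-3)
})

test_that("balanced positive feedback conserves the rate after offset", {
  p <- feedback_params(tau = 20, w_pos = 1)
  tr <- simulate_positive_feedback(p, pulse_stim(total = 2000), dt = 0.1)
  r_off <- tr$rate[tr$time == 100]
  expect_gt(r_off, 0)
  expect_identical(tr$rate[tr$time >= 100],
                   rep(r_off, sum(tr$time >= 100)))
})

test_that("supercritical feedback grows exponentially at rate (w_pos-1)/tau", {
  p <- feedback_params(tau = 20, w_pos = 1.05)
  tr <- simulate_positive_feedback(p, pulse_stim(total = 2000), dt = 0.1)
  post <- tr[tr$time >= 100, ]
  slope <- diff(log(post$rate)) / diff(post$time)
  expect_equal(mean(slope), (1.05 - 1) / 20, tolerance = 1e-3)
  expect_lt(stats::sd(slope), 1e-10)  # exactly log-linear
})

test_that("matched feedback strengths give an identically zero difference", {
  p <- feedback_params(tau = 20, w_pos = 1.2, w_der = 1.2)
  out <- simulate_derivative_feedback(p, pulse_stim())
  expect_identical(out$difference$rate, rep(0, nrow(out$difference)))
  expect_identical(out$r_e$rate, out$r_i$rate)
})

test_that("fast inhibitory decay leaves a positive difference after offset", {
  p <- feedback_params(tau = 20, w_pos = 1, w_der = 4)
  out <- simulate_derivative_feedback(p, pulse_stim(), dt = 0.01)
  post <- out$r_e$time > 100
  expect_true(all(out$difference$rate[post] > 0))
  # each pathway matches its own closed-form exponential after offset
  # (compared over the first 100 ms, where the trace is non-negligible)
  win <- out$r_e$time > 100 & out$r_e$time <= 200
  t_win <- out$r_e$time[win] - 100
  r_off_e <- out$r_e$rate[out$r_e$time == 100]
  r_off_i <- out$r_i$rate[out$r_i$time == 100]
  expect_equal(out$r_e$rate[win], r_off_e * exp(-1 * t_win / 20),
               tolerance = 0.02)
  expect_equal(out$r_i$rate[win], r_off_i * exp(-4 * t_win / 20),
               tolerance = 0.02)
})

test_that("zero input from rest stays at the zero fixed point", {
  p <- feedback_params(tau = 20, w_pos = 1, w_der = 2)
  stim <- stimulus_protocol(total_duration = 100)
  out <- simulate_derivative_feedback(p, stim)
  expect_identical(out$r_e$rate, rep(0, nrow(out$r_e)))
  expect_identical(out$r_i$rate, rep(0, nrow(out$r_i)))
  expect_identical(out$difference$rate, rep(0, nrow(out$difference)))
})

test_that("the hybrid model with w_der = 0 reduces bitwise to pure positive feedback", {
  p <- feedback_params(tau = 20, w_pos = 0.95, w_der = 0)
  stim <- pulse_stim()
  expect_identical(simulate_hpnf(p, stim, dt = 0.1)$rate,
                   simulate_positive_feedback(p, stim, dt = 0.1)$rate)
})

test_that("derivative feedback slows post-offset drift of a mistuned unit", {
  stim <- pulse_stim(amplitude = 2, duration = 200, total = 1200)
  tr0 <- simulate_hpnf(feedback_params(20, 0.9, 0), stim)
  tr1 <- simulate_hpnf(feedback_params(20, 0.9, 100), stim)
  drift <- function(tr) abs(tr$rate[tr$time == 1200] -
                              tr$rate[tr$time == 200])
  expect_lt(drift(tr1), drift(tr0))
  # and the hybrid's effective time constant is (tau + w_der)/(1 - w_pos)
  post <- tr1$time >= 200
  tau_eff <- (20 + 100) / (1 - 0.9)
  expect_equal(tr1$rate[post],
               tr1$rate[tr1$time == 200] * exp(-(tr1$time[post] - 200) /
                                                 tau_eff),
               tolerance = 1e-3)
})

test_that("balanced hybrid feedback holds the rate regardless of w_der", {
  stim <- pulse_stim(total = 2000)
  for (w_der in c(0, 10, 100)) {
    tr <- simulate_hpnf(feedback_params(20, 1, w_der), stim)
    post <- tr$rate[tr$time >= 100]
    expect_identical(post, rep(post[1], length(post)))
  }
})

test_that("the unrectified models are linear in the input", {
  stim1 <- pulse_stim(amplitude = 1)
  stim2 <- pulse_stim(amplitude = 2)
  p <- feedback_params(20, 0.9, 50)
  expect_equal(2 * simulate_positive_feedback(p, stim1)$rate,
               simulate_positive_feedback(p, stim2)$rate)
  expect_equal(2 * simulate_hpnf(p, stim1)$rate,
               simulate_hpnf(p, stim2)$rate)
  d1 <- simulate_derivative_feedback(p, stim1)$difference$rate
  d2 <- simulate_derivative_feedback(p, stim2)$difference$rate
  expect_equal(2 * d1, d2)
})

test_that("forward-Euler traces converge to the RK4 reference as dt shrinks", {
  p <- feedback_params(tau = 20, w_pos = 0.8)
  stim <- pulse_stim(amplitude = 2, duration = 50, total = 200)
  errs <- vapply(c(1, 0.1, 0.01), function(dt) {
    tr <- simulate_positive_feedback(p, stim, dt = dt)
    max(abs(tr$rate - unit_rk4_oracle(20, 1 - 0.8, stim, tr$time)))
  }, 0)
  expect_true(all(diff(errs) < 0))        # strictly decreasing
  expect_lt(errs[3], errs[1] / 50)        # roughly first-order gain
})

test_that("divergent runs are flagged as overflow instead of crashing", {
  p <- feedback_params(tau = 20, w_pos = 3)
  stim <- pulse_stim(amplitude = 10, duration = 100, total = 60000)
  expect_warning(tr <- simulate_positive_feedback(p, stim, dt = 0.1),
                 "overflow")
  expect_identical(trace_status(tr), "overflow")
  expect_true(anyNA(tr$rate))
})

test_that("the integration step must resolve the time constant", {
  p <- feedback_params(tau = 20, w_pos = 1)
  expect_error(simulate_positive_feedback(p, pulse_stim(), dt = 5),
               "tau/10")
})
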