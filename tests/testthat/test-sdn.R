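test_that("a fresh SDN has four free SETs and rebuilding is deterministic", {
  st <- build_sdn()
  expect_identical(nrow(held_items(st)), 0L)
  expect_identical(st$clock, 0)
  expect_identical(build_sdn(), st)
})

test_that("weight configs violating inhibition dominance are rejected by name", {
  bad <- sdn_weights(overrides = c("I11->E22" = 0.5))
  expect_error(build_sdn(bad), "I11->E22")
  # dominance on inhibitory targets of other interneurons is not an
  # excitatory-drive constraint, so a strong I->I override still builds
  expect_s3_class(build_sdn(sdn_weights(overrides = c("I12->I11" = 5))),
                  "sdn_state")
})

test_that("routing follows branch order and winner-take-all", {
  st <- build_sdn()
  r1 <- route_stimulus(st, "a", 50)
  expect_identical(r1$set_id, "set11")
  expect_true(all(c("E00", "E11", "E12") %in% r1$state$nodes))
  expect_false(any(c("E22", "E32", "E42") %in% r1$state$nodes))
  st <- store_or_update(r1$state, "set11", "a")
  st <- present_stimulus(st, "b", 50)
  expect_identical(attr(st, "set_id"), "set21")
  r3 <- route_stimulus(st, "c", 50)
  expect_identical(r3$set_id, "set31")   # E11/E21 branches locked
})

test_that("a repeated feature resonates with its original SET and is refreshed", {
  st <- build_sdn()
  st <- present_stimulus(st, "a", 50)
  st <- advance_time(st, 5000)
  rate_before <- held_items(st)$rate
  st <- present_stimulus(st, "a", 50)
  expect_identical(attr(st, "set_id"), "set11")
  ev <- sdn_events(st)
  expect_identical(ev$event, c("stored", "refreshed"))
  expect_gt(held_items(st)$rate, rate_before)
  expect_identical(nrow(held_items(st)), 1L)
})

test_that("capacity is four and the fifth item evicts the earliest stored", {
  st <- build_sdn()
  counts <- integer(0)
  for (k in 1:6) {
    st <- advance_time(st, 500)
    st <- present_stimulus(st, paste0("f", k), 50)
    counts <- c(counts, nrow(held_items(st)))
  }
  expect_identical(counts, c(1L, 2L, 3L, 4L, 4L, 4L))
  ev <- sdn_events(st)
  expect_identical(ev$feature_id[ev$event == "evicted"], c("f1", "f2"))
  expect_setequal(held_items(st)$feature_id, c("f3", "f4", "f5", "f6"))
})

test_that("rehearsal changes the eviction victim to the now-weakest item", {
  st <- build_sdn()
  for (k in 1:4) {
    st <- advance_time(st, 500)
    st <- present_stimulus(st, paste0("h", k), 50)
  }
  st <- advance_time(st, 500)
  st <- present_stimulus(st, "h1", 50)    # rehearse the oldest
  st <- advance_time(st, 500)
  st <- present_stimulus(st, "h5", 50)
  ev <- sdn_events(st)
  expect_identical(ev$feature_id[ev$event == "evicted"], "h2")
  expect_identical(nrow(held_items(st)), 4L)
})

test_that("sub-threshold stimuli do not engage the circuit", {
  st <- build_sdn()
  expect_warning(out <- route_stimulus(st, "weak", 10), "sub-threshold")
  expect_true(is.na(out$set_id))
  expect_identical(held_items(out$state), held_items(st))
})

test_that("time passes: decay is monotone, staggered items keep their order", {
  st <- build_sdn()
  st0 <- advance_time(st, 1000)
  expect_identical(held_items(st0), held_items(st))  # nothing to decay
  expect_identical(st0$clock, 1000)
  st <- present_stimulus(st, "x", 50)
  st <- advance_time(st, 2000)
  st <- present_stimulus(st, "y", 50)
  h <- held_items(st)
  expect_lt(h$rate[h$feature_id == "x"], h$rate[h$feature_id == "y"])
  st2 <- advance_time(st, 10000)
  h2 <- held_items(st2)
  expect_lt(h2$rate[h2$feature_id == "x"], h$rate[h$feature_id == "x"])
  expect_lt(h2$rate[h2$feature_id == "x"], h2$rate[h2$feature_id == "y"])
})

test_that("an item whose rate crosses the threshold is forgotten and frees its SET", {
  fast <- feedback_params(tau = 20, w_pos = 0.99, w_der = 0)  # tau_eff 2 s
  st <- build_sdn(decay_params = fast)
  st <- present_stimulus(st, "x", 50)
  st <- advance_time(st, 60000)
  expect_identical(nrow(held_items(st)), 0L)
  ev <- sdn_events(st)
  forgotten <- ev[ev$event == "forgotten", ]
  expect_identical(forgotten$feature_id, "x")
  expect_equal(forgotten$t, 2000 * log(10), tolerance = 1e-8)
  expect_equal(forgotten$rate, 5)        # 10% of the 50-unit plateau
  # the freed branch is reused by the next stimulus
  st <- present_stimulus(st, "z", 50)
  expect_identical(attr(st, "set_id"), "set11")
})

test_that("eviction order matches the discrete-event oracle on random schedules", {
  fast <- feedback_params(tau = 20, w_pos = 0.99, w_der = 0)  # tau_eff 2 s
  tau_eff <- (20 + 0) / (1 - 0.99)
  withr::with_seed(20240501, {
    for (rep in 1:5) {
      n_ev <- 12
      schedule <- data.frame(
        t = cumsum(round(runif(n_ev, 200, 1500))),
        feature_id = paste0("f", sample(1:8, n_ev, replace = TRUE)),
        amplitude = 50)
      st <- run_sdn_schedule(build_sdn(decay_params = fast), schedule)
      ev <- sdn_events(st)
      oracle <- fifo_oracle(schedule, tau_eff, 0.1)
      expect_identical(ev$feature_id[ev$event == "evicted"],
                       oracle$evicted)
      expect_setequal(held_items(st)$feature_id, oracle$held)
    }
  })
})

test_that("rate mode selects the same branch sequence as logic mode", {
  st <- build_sdn(mode = "rate")
  sel <- character(0)
  for (k in 1:5) {
    st <- advance_time(st, 500)
    st <- present_stimulus(st, paste0("g", k), 50)
    sel <- c(sel, attr(st, "set_id"))
  }
  expect_identical(sel, c("set11", "set21", "set31", "set41", "set11"))
  # winner-take-all holds dynamically too
  r1 <- route_stimulus(build_sdn(mode = "rate"), "a", 50)
  expect_false(any(c("E22", "E32", "E42") %in% r1$state$nodes))
})

test_that("storing requires a fresh routing decision", {
  st <- build_sdn()
  expect_error(store_or_update(st, "set11", "a"), "route_stimulus")
  r <- route_stimulus(st, "a", 50)
  expect_error(store_or_update(r$state, "set21", "a"), "route_stimulus")
})
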