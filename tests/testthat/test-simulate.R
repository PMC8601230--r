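test_that("identical parameters and seed give bit-identical traces", {
  p <- simulation_params(recording_len_s = 1200)
  s1 <- simulate_trace(p, seed = 42)
  s2 <- simulate_trace(p, seed = 42)
  expect_identical(s1$trace$values, s2$trace$values)
  expect_identical(s1$events, s2$events)
  s3 <- simulate_trace(p, seed = 43)
  expect_false(identical(s1$trace$values, s3$trace$values))
})

test_that("non-responders emit baseline plus drift only", {
  p <- oracle_params(responder_frac = 0, drift_per_min = 0.06,
                     recording_len_s = 600)
  s <- simulate_trace(p, seed = 1)
  tm <- (seq_along(s$trace$values) - 1) * 7.5
  expect_equal(s$trace$values, 0.8 + 0.06 * tm / 60)
  expect_identical(s$egg$responder, FALSE)
  expect_identical(s$egg$n_events, 0L)
})

test_that("a single noiseless transient has the stated peak and support", {
  # cessation 0: no transient after the first
  p <- oracle_params(latency_mean_s = 120, first_dur_mean_s = 60,
                     amp_first = 0.5, cessation_mean_s = 0,
                     recording_len_s = 600)
  s <- simulate_trace(p, seed = 7)
  expect_identical(s$egg$n_events, 1L)
  v <- s$trace$values
  expect_equal(max(v) - 0.8, 0.5)
  elevated <- which(v > 0.8 + 1e-12)
  support <- (max(elevated) - min(elevated)) * 7.5
  expect_lte(abs(support - 60), 7.5)
  # elevation confined to [onset, onset + duration]
  tm <- (seq_along(v) - 1) * 7.5
  expect_true(all(tm[elevated] >= s$events$onset_s - 1e-9))
  expect_true(all(tm[elevated] <= s$events$onset_s +
                    s$events$duration_s + 1e-9))
})

test_that("a paired experiment has the expected shape and substreams", {
  sc <- scenario("sr_null")
  sim <- simulate_experiment(sc$a, sc$b, seed = 5)
  expect_length(sim$traceset, 153L)  # 75 + 78 eggs
  expect_true(all(vapply(sim$traceset$traces,
                         function(t) length(t$values), 1L) == 881L))
  expect_identical(sum(sim$truth$eggs$group == "NC"), 75L)
  expect_identical(sum(sim$truth$eggs$group == "SOV"), 78L)

  # adding eggs to group A must not perturb group B
  a_small <- scenario("sr_null", n_a = 3, n_b = 4)
  a_big <- scenario("sr_null", n_a = 6, n_b = 4)
  a_small$a$recording_len_s <- a_small$b$recording_len_s <- 600
  a_big$a$recording_len_s <- a_big$b$recording_len_s <- 600
  s1 <- simulate_experiment(a_small$a, a_small$b, seed = 9)
  s2 <- simulate_experiment(a_big$a, a_big$b, seed = 9)
  for (id in grep("^SOV", names(s1$traceset$traces), value = TRUE)) {
    expect_identical(s1$traceset[[id]]$values, s2$traceset[[id]]$values)
  }
  expect_identical(s1$traceset[["NC_001"]]$values,
                   s2$traceset[["NC_001"]]$values)
})

test_that("experiment simulation rejects mismatched acquisition", {
  a <- simulation_params(recording_len_s = 600)
  b <- simulation_params(recording_len_s = 900)
  expect_error(simulate_experiment(a, b), class = "caosc_config_error")
})

test_that("truth tables satisfy the non-overlap invariant", {
  p <- simulation_params(n_eggs = 1, recording_len_s = 2400)
  for (seed in 1:8) {
    s <- simulate_trace(p, seed = seed)
    ev <- s$events
    if (nrow(ev) > 1L) {
      expect_true(all(diff(ev$onset_s) > 0))
      expect_true(all(ev$onset_s[-1L] >=
                        ev$onset_s[-nrow(ev)] +
                        ev$duration_s[-nrow(ev)] - 1e-9))
    }
  }
})

test_that("empirical truth moments match the generator parameters", {
  # 500 eggs; amp/dur heterogeneity off so moments are the stated means
  sc <- list(
    a = oracle_params(n_eggs = 250, latency_mean_s = 120,
                      latency_sd_s = 30, sub_dur_mean_s = 60,
                      sub_dur_sd_s = 15, iti_mean_s = 170, iti_sd_s = 35,
                      iti_slowdown = 1, cessation_mean_s = 1e6,
                      recording_len_s = 1500, group = "A"),
    b = NULL)
  sc$b <- sc$a
  sc$b$group <- "B"
  sim <- simulate_experiment(sc$a, sc$b, seed = 13)
  eggs <- sim$truth$eggs
  ev <- sim$truth$events

  lat <- eggs$first_onset_s[eggs$responder]
  expect_gte(length(lat), 500L)
  expect_lte(abs(mean(lat) - 120), 3 * 30 / sqrt(length(lat)))

  sub <- ev$duration_s[ev$event > 1L]
  expect_lte(abs(mean(sub) - 60), 3 * 15 / sqrt(length(sub)))

  iti <- unlist(lapply(split(ev$onset_s, ev$egg_id), diff),
                use.names = FALSE)
  # onset-grid snapping and the >= duration floor shift intervals by at
  # most a sample; allow that on top of the Monte Carlo band
  expect_lte(abs(mean(iti) - 170), 3 * 35 / sqrt(length(iti)) + 7.5)
})

test_that("scenarios encode the documented group contrasts", {
  sp <- scenario("sr_paper")
  expect_equal(sp$b$first_dur_mean_s / sp$a$first_dur_mean_s, 1.5)
  expect_equal(sp$b$latency_mean_s / sp$a$latency_mean_s, 1.15)
  others <- setdiff(names(sp$a), c("n_eggs", "group", "latency_mean_s",
                                   "first_dur_mean_s"))
  expect_identical(unclass(sp$a)[others], unclass(sp$b)[others])

  sn <- scenario("sr_null")
  same <- setdiff(names(sn$a), c("n_eggs", "group"))
  expect_identical(unclass(sn$a)[same], unclass(sn$b)[same])

  iv <- scenario("ivf_shift")
  expect_equal(iv$b$latency_mean_s / iv$a$latency_mean_s, 1.5)
  expect_identical(scenario("ivf_null")$a$mode, "ivf")
  expect_error(scenario("unknown"), class = "caosc_config_error")
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(simulation_params(responder_frac = 1.2),
               class = "caosc_config_error")
  expect_error(simulation_params(iti_slowdown = 0.9),
               class = "caosc_config_error")
  expect_error(simulation_params(amp_first = 0),
               class = "caosc_config_error")
  expect_error(simulation_params(recording_len_s = 5),
               class = "caosc_config_error")
})
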