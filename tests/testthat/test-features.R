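flat_baseline <- function(b = 0.8) {
  structure(list(baseline = b, noise_sd = 0, method_tag = "fixed"),
            class = "baseline_model")
}

transients_at <- function(onsets_s, durations_s = 30) {
  durations_s <- rep_len(durations_s, length(onsets_s))
  data.frame(onset_s = onsets_s, peak_s = onsets_s + 15,
             offset_s = onsets_s + durations_s,
             amplitude = rep_len(0.5, length(onsets_s)),
             duration_s = durations_s,
             truncated = rep(FALSE, length(onsets_s)))
}

test_that("a single transient yields the defining feature values", {
  t <- pulse_trace(n = 1000, amp = 0.5, start_s = 120, width_s = 90)
  f <- extract_features(t, transients_at(120, 90), flat_baseline())
  expect_true(f$responder)
  expect_equal(f$time_to_first_s, 120)
  expect_equal(f$first_duration_s, 90)
  expect_identical(f$n_osc_60, 1L)
  expect_identical(f$n_osc_120, 1L)
  expect_equal(f$freq_per_10min, 1 / 6)
  expect_equal(f$cessation_s, 0)
})

test_that("oscillation counting windows anchor at the first onset", {
  # onsets every 10 min for 110 min starting at 600 s (12 events)
  onsets <- 600 + (0:11) * 600
  t <- ca_trace("count", rep(0.8, 1100))  # 8242.5 s recording
  f <- extract_features(t, transients_at(onsets), flat_baseline())
  expect_identical(f$n_osc_60, 6L)
  expect_identical(f$n_osc_120, 12L)
  expect_equal(f$freq_per_10min, 1)
  expect_equal(f$cessation_s, 11 * 600)
})

test_that("eggs without transients become non-responder rows", {
  t <- ca_trace("none", rep(0.8, 100))
  f <- extract_features(t, transients_at(numeric(0)), flat_baseline())
  expect_false(f$responder)
  expect_true(is.na(f$time_to_first_s))
  expect_true(is.na(f$n_osc_60))
})

test_that("the frequency identity freq = n_osc_60 / 6 holds throughout", {
  sc <- scenario("sr_null", n_a = 10, n_b = 10)
  sc$a$recording_len_s <- sc$b$recording_len_s <- 2400
  sim <- simulate_experiment(sc$a, sc$b, seed = 21)
  f <- extract_features_set(sim$traceset)$features
  resp <- f[f$responder, ]
  expect_gt(nrow(resp), 0L)
  expect_equal(resp$freq_per_10min, resp$n_osc_60 / 6)
  # determinism of the extraction
  f2 <- extract_features_set(sim$traceset)$features
  expect_identical(f, f2)
})

test_that("censoring follows the horizon lookahead and truncation rules", {
  t <- ca_trace("c", rep(0.8, 1000))  # 7492.5 s
  # last onset well before horizon - 10 min: not censored
  f1 <- extract_features(t, transients_at(c(0, 600)), flat_baseline())
  expect_false(f1$censored)
  # last onset within 10 min of the (recording-capped) horizon
  f2 <- extract_features(t, transients_at(c(0, 7100)), flat_baseline())
  expect_true(f2$censored)
  # right-truncated final transient
  tr <- transients_at(c(0, 600))
  tr$truncated[2] <- TRUE
  f3 <- extract_features(t, tr, flat_baseline())
  expect_true(f3$censored)
})

test_that("persistence curves step at the observed cessation times", {
  f <- features_table("NC", cessation_s = c(30, 60, 90) * 60)
  pc <- persistence_curve(f, grid_step_min = 10, horizon_min = 110)
  expect_equal(pc$fraction[pc$time_min == 0], 1)
  expect_equal(pc$fraction[pc$time_min == 20], 1)
  expect_equal(pc$fraction[pc$time_min == 30], 2 / 3)
  expect_equal(pc$fraction[pc$time_min == 60], 1 / 3)
  expect_equal(pc$fraction[pc$time_min == 90], 0)
  expect_true(all(diff(pc$fraction) <= 1e-12))

  all_cens <- features_table("NC", cessation_s = rep(100, 5),
                             censored = TRUE)
  pc2 <- persistence_curve(all_cens)
  expect_true(all(pc2$fraction == 1))

  none <- features_table("NC", cessation_s = 1, censored = FALSE)
  none$responder <- FALSE
  expect_error(persistence_curve(none), class = "caosc_feature_error")
})

test_that("the persistence curve tracks the generator's survival law", {
  # cessation ~ truncated Gaussian(4800 s, 600 s); no censoring
  set.seed(31)
  cess <- caosc:::rtnorm(300, 4800, 600, 0)
  f <- features_table("NC", cessation_s = cess)
  pc <- persistence_curve(f, grid_step_min = 10, horizon_min = 110)
  surv80 <- (1 - pnorm((80 * 60 - 4800) / 600)) /
    (1 - pnorm((0 - 4800) / 600))
  expect_lt(abs(pc$fraction[pc$time_min == 80] - surv80), 0.05)
  surv90 <- (1 - pnorm((90 * 60 - 4800) / 600)) /
    (1 - pnorm((0 - 4800) / 600))
  expect_lt(abs(pc$fraction[pc$time_min == 90] - surv90), 0.05)
})

test_that("the engineered first-transient contrast is recovered", {
  # noiseless sr_paper-style contrast: median first duration ratio ~ 1.5
  sc <- scenario("sr_paper", n_a = 100, n_b = 100)
  for (g in c("a", "b")) {
    sc[[g]]$recording_len_s <- 1200
    sc[[g]]$noise_sd <- 0
    sc[[g]]$amp_cv <- 0
    sc[[g]]$dur_cv <- 0
  }
  sim <- simulate_experiment(sc$a, sc$b, seed = 17)
  # the generator's truth realises the engineered 1.5 ratio exactly
  ev1 <- sim$truth$events[sim$truth$events$event == 1L, ]
  truth_ratio <-
    median(ev1$duration_s[grepl("^SOV", ev1$egg_id)]) /
    median(ev1$duration_s[grepl("^NC", ev1$egg_id)])
  expect_lt(abs(truth_ratio - 1.5), 0.075)
  # extracted durations carry a known ~one-sample additive bias (onset
  # lags the threshold crossing; offsets snap up to sample times), so
  # the recovered ratio is looser at 7.5-s sampling of ~1-min events
  f <- extract_features_set(sim$traceset)$features
  ratio <- median(f$first_duration_s[f$group == "SOV"], na.rm = TRUE) /
    median(f$first_duration_s[f$group == "NC"], na.rm = TRUE)
  expect_lt(abs(ratio - 1.5), 0.15)
})
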