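test_that("worked Mann-Whitney examples match enumeration", {
  r1 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r1$U, 0)
  expect_equal(r1$p_value, 0.1)
  expect_identical(r1$method, "mw_exact")

  r2 <- mann_whitney_u(c(1, 3), c(2, 4))
  expect_equal(r2$U, 1)
  expect_equal(r2$p_value, 2 / 3)

  # identical samples: degenerate at the centre
  r3 <- mann_whitney_u(rep(2, 4), rep(2, 4))
  expect_equal(r3$U, 8)
  expect_equal(r3$p_value, 1)
})

test_that("exact p equals brute-force enumeration on random instances", {
  set.seed(71)
  for (i in 1:60) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    x <- sample(seq_len(50), n1)  # tie-free by construction
    y <- sample(setdiff(seq_len(50), x), n2)
    got <- mann_whitney_u(x, y, method = "exact")
    want <- mw_brute_force(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p_value, want$p)
  }
})

test_that("the asymptotic branch approximates the exact one at n = 10", {
  set.seed(72)
  for (i in 1:40) {
    x <- sample(seq_len(200), 10)
    y <- sample(setdiff(seq_len(200), x), 10)
    pe <- mann_whitney_u(x, y, method = "exact")$p_value
    pa <- mann_whitney_u(x, y, method = "asymptotic")$p_value
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("tied data fall back to the corrected normal approximation", {
  set.seed(73)
  x <- sample(1:5, 8, replace = TRUE)
  y <- sample(1:5, 9, replace = TRUE)
  got <- mann_whitney_u(x, y)
  expect_identical(got$method, "mw_asymptotic")
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-12)
  expect_equal(got$U, min(unname(ref$statistic),
                          length(x) * length(y) - unname(ref$statistic)))
})

test_that("p-values are invariant under monotone transformation", {
  set.seed(74)
  x <- rlnorm(12)
  y <- rlnorm(15) * 1.5
  p1 <- mann_whitney_u(x, y)$p_value
  p2 <- mann_whitney_u(log(x), log(y))$p_value
  p3 <- mann_whitney_u(rank(c(x, y))[1:12],
                       rank(c(x, y))[13:27])$p_value
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("log-rank matches the hand-tabulated small example", {
  # A events at 1, 2; B events at 3, 4; no censoring.
  # O/E/V table: t=1 (E=1/2, V=1/4), t=2 (E=1/3, V=2/9), t=3, t=4 (V=0)
  # => O = 2, E = 5/6, V = 17/36, chi = (7/6)^2 / (17/36) = 49/17
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1),
                     c("A", "A", "B", "B"))
  expect_equal(lr$chi_square, 49 / 17)
  expect_equal(lr$p_value, pchisq(49 / 17, 1, lower.tail = FALSE))
})

test_that("identical groups give chi-square 0 and p 1", {
  lr <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                     rep(c("A", "B"), each = 3))
  expect_equal(lr$chi_square, 0)
  expect_equal(lr$p_value, 1)
})

test_that("log-rank agrees with an independent implementation", {
  skip_if_not_installed("survival")
  set.seed(75)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    time <- round(rexp(n, 1 / 50), 1)
    event <- rbinom(n, 1, 0.7)
    group <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(group)) < 2L || sum(event) == 0L) next
    got <- logrank_test(time, event, group)
    ref <- survival::survdiff(survival::Surv(time, event) ~ group)
    expect_equal(got$chi_square, unname(ref$chisq), tolerance = 1e-10)
    expect_equal(got$p_value,
                 pchisq(unname(ref$chisq), 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("the log-rank statistic is invariant under group relabelling", {
  set.seed(76)
  time <- rexp(30, 1 / 40)
  event <- rbinom(30, 1, 0.6)
  group <- rep(c("A", "B"), 15)
  if (sum(event) == 0) event[1] <- 1L
  g1 <- logrank_test(time, event, group)
  g2 <- logrank_test(time, event, ifelse(group == "A", "B", "A"))
  expect_equal(g1$chi_square, g2$chi_square)
})

test_that("log-rank input validation rejects degenerate designs", {
  expect_error(logrank_test(1:4, rep(1, 4), rep("A", 4)),
               class = "caosc_stats_error")
  expect_error(logrank_test(1:4, rep(0, 4), rep(c("A", "B"), 2)),
               class = "caosc_stats_error")
  expect_error(mann_whitney_u(numeric(0), 1:3),
               class = "caosc_stats_error")
})

test_that("compare_groups assembles the six-panel comparison", {
  fa <- features_table("NC", cessation_s = c(10, 20, 30, 40, 50) * 60)
  fb <- features_table("SOV", cessation_s = c(15, 25, 35, 45, 55) * 60)
  # perturb one metric so medians differ somewhere
  fb$first_duration_s <- fb$first_duration_s + c(1, 2, 3, 4, 5)
  cmp <- compare_groups(fa, fb)
  expect_s3_class(cmp, "group_comparison")
  expect_identical(cmp$metric,
                   c("time_to_first_s", "first_duration_s",
                     "freq_per_10min", "auc_60", "n_osc_120",
                     "persistence"))
  expect_true(all(cmp$testable))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))

  # comparing a table against itself: every p-value is 1
  self <- compare_groups(fa, fa)
  expect_true(all(self$p_value == 1))

  # fewer than 3 responders: flagged untestable, not dropped
  tiny <- compare_groups(fa[1:2, ], fb)
  expect_identical(nrow(tiny), 6L)
  expect_true(all(!tiny$testable))
  expect_true(all(is.na(tiny$p_value)))
})

test_that("null-scenario p-values are uniform for every metric", {
  # exchangeable groups => p ~ U(0,1) up to rank-test discreteness
  oc <- simulate_pvalues("sr_null", n_reps = 150, seed = 907,
                         overrides = list(recording_len_s = 1500))
  for (m in c("time_to_first_s", "first_duration_s", "freq_per_10min",
              "auc_60", "n_osc_120")) {
    ks <- suppressWarnings(stats::ks.test(oc$p_values[, m], "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("Holm correction is applied across panels when requested", {
  fa <- features_table("NC", cessation_s = c(10, 20, 30, 40, 50) * 60)
  fb <- features_table("SOV", cessation_s = c(15, 25, 35, 45, 55) * 60)
  fb$time_to_first_s <- fb$time_to_first_s + seq_len(5)
  plain <- compare_groups(fa, fb)
  holm <- compare_groups(fa, fb, holm = TRUE)
  expect_identical(plain$p_value, holm$p_value)  # raw p reported either way
  expect_true(sum(holm$significant) <= sum(plain$significant))
})
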