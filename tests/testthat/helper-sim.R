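# Shared fixture builders. All synthetic inputs are constructed in code.

# Homogeneous-egg parameters: no per-egg scale heterogeneity, so truth
# moments are exactly the stated means (oracle-friendly).
oracle_params <- function(...) {
  defaults <- list(n_eggs = 1, noise_sd = 0, drift_per_min = 0,
                   amp_cv = 0, dur_cv = 0, latency_sd_s = 0,
                   first_dur_sd_s = 0, sub_dur_sd_s = 0, iti_sd_s = 0,
                   cessation_sd_s = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_params, args)
}

# A flat trace carrying a single rectangular pulse of amplitude `amp`
# occupying samples in [start_s, start_s + width_s).
pulse_trace <- function(n = 481, dt = 7.5, baseline = 0.8, amp = 0.5,
                        start_s = 600, width_s = 300, egg_id = "pulse") {
  tm <- (seq_len(n) - 1) * dt
  v <- rep(baseline, n)
  v[tm >= start_s - 1e-9 & tm < start_s + width_s - 1e-9] <- baseline + amp
  ca_trace(egg_id, v, sampling_interval_s = dt)
}

# Minimal egg_features rows for direct stats/persistence tests.
features_row <- function(egg_id, group, cessation_s, censored = FALSE,
                         responder = TRUE) {
  df <- data.frame(
    egg_id = egg_id, group = group, mode = "strontium",
    responder = responder, time_to_first_s = 100, first_duration_s = 60,
    n_osc_60 = 6L, n_osc_120 = 10L, freq_per_10min = 1, auc_60 = 100,
    cessation_s = cessation_s, censored = censored,
    stringsAsFactors = FALSE)
  class(df) <- c("egg_features", "data.frame")
  df
}

features_table <- function(group, cessation_s, censored = FALSE) {
  rows <- lapply(seq_along(cessation_s), function(i) {
    features_row(sprintf("%s_%02d", group, i), group, cessation_s[i],
                 censored = if (length(censored) > 1L) censored[i]
                 else censored)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("egg_features", "data.frame")
  out
}

# Brute-force Mann-Whitney oracle: enumerate every group assignment of
# the pooled sample and count assignments with min(U, n1*n2 - U) at
# most the observed value. Independent of the package's DP routine.
mw_brute_force <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n2 <- length(y)
  u_of <- function(idx) {
    xs <- pooled[idx]
    ys <- pooled[-idx]
    u1 <- sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
    min(u1, n1 * n2 - u1)
  }
  obs <- u_of(seq_len(n1))
  assignments <- utils::combn(n1 + n2, n1)
  dist <- apply(assignments, 2, u_of)
  list(U = obs, p = mean(dist <= obs + 1e-9))
}

# Greedy matching of detected onsets to true onsets within a tolerance.
match_events <- function(true_onsets, det_onsets, tol) {
  used <- logical(length(det_onsets))
  err <- rep(NA_real_, length(true_onsets))
  for (i in seq_along(true_onsets)) {
    d <- abs(det_onsets - true_onsets[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE
      err[i] <- det_onsets[j] - true_onsets[i]
    }
  }
  list(matched = sum(!is.na(err)), err = err[!is.na(err)],
       n_true = length(true_onsets), n_det = length(det_onsets))
}
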