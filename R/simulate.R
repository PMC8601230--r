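#' Parameters for the synthetic calcium-trace generator
#'
#' Defines one group's generative regime. A responding egg shows a
#' latency from the stimulus to a first, larger and longer transient,
#' followed by shorter transients whose inter-onset interval slowly
#' stretches (frequency decay), until a per-egg cessation time after
#' which no further transients occur. Transients are piecewise
#' linear-rise / exponential-decay pulses added to a slowly drifting
#' baseline with i.i.d. Gaussian noise. Latencies, durations and
#' inter-transient intervals are truncated-Gaussian draws (floored at
#' one sampling interval), and two unit-mean lognormal per-egg scale
#' factors (`amp_cv`, `dur_cv`) model egg-to-egg heterogeneity in
#' release magnitude and transient length.
#'
#' All times are seconds, amplitudes are ratio units above baseline.
#'
#' @param n_eggs Number of eggs to simulate for this group.
#' @param group Group label attached to simulated traces.
#' @param mode Activation mode, `"strontium"` or `"ivf"`.
#' @param baseline Resting F340/F380 ratio.
#' @param noise_sd SD of additive Gaussian noise (ratio units).
#' @param drift_per_min Linear baseline drift (ratio units per minute).
#' @param latency_mean_s,latency_sd_s Stimulus-to-first-onset latency.
#' @param first_dur_mean_s,first_dur_sd_s Duration of the first transient.
#' @param sub_dur_mean_s,sub_dur_sd_s Duration of subsequent transients.
#' @param amp_first,amp_sub Peak amplitudes of the first and subsequent
#'   transients (ratio units above baseline).
#' @param amp_cv,dur_cv Coefficients of variation of the per-egg
#'   amplitude and duration scale factors (0 disables).
#' @param iti_mean_s,iti_sd_s Inter-transient onset interval.
#' @param iti_slowdown Multiplicative stretch of the interval mean per
#'   successive transient (>= 1); models slowly decaying frequency.
#' @param cessation_mean_s,cessation_sd_s Time after the first onset at
#'   which oscillations stop; may exceed the recording length, in which
#'   case the egg is censored at the end of the recording.
#' @param responder_frac Fraction of eggs that ever oscillate.
#' @param recording_len_s Recording length.
#' @param sampling_interval_s Sampling interval.
#' @param stimulus_time_s Stimulus time relative to recording start.
#' @return An object of class `"sim_params"`.
#' @seealso [scenario()], [simulate_trace()], [simulate_experiment()]
#' @export
simulation_params <- function(n_eggs = 75, group = "A", mode = "strontium",
                              baseline = 0.8, noise_sd = 0.02,
                              drift_per_min = 0.0002,
                              latency_mean_s = 120, latency_sd_s = 30,
                              first_dur_mean_s = 70, first_dur_sd_s = 15,
                              sub_dur_mean_s = 60, sub_dur_sd_s = 15,
                              amp_first = 0.4, amp_sub = 0.35,
                              amp_cv = 0.6, dur_cv = 0.25,
                              iti_mean_s = 170, iti_sd_s = 35,
                              iti_slowdown = 1.02,
                              cessation_mean_s = 5400,
                              cessation_sd_s = 1800,
                              responder_frac = 1,
                              recording_len_s = 6600,
                              sampling_interval_s = 7.5,
                              stimulus_time_s = 0) {
  p <- list(n_eggs = n_eggs, group = as.character(group),
            mode = match.arg(mode, c("strontium", "ivf")),
            baseline = baseline, noise_sd = noise_sd,
            drift_per_min = drift_per_min,
            latency_mean_s = latency_mean_s, latency_sd_s = latency_sd_s,
            first_dur_mean_s = first_dur_mean_s,
            first_dur_sd_s = first_dur_sd_s,
            sub_dur_mean_s = sub_dur_mean_s, sub_dur_sd_s = sub_dur_sd_s,
            amp_first = amp_first, amp_sub = amp_sub,
            amp_cv = amp_cv, dur_cv = dur_cv,
            iti_mean_s = iti_mean_s, iti_sd_s = iti_sd_s,
            iti_slowdown = iti_slowdown,
            cessation_mean_s = cessation_mean_s,
            cessation_sd_s = cessation_sd_s,
            responder_frac = responder_frac,
            recording_len_s = recording_len_s,
            sampling_interval_s = sampling_interval_s,
            stimulus_time_s = stimulus_time_s)
  check_number(p$n_eggs, "n_eggs", 1)
  check_number(p$baseline, "baseline", 0, strict_lower = TRUE)
  check_number(p$sampling_interval_s, "sampling_interval_s", 0,
               strict_lower = TRUE)
  if (p$recording_len_s < p$sampling_interval_s) {
    caosc_stop("recording_len_s must cover at least one sampling interval",
               "caosc_config_error")
  }
  for (f in c("noise_sd", "drift_per_min", "latency_mean_s", "latency_sd_s",
              "first_dur_mean_s", "first_dur_sd_s", "sub_dur_mean_s",
              "sub_dur_sd_s", "iti_mean_s", "iti_sd_s", "cessation_mean_s",
              "cessation_sd_s", "amp_cv", "dur_cv", "stimulus_time_s")) {
    check_number(p[[f]], f, 0)
  }
  check_number(p$amp_first, "amp_first", 0, strict_lower = TRUE)
  check_number(p$amp_sub, "amp_sub", 0, strict_lower = TRUE)
  check_number(p$responder_frac, "responder_frac", 0, 1)
  check_number(p$iti_slowdown, "iti_slowdown", 1)
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_params> group '%s' (%s): %d eggs, %.0f s recording @ %g s\n",
           "  latency %g±%g s, first transient %g±%g s x %g, ",
           "subsequent %g±%g s x %g\n",
           "  inter-onset %g±%g s (stretch %g), cessation %g±%g s, ",
           "noise sd %g\n"),
    x$group, x$mode, x$n_eggs, x$recording_len_s, x$sampling_interval_s,
    x$latency_mean_s, x$latency_sd_s, x$first_dur_mean_s, x$first_dur_sd_s,
    x$amp_first, x$sub_dur_mean_s, x$sub_dur_sd_s, x$amp_sub,
    x$iti_mean_s, x$iti_sd_s, x$iti_slowdown, x$cessation_mean_s,
    x$cessation_sd_s, x$noise_sd))
  invisible(x)
}

# IVF regime defaults: longer latency (sperm fusion), sparser oscillations,
# longer recording (120 min vs 110 min for strontium).
ivf_defaults <- function(n_eggs = 68, group = "A") {
  simulation_params(n_eggs = n_eggs, group = group, mode = "ivf",
                    latency_mean_s = 900, latency_sd_s = 240,
                    first_dur_mean_s = 90, first_dur_sd_s = 20,
                    amp_first = 0.5, iti_mean_s = 240, iti_sd_s = 50,
                    iti_slowdown = 1.03, recording_len_s = 7200)
}

#' Canonical paired simulation scenarios
#'
#' Returns the two-group parameter sets used throughout the package's
#' validation studies:
#' \describe{
#'   \item{`sr_null`}{Strontium regime, identical groups (n = 75 vs 78).}
#'   \item{`sr_paper`}{Strontium regime in which group B has a slightly
#'     delayed first-transient onset (latency mean x 1.15) and a 50%
#'     longer first transient (duration mean x 1.5), all else equal —
#'     the pattern reported for superovulated eggs under strontium
#'     activation.}
#'   \item{`ivf_null`}{IVF regime, identical groups (n = 68 vs 92).}
#'   \item{`ivf_shift`}{IVF regime positive control: group B latency
#'     mean x 1.5.}
#' }
#'
#' @param name Scenario name.
#' @param n_a,n_b Optional overrides of the per-group egg counts.
#' @return A list with elements `a` and `b`, each a [simulation_params()].
#' @export
scenario <- function(name = c("sr_null", "sr_paper", "ivf_null",
                              "ivf_shift"),
                     n_a = NULL, n_b = NULL) {
  if (!is.character(name) || !name[1L] %in% c("sr_null", "sr_paper",
                                              "ivf_null", "ivf_shift")) {
    caosc_stop(sprintf("unknown scenario '%s'", as.character(name)[1L]),
               "caosc_config_error")
  }
  name <- match.arg(name)
  if (startsWith(name, "sr")) {
    a <- simulation_params(n_eggs = n_a %||% 75, group = "NC")
    b <- simulation_params(n_eggs = n_b %||% 78, group = "SOV")
  } else {
    a <- ivf_defaults(n_eggs = n_a %||% 68, group = "NC")
    b <- ivf_defaults(n_eggs = n_b %||% 92, group = "SOV")
  }
  if (name == "sr_paper") {
    b$latency_mean_s <- b$latency_mean_s * 1.15
    b$first_dur_mean_s <- b$first_dur_mean_s * 1.5
  } else if (name == "ivf_shift") {
    b$latency_mean_s <- b$latency_mean_s * 1.5
  }
  list(a = a, b = b)
}

# Piecewise pulse: linear rise over ~20% of the duration (snapped to the
# sampling grid so the peak falls on a sample), then exponential decay
# reaching ~5% of the amplitude at the end of the duration; zero outside.
add_transient_shape <- function(vals, times, onset, dur, amp, dt) {
  n <- length(vals)
  # onset sits on the sampling grid, so the index range is arithmetic
  i0 <- as.integer(round(onset / dt)) + 1L
  i1 <- min(n, as.integer(floor((onset + dur) / dt + 1e-9)) + 1L)
  if (i0 > n || i1 < i0) return(vals)
  rise_n <- max(1L, as.integer(round(0.2 * dur / dt)))
  rise_t <- rise_n * dt
  i <- i0:i1
  tt <- (i - i0) * dt
  tau <- max((dur - rise_t) / 3, dt / 3)
  r <- tt <= rise_t + 1e-9
  shape <- numeric(length(tt))
  shape[r] <- amp * tt[r] / rise_t
  shape[!r] <- amp * exp(-(tt[!r] - rise_t) / tau)
  vals[i] <- vals[i] + shape
  vals
}

# Simulate one egg with the current RNG state. Returns trace + truth.
sim_egg <- function(p, egg_id, replicate = "r1") {
  dt <- p$sampling_interval_s
  n <- as.integer(floor(p$recording_len_s / dt + 1e-9)) + 1L
  times <- (seq_len(n) - 1) * dt
  vals <- p$baseline + p$drift_per_min * times / 60
  responder <- stats::runif(1) < p$responder_frac
  onsets <- durs <- amps <- numeric(0)
  cess <- NA_real_
  if (responder) {
    lat <- rtnorm1(p$latency_mean_s, p$latency_sd_s, dt)
    amp_scale <- rlnorm_scale(1, p$amp_cv)
    dur_scale <- rlnorm_scale(1, p$dur_cv)
    cess <- rtnorm1(p$cessation_mean_s, p$cessation_sd_s, 0)
    onset <- snap_to_grid(p$stimulus_time_s + lat, dt)
    dur <- max(2 * dt,
               rtnorm1(p$first_dur_mean_s, p$first_dur_sd_s, 2 * dt) *
                 dur_scale)
    first_onset <- onset
    k <- 0L
    rec_last <- p$recording_len_s - dt + 1e-9
    iti_mean <- p$iti_mean_s
    iti_sd <- p$iti_sd_s
    slow <- p$iti_slowdown
    sub_mean <- p$sub_dur_mean_s
    sub_sd <- p$sub_dur_sd_s
    amp1 <- p$amp_first * amp_scale
    amp2 <- p$amp_sub * amp_scale
    while (onset <= rec_last) {
      k <- k + 1L
      onsets[k] <- onset
      durs[k] <- dur
      amps[k] <- if (k == 1L) amp1 else amp2
      vals <- add_transient_shape(vals, times, onset, dur, amps[k], dt)
      # next onset: interval floored at the current duration so events
      # never overlap (redraw a bounded number of times, then clamp)
      m <- iti_mean * slow^(k - 1L)
      iti <- rtnorm1(m, iti_sd, dt)
      tries <- 0L
      while (iti < dur && tries < 50L) {
        iti <- rtnorm1(m, iti_sd, dt)
        tries <- tries + 1L
      }
      if (iti < dur) iti <- dur + dt
      nxt <- snap_to_grid(onset + iti, dt)
      while (nxt < onset + dur - 1e-9) nxt <- nxt + dt
      ndur <- max(2 * dt, rtnorm1(sub_mean, sub_sd, 2 * dt) * dur_scale)
      if (nxt - first_onset > cess || nxt > rec_last) break
      onset <- nxt
      dur <- ndur
    }
  }
  if (p$noise_sd > 0) vals <- vals + stats::rnorm(n, 0, p$noise_sd)
  tr <- new_trace(egg_id, vals, dt, p$stimulus_time_s, p$group, p$mode,
                  replicate)
  truncated_last <- length(onsets) > 0 &&
    onsets[length(onsets)] + durs[length(durs)] > p$recording_len_s
  egg_row <- list(
    egg_id = egg_id, group = p$group, responder = responder,
    n_events = length(onsets),
    first_onset_s = if (length(onsets)) onsets[1L] else NA_real_,
    last_onset_s = if (length(onsets)) onsets[length(onsets)] else NA_real_,
    cessation_s = cess,
    censored_at_end = isTRUE(!is.na(cess) &&
                               length(onsets) > 0 &&
                               onsets[1L] + cess > p$recording_len_s),
    truncated_last = truncated_last)
  events <- list(egg_id = rep(egg_id, length(onsets)),
                 event = seq_along(onsets), onset_s = onsets,
                 duration_s = durs, amplitude = amps)
  list(trace = tr, egg = egg_row, events = events)
}

bind_truth <- function(sims) {
  egg_cols <- names(sims[[1L]]$egg)
  eggs <- lapply(egg_cols, function(cn) {
    unlist(lapply(sims, function(s) s$egg[[cn]]), use.names = FALSE)
  })
  names(eggs) <- egg_cols
  ev_cols <- names(sims[[1L]]$events)
  events <- lapply(ev_cols, function(cn) {
    unlist(lapply(sims, function(s) s$events[[cn]]), use.names = FALSE)
  })
  names(events) <- ev_cols
  if (is.null(events$egg_id)) events$egg_id <- character(0)
  list(eggs = as.data.frame(eggs, stringsAsFactors = FALSE),
       events = as.data.frame(events, stringsAsFactors = FALSE))
}

#' Simulate a single calcium trace with ground truth
#'
#' @param p A [simulation_params()] object.
#' @param seed Integer seed (per-trace RNG stream).
#' @param egg_id Identifier for the simulated egg.
#' @return A list with elements `trace` (a [ca_trace()]), `egg` (one-row
#'   truth data frame: responder flag, true first/last onsets, true
#'   cessation time relative to the first onset, censoring flag) and
#'   `events` (one row per true transient: onset, duration, amplitude).
#' @examples
#' p <- simulation_params(n_eggs = 1, noise_sd = 0)
#' sim <- simulate_trace(p, seed = 1)
#' sim$egg$n_events
#' @export
simulate_trace <- function(p, seed = 1L, egg_id = "egg_001") {
  if (!inherits(p, "sim_params")) {
    caosc_stop("'p' must be a sim_params object", "caosc_config_error")
  }
  set.seed(seed)
  s <- sim_egg(p, egg_id)
  truth <- bind_truth(list(s))
  list(trace = s$trace, egg = truth$eggs, events = truth$events)
}

#' Simulate a paired two-group experiment
#'
#' Simulates both groups of one imaging experiment. Each group draws
#' from its own RNG substream derived from `seed`, and each egg from a
#' per-egg substream, so adding eggs to one group perturbs neither the
#' other group nor earlier eggs.
#'
#' @param p_a,p_b [simulation_params()] for groups A and B; must share
#'   `recording_len_s` and `sampling_interval_s`.
#' @param seed Integer master seed.
#' @return A list with elements `traceset` (a [traceset()] holding both
#'   groups) and `truth` (list of `eggs` and `events` data frames).
#' @export
simulate_experiment <- function(p_a, p_b, seed = 1L) {
  if (!inherits(p_a, "sim_params") || !inherits(p_b, "sim_params")) {
    caosc_stop("'p_a' and 'p_b' must be sim_params objects",
               "caosc_config_error")
  }
  if (p_a$recording_len_s != p_b$recording_len_s ||
      p_a$sampling_interval_s != p_b$sampling_interval_s) {
    caosc_stop("groups must share recording length and sampling interval",
               "caosc_config_error")
  }
  if (!identical(p_a$mode, p_b$mode)) {
    caosc_stop("groups must share the activation mode",
               "caosc_config_error")
  }
  sims <- vector("list", p_a$n_eggs + p_b$n_eggs)
  gseeds <- derived_seeds(seed, 2L)
  j <- 0L
  for (g in 1:2) {
    p <- if (g == 1L) p_a else p_b
    eseeds <- derived_seeds(gseeds[g], p$n_eggs)
    for (i in seq_len(p$n_eggs)) {
      set.seed(eseeds[i])
      j <- j + 1L
      sims[[j]] <- sim_egg(p, sprintf("%s_%03d", p$group, i))
    }
  }
  ts <- new_traceset(lapply(sims, `[[`, "trace"), mode = p_a$mode,
                     provenance = "simulated")
  list(traceset = ts, truth = bind_truth(sims))
}
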