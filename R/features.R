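#' Feature-extraction options
#'
#' @param horizon_min Persistence analysis horizon in minutes from the
#'   first transient onset: 110 for strontium activation, 120 for IVF
#'   (`NULL` picks by trace mode).
#' @param censor_window_min Eggs whose last onset falls within this many
#'   minutes of the horizon (or whose last transient is right-truncated)
#'   are censored rather than scored as ceased; one typical
#'   inter-transient interval of lookahead avoids edge-of-recording
#'   bias.
#' @param auc_anchor Where the 60-min AUC window starts: at the first
#'   transient onset (default, consistent with the other metrics) or at
#'   the stimulus.
#' @return An object of class `"feature_config"`.
#' @export
feature_config <- function(horizon_min = NULL, censor_window_min = 10,
                           auc_anchor = c("first_transient", "stimulus")) {
  if (!is.null(horizon_min)) check_number(horizon_min, "horizon_min", 0,
                                          strict_lower = TRUE)
  check_number(censor_window_min, "censor_window_min", 0)
  structure(list(horizon_min = horizon_min,
                 censor_window_min = censor_window_min,
                 auc_anchor = match.arg(auc_anchor)),
            class = "feature_config")
}

default_horizon <- function(mode) if (identical(mode, "ivf")) 120 else 110

empty_feature_row <- function(egg_id, group, mode) {
  list(egg_id = egg_id, group = group, mode = mode, responder = FALSE,
       time_to_first_s = NA_real_, first_duration_s = NA_real_,
       n_osc_60 = NA_integer_, n_osc_120 = NA_integer_,
       freq_per_10min = NA_real_, auc_60 = NA_real_,
       cessation_s = NA_real_, censored = NA)
}

# Per-egg metric panel on core data structures (hot path).
# det is a detect_core() result; bl a baseline_core() result.
feature_core <- function(t, det, bl, config, det_config) {
  if (length(det$onset_s) == 0L) {
    return(empty_feature_row(t$egg_id, t$group, t$mode))
  }
  horizon_min <- config$horizon_min %||% default_horizon(t$mode)
  rec_end <- (length(t$values) - 1L) * t$sampling_interval_s
  on <- det$onset_s
  first <- on[1L]
  last <- on[length(on)]
  n60 <- sum(on < first + 3600 - 1e-9)
  n120 <- sum(on < first + 7200 - 1e-9)
  anchor <- if (config$auc_anchor == "stimulus") t$stimulus_time_s else first
  auc <- auc_core(t$values, t$sampling_interval_s, bl$baseline, anchor,
                  min(anchor + 3600, rec_end), det_config$clip_negative)
  horizon_abs <- min(first + horizon_min * 60, rec_end)
  censored <- last >= horizon_abs - config$censor_window_min * 60 - 1e-9 ||
    det$truncated[length(det$truncated)]
  list(egg_id = t$egg_id, group = t$group, mode = t$mode, responder = TRUE,
       time_to_first_s = first - t$stimulus_time_s,
       first_duration_s = det$duration_s[1L],
       n_osc_60 = as.integer(n60), n_osc_120 = as.integer(n120),
       freq_per_10min = n60 / 6, auc_60 = auc,
       cessation_s = last - first, censored = censored)
}

feature_rows_to_df <- function(rows) {
  cols <- names(rows[[1L]])
  out <- lapply(cols, function(cn) unlist(lapply(rows, `[[`, cn),
                                          use.names = FALSE))
  names(out) <- cols
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  class(out) <- c("egg_features", "data.frame")
  out
}

#' Extract the per-egg metric panel
#'
#' Computes, from a trace and its detected transients, the standard
#' per-egg summary of egg-activation calcium signalling: latency from
#' stimulus to the first transient, duration of the first transient,
#' number of oscillations within 60 and 120 min of the first onset
#' (the first transient counts as oscillation 1), oscillation frequency
#' per 10 min (`n_osc_60 / 6` by construction), area under the curve
#' over 60 min, and cessation/censoring information for persistence
#' analysis. An egg with no detected transients yields a
#' `responder = FALSE` row with all oscillation fields `NA`; an egg
#' whose last onset falls within `censor_window_min` of the horizon, or
#' whose last transient is right-truncated, is flagged `censored`.
#'
#' @param t A [ca_trace()].
#' @param transients Data frame from [detect_transients()] on `t`.
#' @param b The [estimate_baseline()] result used for detection.
#' @param config A [feature_config()].
#' @param det_config The [detection_config()] (for AUC clipping).
#' @return One-row data frame of class `"egg_features"` with columns
#'   `egg_id`, `group`, `mode`, `responder`, `time_to_first_s`,
#'   `first_duration_s`, `n_osc_60`, `n_osc_120`, `freq_per_10min`,
#'   `auc_60`, `cessation_s` (last onset minus first onset, s),
#'   `censored`.
#' @export
extract_features <- function(t, transients, b, config = feature_config(),
                             det_config = detection_config()) {
  if (!inherits(t, "ca_trace")) {
    caosc_stop("'t' must be a trace", "caosc_trace_error")
  }
  det <- if (is.null(transients) || nrow(transients) == 0L) {
    list(onset_s = numeric(0))
  } else {
    as.list(transients)
  }
  feature_rows_to_df(list(feature_core(t, det, b, config, det_config)))
}

#' Detect and extract features for every egg in a traceset
#'
#' Convenience wrapper running [estimate_baseline()],
#' [detect_transients()] and [extract_features()] per egg.
#'
#' @param ts A [traceset()].
#' @param det_config A [detection_config()].
#' @param config A [feature_config()].
#' @return A list with `features` (row-bound `egg_features` data
#'   frame), `transients` (row-bound detection table with an `egg_id`
#'   column) and `baselines` (per-egg baseline, noise SD and the
#'   estimation branch used).
#' @export
extract_features_set <- function(ts, det_config = detection_config(),
                                 config = feature_config()) {
  if (!inherits(ts, "traceset")) {
    caosc_stop("'ts' must be a traceset", "caosc_trace_error")
  }
  n <- length(ts$traces)
  rows <- vector("list", n)
  dets <- vector("list", n)
  bls <- vector("list", n)
  for (i in seq_len(n)) {
    t <- ts$traces[[i]]
    bl <- baseline_core(t$values, t$sampling_interval_s, t$stimulus_time_s)
    det <- detect_core(t$values, t$sampling_interval_s, t$stimulus_time_s,
                       bl$baseline, bl$noise_sd, det_config)
    rows[[i]] <- feature_core(t, det, bl, config, det_config)
    bls[[i]] <- c(list(egg_id = t$egg_id), bl)
    if (length(det$onset_s)) dets[[i]] <- c(list(egg_id = rep(t$egg_id,
                                                length(det$onset_s))), det)
  }
  features <- feature_rows_to_df(rows)
  baselines <- data.frame(
    egg_id = vapply(bls, `[[`, "", "egg_id"),
    baseline = vapply(bls, `[[`, 0, "baseline"),
    noise_sd = vapply(bls, `[[`, 0, "noise_sd"),
    method_tag = vapply(bls, `[[`, "", "method_tag"),
    stringsAsFactors = FALSE)
  dets <- dets[!vapply(dets, is.null, TRUE)]
  transients <- if (length(dets)) {
    cols <- names(dets[[1L]])
    df <- lapply(cols, function(cn) unlist(lapply(dets, `[[`, cn),
                                           use.names = FALSE))
    names(df) <- cols
    as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    data.frame(egg_id = character(), onset_s = numeric(),
               peak_s = numeric(), offset_s = numeric(),
               amplitude = numeric(), duration_s = numeric(),
               truncated = logical())
  }
  list(features = features, transients = transients,
       baselines = baselines)
}

#' Oscillation persistence curve
#'
#' Fraction of responder eggs still oscillating — operationalised as
#' "has a transient onset strictly after the grid time" — at each point
#' of a time grid measured in minutes from the first transient onset.
#' Censored eggs (still oscillating at the analysis horizon) count as
#' oscillating throughout. By definition every responder is oscillating
#' at its own first onset, so the curve starts at 1.
#'
#' @param features An `egg_features` data frame for **one** group.
#' @param grid_step_min Grid spacing in minutes.
#' @param horizon_min Last grid point in minutes.
#' @return An object of class `"persistence_curve"`: data frame with
#'   `time_min` and `fraction`, plus attributes `group` and `n`.
#' @export
persistence_curve <- function(features, grid_step_min = 10,
                              horizon_min = 110) {
  resp <- features[which(features$responder), , drop = FALSE]
  if (nrow(resp) == 0L) {
    caosc_stop("no responder eggs: persistence curve undefined",
               "caosc_feature_error")
  }
  check_number(grid_step_min, "grid_step_min", 0, strict_lower = TRUE)
  grid <- seq(0, horizon_min, by = grid_step_min)
  cess_min <- resp$cessation_s / 60
  frac <- vapply(grid, function(g) {
    if (g == 0) 1 else mean(resp$censored | cess_min > g + 1e-9)
  }, numeric(1))
  structure(data.frame(time_min = grid, fraction = frac),
            class = c("persistence_curve", "data.frame"),
            group = if (length(unique(resp$group)) == 1L)
              resp$group[1L] else "mixed",
            n = nrow(resp))
}

#' @export
plot.persistence_curve <- function(x, add = FALSE, col = "black", ...) {
  if (!add) {
    graphics::plot(NA, xlim = range(x$time_min), ylim = c(0, 1),
                   xlab = "Time from first transient (min)",
                   ylab = "Fraction of eggs oscillating", ...)
  }
  graphics::lines(stats::stepfun(x$time_min[-1L], x$fraction),
                  do.points = FALSE, col = col)
  invisible(x)
}
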