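#' Construct a single-egg calcium trace
#'
#' A `trace` holds one egg's ratiometric (F340/F380) calcium time series
#' together with the metadata needed to interpret it: the sampling
#' interval, the time at which the activating stimulus (strontium or
#' sperm) was applied, and grouping labels. Ratio values are
#' dimensionless; all times are seconds from the start of the recording.
#'
#' @param egg_id Character identifier, unique within a [traceset()].
#' @param values Numeric vector of F340/F380 ratio samples (>= 2 samples,
#'   all finite and strictly positive).
#' @param sampling_interval_s Sampling interval in seconds (> 0). The
#'   study regime this package targets records one ratio image every
#'   7.5 s.
#' @param stimulus_time_s Time of stimulus application, seconds from the
#'   start of the recording; must fall within the recording.
#' @param group Group label (e.g. `"NC"` vs `"SOV"`).
#' @param mode Activation mode, `"strontium"` or `"ivf"`.
#' @param replicate Replicate identifier (free text).
#' @return An object of class `"trace"`.
#' @seealso [traceset()], [read_traceset()], [detect_transients()]
#' @examples
#' tr <- ca_trace("egg1", values = rep(0.8, 10), sampling_interval_s = 7.5)
#' tr
#' @export
ca_trace <- function(egg_id, values, sampling_interval_s = 7.5,
                     stimulus_time_s = 0, group = "A", mode = "strontium",
                     replicate = "r1") {
  if (!is.character(egg_id) || length(egg_id) != 1L || !nzchar(egg_id)) {
    caosc_stop("'egg_id' must be a non-empty string", "caosc_trace_error")
  }
  if (!is.numeric(values) || length(values) < 2L) {
    caosc_stop(sprintf("trace '%s': needs >= 2 ratio samples", egg_id),
               "caosc_trace_error")
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    bad <- which(!is.finite(values) | values <= 0)
    caosc_stop(sprintf(
      "trace '%s': non-finite or non-positive ratio at sample(s) %s",
      egg_id, paste(utils::head(bad, 5L), collapse = ", ")),
      "caosc_trace_error")
  }
  check_number(sampling_interval_s, "sampling_interval_s", 0,
               strict_lower = TRUE)
  check_number(stimulus_time_s, "stimulus_time_s", 0)
  duration <- (length(values) - 1L) * sampling_interval_s
  if (stimulus_time_s >= duration) {
    caosc_stop(sprintf(
      "trace '%s': stimulus_time_s (%g s) not within recording (%g s)",
      egg_id, stimulus_time_s, duration), "caosc_trace_error")
  }
  structure(
    list(egg_id = egg_id, group = as.character(group),
         mode = match.arg(mode, c("strontium", "ivf")),
         replicate = as.character(replicate),
         sampling_interval_s = sampling_interval_s,
         stimulus_time_s = stimulus_time_s,
         values = as.numeric(values)),
    class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf(
    "<trace> egg '%s' (%s, %s): %d samples @ %g s (%.1f min), stimulus at %g s\n",
    x$egg_id, x$group, x$mode, length(x$values), x$sampling_interval_s,
    trace_duration(x) / 60, x$stimulus_time_s))
  invisible(x)
}

trace_times <- function(t) (seq_along(t$values) - 1) * t$sampling_interval_s
trace_duration <- function(t) (length(t$values) - 1) * t$sampling_interval_s

# Unvalidated constructor for internal producers (the simulator) whose
# outputs satisfy the invariants by construction.
new_trace <- function(egg_id, values, sampling_interval_s,
                      stimulus_time_s, group, mode, replicate) {
  structure(list(egg_id = egg_id, group = group, mode = mode,
                 replicate = replicate,
                 sampling_interval_s = sampling_interval_s,
                 stimulus_time_s = stimulus_time_s, values = values),
            class = "ca_trace")
}

new_traceset <- function(traces, mode, provenance) {
  names(traces) <- vapply(traces, `[[`, "", "egg_id")
  structure(list(traces = traces, mode = mode, provenance = provenance),
            class = "traceset")
}

#' Bundle traces recorded in one experiment
#'
#' A `traceset` is a collection of [ca_trace()] objects sharing the same
#' activation mode, typically one imaging dish in which both groups of
#' eggs were recorded side by side.
#'
#' @param traces List of [ca_trace()] objects with unique `egg_id`s and a
#'   shared `mode`.
#' @param provenance Free text describing where the data came from
#'   (e.g. `"simulated"` or `"loaded"`).
#' @return An object of class `"traceset"`.
#' @export
traceset <- function(traces, provenance = "loaded") {
  if (!is.list(traces) || !all(vapply(traces, inherits, TRUE, "ca_trace"))) {
    caosc_stop("'traces' must be a list of trace objects",
               "caosc_trace_error")
  }
  ids <- vapply(traces, `[[`, "", "egg_id")
  if (anyDuplicated(ids)) {
    caosc_stop(sprintf("duplicate egg_id in traceset: %s",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")),
               "caosc_trace_error")
  }
  modes <- unique(vapply(traces, `[[`, "", "mode"))
  if (length(traces) && length(modes) != 1L) {
    caosc_stop("all traces in a traceset must share the same mode",
               "caosc_trace_error")
  }
  names(traces) <- ids
  structure(list(traces = traces,
                 mode = if (length(traces)) modes else "strontium",
                 provenance = provenance),
            class = "traceset")
}

#' @export
print.traceset <- function(x, ...) {
  groups <- table(vapply(x$traces, `[[`, "", "group"))
  cat(sprintf("<traceset> %d eggs (%s, %s): %s\n",
              length(x$traces), x$mode, x$provenance,
              paste(sprintf("%s n=%d", names(groups), as.integer(groups)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
length.traceset <- function(x) length(x$traces)

#' @export
`[[.traceset` <- function(x, i) x$traces[[i]]

metadata_path <- function(path) paste0(path, ".meta.yaml")

#' Read a trace dataset from delimited text
#'
#' Reads a set of per-egg calcium traces from a tab-separated file in
#' either of two dialects: *long* (columns `egg_id`, `time_s`, `ratio`)
#' or *wide* (column `time_s` plus one ratio column per egg). Per-egg
#' metadata (group, mode, replicate, stimulus time) is read from a YAML
#' sidecar at `<path>.meta.yaml` when present; a long file may instead
#' carry the metadata as extra columns (`group`, `mode`, `replicate`,
#' `stimulus_time_s`). The sampling interval is inferred from the time
#' column and verified to be uniform to a relative tolerance of 1e-6.
#'
#' @param path Path to the data file.
#' @param format `"long"` or `"wide"`.
#' @return A [traceset()].
#' @seealso [write_traceset()]
#' @export
read_traceset <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    caosc_stop(sprintf("file not found: %s", path), "caosc_io_error")
  }
  df <- read_tsv_plain(path)
  meta <- NULL
  if (file.exists(metadata_path(path))) {
    meta <- yaml::read_yaml(metadata_path(path))
  }
  if (format == "long") {
    need <- c("egg_id", "time_s", "ratio")
    if (!all(need %in% names(df))) {
      caosc_stop(sprintf("long format requires columns %s",
                         paste(need, collapse = ", ")), "caosc_io_error")
    }
    blocks <- rle(as.character(df$egg_id))$values
    if (anyDuplicated(blocks)) {
      caosc_stop(sprintf("duplicate egg_id in long file: %s",
                         paste(unique(blocks[duplicated(blocks)]),
                               collapse = ", ")), "caosc_io_error")
    }
    split_rows <- split(seq_len(nrow(df)), df$egg_id)
    # preserve file order of eggs
    split_rows <- split_rows[unique(df$egg_id)]
    traces <- lapply(names(split_rows), function(id) {
      rows <- split_rows[[id]]
      tm <- as.numeric(df$time_s[rows])
      dt <- infer_interval(tm, id)
      m <- egg_meta(meta, id, df[rows[1L], , drop = FALSE])
      ca_trace(id, as.numeric(df$ratio[rows]), sampling_interval_s = dt,
            stimulus_time_s = m$stimulus_time_s, group = m$group,
            mode = m$mode, replicate = m$replicate)
    })
  } else {
    if (!"time_s" %in% names(df)) {
      caosc_stop("wide format requires a 'time_s' column", "caosc_io_error")
    }
    ids <- setdiff(names(df), "time_s")
    if (anyDuplicated(ids)) {
      caosc_stop("duplicate egg_id column in wide file", "caosc_io_error")
    }
    tm <- as.numeric(df$time_s)
    traces <- lapply(ids, function(id) {
      dt <- infer_interval(tm, id)
      m <- egg_meta(meta, id, NULL)
      ca_trace(id, as.numeric(df[[id]]), sampling_interval_s = dt,
            stimulus_time_s = m$stimulus_time_s, group = m$group,
            mode = m$mode, replicate = m$replicate)
    })
  }
  prov <- if (!is.null(meta$provenance)) meta$provenance else "loaded"
  traceset(traces, provenance = prov)
}

infer_interval <- function(tm, id) {
  if (length(tm) < 2L) {
    caosc_stop(sprintf("egg '%s': needs >= 2 time points", id),
               "caosc_io_error")
  }
  d <- diff(tm)
  dt <- d[1L]
  if (dt <= 0 || any(abs(d - dt) > 1e-6 * max(abs(dt), 1))) {
    bad <- which(abs(d - dt) > 1e-6 * max(abs(dt), 1)) + 1L
    caosc_stop(sprintf(
      "egg '%s': non-uniform sampling at time row(s) %s",
      id, paste(utils::head(bad, 5L), collapse = ", ")),
      "caosc_sampling_error")
  }
  dt
}

egg_meta <- function(meta, id, row) {
  out <- list(group = "A", mode = "strontium", replicate = "r1",
              stimulus_time_s = 0)
  if (!is.null(meta)) {
    if (!is.null(meta$mode)) out$mode <- meta$mode
    em <- meta$eggs[[id]]
    for (f in c("group", "mode", "replicate", "stimulus_time_s")) {
      if (!is.null(em[[f]])) out[[f]] <- em[[f]]
    }
  } else if (!is.null(row)) {
    for (f in c("group", "mode", "replicate", "stimulus_time_s")) {
      if (f %in% names(row)) out[[f]] <- row[[f]]
    }
  }
  out$stimulus_time_s <- as.numeric(out$stimulus_time_s)
  out
}

#' Write a trace dataset to delimited text
#'
#' Writes a [traceset()] in the long or wide dialect understood by
#' [read_traceset()], plus a YAML metadata sidecar at
#' `<path>.meta.yaml`. Ratio values are written at full double precision
#' so a read/write round trip is bit-exact.
#'
#' @param ts A [traceset()].
#' @inheritParams read_traceset
#' @return `path`, invisibly.
#' @export
write_traceset <- function(ts, path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (!inherits(ts, "traceset")) {
    caosc_stop("'ts' must be a traceset", "caosc_trace_error")
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    caosc_stop(sprintf("directory does not exist: %s", dir),
               "caosc_io_error")
  }
  if (format == "long") {
    if (length(ts$traces)) {
      parts <- lapply(ts$traces, function(t) {
        data.frame(egg_id = t$egg_id, time_s = trace_times(t),
                   ratio = t$values, stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
    } else {
      df <- data.frame(egg_id = character(), time_s = numeric(),
                       ratio = numeric())
    }
  } else {
    if (length(ts$traces)) {
      ns <- vapply(ts$traces, function(t) length(t$values), 1L)
      dts <- vapply(ts$traces, `[[`, 1, "sampling_interval_s")
      if (length(unique(ns)) != 1L || length(unique(dts)) != 1L) {
        caosc_stop("wide format requires equal-length, equal-interval traces",
                   "caosc_io_error")
      }
      df <- data.frame(time_s = trace_times(ts$traces[[1L]]))
      for (t in ts$traces) df[[t$egg_id]] <- t$values
    } else {
      df <- data.frame(time_s = numeric())
    }
  }
  write_tsv_det(df, path)
  eggs <- lapply(ts$traces, function(t) {
    list(group = t$group, mode = t$mode, replicate = t$replicate,
         stimulus_time_s = t$stimulus_time_s)
  })
  yaml::write_yaml(list(mode = ts$mode, provenance = ts$provenance,
                        eggs = eggs),
                   metadata_path(path))
  invisible(path)
}

#' Coerce a traceset to a long data frame
#'
#' @param x A [traceset()].
#' @param row.names,optional,... Ignored; present for method compatibility.
#' @return A data frame with columns `egg_id`, `group`, `time_s`, `ratio`.
#' @export
as.data.frame.traceset <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  parts <- lapply(x$traces, function(t) {
    data.frame(egg_id = t$egg_id, group = t$group,
               time_s = trace_times(t), ratio = t$values,
               stringsAsFactors = FALSE)
  })
  if (!length(parts)) {
    return(data.frame(egg_id = character(), group = character(),
                      time_s = numeric(), ratio = numeric()))
  }
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

#' Plot a calcium trace
#'
#' Plots the ratio time series; if a table of detected transients is
#' supplied, their extents are shaded and onsets marked.
#'
#' @param x A [ca_trace()].
#' @param transients Optional data frame from [detect_transients()].
#' @param baseline Optional [estimate_baseline()] result; drawn as a
#'   dashed line.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ca_trace <- function(x, transients = NULL, baseline = NULL, ...) {
  tm <- trace_times(x) / 60
  graphics::plot(tm, x$values, type = "l", xlab = "Time (min)",
                 ylab = "F340/F380 ratio", main = x$egg_id, ...)
  if (!is.null(transients) && nrow(transients)) {
    usr <- graphics::par("usr")
    graphics::rect(transients$onset_s / 60, usr[3], transients$offset_s / 60,
                   usr[4], col = grDevices::adjustcolor("steelblue", 0.15),
                   border = NA)
    graphics::points(transients$peak_s / 60,
                     transients$amplitude +
                       (baseline$baseline %||% min(x$values)),
                     pch = 20, col = "firebrick")
  }
  if (!is.null(baseline)) {
    graphics::abline(h = baseline$baseline, lty = 2, col = "grey40")
  }
  invisible(x)
}
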