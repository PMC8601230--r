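# Exact null distribution of the rank sum of a size-m subset of ranks
# 1..N (tie-free): dynamic programme over elements. Returns counts
# indexed by rank sum 0..m*N (only m(m+1)/2 .. upper range populated).
rank_sum_counts <- function(N, m) {
  max_s <- m * N
  g <- matrix(0, nrow = m + 1L, ncol = max_s + 1L)
  g[1L, 1L] <- 1
  for (r in seq_len(N)) {
    for (k in rev(seq_len(min(r, m)))) {
      idx <- (r + 1L):(max_s + 1L)
      g[k + 1L, idx] <- g[k + 1L, idx] + g[k, idx - r]
    }
  }
  g[m + 1L, ]
}

# Exact two-sided p for the Mann-Whitney statistic with tie-free data:
# probability, over all equally likely group assignments, that
# min(U, n1*n2 - U) is at most the observed value.
mw_exact_p <- function(u_min, n1, n2) {
  counts <- rank_sum_counts(n1 + n2, n1)
  s <- seq_along(counts) - 1L            # rank sums
  u <- s - n1 * (n1 + 1L) / 2            # U for group 1
  extreme <- u <= u_min + 1e-9 | u >= n1 * n2 - u_min - 1e-9
  sum(counts[extreme]) / choose(n1 + n2, n1)
}

#' Mann-Whitney U test for two independent samples
#'
#' Rank-based two-sample test. The reported statistic is
#' `min(U_x, U_y)`, where `U_x` counts pairs with the x-value larger
#' (ties counting one half). With `method = "auto"`, the exact
#' two-sided p-value — the permutation probability of a U at least as
#' extreme, enumerated over all group assignments — is used when the
#' combined sample size is at most 20 and the data are tie-free;
#' otherwise the tie-corrected normal approximation with continuity
#' correction is used. The exact branch refuses tied data (falls back
#' to the approximation).
#'
#' @param x,y Numeric samples (non-empty).
#' @param method `"auto"`, `"exact"` or `"asymptotic"`.
#' @return A list of class `"mw_test"`: `U`, `p_value`, `method`
#'   (branch actually used), `n_x`, `n_y`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact",
                                            "asymptotic")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (!length(x) || !length(y) || anyNA(x) || anyNA(y)) {
    caosc_stop("both samples must be non-empty and free of NA",
               "caosc_stats_error")
  }
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  ux <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2  # pairs with x > y (+ ties/2)
  uy <- n1 * n2 - ux
  u <- min(ux, uy)
  ties <- anyDuplicated(pooled) > 0L

  if (length(unique(pooled)) == 1L) {
    out <- list(U = n1 * n2 / 2, p_value = 1, method = "degenerate",
                n_x = n1, n_y = n2)
    class(out) <- "mw_test"
    return(out)
  }
  use_exact <- switch(method,
    exact = TRUE,
    asymptotic = FALSE,
    auto = (n1 + n2 <= 20L) && !ties)
  if (use_exact && ties) use_exact <- FALSE  # exact branch refuses ties
  if (use_exact) {
    p <- mw_exact_p(u, n1, n2)
    used <- "mw_exact"
  } else {
    tie_tab <- table(pooled)
    N <- n1 + n2
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(ux - mu) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    used <- "mw_asymptotic"
  }
  out <- list(U = u, p_value = p, method = used, n_x = n1, n_y = n2)
  class(out) <- "mw_test"
  out
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s): U = %g, n = %d/%d, p = %.4g\n",
              x$method, x$U, x$n_x, x$n_y, x$p_value))
  invisible(x)
}

#' Mantel-Cox log-rank test for two groups
#'
#' At each distinct event time, the observed number of events in group
#' A is compared with its hypergeometric expectation given the margins
#' (numbers at risk and total events); the statistic
#' `(sum O - sum E)^2 / sum V` is referred to the chi-square
#' distribution with 1 df. Censored observations contribute at-risk
#' time only.
#'
#' @param time Event/censoring times (>= 0).
#' @param event 1 (or `TRUE`) if the event (cessation of oscillations)
#'   was observed, 0 if censored.
#' @param group Two-level grouping vector.
#' @return A list of class `"logrank_test"`: `chi_square`, `p_value`,
#'   `observed`, `expected` (both per group), `n`.
#' @export
logrank_test <- function(time, event, group) {
  time <- as.numeric(time)
  event <- as.integer(as.logical(event))
  group <- as.character(group)
  if (length(time) != length(event) || length(time) != length(group)) {
    caosc_stop("'time', 'event' and 'group' must have equal length",
               "caosc_stats_error")
  }
  if (anyNA(time) || anyNA(event) || any(time < 0)) {
    caosc_stop("times must be non-negative and free of NA",
               "caosc_stats_error")
  }
  lev <- unique(group)
  if (length(lev) != 2L) {
    caosc_stop("exactly two groups are required", "caosc_stats_error")
  }
  if (sum(event) == 0L) {
    caosc_stop("no events observed: log-rank test undefined",
               "caosc_stats_error")
  }
  g1 <- group == lev[1L]
  ev_times <- sort(unique(time[event == 1L]))
  O1 <- E1 <- V <- 0
  o_tot <- c(0, 0)
  for (tt in ev_times) {
    at_risk <- time >= tt - 1e-12
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & g1)
    d_t <- sum(event == 1L & abs(time - tt) < 1e-12)
    d1_t <- sum(event == 1L & abs(time - tt) < 1e-12 & g1)
    O1 <- O1 + d1_t
    E1 <- E1 + d_t * n1_t / n_t
    if (n_t > 1L) {
      V <- V + d_t * (n1_t / n_t) * (1 - n1_t / n_t) *
        (n_t - d_t) / (n_t - 1)
    }
    o_tot <- o_tot + c(d1_t, d_t - d1_t)
  }
  chi <- if (V > 0) (O1 - E1)^2 / V else 0
  p <- if (V > 0) stats::pchisq(chi, df = 1, lower.tail = FALSE) else 1
  out <- list(chi_square = chi, p_value = p,
              observed = stats::setNames(o_tot, lev),
              expected = stats::setNames(c(E1, sum(o_tot) - E1), lev),
              n = stats::setNames(c(sum(g1), sum(!g1)), lev))
  class(out) <- "logrank_test"
  out
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank (Mantel-Cox) test: chi-square = %.4g (1 df), p = %.4g\n",
              x$chi_square, x$p_value))
  invisible(x)
}

mw_metrics <- c("time_to_first_s", "first_duration_s", "freq_per_10min",
                "auc_60", "n_osc_120")

#' Compare the full metric panel between two groups
#'
#' Runs the five scalar Mann-Whitney comparisons (time to first
#' transient, first-transient duration, oscillation frequency, 60-min
#' AUC, oscillation count over 120 min) plus the log-rank persistence
#' comparison, on the responder eggs of each group. A metric with fewer
#' than 3 responders in either group is flagged untestable rather than
#' dropped.
#'
#' @param features_a,features_b `egg_features` data frames (from
#'   [extract_features_set()]) for the two groups.
#' @param alpha Significance level used for the `significant` flag.
#' @param method Mann-Whitney branch selection, see [mann_whitney_u()].
#' @param holm If `TRUE`, apply a Holm correction across the six
#'   comparisons before flagging significance (off by default: the
#'   panels are conventionally reported per-metric).
#' @return A data frame of class `"group_comparison"`, one row per
#'   comparison: `metric`, `n_a`, `n_b`, `median_a`, `median_b`,
#'   `statistic`, `test`, `p_value`, `significant`, `testable`; the
#'   configuration hash of the call is attached as attribute
#'   `config_hash`, responder tallies as `n_responders`.
#' @export
compare_groups <- function(features_a, features_b, alpha = 0.05,
                           method = "auto", holm = FALSE) {
  fa <- features_a[which(features_a$responder), , drop = FALSE]
  fb <- features_b[which(features_b$responder), , drop = FALSE]
  rows <- vector("list", length(mw_metrics) + 1L)
  for (i in seq_along(mw_metrics)) {
    m <- mw_metrics[i]
    xa <- fa[[m]][!is.na(fa[[m]])]
    xb <- fb[[m]][!is.na(fb[[m]])]
    testable <- length(xa) >= 3L && length(xb) >= 3L
    if (testable) {
      tst <- mann_whitney_u(xa, xb, method = method)
      rows[[i]] <- data.frame(
        metric = m, n_a = length(xa), n_b = length(xb),
        median_a = stats::median(xa), median_b = stats::median(xb),
        statistic = tst$U, test = tst$method, p_value = tst$p_value,
        testable = TRUE, stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        metric = m, n_a = length(xa), n_b = length(xb),
        median_a = NA_real_, median_b = NA_real_, statistic = NA_real_,
        test = "untestable", p_value = NA_real_, testable = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  surv <- rbind(
    data.frame(time = fa$cessation_s / 60, event = !fa$censored,
               group = "A", stringsAsFactors = FALSE),
    data.frame(time = fb$cessation_s / 60, event = !fb$censored,
               group = "B", stringsAsFactors = FALSE))
  surv <- surv[!is.na(surv$time), , drop = FALSE]
  lr_ok <- nrow(fa) >= 3L && nrow(fb) >= 3L && sum(surv$event) > 0L
  if (lr_ok) {
    lr <- logrank_test(surv$time, surv$event, surv$group)
    rows[[length(rows)]] <- data.frame(
      metric = "persistence", n_a = nrow(fa), n_b = nrow(fb),
      median_a = stats::median(fa$cessation_s / 60),
      median_b = stats::median(fb$cessation_s / 60),
      statistic = lr$chi_square, test = "logrank",
      p_value = lr$p_value, testable = TRUE, stringsAsFactors = FALSE)
  } else {
    rows[[length(rows)]] <- data.frame(
      metric = "persistence", n_a = nrow(fa), n_b = nrow(fb),
      median_a = NA_real_, median_b = NA_real_, statistic = NA_real_,
      test = "untestable", p_value = NA_real_, testable = FALSE,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  p_adj <- if (holm) stats::p.adjust(out$p_value, "holm") else out$p_value
  out$significant <- !is.na(p_adj) & p_adj < alpha
  class(out) <- c("group_comparison", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "config_hash") <- config_hash(list(alpha = alpha,
                                               method = method,
                                               holm = holm))
  attr(out, "n_responders") <- c(a = nrow(fa), b = nrow(fb))
  attr(out, "n_total") <- c(a = nrow(features_a), b = nrow(features_b))
  out
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("Two-group comparison (alpha = %g)\n",
              attr(x, "alpha") %||% 0.05))
  df <- as.data.frame(x)
  df$median_a <- signif(df$median_a, digits)
  df$median_b <- signif(df$median_b, digits)
  df$statistic <- signif(df$statistic, digits)
  df$p_value <- signif(df$p_value, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
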