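# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed error
#'
#' All user-facing errors in the package carry condition class
#' `"caosc_error"` plus a more specific subclass, so callers can
#' distinguish e.g. malformed input from invalid configuration.
#' @noRd
caosc_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "caosc_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is_number(x)) {
    caosc_stop(sprintf("'%s' must be a single finite number", name),
               "caosc_config_error")
  }
  ok <- if (strict_lower) x > lower else x >= lower
  if (!ok || x > upper) {
    cmp <- if (strict_lower) ">" else ">="
    caosc_stop(sprintf("'%s' must be %s %g and <= %g (got %g)",
                       name, cmp, lower, upper, x),
               "caosc_config_error")
  }
  invisible(x)
}

# Snap a time to the sampling grid (nearest sample time).
snap_to_grid <- function(t, dt) round(t / dt) * dt

# Lower-truncated Gaussian draw by inverse-CDF, so the number of uniforms
# consumed per draw is fixed (keeps seeded streams stable).
rtnorm <- function(n, mean, sd, lower) {
  if (sd <= 0) return(pmax(rep_len(mean, n), lower))
  lo <- stats::pnorm(lower, mean, sd)
  lo <- pmin(lo, 1 - 1e-12)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

# Scalar variant on the standardized scale (hot path).
rtnorm1 <- function(mean, sd, lower) {
  if (sd <= 0) return(max(mean, lower))
  lo <- stats::pnorm((lower - mean) / sd)
  if (lo > 1 - 1e-12) lo <- 1 - 1e-12
  mean + sd * stats::qnorm(stats::runif(1, lo, 1))
}

# Unit-mean lognormal multiplier with coefficient of variation cv.
rlnorm_scale <- function(n, cv) {
  if (cv <= 0) return(rep_len(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Derive n child seeds from a parent seed by drawing them through the
# generator itself. Linearly related set.seed() values (parent + k, or
# an LCG over keys) produce Mersenne-Twister streams with enough joint
# structure to distort rank-statistic levels in large replication
# studies; RNG-drawn seeds carry no such structure. The vector is
# prefix-stable: its first k entries do not depend on n, so growing a
# design never perturbs existing substreams. Overwrites the global RNG
# state.
derived_seeds <- function(seed, n) {
  set.seed(seed)
  as.integer(floor(stats::runif(n) * 2147483645)) + 1L
}

# Deterministic text formatting for file output (full double precision,
# locale-independent) so identical runs give byte-identical files.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

# Stable short hash of an R object (djb2 over its deparsed form); used to
# stamp outputs with the configuration that produced them.
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_tsv_det <- function(df, path) {
  is_num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  out <- df
  for (j in which(is_num)) out[[j]] <- fmt_num(df[[j]])
  lines <- c(
    paste(names(out), collapse = "\t"),
    if (nrow(out)) do.call(paste, c(unname(out), sep = "\t"))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
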