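#' Quarterly (or yearly) scalar time series
#'
#' A light container for the derived survey series: a data frame with
#' columns `step` (integer time index), `year`, `quarter` (`"Q1"`/`"Q3"`, or
#' `NA` on the yearly grid) and `value`, plus provenance attributes recording
#' the series name, the time grid, and whether it has been detrended and
#' z-score normalized.  Biquarterly series index time by a 0-based step over
#' the interleaved Q1/Q3 sequence; yearly series use the calendar year.
#'
#' @param step integer time index (0-based biquarterly step, or year).
#' @param value numeric values, one per step.
#' @param year,quarter optional calendar columns.
#' @param name series name.
#' @param grid `"biquarterly"` or `"yearly"`.
#' @param mu,sigma optional per-step spatial moments (kept by [spatial_cv()]).
#' @return a `quarter_series` data frame.
#' @export
quarter_series <- function(step, value, year = NULL, quarter = NULL,
                           name = "series", grid = c("biquarterly", "yearly"),
                           mu = NULL, sigma = NULL) {
  grid <- match.arg(grid)
  stopifnot(length(step) == length(value))
  o <- order(step)
  df <- data.frame(step = as.integer(step)[o], value = as.numeric(value)[o])
  if (!is.null(year)) df$year <- as.integer(year)[o]
  if (!is.null(quarter)) df$quarter <- as.character(quarter)[o]
  if (!is.null(mu)) df$mu <- as.numeric(mu)[o]
  if (!is.null(sigma)) df$sigma <- as.numeric(sigma)[o]
  if (anyDuplicated(df$step)) stop("duplicate time steps", call. = FALSE)
  structure(df,
            class = c("quarter_series", "data.frame"),
            name = name, grid = grid,
            normalized = FALSE, detrended = FALSE,
            detrend_slope = NA_real_, detrend_pvalue = NA_real_)
}

#' @export
print.quarter_series <- function(x, ...) {
  cat(sprintf("<quarter_series '%s'> %d steps on the %s grid%s%s\n",
              attr(x, "name"), nrow(x), attr(x, "grid"),
              if (isTRUE(attr(x, "detrended"))) ", detrended" else "",
              if (isTRUE(attr(x, "normalized"))) ", normalized" else ""))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

# Numeric values of a series (accepts plain numeric vectors too).
series_values <- function(x) {
  if (inherits(x, "quarter_series")) x$value else as.numeric(x)
}

series_name <- function(x, default = "series") {
  if (inherits(x, "quarter_series")) attr(x, "name") else default
}

#' Detrend (if significant) and z-score normalize a series
#'
#' Fits an ordinary least-squares trend of the values on the time step.  If
#' the two-sided p-value of the slope is below `alpha_trend` the residuals
#' replace the values and the series is flagged as detrended.  The series is
#' then normalized to mean 0 and sample standard deviation 1 (denominator
#' n - 1).  Both steps are applied before any state-space analysis.
#'
#' @param series a [quarter_series()] or numeric vector.
#' @param alpha_trend two-sided significance level of the trend test.
#' @return the preprocessed `quarter_series`, with attributes `detrended`,
#'   `detrend_slope`, `detrend_pvalue` and `normalized` set.
#' @export
#' @examples
#' s <- quarter_series(0:49, rnorm(50) + 0.2 * (0:49))
#' p <- preprocess_series(s)
#' attr(p, "detrended")
preprocess_series <- function(series, alpha_trend = 0.05) {
  if (!inherits(series, "quarter_series"))
    series <- quarter_series(seq_along(series) - 1L, series)
  if (nrow(series) < 5) stop("series too short to preprocess (need >= 5 points)",
                             call. = FALSE)
  v <- series$value
  if (any(!is.finite(v))) stop("non-finite values in series", call. = FALSE)
  tt <- series$step
  fit <- lm(v ~ tt)
  sl <- suppressWarnings(summary(fit))$coefficients  # exact fits are legal input
  slope <- sl[2, 1]
  pval <- sl[2, 4]
  if (sd(as.numeric(residuals(fit))) < 1e-12 * max(sd(v), 1e-300))
    stop("degenerate series: zero variance after detrending", call. = FALSE)
  detrended <- is.finite(pval) && pval < alpha_trend
  if (detrended) v <- as.numeric(residuals(fit))
  s <- sd(v)
  if (!is.finite(s) || s == 0)
    stop("degenerate series: zero variance after detrending", call. = FALSE)
  v <- (v - mean(v)) / s
  out <- series
  out$value <- v
  attr(out, "detrended") <- detrended
  attr(out, "detrend_slope") <- slope
  attr(out, "detrend_pvalue") <- pval
  attr(out, "normalized") <- TRUE
  out
}

#' Average a biquarterly series to the yearly grid
#'
#' Takes the mean of the available Q1/Q3 values within each calendar year;
#' years without data are dropped.  Used for all analyses involving the
#' yearly fishing-mortality series.
#'
#' @param series a biquarterly [quarter_series()] carrying a `year` column.
#' @return a yearly `quarter_series` whose `step` is the calendar year.
#' @export
to_yearly <- function(series) {
  stopifnot(inherits(series, "quarter_series"))
  if (identical(attr(series, "grid"), "yearly")) return(series)
  if (is.null(series$year)) stop("series has no year column", call. = FALSE)
  m <- tapply(series$value, series$year, mean)
  yrs <- as.integer(names(m))
  quarter_series(step = yrs, value = as.numeric(m), year = yrs,
                 name = attr(series, "name"), grid = "yearly")
}

# Restrict a set of series to their common time steps, in step order.
align_series <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  grids <- vapply(series_list, function(s) attr(s, "grid"), "")
  if (length(unique(grids)) != 1)
    stop("alignment error: series are on different time grids", call. = FALSE)
  steps <- Reduce(intersect, lapply(series_list, function(s) s$step))
  if (length(steps) == 0)
    stop("alignment error: no common time steps", call. = FALSE)
  steps <- sort(steps)
  lapply(series_list, function(s) {
    out <- s[match(steps, s$step), , drop = FALSE]
    rownames(out) <- NULL
    a <- attributes(s)
    for (nm in setdiff(names(a), c("row.names", "names")))
      attr(out, nm) <- a[[nm]]
    out
  })
}
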