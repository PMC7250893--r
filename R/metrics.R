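#' Spatial coefficient of variation of total CPUE
#'
#' For each quarter, CPUE is summed over classes within each subarea and the
#' coefficient of variation (sample SD / mean, denominator n - 1) of those
#' subarea totals is taken over subareas.  This is the population
#' spatial-variability index: low values indicate a broad, homogeneous
#' distribution.  Quarters with zero mean CPUE are undefined and excluded
#' (recorded in the series log attribute).
#'
#' @param tab a filtered [survey_table()].
#' @return a [quarter_series()] named `"spatial_cv"` with per-step spatial
#'   mean (`mu`) and SD (`sigma`) columns.
#' @export
#' @examples
#' tab <- survey_table(data.frame(year = 2000, quarter = 1,
#'   subarea = c("a", "b"), class_id = 0, cpue = c(1, 3)))
#' spatial_cv(tab)$value  # sd(c(1,3)) / 2
spatial_cv <- function(tab) {
  stopifnot(inherits(tab, "survey_table"))
  by_sub <- step_subarea_totals(tab)
  mu <- tapply(by_sub$cpue, by_sub$quarter_step, mean)
  sig <- tapply(by_sub$cpue, by_sub$quarter_step, sd)
  steps <- as.integer(names(mu))
  keep <- mu > 0
  log <- if (any(!keep))
    sprintf("spatial_cv: quarter_step %d undefined (zero mean CPUE), excluded",
            steps[!keep]) else character()
  cal <- step_calendar(tab, steps[keep])
  out <- quarter_series(step = steps[keep], value = (sig / mu)[keep],
                        year = cal$year, quarter = cal$quarter,
                        name = "spatial_cv",
                        mu = mu[keep], sigma = sig[keep])
  attr(out, "log") <- log
  out
}

#' Shannon age diversity
#'
#' For each quarter, CPUE is summed over subareas within each age class, the
#' age-class proportions are formed, and their Shannon entropy
#' (natural log) is returned; zero-proportion classes contribute zero.
#' Quarters with zero total CPUE are undefined and excluded.
#'
#' @param tab an age-classed [survey_table()].
#' @return a [quarter_series()] named `"age_diversity"`.
#' @export
age_diversity <- function(tab) {
  stopifnot(inherits(tab, "survey_table"))
  if (!identical(attr(tab, "class_kind"), "age"))
    stop("age_diversity needs an age-classed table", call. = FALSE)
  agg <- aggregate(cpue ~ quarter_step + class_id, data = tab, FUN = sum)
  sh <- tapply(agg$cpue, agg$quarter_step, function(x) {
    tot <- sum(x)
    if (tot <= 0) return(NA_real_)
    p <- x[x > 0] / tot
    -sum(p * log(p))
  })
  steps <- as.integer(names(sh))
  keep <- !is.na(sh)
  log <- if (any(!keep))
    sprintf("age_diversity: quarter_step %d undefined (all-zero CPUE), excluded",
            steps[!keep]) else character()
  cal <- step_calendar(tab, steps[keep])
  out <- quarter_series(step = steps[keep], value = sh[keep],
                        year = cal$year, quarter = cal$quarter,
                        name = "age_diversity")
  attr(out, "log") <- log
  out
}

#' Total abundance index
#'
#' Sums CPUE over all classes and subareas for each quarter.
#'
#' @param tab a filtered [survey_table()].
#' @return a [quarter_series()] named `"abundance"`.
#' @export
total_abundance <- function(tab) {
  stopifnot(inherits(tab, "survey_table"))
  tot <- tapply(tab$cpue, tab$quarter_step, sum)
  steps <- as.integer(names(tot))
  cal <- step_calendar(tab, steps)
  quarter_series(step = steps, value = as.numeric(tot),
                 year = cal$year, quarter = cal$quarter,
                 name = "abundance")
}

# Per (quarter_step, subarea) totals over classes.
step_subarea_totals <- function(tab) {
  aggregate(cpue ~ quarter_step + subarea, data = tab, FUN = sum)
}

step_calendar <- function(tab, steps) {
  idx <- match(steps, tab$quarter_step)
  list(year = tab$year[idx], quarter = tab$quarter[idx])
}

#' Fit Taylor's power law
#'
#' Regresses the log spatial variance of CPUE on the log spatial mean over
#' quarters: log V = log a + b log M, where M and V are the mean and sample
#' variance of per-subarea total CPUE within a quarter.  The exponent b
#' measures aggregation tendency; b = 2 is the neutral point at which
#' spatial CV is independent of abundance (CV = a' M^(b/2 - 1)).
#' Quarters with M = 0, V = 0, or fewer than 3 subareas are excluded.
#'
#' @param tab a filtered [survey_table()].
#' @return a `taylor_fit` list with elements `a`, `b`, `r_squared`,
#'   `n_points`, and the `points` data frame (`log_M`, `log_V` per quarter).
#' @export
fit_taylor <- function(tab) {
  stopifnot(inherits(tab, "survey_table"))
  by_sub <- step_subarea_totals(tab)
  M <- tapply(by_sub$cpue, by_sub$quarter_step, mean)
  V <- tapply(by_sub$cpue, by_sub$quarter_step, var)
  nsub <- tapply(by_sub$cpue, by_sub$quarter_step, length)
  keep <- is.finite(M) & is.finite(V) & M > 0 & V > 0 & nsub >= 3
  if (sum(keep) < 3)
    stop("insufficient-data error: fewer than 3 usable quarters for Taylor fit",
         call. = FALSE)
  pts <- data.frame(quarter_step = as.integer(names(M))[keep],
                    log_M = log(M[keep]), log_V = log(V[keep]))
  fit <- lm(log_V ~ log_M, data = pts)
  structure(list(a = exp(unname(coef(fit)[1])),
                 b = unname(coef(fit)[2]),
                 r_squared = suppressWarnings(summary(fit))$r.squared,
                 n_points = nrow(pts),
                 points = pts),
            class = "taylor_fit")
}

#' @export
print.taylor_fit <- function(x, ...) {
  cat(sprintf("Taylor power law: V = %.4g * M^%.4g  (r^2 = %.3f, n = %d)\n",
              x$a, x$b, x$r_squared, x$n_points))
  invisible(x)
}

#' Direction of the CV-abundance relationship implied by Taylor's exponent
#'
#' From V = a M^b it follows that CV = a' M^(b/2 - 1): spatial variability
#' decreases with abundance when b < 2, increases when b > 2, and is
#' independent of abundance at b = 2.
#'
#' @param fit a `taylor_fit` or a numeric exponent b.
#' @param tol tie tolerance around b = 2.
#' @return `"negative"`, `"positive"`, or `"neutral"`.
#' @export
#' @examples
#' cv_abundance_direction(1.5)
#' cv_abundance_direction(2.5)
cv_abundance_direction <- function(fit, tol = 1e-6) {
  b <- if (inherits(fit, "taylor_fit")) fit$b else as.numeric(fit)
  stopifnot(is.finite(b))
  if (abs(b - 2) < tol) "neutral" else if (b < 2) "negative" else "positive"
}
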