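#' Delay embedding of a time series
#'
#' Builds the matrix of lagged coordinates `<x(t), x(t - tau), ...,
#' x(t - (E - 1) tau)>` together with the aligned next-step target `x(t + 1)`.
#' Rows containing any missing coordinate are excluded; the target of the
#' last row is `NA` (no next step exists).  For a complete length-n series
#' with `tau = 1` there are exactly `n - E + 1` state rows.
#'
#' @param x numeric vector or [quarter_series()].
#' @param E embedding dimension (number of lagged coordinates).
#' @param tau lag step size.
#' @return a `state_matrix`: list with `states` (rows = embedding vectors),
#'   `target` (next-step value per row, `NA` where undefined), `time`
#'   (position of each row in the input series), `E`, `tau`, `var_names`.
#' @export
#' @examples
#' lag_embed(c(1, 2, 3, 4), E = 2)$states
lag_embed <- function(x, E, tau = 1L) {
  v <- series_values(x)
  n <- length(v)
  E <- as.integer(E); tau <- as.integer(tau)
  stopifnot(E >= 1, tau >= 1)
  t0 <- (E - 1L) * tau + 1L
  if (t0 > n) stop("insufficient-data error: series shorter than embedding window",
                   call. = FALSE)
  tt <- t0:n
  states <- vapply(0:(E - 1L), function(j) v[tt - j * tau], numeric(length(tt)))
  states <- matrix(states, nrow = length(tt), ncol = E)
  target <- v[ifelse(tt + 1L <= n, tt + 1L, NA_integer_)]
  ok <- complete.cases(states)
  states <- states[ok, , drop = FALSE]
  target <- target[ok]
  tt <- tt[ok]
  if (nrow(states) < 2L)
    stop("insufficient-data error: fewer than 2 complete state rows",
         call. = FALSE)
  structure(list(states = states, target = target, time = tt,
                 E = E, tau = tau,
                 var_names = paste0("lag", 0:(E - 1L))),
            class = "state_matrix")
}

#' Multivariate embedding from a target and lagged causal variables
#'
#' Coordinates are the target at time t followed by each causal series at
#' `t - lag`; the prediction target is the target series at `t + 1`.  Rows
#' with any unavailable coordinate are excluded.  The target itself may not
#' be supplied again as a lag-0 cause (that would make the state predict
#' itself trivially).
#'
#' @param target numeric vector or [quarter_series()] being predicted.
#' @param causes list of numeric vectors/series, aligned to `target`'s grid.
#' @param lags integer vector of non-negative lags, one per cause.
#' @param names optional coordinate names for the causes.
#' @param target_name name of the target coordinate.
#' @return a `state_matrix` with `E = 1 + length(causes)`.
#' @export
multi_embed <- function(target, causes, lags, names = NULL,
                        target_name = series_name(target, "target")) {
  tv <- series_values(target)
  cvs <- lapply(causes, series_values)
  lags <- as.integer(lags)
  stopifnot(length(cvs) == length(lags), all(lags >= 0))
  if (is.null(names)) {
    names <- vapply(seq_along(causes), function(i)
      series_name(causes[[i]], paste0("cause", i)), "")
  }
  nm <- ifelse(lags > 0, paste0(names, "_lag", lags), names)
  if (any(names == target_name & lags == 0L))
    stop("precondition violation: target may not appear as its own lag-0 predictor",
         call. = FALSE)
  n <- length(tv)
  if (any(vapply(cvs, length, 1L) != n))
    stop("alignment error: cause series differ in length from target",
         call. = FALSE)
  tt <- (max(c(lags, 0L)) + 1L):n
  states <- cbind(tv[tt],
                  vapply(seq_along(cvs),
                         function(i) cvs[[i]][tt - lags[i]],
                         numeric(length(tt))))
  target_next <- tv[ifelse(tt + 1L <= n, tt + 1L, NA_integer_)]
  ok <- complete.cases(states)
  states <- states[ok, , drop = FALSE]
  target_next <- target_next[ok]
  tt <- tt[ok]
  E <- ncol(states)
  if (nrow(states) < E + 2L)
    stop("insufficient-data error: fewer than E + 2 complete state rows",
         call. = FALSE)
  colnames(states) <- c(target_name, nm)
  structure(list(states = states, target = target_next, time = tt,
                 E = E, tau = 1L, var_names = c(target_name, nm)),
            class = "state_matrix")
}

# Rows of a state matrix that have a defined next-step target.
forecastable <- function(sm) {
  ok <- !is.na(sm$target)
  list(states = sm$states[ok, , drop = FALSE],
       target = sm$target[ok], time = sm$time[ok])
}

#' Simplex projection forecast skill
#'
#' Leave-one-out one-step-ahead forecasts: each state is predicted from its
#' `E + 1` nearest neighbours (itself excluded), weighted by
#' `exp(-d / d_nearest)`.  Skill is the Pearson correlation between
#' predictions and observations.
#'
#' @param x numeric vector or [quarter_series()] (preprocessed).
#' @param E embedding dimension.
#' @param tau lag step size.
#' @return list with `rho`, `E`, `n`, `predictions`, `observations`.
#' @export
simplex_forecast <- function(x, E, tau = 1L) {
  v <- series_values(x)
  if (!is.finite(sd(v)) || sd(v) == 0)
    stop("degenerate-series error: constant series has undefined forecast skill",
         call. = FALSE)
  sm <- lag_embed(v, E, tau)
  fc <- forecastable(sm)
  if (nrow(fc$states) < E + 2L)
    stop("insufficient-data error: too few forecastable states", call. = FALSE)
  pred <- cpp_simplex_loo(fc$states, fc$target, as.integer(E) + 1L)
  rho <- suppressWarnings(cor(pred, fc$target))
  list(rho = rho, E = as.integer(E), n = length(pred),
       predictions = pred, observations = fc$target, time = fc$time)
}

#' Select the optimal embedding dimension by simplex projection
#'
#' Scans `E = 1..E_max` and returns the dimension with the highest
#' leave-one-out forecast skill; ties break toward the smaller dimension.
#' The result is flagged `low_skill` when the best rho is below 0.1
#' (essentially unforecastable series, e.g. white noise).
#'
#' @param x numeric vector or [quarter_series()].
#' @param E_max largest dimension scanned.
#' @param tau lag step size.
#' @return list with `E_star`, `rho_by_E`, `low_skill`.
#' @export
select_E <- function(x, E_max = 10L, tau = 1L) {
  rho <- rep(NA_real_, E_max)
  for (E in seq_len(E_max)) {
    r <- tryCatch(simplex_forecast(x, E, tau)$rho, error = function(e) NA_real_)
    rho[E] <- r
  }
  if (all(is.na(rho)))
    stop("insufficient-data error: no embedding dimension is feasible",
         call. = FALSE)
  E_star <- which.max(rho)  # first maximum = smallest E on ties
  list(E_star = as.integer(E_star), rho_by_E = rho,
       low_skill = max(rho, na.rm = TRUE) < 0.1)
}

#' Solve the S-map at a fixed nonlinearity parameter
#'
#' For every state with a defined next-step target, all other such states
#' form the library (leave-one-out).  Library states are weighted by
#' `w(d) = exp(-theta d / dbar)`, with `d` the Euclidean distance to the
#' target state and `dbar` the mean library distance, and the weighted
#' linear model (intercept plus one coefficient per coordinate) is solved by
#' singular value decomposition with relative truncation `svd_tol`.  The
#' per-state coefficients are local Jacobian estimates: time-varying
#' influence strengths of each coordinate on the next-step target.  At
#' `theta = 0` every state receives equal weight and the fit reduces to a
#' single global linear (vector-autoregression-style) model; with
#' `exclude_target = FALSE` the theta = 0 coefficients equal the global
#' ordinary least-squares solution exactly.
#'
#' @param states a `state_matrix` from [lag_embed()] or [multi_embed()].
#' @param theta nonlinearity parameter (>= 0).
#' @param exclude_target leave the target state's own row out of its library
#'   (the default; used for all skill evaluation).
#' @param svd_tol relative singular-value truncation threshold.
#' @return an `smap_model`: list with `theta`, `coefficients` (one row per
#'   predictable state; columns `(Intercept)` then the coordinate names),
#'   `rho`, `p_value` (one-sided test of rho > 0), `predictions`,
#'   `observations`, `time`, `dbar`, `n`.
#' @export
smap_solve <- function(states, theta, exclude_target = TRUE, svd_tol = 1e-10) {
  stopifnot(inherits(states, "state_matrix"), theta >= 0)
  fc <- forecastable(states)
  m <- nrow(fc$states)
  if (m < states$E + 2L)
    stop("insufficient-data error: fewer than E + 2 forecastable states",
         call. = FALSE)
  res <- cpp_smap(fc$states, fc$target, theta, exclude_target, svd_tol)
  coefs <- res$coefficients
  colnames(coefs) <- c("(Intercept)", states$var_names)
  rho <- suppressWarnings(cor(res$predictions, fc$target))
  structure(list(theta = theta,
                 coefficients = coefs,
                 rho = rho,
                 p_value = rho_pvalue(rho, m),
                 predictions = as.numeric(res$predictions),
                 observations = fc$target,
                 time = fc$time,
                 dbar = as.numeric(res$dbar),
                 n = m,
                 var_names = states$var_names),
            class = "smap_model")
}

#' @export
print.smap_model <- function(x, ...) {
  cat(sprintf("S-map model: theta = %g, rho = %.4f (p = %.4g), %d states, %d coordinates\n",
              x$theta, x$rho, x$p_value, x$n, length(x$var_names)))
  cat("time-mean coefficients:\n")
  print(colMeans(x$coefficients))
  invisible(x)
}

#' Tune the S-map nonlinearity parameter
#'
#' Fits [smap_solve()] at every value of `theta_grid` and returns the model
#' with the highest forecast skill; ties break toward the smaller theta
#' (the less state-dependent model).
#'
#' @param states a `state_matrix`.
#' @param theta_grid candidate theta values.
#' @param ... passed to [smap_solve()].
#' @return the best `smap_model`, with `theta_grid` and `rho_by_theta` fields
#'   added.
#' @export
tune_theta <- function(states, theta_grid = 0:8, ...) {
  stopifnot(length(theta_grid) >= 1)
  theta_grid <- sort(as.numeric(theta_grid))
  best <- NULL
  rhos <- rep(NA_real_, length(theta_grid))
  for (i in seq_along(theta_grid)) {
    mod <- smap_solve(states, theta_grid[i], ...)
    rhos[i] <- mod$rho
    if (is.null(best) || (is.finite(mod$rho) && mod$rho > best$rho))
      best <- mod
  }
  best$theta_grid <- theta_grid
  best$rho_by_theta <- rhos
  best
}

# One-sided p-value for H1: rho > 0 via the t transform, df = n - 2.
rho_pvalue <- function(rho, n) {
  if (!is.finite(rho) || n <= 2) return(NA_real_)
  if (rho >= 1) return(0)
  if (rho <= -1) return(1)
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  pt(t, df = n - 2, lower.tail = FALSE)
}
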