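#' Cross-map skill from one random library
#'
#' Tests whether `cause` leaves an imprint on `effect`: the shadow manifold
#' of the *effect* (library variable) is used to predict the contemporaneous
#' cause values.  A random size-`L` subsample of the effect's embedding rows
#' (drawn without replacement) forms the library; every embedding row is
#' predicted from its `E + 1` nearest library neighbours (itself excluded)
#' with `exp(-d / d_nearest)` weights, and the Pearson correlation between
#' predicted and observed cause values is returned.
#'
#' With `lag > 0` the manifold at time t predicts `cause(t - lag)`, probing
#' delayed causal effects (positive lag = cause precedes the effect's
#' response).
#'
#' @param effect numeric vector or [quarter_series()]; the affected
#'   (library) variable.
#' @param cause numeric vector or [quarter_series()]; the putative cause.
#' @param E embedding dimension of the effect manifold.
#' @param L library size (`E <= L <=` number of usable embedding rows).
#' @param lag non-negative integer lag in time steps.
#' @param tau embedding lag step.
#' @return the cross-map skill rho (scalar).
#' @export
cross_map <- function(effect, cause, E, L, lag = 0L, tau = 1L) {
  su <- ccm_setup(effect, cause, E, lag, tau)
  L <- as.integer(L)
  if (L < E) stop("invalid-library error: L must be at least E", call. = FALSE)
  if (L > su$n) stop("invalid-library error: L exceeds available states",
                     call. = FALSE)
  lib <- sample.int(su$n, L)
  as.numeric(cpp_cross_map_rho(su$D, su$cause, list(lib), as.integer(E) + 1L))
}

# Shared cross-map scaffolding: effect embedding rows, lag-aligned cause
# values at those rows, and the full distance matrix.
ccm_setup <- function(effect, cause, E, lag = 0L, tau = 1L) {
  ev <- series_values(effect)
  cv <- series_values(cause)
  if (length(ev) != length(cv))
    stop("alignment error: effect and cause differ in length", call. = FALSE)
  if (!is.finite(sd(cv)) || sd(cv) == 0)
    stop("degenerate-series error: constant cause has undefined skill",
         call. = FALSE)
  lag <- as.integer(lag)
  stopifnot(lag >= 0)
  sm <- lag_embed(ev, E, tau)
  keep <- sm$time - lag >= 1L & !is.na(cv[pmax(sm$time - lag, 1L)])
  states <- sm$states[keep, , drop = FALSE]
  cvals <- cv[sm$time[keep] - lag]
  n <- nrow(states)
  if (n < E + 2L)
    stop("insufficient-data error: too few states after lag alignment",
         call. = FALSE)
  D <- as.matrix(stats::dist(states))
  list(D = D, cause = cvals, n = n, time = sm$time[keep])
}

#' Convergence test for one replicate's cross-map profile
#'
#' Convergence of cross-map skill with library size distinguishes causation
#' from mere correlation.  Two one-sided criteria must both hold at level
#' `alpha`: (1) rho(L) increases monotonically with L (Kendall's tau test);
#' (2) rho at the largest library exceeds zero (Student's t-test with
#' `n_pred - 2` degrees of freedom).
#'
#' @param rho_by_L cross-map skill at each library size, one replicate.
#' @param L_grid the library sizes.
#' @param n_pred number of predicted points behind each rho.
#' @param alpha significance level for both tests.
#' @return list with `kendall_p`, `ttest_p`, `pass`.
#' @export
convergence_test <- function(rho_by_L, L_grid, n_pred, alpha = 0.05) {
  ok <- is.finite(rho_by_L) & is.finite(L_grid)
  rho_by_L <- rho_by_L[ok]; L_grid <- L_grid[ok]
  if (length(rho_by_L) < 3)
    stop("insufficient-grid error: need at least 3 library sizes", call. = FALSE)
  kp <- if (sd(rho_by_L) == 0) 1 else
    suppressWarnings(cor.test(L_grid, rho_by_L, method = "kendall",
                              alternative = "greater", exact = FALSE)$p.value)
  tp <- rho_pvalue(rho_by_L[which.max(L_grid)], n_pred)
  pass <- is.finite(kp) && is.finite(tp) && kp < alpha && tp < alpha
  list(kendall_p = kp, ttest_p = tp, pass = pass)
}

#' Replicated convergent cross mapping at one lag
#'
#' Runs `n_ccm_replicates` independent cross-map analyses.  In each
#' replicate a fresh random library is drawn at every size of the library
#' grid (`L_grid_size` sizes from `E*` to the number of usable embedding
#' rows) and the replicate's rho(L) profile is submitted to
#' [convergence_test()].  The causal verdict requires the convergence test
#' to pass in at least `ccm_pass_fraction` (default 95%) of replicates.
#'
#' @param effect,cause aligned, preprocessed series.
#' @param lag non-negative lag in steps (see [cross_map()]).
#' @param config a [run_config()].
#' @param E_star optional precomputed embedding dimension of the effect
#'   series; selected by [select_E()] when `NULL`.
#' @return a `ccm_result`: list with `cause_name`, `effect_name`, `lag`,
#'   `E_star`, `L_grid`, `rho_by_L` (replicate mean), `rho_Lmax`,
#'   `pass_fraction`, `significant`, `n_pred`.
#' @export
ccm_with_replicates <- function(effect, cause, lag = 0L, config = run_config(),
                                E_star = NULL) {
  if (is.null(E_star)) E_star <- select_E(effect, config$E_max)$E_star
  su <- ccm_setup(effect, cause, E_star, lag)
  L_min <- max(as.integer(E_star), 2L)
  L_max <- su$n
  n_L <- min(config$L_grid_size, L_max - L_min + 1L)
  if (n_L < 3)
    stop("insufficient-grid error: library range too small", call. = FALSE)
  L_grid <- unique(round(seq(L_min, L_max, length.out = n_L)))
  R <- config$n_ccm_replicates
  libs <- vector("list", R * length(L_grid))
  k <- 0L
  for (r in seq_len(R))
    for (L in L_grid) {
      k <- k + 1L
      libs[[k]] <- sample.int(su$n, L)
    }
  rho <- cpp_cross_map_rho(su$D, su$cause, libs, E_star + 1L)
  rho <- matrix(rho, nrow = R, ncol = length(L_grid), byrow = TRUE)
  pass <- vapply(seq_len(R), function(r) {
    ct <- tryCatch(convergence_test(rho[r, ], L_grid, su$n, config$alpha_ccm),
                   error = function(e) list(pass = FALSE))
    isTRUE(ct$pass)
  }, logical(1))
  pf <- mean(pass)
  structure(list(cause_name = series_name(cause, "cause"),
                 effect_name = series_name(effect, "effect"),
                 lag = as.integer(lag),
                 E_star = as.integer(E_star),
                 L_grid = L_grid,
                 rho_by_L = colMeans(rho),
                 rho_Lmax = mean(rho[, length(L_grid)]),
                 pass_fraction = pf,
                 significant = pf >= config$ccm_pass_fraction,
                 n_pred = su$n,
                 n_replicates = R),
            class = "ccm_result")
}

#' @export
print.ccm_result <- function(x, ...) {
  cat(sprintf("CCM %s -> %s (lag %d): rho(Lmax) = %.4f, pass %.1f%%, %s\n",
              x$cause_name, x$effect_name, x$lag, x$rho_Lmax,
              100 * x$pass_fraction,
              if (x$significant) "significant" else "n.s."))
  invisible(x)
}

#' Scan cross-map lags and retain the best
#'
#' Runs [ccm_with_replicates()] at every lag in `0..lag_max` and retains the
#' lag with the highest mean rho(Lmax) among significant lags.  When no lag
#' is significant the verdict is `"n.s."` (no detectable causal effect).
#' Lags that leave too few states are skipped and logged.
#'
#' @param effect,cause aligned, preprocessed series.
#' @param lag_max largest lag scanned.
#' @param config a [run_config()].
#' @param E_star optional precomputed embedding dimension of the effect.
#' @return a `ccm_scan`: list with `results` (per lag), `best` (the winning
#'   `ccm_result` or `NULL`), `best_lag`, `verdict` (`"causal"`/`"n.s."`),
#'   `E_star`, `skipped` (log of skipped lags).
#' @export
lag_scan <- function(effect, cause, lag_max, config = run_config(),
                     E_star = NULL) {
  if (is.null(E_star)) E_star <- select_E(effect, config$E_max)$E_star
  lags <- 0:lag_max
  results <- setNames(vector("list", length(lags)), paste0("lag", lags))
  skipped <- character()
  for (i in seq_along(lags)) {
    results[[i]] <- tryCatch(
      ccm_with_replicates(effect, cause, lags[i], config, E_star),
      error = function(e) {
        skipped <<- c(skipped,
                      sprintf("lag %d skipped: %s", lags[i], conditionMessage(e)))
        NULL
      })
  }
  done <- Filter(Negate(is.null), results)
  sig <- Filter(function(r) isTRUE(r$significant), done)
  best <- NULL
  if (length(sig)) {
    rhos <- vapply(sig, function(r) r$rho_Lmax, 1)
    best <- sig[[which.max(rhos)]]
  }
  structure(list(cause_name = series_name(cause, "cause"),
                 effect_name = series_name(effect, "effect"),
                 E_star = as.integer(E_star),
                 results = results,
                 best = best,
                 best_lag = if (is.null(best)) NA_integer_ else best$lag,
                 verdict = if (is.null(best)) "n.s." else "causal",
                 skipped = skipped),
            class = "ccm_scan")
}

#' @export
print.ccm_scan <- function(x, ...) {
  if (identical(x$verdict, "causal"))
    cat(sprintf("CCM scan %s -> %s: causal, best lag %d, rho = %.4f\n",
                x$cause_name, x$effect_name, x$best_lag, x$best$rho_Lmax))
  else
    cat(sprintf("CCM scan %s -> %s: n.s.\n", x$cause_name, x$effect_name))
  invisible(x)
}
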