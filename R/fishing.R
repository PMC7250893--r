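#' Yearly analyses involving fishing mortality
#'
#' Fishing mortality is only available yearly, so every series entering this
#' analysis must first be averaged to the yearly grid ([to_yearly()]).  For
#' each target variable, every other series is scanned as a candidate cause
#' over lags `0..lag_max_yearly`.  Each significant (cause, lag) term is
#' then fitted in its own multivariate S-map model — the target plus the
#' cause at that lag, with the remaining embedding slots filled by the other
#' significant causes at their best lags — and a cause's influence is the
#' signed average of its time-mean coefficient over all its significant
#' lagged terms.  Averaging separate per-lag models (rather than packing
#' collinear lagged copies into one model) damps the variability that short
#' yearly series induce in any single fit.
#'
#' @param series_list named list of *yearly* [quarter_series()] (typically
#'   spatial CV, age diversity, abundance, environmental series and
#'   `fishing_mortality`), already preprocessed.
#' @param config a [run_config()].
#' @param targets names of the series to analyse as targets.
#' @return named list (per target) of `fishing_result`s: `verdict`
#'   (`"causal"` when any term is CCM-significant), `terms` (data frame of
#'   significant cause/lag terms with per-model theta, rho, p and time-mean
#'   coefficient), `significant` (any term's S-map model passed the skill
#'   gate), and `mean_influence` (per cause, averaged over its lags with a
#'   significant model; `NULL` when none).
#' @export
fishing_analysis <- function(series_list, config = run_config(),
                             targets = c("spatial_cv", "age_diversity",
                                         "abundance")) {
  grids <- vapply(series_list, function(s) attr(s, "grid"), "")
  if (!all(grids == "yearly"))
    stop("precondition violation: all series must be on the yearly grid ",
         "(use to_yearly())", call. = FALSE)
  series_list <- align_series(series_list)
  names(series_list) <- vapply(series_list, function(s) attr(s, "name"), "")
  n <- nrow(series_list[[1]])
  if (n < 20)
    warning(sprintf("only %d yearly points: low power for attractor reconstruction",
                    n), call. = FALSE)
  targets <- intersect(targets, names(series_list))
  out <- list()
  for (tg in targets) {
    target <- series_list[[tg]]
    causes <- setdiff(names(series_list), tg)
    E_star <- select_E(target, min(config$E_max, max(2L, n %/% 3L)))$E_star
    terms <- data.frame(name = character(), lag = integer(), rho = numeric(),
                        stringsAsFactors = FALSE)
    for (cs in causes) {
      scan <- lag_scan(target, series_list[[cs]], config$lag_max_yearly,
                       config, E_star)
      for (r in Filter(Negate(is.null), scan$results))
        if (isTRUE(r$significant))
          terms <- rbind(terms, data.frame(name = cs, lag = r$lag,
                                           rho = r$rho_Lmax))
    }
    if (nrow(terms) == 0) {
      out[[tg]] <- structure(list(target = tg, verdict = "n.s.",
                                  terms = terms, significant = FALSE,
                                  mean_influence = NULL),
                             class = "fishing_result")
      next
    }
    terms <- terms[order(-terms$rho, terms$lag, terms$name), , drop = FALSE]
    # best significant lag per cause, used to fill companion slots
    best_lag <- vapply(split(terms, terms$name),
                       function(d) d$lag[which.max(d$rho)], 1L)
    terms$theta <- terms$rho_smap <- terms$p_value <- terms$coefficient <-
      NA_real_
    for (i in seq_len(nrow(terms))) {
      cs <- terms$name[i]; lg <- terms$lag[i]
      others <- setdiff(names(best_lag), cs)
      others <- others[order(-vapply(others, function(o)
        max(terms$rho[terms$name == o]), 1))]
      others <- utils::head(others, max(0L, min(E_star - 2L, n - 6L)))
      emb_names <- c(cs, others)
      # coordinate lags are counted from the predicted step t + 1
      emb_lags <- pmax(c(lg, unname(best_lag[others])) - 1L, 0L)
      mod <- tryCatch({
        sm <- multi_embed(target, series_list[emb_names], emb_lags,
                          names = emb_names, target_name = tg)
        tune_theta(sm, config$theta_grid)
      }, error = function(e) NULL)
      if (is.null(mod)) next
      cn <- if (emb_lags[1] > 0) paste0(cs, "_lag", emb_lags[1]) else cs
      terms$theta[i] <- mod$theta
      terms$rho_smap[i] <- mod$rho
      terms$p_value[i] <- mod$p_value
      terms$coefficient[i] <- mean(mod$coefficients[, cn])
    }
    sig <- is.finite(terms$p_value) & terms$p_value < config$alpha_smap
    mean_influence <- NULL
    if (any(sig)) {
      kept <- terms[sig, , drop = FALSE]
      mean_influence <- tapply(kept$coefficient, kept$name, mean)
    }
    out[[tg]] <- structure(list(target = tg, verdict = "causal",
                                terms = terms,
                                significant = any(sig),
                                mean_influence = mean_influence),
                           class = "fishing_result")
  }
  out
}

#' @export
print.fishing_result <- function(x, ...) {
  cat(sprintf("yearly attribution for '%s': %s\n", x$target, x$verdict))
  if (!is.null(x$mean_influence)) print(x$mean_influence)
  invisible(x)
}
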