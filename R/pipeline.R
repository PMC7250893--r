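#' Run the full spatial-variability attribution pipeline
#'
#' End to end for one species: filter the survey tables, derive the spatial
#' CV, age diversity and abundance series, align them with the supplied
#' environmental series, preprocess (detrend where significant, normalize),
#' scan cross-map lags for every candidate cause of the spatial CV, build the
#' multivariate embedding from the significant causes, estimate time-varying
#' influence strengths by S-map, run the sensitivity re-embeddings, and fit
#' Taylor's power law.  Deterministic given `config$rng_seed`.
#'
#' @param config a [run_config()].
#' @param age_table an age-classed [survey_table()] (or CSV path).
#' @param length_table a length-classed [survey_table()] (or CSV path);
#'   defaults to the age table (summing over either classification gives the
#'   same totals).
#' @param env_series named list of biquarterly [quarter_series()] used as
#'   additional candidate causes (e.g. temperature mean/CV, climate index).
#' @param outdir optional directory; when given, result tables are written
#'   there via [write_results_tables()].
#' @return a `spatcv_report` list: `series` (preprocessed), `scans`,
#'   `embedding`, `attribution`, `sensitivity`, `taylor`, `direction`,
#'   `E_star`, `log`.
#' @export
run_pipeline <- function(config = run_config(), age_table,
                         length_table = NULL, env_series = list(),
                         outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$rng_seed)
  if (is.character(age_table))
    age_table <- read_survey_table(age_table, "age")
  if (is.character(length_table))
    length_table <- read_survey_table(length_table, "length")
  if (is.null(length_table)) length_table <- age_table
  log <- character()
  f_age <- filter_survey(age_table, config$min_grids)
  f_len <- filter_survey(length_table, config$min_grids)
  log <- c(log, attr(f_age, "filter_log"), attr(f_len, "filter_log"))

  cv <- spatial_cv(f_len)
  sh <- age_diversity(f_age)
  ab <- total_abundance(f_len)
  log <- c(log, attr(cv, "log"), attr(sh, "log"))
  raw <- c(list(spatial_cv = cv, age_diversity = sh, abundance = ab),
           env_series)
  raw <- align_series(raw)
  names(raw) <- vapply(raw, function(s) attr(s, "name"), "")
  series <- lapply(raw, preprocess_series, alpha_trend = config$alpha_trend)
  for (nm in names(series))
    if (isTRUE(attr(series[[nm]], "detrended")))
      log <- c(log, sprintf("preprocess: '%s' detrended (slope p = %.3g)",
                            nm, attr(series[[nm]], "detrend_pvalue")))

  E_star <- select_E(series$spatial_cv, config$E_max)$E_star
  causes <- setdiff(names(series), "spatial_cv")
  scans <- lapply(causes, function(nm)
    lag_scan(series$spatial_cv, series[[nm]], config$lag_max_quarterly,
             config, E_star))
  names(scans) <- causes
  for (s in scans) log <- c(log, s$skipped)

  embedding <- select_embedding("spatial_cv", scans, E_star)
  attribution <- NULL
  sensitivity <- list()
  if (identical(embedding$verdict, "ok")) {
    attribution <- estimate_influence(embedding, series, config)
    sensitivity <- sensitivity_combinations(embedding, series, config)
  } else {
    log <- c(log, "attribution: no causal variables to reconstruct the attractor")
  }
  taylor <- tryCatch(fit_taylor(f_len), error = function(e) {
    log <<- c(log, paste("taylor:", conditionMessage(e)))
    NULL
  })
  report <- structure(list(series = series,
                           scans = scans,
                           embedding = embedding,
                           attribution = attribution,
                           sensitivity = sensitivity,
                           taylor = taylor,
                           direction = if (is.null(taylor)) NA_character_
                                       else cv_abundance_direction(taylor),
                           E_star = E_star,
                           config = config,
                           log = log),
                      class = "spatcv_report")
  if (!is.null(outdir)) write_results_tables(scans, attribution, sensitivity,
                                             taylor, outdir, log = log)
  report
}

#' @export
print.spatcv_report <- function(x, ...) {
  cat(sprintf("spatial-variability attribution report (E* = %d)\n", x$E_star))
  for (s in x$scans) print(s)
  if (!is.null(x$attribution)) print(x$attribution)
  else cat("S-map attribution: not available\n")
  if (!is.null(x$taylor)) {
    print(x$taylor)
    cat(sprintf("implied CV-abundance direction: %s\n", x$direction))
  }
  invisible(x)
}

#' Write the pipeline's result tables
#'
#' Emits four CSVs into `path`: `table1.csv` (per candidate cause: best lag,
#' cross-map skill, pass fraction, verdict, `n.s.` markers included),
#' `table2.csv` (primary and sensitivity S-map models: theta, rho, p, mean
#' influence per cause), `coefficients.csv` (per-time-step coefficient
#' series of the primary model, long format), and `taylor.csv`.  Empty
#' inputs yield files with headers only.
#'
#' @param scans named list of `ccm_scan` objects (may be empty).
#' @param attribution primary `attribution_result` or `NULL`.
#' @param sensitivity list of alternate `attribution_result`s.
#' @param taylor a `taylor_fit` or `NULL`.
#' @param path output directory (created if needed).
#' @param log optional character vector written to `log.txt`.
#' @return the directory path, invisibly.
#' @export
write_results_tables <- function(scans, attribution = NULL,
                                 sensitivity = list(), taylor = NULL,
                                 path, log = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  t1 <- data.frame(variable = character(), best_lag = integer(),
                   rho = numeric(), pass_fraction = numeric(),
                   verdict = character(), stringsAsFactors = FALSE)
  for (s in scans) {
    t1 <- rbind(t1, data.frame(
      variable = s$cause_name,
      best_lag = s$best_lag,
      rho = if (is.null(s$best)) NA_real_ else s$best$rho_Lmax,
      pass_fraction = if (is.null(s$best)) NA_real_ else s$best$pass_fraction,
      verdict = s$verdict))
  }
  data.table::fwrite(t1, file.path(path, "table1.csv"))

  models <- list()
  if (!is.null(attribution) && isTRUE(attribution$significant))
    models$primary <- attribution
  sig_alt <- Filter(function(a) isTRUE(a$significant), sensitivity)
  if (length(sig_alt))
    models[paste0("alt", seq_along(sig_alt))] <- sig_alt
  t2 <- data.frame(model = character(), variable = character(),
                   lag = integer(), mean_influence = numeric(),
                   theta = numeric(), rho = numeric(), p_value = numeric(),
                   stringsAsFactors = FALSE)
  for (nm in names(models)) {
    a <- models[[nm]]
    t2 <- rbind(t2, data.frame(
      model = nm,
      variable = a$embedding$causes$name,
      lag = a$embedding$causes$lag,
      mean_influence = as.numeric(a$mean_influence),
      theta = a$theta, rho = a$rho, p_value = a$p_value))
  }
  data.table::fwrite(t2, file.path(path, "table2.csv"))

  co <- data.frame(time = integer(), coordinate = character(),
                   coefficient = numeric(), stringsAsFactors = FALSE)
  if (!is.null(attribution)) {
    cf <- attribution$model$coefficients
    co <- data.frame(time = rep(attribution$model$time, ncol(cf)),
                     coordinate = rep(colnames(cf), each = nrow(cf)),
                     coefficient = as.numeric(cf))
  }
  data.table::fwrite(co, file.path(path, "coefficients.csv"))

  tf <- data.frame(a = numeric(), b = numeric(), r_squared = numeric(),
                   n_points = integer(), direction = character())
  if (!is.null(taylor))
    tf <- data.frame(a = taylor$a, b = taylor$b, r_squared = taylor$r_squared,
                     n_points = taylor$n_points,
                     direction = cv_abundance_direction(taylor))
  data.table::fwrite(tf, file.path(path, "taylor.csv"))
  if (!is.null(log))
    writeLines(log, file.path(path, "log.txt"))
  invisible(path)
}
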