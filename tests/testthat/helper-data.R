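# Small deterministic generators shared across tests.

logistic_series <- function(n, r = 3.8, x0 = 0.4, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- numeric(n)
  x[1] <- x0
  for (t in 2:n) x[t] <- r * x[t - 1] * (1 - x[t - 1])
  if (noise > 0) x <- x + rnorm(n, 0, noise)
  x
}

ar1_series <- function(n, phi = 0.5, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd / sqrt(1 - phi^2))
  for (t in 2:n) x[t] <- phi * x[t - 1] + rnorm(1, 0, sd)
  x
}

# A tiny survey data frame: one row per (year, quarter, subarea, class).
make_survey_df <- function(years, quarters = c(1, 3), subareas = c("a", "b"),
                           classes = 0:1, cpue_fun = function(...) 1) {
  g <- expand.grid(year = years, quarter = quarters, subarea = subareas,
                   class_id = classes, stringsAsFactors = FALSE)
  g$cpue <- mapply(cpue_fun, g$year, g$quarter, g$subarea, g$class_id)
  g
}

quick_config <- function(n_ccm_replicates = 30L, L_grid_size = 8L, ...) {
  run_config(n_ccm_replicates = n_ccm_replicates, L_grid_size = L_grid_size,
             ...)
}
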