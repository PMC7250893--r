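# Fabricate a ccm_scan with a given verdict, for embedding-selection tests.
fake_scan <- function(cause, rho, lag = 1L, significant = TRUE) {
  best <- if (significant)
    structure(list(cause_name = cause, effect_name = "spatial_cv",
                   lag = as.integer(lag), rho_Lmax = rho,
                   pass_fraction = 1, significant = TRUE),
              class = "ccm_result")
  structure(list(cause_name = cause, effect_name = "spatial_cv",
                 E_star = 4L, results = list(), best = best,
                 best_lag = if (significant) as.integer(lag) else NA_integer_,
                 verdict = if (significant) "causal" else "n.s.",
                 skipped = character()),
            class = "ccm_scan")
}

test_that("embedding selection takes the top E* - 1 causes by cross-map skill", {
  scans <- list(fake_scan("a", 0.9), fake_scan("b", 0.8), fake_scan("c", 0.7),
                fake_scan("d", 0.6), fake_scan("e", 0.5))
  spec <- select_embedding("spatial_cv", scans, E_star = 4)
  expect_equal(spec$verdict, "ok")
  expect_equal(spec$E, 4L)
  expect_equal(spec$causes$name, c("a", "b", "c"))
  expect_false(spec$suboptimal)
  # ties break toward smaller lag then name
  scans2 <- list(fake_scan("b", 0.8, lag = 2), fake_scan("a", 0.8, lag = 1))
  spec2 <- select_embedding("spatial_cv", scans2, E_star = 2)
  expect_equal(spec2$causes$name, "a")
})

test_that("too few causes fall back to the suboptimal dimension", {
  scans <- list(fake_scan("a", 0.9), fake_scan("b", 0.5),
                fake_scan("c", 0.4, significant = FALSE))
  spec <- select_embedding("spatial_cv", scans, E_star = 7)
  expect_equal(spec$E, 3L)  # 2 causes + target
  expect_true(spec$suboptimal)
})

test_that("no significant causes is a recorded verdict, not an error", {
  scans <- list(fake_scan("a", 0.4, significant = FALSE))
  spec <- select_embedding("spatial_cv", scans, E_star = 3)
  expect_equal(spec$verdict, "no_causal_variables")
  expect_error(estimate_influence(spec, list()), "no-causal-variables")
})

test_that("the target cannot appear as its own lag-0 predictor", {
  x <- rnorm(50)
  expect_error(multi_embed(quarter_series(0:49, x, name = "cv"),
                           list(quarter_series(0:49, x, name = "cv")),
                           lags = 0L),
               "precondition violation")
})

test_that("influence estimation recovers a linear VAR's coefficient matrix", {
  # x(t+1) = 0.5 x(t) + 0.3 y(t) - 0.4 z(t) + eps; y, z exogenous noise
  A <- matrix(0, 3, 3, dimnames = rep(list(c("x", "y", "z")), 2))
  A["x", "x"] <- 0.5; A["y", "x"] <- 0.3; A["z", "x"] <- -0.4
  dl <- matrix(0L, 3, 3); dl[2, 1] <- 1L; dl[3, 1] <- 1L
  sys <- gen_coupled_system(coupled_system_truth("var", A, dl, noise_sd = 1,
                                                 var_names = c("x", "y", "z")),
                            n = 400, seed = 50)
  ser <- list(x = quarter_series(0:399, sys$series$x, name = "x"),
              y = quarter_series(0:399, sys$series$y, name = "y"),
              z = quarter_series(0:399, sys$series$z, name = "z"))
  scans <- list(fake_scan("y", 0.8, lag = 0), fake_scan("z", 0.7, lag = 0))
  spec <- select_embedding("x", scans, E_star = 3)
  res <- estimate_influence(spec, ser, run_config())
  expect_true(res$significant)
  expect_lt(abs(res$mean_influence[["y"]] - 0.3), 0.1)
  expect_lt(abs(res$mean_influence[["z"]] + 0.4), 0.1)
  expect_lte(res$theta, 1)  # linear system: little gain from state dependence
})

test_that("mean influences are only reported for significant models", {
  set.seed(51)
  ser <- list(x = quarter_series(0:39, rnorm(40), name = "x"),
              y = quarter_series(0:39, rnorm(40), name = "y"))
  spec <- select_embedding("x", list(fake_scan("y", 0.3, lag = 0)), E_star = 2)
  res <- estimate_influence(spec, ser, run_config())
  if (!res$significant) expect_null(res$mean_influence)
  expect_true(is.null(res$mean_influence) == !res$significant)
})

test_that("sensitivity enumeration covers alternative cause subsets", {
  scans <- lapply(seq_len(5), function(i)
    fake_scan(letters[i], 0.9 - 0.1 * i, lag = 0))
  set.seed(52)
  ser <- setNames(lapply(1:6, function(i) {
    v <- as.numeric(arima.sim(list(ar = 0.5), 80))
    quarter_series(0:79, v, name = c("t", letters[1:5])[i])
  }), c("t", letters[1:5]))
  spec <- select_embedding("t", scans, E_star = 4)
  alts <- sensitivity_combinations(spec, ser, quick_config())
  expect_equal(length(alts), choose(5, 3) - 1)
  combos <- vapply(alts, function(a)
    paste(sort(a$embedding$causes$name), collapse = ""), "")
  expect_false(any(duplicated(combos)))
  expect_false("abc" %in% combos)  # the primary set is not re-fitted

  # exactly E* - 1 causes: nothing to vary
  spec2 <- select_embedding("t", scans[1:3], E_star = 4)
  expect_equal(sensitivity_combinations(spec2, ser, quick_config()), list())
})

test_that("yearly fishing analysis enforces the yearly grid and finds truncation",
{
  # quarterly series are rejected outright
  qs <- quarter_series(0:39, rnorm(40), year = rep(2000:2019, each = 2),
                       name = "spatial_cv")
  expect_error(fishing_analysis(list(spatial_cv = qs)), "yearly grid")

  # fishing (persistent pressure) suppresses age diversity; the averaged
  # per-lag influence must come out negative
  hits <- 0L; tried <- 0L
  for (seed in 1:4) {
    set.seed(seed)
    n <- 50
    ph <- runif(1, 0, 2 * pi)
    f <- 0.5 + 0.35 * sin(2 * pi * (1:n) / 11.3 + ph)
    div <- numeric(n); div[1] <- runif(1, 0.3, 0.7)
    for (t in 2:n)
      div[t] <- div[t - 1] * (3.6 - 3.6 * div[t - 1] - 0.4 * f[t - 1])
    yrs <- 1951:(1950 + n)
    ser <- list(
      age_diversity = quarter_series(yrs, div, year = yrs,
                                     name = "age_diversity", grid = "yearly"),
      fishing_mortality = quarter_series(yrs, f, year = yrs,
                                         name = "fishing_mortality",
                                         grid = "yearly"))
    set.seed(seed)
    out <- fishing_analysis(ser, quick_config(), targets = "age_diversity")
    res <- out$age_diversity
    expect_s3_class(res, "fishing_result")
    expect_equal(res$verdict, "causal")
    if (isTRUE(res$significant)) {
      tried <- tried + 1L
      hits <- hits + (res$mean_influence[["fishing_mortality"]] < 0)
    }
  }
  expect_gte(tried, 2)
  expect_equal(hits, tried)
})

test_that("an independent yearly driver yields an n.s. verdict", {
  set.seed(54)
  n <- 40
  yrs <- 1961:(1960 + n)
  ser <- list(
    abundance = quarter_series(yrs, ar1_series(n, 0.5), year = yrs,
                               name = "abundance", grid = "yearly"),
    fishing_mortality = quarter_series(yrs, ar1_series(n, 0.5), year = yrs,
                                       name = "fishing_mortality",
                                       grid = "yearly"))
  out <- fishing_analysis(ser, quick_config(), targets = "abundance")
  expect_equal(out$abundance$verdict, "n.s.")
})
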