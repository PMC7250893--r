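test_that("coverage filters drop dead subareas then thin quarters, in order", {
  df <- make_survey_df(2000:2016, subareas = letters[1:12], classes = 0,
                       cpue_fun = function(y, q, s, a) if (s == "a") 0 else 5)
  tab <- survey_table(df, "age")
  filt <- suppressWarnings(filter_survey(tab, min_grids = 10))
  expect_false("a" %in% filt$subarea)
  expect_equal(length(unique(filt$subarea)), 11)

  # a quarter surveyed in only 9 subareas is removed at min_grids = 10
  df2 <- make_survey_df(2000:2016, subareas = letters[1:10], classes = 0,
                        cpue_fun = function(...) 1)
  df2 <- df2[!(df2$year == 2005 & df2$quarter == 1 & df2$subarea == "a"), ]
  tab2 <- survey_table(df2, "age")
  filt2 <- filter_survey(tab2, min_grids = 10)
  expect_false(10L %in% filt2$quarter_step)  # 2005Q1 = step 10
  expect_true(any(grepl("quarter_step 10", attr(filt2, "filter_log"))))

  # clean tables pass through unchanged
  tab3 <- survey_table(make_survey_df(2000:2016, subareas = letters[1:10],
                                      classes = 0:1), "age")
  expect_equal(nrow(filter_survey(tab3, 10)), nrow(tab3))

  expect_warning(filter_survey(survey_table(
    make_survey_df(2000:2005, subareas = letters[1:10]), "age"), 10),
    "n >= 30")
})

test_that("spatial CV matches hand computations and is scale invariant", {
  mk <- function(cpues) survey_table(data.frame(
    year = 2000, quarter = 1, subarea = letters[seq_along(cpues)],
    class_id = 0, cpue = cpues), "age")
  expect_equal(spatial_cv(mk(c(10, 10, 10, 10)))$value, 0)
  expect_equal(spatial_cv(mk(c(1, 3)))$value, sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(round(spatial_cv(mk(c(1, 3)))$value, 5), 0.70711)
  expect_equal(spatial_cv(mk(c(2, 6)))$value, spatial_cv(mk(c(1, 3)))$value)
  # classes are summed within subarea before the CV
  two_class <- survey_table(data.frame(
    year = 2000, quarter = 1, subarea = rep(c("a", "b"), each = 2),
    class_id = rep(0:1, 2), cpue = c(0.5, 0.5, 1.5, 1.5)), "age")
  expect_equal(spatial_cv(two_class)$value, sqrt(2) / 2)
  # all-zero quarter is excluded, not returned as NaN
  withzero <- survey_table(data.frame(
    year = 2000, quarter = c(1, 1, 3, 3), subarea = c("a", "b", "a", "b"),
    class_id = 0, cpue = c(1, 3, 0, 0)), "age")
  s <- spatial_cv(withzero)
  expect_equal(s$step, 0L)
  expect_match(attr(s, "log"), "undefined")
})

test_that("Shannon age diversity matches closed forms and its bounds", {
  mk <- function(cpue_by_age) survey_table(data.frame(
    year = 2000, quarter = 1, subarea = "a",
    class_id = seq_along(cpue_by_age) - 1, cpue = cpue_by_age), "age")
  expect_equal(age_diversity(mk(rep(2, 4)))$value, log(4))
  expect_equal(age_diversity(mk(c(0, 7, 0)))$value, 0)
  expect_equal(age_diversity(mk(c(2, 1, 1)))$value,
               -(0.5 * log(0.5) + 0.5 * log(0.25)), tolerance = 1e-12)
  expect_equal(round(age_diversity(mk(c(2, 1, 1)))$value, 5), 1.03972)
  # bounds on random compositions
  set.seed(1)
  for (i in 1:20) {
    p <- rexp(5)
    sh <- age_diversity(mk(p))$value
    expect_gte(sh, 0)
    expect_lte(sh, log(5) + 1e-12)
  }
})

test_that("total abundance sums everything and is additive over subareas", {
  df <- make_survey_df(2000, quarters = 1, subareas = c("a", "b"),
                       classes = 0:1, cpue_fun = function(...) 1)
  expect_equal(total_abundance(survey_table(df, "age"))$value, 4)
  set.seed(2)
  df2 <- make_survey_df(2000:2001, subareas = letters[1:6], classes = 0:2,
                        cpue_fun = function(...) rexp(1))
  tab <- survey_table(df2, "age")
  left <- tab[tab$subarea %in% letters[1:3], ]
  right <- tab[tab$subarea %in% letters[4:6], ]
  class(left) <- class(right) <- c("survey_table", "data.frame")
  expect_equal(total_abundance(tab)$value,
               total_abundance(left)$value + total_abundance(right)$value)
  # record order does not matter
  shuf <- survey_table(df2[sample(nrow(df2)), ], "age")
  expect_equal(total_abundance(shuf)$value, total_abundance(tab)$value)
})

test_that("preprocessing detrends only significant trends and normalizes", {
  set.seed(3)
  s <- quarter_series(0:49, rnorm(50))
  p <- preprocess_series(s)
  expect_false(attr(p, "detrended"))
  expect_lt(abs(mean(p$value)), 1e-9)
  expect_lt(abs(sd(p$value) - 1), 1e-9)

  s2 <- quarter_series(0:49, 0.5 * (0:49) + rnorm(50, 0, 0.5))
  p2 <- preprocess_series(s2)
  expect_true(attr(p2, "detrended"))
  expect_lt(abs(cor(p2$value, p2$step)), 0.05)

  expect_error(preprocess_series(quarter_series(0:49, 2 * (0:49))),
               "degenerate")
})

test_that("yearly averaging halves the grid correctly", {
  s <- quarter_series(step = c(0, 1, 2), value = c(1, 3, 5),
                      year = c(1991, 1991, 1992),
                      quarter = c("Q1", "Q3", "Q1"))
  y <- to_yearly(s)
  expect_equal(attr(y, "grid"), "yearly")
  expect_equal(y$value, c(2, 5))
  expect_equal(y$step, c(1991L, 1992L))
  const <- to_yearly(quarter_series(0:9, rep(4, 10), year = rep(2000:2004, each = 2)))
  expect_equal(const$value, rep(4, 5))
})

test_that("Taylor's law recovers analytic exponents", {
  # identical spatial pattern scaled by abundance => V scales as M^2 exactly
  set.seed(4)
  pattern <- rexp(20)
  rows <- do.call(rbind, lapply(1:30, function(q) {
    scale <- exp(rnorm(1))
    data.frame(year = 2000 + (q - 1) %/% 2, quarter = c(1, 3)[(q - 1) %% 2 + 1],
               subarea = paste0("s", 1:20), class_id = 0,
               cpue = scale * pattern)
  }))
  fit <- fit_taylor(survey_table(rows, "age"))
  expect_equal(fit$b, 2, tolerance = 1e-9)
  expect_equal(cv_abundance_direction(fit), "neutral")

  # Poisson-like counts: V = M => slope 1
  set.seed(5)
  rows2 <- do.call(rbind, lapply(1:50, function(q) {
    lambda <- exp(rnorm(1, 1, 1))
    data.frame(year = 2000 + (q - 1) %/% 2, quarter = c(1, 3)[(q - 1) %% 2 + 1],
               subarea = paste0("s", 1:40), class_id = 0,
               cpue = rpois(40, lambda))
  }))
  fit2 <- fit_taylor(survey_table(rows2, "age"))
  expect_lt(abs(fit2$b - 1), 0.15)

  expect_error(fit_taylor(survey_table(data.frame(
    year = 2000, quarter = 1, subarea = c("a", "b", "c"), class_id = 0,
    cpue = c(1, 2, 3)), "age")), "insufficient")
})

test_that("the Taylor exponent maps onto the CV-abundance direction", {
  expect_equal(cv_abundance_direction(1.5), "negative")
  expect_equal(cv_abundance_direction(2.5), "positive")
  expect_equal(cv_abundance_direction(2), "neutral")
})
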