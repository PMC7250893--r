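test_that("delay embedding enumerates lagged coordinates correctly", {
  sm <- lag_embed(c(1, 2, 3, 4), E = 2)
  expect_equal(sm$states, cbind(c(2, 3, 4), c(1, 2, 3)))
  expect_equal(sm$target, c(3, 4, NA))
  e1 <- lag_embed(c(5, 6, 7, 8), E = 1)
  expect_equal(as.numeric(e1$states), c(5, 6, 7, 8))
  # one interior missing value at E = 3 removes exactly the 3 windows touching it
  x <- seq_len(12); x[6] <- NA
  sm3 <- lag_embed(x, E = 3)
  expect_equal(nrow(sm3$states), (12 - 3 + 1) - 3)
  expect_false(6 %in% c(sm3$states))
})

test_that("the embedding row-count formula holds across (n, E, tau)", {
  set.seed(10)
  for (i in 1:30) {
    E <- sample(1:5, 1); tau <- sample(1:3, 1)
    n <- sample((E * tau + 4):60, 1)
    sm <- lag_embed(rnorm(n), E, tau)
    expect_equal(nrow(sm$states), n - (E - 1) * tau,
                 label = sprintf("n=%d E=%d tau=%d", n, E, tau))
    expect_equal(sum(!is.na(sm$target)), n - (E - 1) * tau - 1)
  }
  expect_error(lag_embed(rnorm(4), E = 4), "insufficient")
})

test_that("simplex projection forecasts deterministic dynamics and not noise", {
  x <- logistic_series(100, seed = 20)
  expect_gte(simplex_forecast(x, 2)$rho, 0.95)
  # a repeated period-4 cycle is perfectly predictable
  cyc <- rep(c(0.1, 0.9, 0.3, 0.6), 10)
  expect_gte(simplex_forecast(cyc, 2)$rho, 0.999)
  # iid noise is not
  set.seed(21)
  rhos <- replicate(5, simplex_forecast(rnorm(100), 2)$rho)
  expect_lt(median(abs(rhos)), 0.3)
  expect_error(simplex_forecast(rep(1, 50), 2), "degenerate")
})

test_that("simplex skill degrades monotonically with observation noise", {
  base <- logistic_series(200, seed = 22)
  rho <- vapply(c(0, 0.1, 0.3, 0.5), function(s) {
    set.seed(23)
    simplex_forecast(base + rnorm(200, 0, s), 2)$rho
  }, 1)
  expect_true(all(diff(rho) < 0.02))  # monotone within simulation error
})

test_that("select_E picks small dimensions for low-dimensional maps", {
  for (seed in 24:26) {
    x <- logistic_series(100, noise = 0.05, seed = seed)
    se <- select_E(x)
    expect_lte(se$E_star, 4)  # attractor dimension is small
    expect_false(se$low_skill)
  }
  set.seed(25)
  sew <- select_E(rnorm(100))
  expect_true(sew$low_skill)
  # single-candidate grid
  expect_equal(select_E(logistic_series(60, seed = 26), E_max = 1)$E_star, 1)
})

test_that("brute-force oracle reproduces simplex predictions", {
  set.seed(30)
  for (n in c(40, 120)) {
    x <- as.numeric(arima.sim(list(ar = 0.6), n))
    sm <- lag_embed(x, 3)
    fc <- spatcv:::forecastable(sm)
    fast <- simplex_forecast(x, 3)$predictions
    slow <- oracle_simplex(fc$states, fc$target, 4)
    expect_lt(max(abs(fast - slow)), 1e-12)
  }
})

test_that("brute-force oracle reproduces cross-map predictions", {
  set.seed(31)
  sys <- logistic_pair(0.35, n = 120, seed = 31)
  E <- 2
  su <- spatcv:::ccm_setup(sys$series$y, sys$series$x, E, lag = 0)
  for (L in c(10, 60, su$n)) {
    lib <- sample.int(su$n, L)
    fast <- as.numeric(spatcv:::cpp_cross_map_rho(su$D, su$cause, list(lib),
                                                  E + 1L))
    sm <- lag_embed(sys$series$y, E)
    slow <- oracle_cross_map(sm$states, su$cause, sort(lib), E + 1)
    expect_lt(abs(fast - slow), 1e-12, label = paste("L =", L))
  }
})

test_that("S-map at theta = 0 equals the global least-squares solution", {
  set.seed(32)
  for (i in 1:10) {
    E <- sample(1:4, 1)
    m <- sample((E + 6):60, 1)
    X <- matrix(rnorm(m * E), m, E)
    y <- rnorm(m)
    sm <- structure(list(states = X, target = y, time = seq_len(m),
                         E = E, tau = 1L, var_names = paste0("v", 1:E)),
                    class = "state_matrix")
    mod <- smap_solve(sm, theta = 0, exclude_target = FALSE)
    ols <- unname(coef(lm(y ~ X)))
    expect_lt(max(abs(sweep(mod$coefficients, 2, ols))), 1e-8)
  }
})

test_that("S-map weights are 1 at distance zero and decay with distance", {
  d <- seq(0, 5, by = 0.5)
  w <- exp(-2 * d / mean(d))
  expect_equal(w[1], 1)
  expect_true(all(diff(w) < 0))
})

test_that("S-map matches its R oracle for theta > 0", {
  set.seed(33)
  X <- matrix(rnorm(80), 40, 2)
  y <- 0.4 * X[, 1] - 0.7 * X[, 2] + rnorm(40, 0, 0.1)
  sm <- structure(list(states = X, target = y, time = 1:40, E = 2L, tau = 1L,
                       var_names = c("a", "b")), class = "state_matrix")
  for (theta in c(0.5, 2, 8)) {
    mod <- smap_solve(sm, theta)
    ora <- oracle_smap(X, y, theta)
    expect_lt(max(abs(mod$coefficients - ora$coefficients)), 1e-10)
    expect_lt(max(abs(mod$predictions - ora$predictions)), 1e-10)
  }
})

test_that("S-map recovers the Jacobian of a linear stochastic system", {
  A <- matrix(c(0.5, 0.3, 0, 0), 2, 2)  # x(t+1) = 0.5 x(t) + 0.3 y(t) + eps
  dl <- matrix(c(0L, 1L, 0L, 0L), 2, 2)
  tr <- coupled_system_truth("var", A, dl, noise_sd = 1,
                             var_names = c("x", "y"))
  sys <- gen_coupled_system(tr, n = 500, seed = 34)
  sm <- multi_embed(sys$series$x, list(sys$series$y), lags = 0L,
                    names = "y", target_name = "x")
  mod <- smap_solve(sm, theta = 0)
  cm <- colMeans(mod$coefficients)
  expect_lt(abs(cm[["x"]] - 0.5), 0.1)
  expect_lt(abs(cm[["y"]] - 0.3), 0.1)
})

test_that("theta tuning prefers state-dependent models only when warranted", {
  # linear system: skill profile flat or best at small theta
  A <- matrix(c(0.6, 0.2, 0, 0), 2, 2)
  dl <- matrix(c(0L, 1L, 0L, 0L), 2, 2)
  sys <- gen_coupled_system(coupled_system_truth("var", A, dl, noise_sd = 1,
                                                 var_names = c("x", "y")),
                            n = 300, seed = 35)
  sm <- multi_embed(sys$series$x, list(sys$series$y), 0L, "y", "x")
  best <- tune_theta(sm, 0:8)
  expect_lt(best$rho_by_theta[9] - best$rho_by_theta[1], 0.05)
  # single-element grid contract
  one <- tune_theta(sm, 0)
  expect_equal(one$theta, 0)
  # chaotic map: nonlinear weighting must help
  x <- logistic_series(300, noise = 0.05, seed = 36)
  smx <- lag_embed(x, 2)
  bx <- tune_theta(smx, 0:8)
  expect_gt(bx$theta, 0)
})

test_that("degenerate geometry is reported", {
  sm <- structure(list(states = matrix(1, 10, 2), target = rnorm(10),
                       time = 1:10, E = 2L, tau = 1L,
                       var_names = c("a", "b")), class = "state_matrix")
  expect_error(smap_solve(sm, 1), "degenerate geometry")
})
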