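#' Specify a coupled dynamical system with known causal structure
#'
#' Ground-truth harness for validating the cross-mapping and S-map
#' estimators.  `adjacency[i, j]` is the strength with which variable i
#' drives variable j; `delays[i, j]` is the corresponding delay in steps,
#' measured at observation time: the effect at time t reflects the cause at
#' time t - delay (delay 0 = contemporaneous).
#'
#' Map types: `"logistic"` — coupled logistic maps
#' `x_j(t) = x_j(t-1) (r_j - r_j x_j(t-1) - sum_i beta_ij x_i(t - d_ij))`,
#' bounded in (0, 1) by parameterization (no clipping; divergence is an
#' error); `"var"` — a linear vector autoregression
#' `x_j(t) = beta_jj x_j(t - 1) + sum_{i != j} beta_ij x_i(t - d_ij) + eps`,
#' with Gaussian process noise `noise_sd` (so a standard VAR lag-1 coupling
#' is `d = 1`).  For logistic maps `noise_sd` is added as observation noise
#' so the dynamics stay bounded.
#'
#' @param map_type `"logistic"` or `"var"`.
#' @param adjacency square matrix of coupling strengths (cause in rows,
#'   effect in columns; diagonal ignored).
#' @param delays integer matrix of per-edge delays (default all 0).
#' @param noise_sd noise standard deviation (see above).
#' @param r per-variable logistic growth rates (default 3.8, 3.5, 3.7, ...).
#' @param var_names variable names.
#' @return a `coupled_system_truth` list.
#' @export
coupled_system_truth <- function(map_type = c("logistic", "var"),
                                 adjacency, delays = NULL, noise_sd = 0,
                                 r = NULL, var_names = NULL) {
  map_type <- match.arg(map_type)
  adjacency <- as.matrix(adjacency)
  V <- nrow(adjacency)
  stopifnot(ncol(adjacency) == V, V >= 1, noise_sd >= 0)
  if (is.null(delays)) delays <- matrix(0L, V, V)
  delays <- matrix(as.integer(delays), V, V)
  stopifnot(all(delays >= 0))
  if (is.null(var_names))
    var_names <- if (V <= 3) c("x", "y", "z")[seq_len(V)] else paste0("v", seq_len(V))
  if (is.null(r)) r <- rep(c(3.8, 3.5, 3.7, 3.6), length.out = V)
  structure(list(map_type = map_type, adjacency = adjacency,
                 delays = delays, noise_sd = noise_sd, r = r,
                 var_names = var_names, V = V),
            class = "coupled_system_truth")
}

#' Realize a coupled system
#'
#' Simulates the system after a burn-in and returns the observed series
#' together with the truth record for recovery scoring.  Contemporaneous
#' (delay-0) couplings are resolved by updating variables in index order, so
#' delay-0 edges must point from lower- to higher-indexed variables.
#'
#' @param truth a [coupled_system_truth()].
#' @param n number of observed time steps (>= 50).
#' @param seed integer RNG seed.
#' @param burn number of discarded initial steps.
#' @return list with `series` (named list of numeric vectors) and `truth`.
#' @export
#' @examples
#' A <- matrix(c(0, 0, 0.3, 0), 2, 2)  # A[1, 2]: x drives y
#' sys <- gen_coupled_system(coupled_system_truth("logistic", A), n = 100, seed = 1)
#' names(sys$series)
gen_coupled_system <- function(truth, n, seed = 1L, burn = 300L) {
  stopifnot(inherits(truth, "coupled_system_truth"), n >= 50)
  set.seed(seed)
  V <- truth$V
  A <- truth$adjacency
  Dl <- truth$delays
  for (j in seq_len(V)) for (i in seq_len(V))
    if (i != j && A[i, j] != 0 && Dl[i, j] == 0 && i >= j)
      stop("parameter error: delay-0 coupling ", truth$var_names[i], " -> ",
           truth$var_names[j], " must run from a lower-indexed variable",
           call. = FALSE)
  maxd <- max(Dl) + 2L
  total <- n + burn + maxd
  X <- matrix(NA_real_, total, V)
  X[seq_len(maxd), ] <- if (truth$map_type == "logistic")
    runif(maxd * V, 0.2, 0.8) else rnorm(maxd * V, 0, 0.1)
  for (t in (maxd + 1L):total) {
    for (j in seq_len(V)) {
      drive <- 0
      for (i in seq_len(V)) if (i != j && A[i, j] != 0)
        drive <- drive + A[i, j] * X[t - Dl[i, j], i]
      if (truth$map_type == "logistic") {
        xp <- X[t - 1L, j]
        X[t, j] <- xp * (truth$r[j] - truth$r[j] * xp - drive)
      } else {
        X[t, j] <- A[j, j] * X[t - 1L, j] + drive + rnorm(1, 0, truth$noise_sd)
      }
    }
    if (any(!is.finite(X[t, ])) ||
        (truth$map_type == "logistic" && any(X[t, ] <= 0 | X[t, ] >= 1))) {
      bad <- which(!is.finite(X[t, ]) |
                     (if (truth$map_type == "logistic")
                        X[t, ] <= 0 | X[t, ] >= 1 else FALSE))[1]
      stop("parameter error: divergent trajectory for variable '",
           truth$var_names[bad], "'; couplings into it are too strong",
           call. = FALSE)
    }
    if (truth$map_type == "var" && any(abs(X[t, ]) > 1e6))
      stop("parameter error: divergent trajectory (VAR unstable)", call. = FALSE)
  }
  obs <- X[(burn + maxd + 1L):total, , drop = FALSE]
  if (truth$map_type == "logistic" && truth$noise_sd > 0)
    obs <- obs + matrix(rnorm(n * V, 0, truth$noise_sd), n, V)
  series <- setNames(lapply(seq_len(V), function(j) obs[, j]),
                     truth$var_names)
  list(series = series, truth = truth)
}

#' Canonical unidirectionally coupled logistic pair
#'
#' Convenience wrapper: variable `x` (growth rate 3.8) drives variable `y`
#' (growth rate 3.5) with the given strength and delay; there is no
#' feedback.
#'
#' @param coupling coupling strength of x into y.
#' @param delay delay in steps (observation-time convention).
#' @param n series length.
#' @param seed RNG seed.
#' @param noise_sd observation noise SD.
#' @return list with `series` (`x`, `y`) and `truth`.
#' @export
logistic_pair <- function(coupling = 0.3, delay = 0L, n = 200L, seed = 1L,
                          noise_sd = 0) {
  A <- matrix(0, 2, 2)
  A[1, 2] <- coupling
  Dl <- matrix(0L, 2, 2)
  Dl[1, 2] <- as.integer(delay)
  tr <- coupled_system_truth("logistic", A, Dl, noise_sd = noise_sd,
                             var_names = c("x", "y"))
  gen_coupled_system(tr, n, seed)
}
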