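#' Specify an age-structured spatial survey scenario
#'
#' Ground-truth generator for end-to-end validation: an age-structured
#' population evolves through recruitment, aging, and natural plus
#' age-selective fishing mortality on a biquarterly (Q1/Q3) grid;
#' individuals distribute over subareas by age-specific Gaussian habitat
#' preference modulated by a temperature field; observed CPUE is the local
#' expected catch under multiplicative lognormal observation noise.
#'
#' Aggregation tendency (Taylor's exponent) is controlled by
#' `width_exponent` (gamma): preference widths scale as
#' `(N_tot / N_ref)^gamma`, so gamma < 0 concentrates the population when
#' abundance rises (b > 2) and gamma > 0 spreads it (b < 2); gamma = 0
#' leaves the spatial pattern abundance-invariant (b = 2 up to noise).
#'
#' Presets: `"baseline"` (constant moderate fishing), `"age_truncation"`
#' (fishing ramps up with old-age-selective removal, eroding age diversity;
#' older ages occupy the broader habitats, so truncation concentrates the
#' population and raises spatial CV), `"taylor_low"` / `"taylor_high"`
#' (shared-habitat regimes whose width exponents are calibrated to Taylor
#' exponents near 1.5 / 2.5), and
#' `"homogeneous"` (uniform preferences, constant temperature, no noise:
#' spatial CV is 0).
#'
#' @param preset scenario preset name.
#' @param n_years,start_year,n_subareas,n_ages survey dimensions.
#' @param recruit_mean,recruit_sd,ricker_K recruitment: lognormal
#'   fluctuations around a Ricker-damped mean.
#' @param recruit_ar year-to-year autocorrelation of the recruitment
#'   anomaly (environmentally driven recruitment regimes; 0 = iid).
#' @param nat_mort natural mortality per year.
#' @param fishing_F yearly fishing mortality (scalar or length `n_years`).
#' @param selectivity per-age fishing selectivity.
#' @param pref_centers,pref_widths per-age habitat preference centers and
#'   widths on the unit habitat axis (`Inf` width = uniform).
#' @param width_exponent Taylor-b control gamma (see above).
#' @param diversity_spread delta >= 0: habitat occupancy responds to age
#'   diversity, all preference widths scaling as
#'   `(S(t) / ln(n_ages))^delta` where `S` is an exponentially smoothed
#'   Shannon diversity (rate 0.4 per half-year, i.e. the spatial footprint
#'   integrates roughly the past year of age structure).  A diverse age
#'   structure thus broadens the population's distribution (the hypothesis
#'   that age truncation elevates spatial variability); 0 disables the
#'   pathway.
#' @param temp_base,temp_trend,temp_spatial_amp,temp_noise_sd,temp_tolerance
#'   temperature field: base (deg C), warming trend per year, spatial
#'   gradient amplitude, haul-level noise SD, and thermal tolerance width.
#' @param temp_cycle_amp amplitude (deg C) of a deterministic, aperiodic
#'   multiannual climate signal in the spatial-mean temperature (a smoothed
#'   chaotic recursion, so the signal is forecastable from its own past but
#'   has no fixed period); 0 disables it.
#' @param catchability CPUE per unit abundance.
#' @param obs_noise_sd lognormal observation noise SD (log scale).
#' @param seed RNG seed.
#' @param burn_years discarded spin-up years.
#' @return a `survey_scenario` list.
#' @export
survey_scenario <- function(preset = c("baseline", "age_truncation",
                                       "taylor_low", "taylor_high",
                                       "homogeneous"),
                            n_years = 25L, start_year = 1991L,
                            n_subareas = 40L, n_ages = 6L,
                            recruit_mean = 100, recruit_sd = 0.5,
                            recruit_ar = 0, ricker_K = 400,
                            nat_mort = 0.3,
                            fishing_F = 0.2,
                            selectivity = NULL,
                            pref_centers = NULL, pref_widths = NULL,
                            width_exponent = 0, diversity_spread = 0,
                            temp_base = 8, temp_trend = 0.04,
                            temp_spatial_amp = 1.5, temp_noise_sd = 0.3,
                            temp_tolerance = 4, temp_cycle_amp = 0,
                            catchability = 1, obs_noise_sd = 0.3,
                            seed = 1L, burn_years = 10L) {
  preset <- match.arg(preset)
  A <- as.integer(n_ages)
  sc <- list(preset = preset, n_years = as.integer(n_years),
             start_year = as.integer(start_year),
             n_subareas = as.integer(n_subareas), n_ages = A,
             recruit_mean = recruit_mean, recruit_sd = recruit_sd,
             recruit_ar = recruit_ar, ricker_K = ricker_K,
             nat_mort = nat_mort,
             fishing_F = fishing_F, selectivity = selectivity,
             pref_centers = pref_centers, pref_widths = pref_widths,
             width_exponent = width_exponent,
             diversity_spread = diversity_spread,
             temp_base = temp_base, temp_trend = temp_trend,
             temp_spatial_amp = temp_spatial_amp,
             temp_noise_sd = temp_noise_sd, temp_tolerance = temp_tolerance,
             temp_cycle_amp = temp_cycle_amp,
             catchability = catchability, obs_noise_sd = obs_noise_sd,
             seed = as.integer(seed), burn_years = as.integer(burn_years))
  mods <- switch(preset,
    baseline = list(),
    age_truncation = list(
      fishing_F = seq(0.2, 1.5, length.out = sc$n_years),
      selectivity = seq(0, 1, length.out = A),
      diversity_spread = 1.5,
      pref_centers = rep(0.5, A), pref_widths = rep(0.18, A),
      temp_tolerance = 1, temp_noise_sd = 0.15, temp_cycle_amp = 0.8,
      recruit_ar = 0.5, recruit_sd = 0.6),
    taylor_low = list(width_exponent = 0.21,
                      pref_centers = rep(0.5, A), pref_widths = rep(0.2, A),
                      ricker_K = 2000, recruit_sd = 0.7),
    taylor_high = list(width_exponent = -0.192,
                       pref_centers = rep(0.5, A), pref_widths = rep(0.2, A),
                       ricker_K = 2000, recruit_sd = 0.7),
    homogeneous = list(pref_widths = rep(Inf, A), temp_spatial_amp = 0,
                       temp_noise_sd = 0, temp_trend = 0, obs_noise_sd = 0,
                       recruit_sd = 0))
  sc[names(mods)] <- mods
  # user-facing call arguments override preset values
  user <- names(match.call())[-1]
  user <- setdiff(user, "preset")
  for (nm in intersect(user, names(mods)))
    sc[[nm]] <- get(nm)
  if (is.null(sc$selectivity))
    sc$selectivity <- rep(1, A)
  if (is.null(sc$pref_centers))
    sc$pref_centers <- (seq_len(A) - 0.5) / A
  if (is.null(sc$pref_widths) && !identical(preset, "homogeneous"))
    sc$pref_widths <- 0.12 * (0.5 + 1.5 * (seq_len(A) - 1) / max(A - 1, 1))
  if (length(sc$fishing_F) == 1)
    sc$fishing_F <- rep(sc$fishing_F, sc$n_years)
  stopifnot(length(sc$fishing_F) == sc$n_years,
            length(sc$selectivity) == A,
            length(sc$pref_centers) == A, length(sc$pref_widths) == A,
            all(sc$fishing_F >= 0), all(sc$selectivity >= 0),
            sc$obs_noise_sd >= 0, sc$recruit_sd >= 0, sc$nat_mort >= 0)
  structure(sc, class = "survey_scenario")
}

# One half-year demographic step: survival, fractional aging (classes have
# exponential residence with a one-year mean, so composition has no
# within-year sawtooth), and settlement of recruits into the first class.
demographic_step <- function(N, Fv, sc, anomaly = 0) {
  N <- N * exp(-(sc$nat_mort + sc$selectivity * Fv) / 2)
  out <- 0.5 * N  # transfer to the next class (the oldest exit)
  N <- N - out + c(0, out[-length(N)])
  N[1] <- N[1] + 0.5 * sc$recruit_mean * exp(-sum(N) / sc$ricker_K) *
    exp(anomaly - sc$recruit_sd^2 / 2)
  N
}

# Deterministic equilibrium population under the first year's mortality
# (reference scale for the width-abundance feedback).
equilibrium_N <- function(sc) {
  N <- rep(sc$recruit_mean / 2, sc$n_ages)
  for (i in 1:400) N <- demographic_step(N, sc$fishing_F[1], sc)
  N
}

#' Realize a survey scenario
#'
#' Simulates the scenario and returns the survey tables, environmental
#' series, and a truth record of the realized (noise-free expected) metrics
#' for recovery scoring.
#'
#' @param scenario a [survey_scenario()].
#' @return list with `age_table` and `length_table` ([survey_table()]s; the
#'   length view relabels the age classes, which leaves all totals-based
#'   metrics unchanged), `env` (named list: biquarterly `temperature`,
#'   `temperature_cv`, `climate_index`; yearly `fishing_mortality`), and
#'   `truth` (per-step data frame: `abundance`, `shannon`,
#'   `spatial_cv_noisefree`, `spatial_cv` expected under observation noise,
#'   plus the scenario).
#' @export
#' @examples
#' sim <- gen_survey(survey_scenario("baseline", n_years = 5, seed = 2))
#' head(sim$truth$metrics)
gen_survey <- function(scenario) {
  stopifnot(inherits(scenario, "survey_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  A <- sc$n_ages; S <- sc$n_subareas
  n_steps <- 2L * sc$n_years
  burn_steps <- 2L * sc$burn_years
  F_by_year <- c(rep(sc$fishing_F[1], sc$burn_years), sc$fishing_F)
  h <- (seq_len(S) - 0.5) / S
  N_eq <- equilibrium_N(sc)
  N_ref <- sum(N_eq)
  Topt <- sc$temp_base + sc$temp_spatial_amp * (sc$pref_centers - 0.5)

  # --- population dynamics over burn + observed steps
  N <- N_eq
  total_steps <- burn_steps + n_steps
  N_mat <- matrix(NA_real_, total_steps, A)
  ru <- 0  # AR(1) recruitment anomaly on the log scale, per year
  ru_sd <- sc$recruit_sd * sqrt(1 - sc$recruit_ar^2)
  for (t in seq_len(total_steps)) {
    yr <- (t - 1L) %/% 2L + 1L
    if (t %% 2L == 1L) {  # yearly recruitment anomaly
      ru <- sc$recruit_ar * ru +
        if (sc$recruit_sd > 0) rnorm(1, 0, max(ru_sd, 1e-12)) else 0
    }
    N <- demographic_step(N, F_by_year[yr], sc, ru)
    N_mat[t, ] <- N
  }
  N_obs <- N_mat[(burn_steps + 1L):total_steps, , drop = FALSE]
  if (all(N_obs <= 1e-12))
    warning("scenario warning: population effectively extinct", call. = FALSE)

  # --- environment on the observed grid
  years <- sc$start_year + (seq_len(n_steps) - 1L) %/% 2L
  q3 <- (seq_len(n_steps) - 1L) %% 2L == 1L
  year_frac <- (seq_len(n_steps) - 1L) / 2
  grad <- sc$temp_spatial_amp * (h - 0.5)
  # deterministic aperiodic climate forcing: chaotic kernel, AR-smoothed
  ck <- numeric(n_steps + 20L)
  ck[1] <- runif(1, 0.2, 0.8)
  for (t in 2:length(ck)) ck[t] <- 3.9 * ck[t - 1] * (1 - ck[t - 1])
  cycle <- as.numeric(stats::filter(ck - mean(ck), 0.5,
                                    method = "recursive"))[-(1:20)]
  cycle <- sc$temp_cycle_amp * 2.8 * cycle
  Tfield <- matrix(sc$temp_base, n_steps, S)
  Tfield <- Tfield + outer(sc$temp_trend * year_frac + cycle, rep(1, S)) +
    outer(rep(1, n_steps), grad) +
    matrix(rnorm(n_steps * S, 0, sc$temp_noise_sd), n_steps, S) +
    0.5 * q3  # mild seasonal offset
  climate <- numeric(n_steps)
  climate[1] <- rnorm(1)
  for (t in 2:n_steps) climate[t] <- 0.8 * climate[t - 1] + rnorm(1, 0, 0.6)

  # --- spatial distribution and observed CPUE
  tau2 <- if (sc$obs_noise_sd > 0) exp(sc$obs_noise_sd^2) - 1 else 0
  cpue <- array(0, c(n_steps, S, A))
  truth <- data.frame(step = seq_len(n_steps) - 1L, year = years,
                      quarter = ifelse(q3, "Q3", "Q1"),
                      abundance = NA_real_, shannon = NA_real_,
                      spatial_cv_noisefree = NA_real_,
                      spatial_cv = NA_real_)
  sh_smooth <- NA_real_  # integrated diversity behind the occupancy response
  for (t in seq_len(n_steps)) {
    Ntot <- sum(N_obs[t, ])
    p_t <- N_obs[t, ] / Ntot
    sh_t <- -sum(p_t[p_t > 0] * log(p_t[p_t > 0]))
    sh_smooth <- if (t == 1L) sh_t else 0.6 * sh_smooth + 0.4 * sh_t
    wmul <- if (sc$width_exponent == 0) 1 else (Ntot / N_ref)^sc$width_exponent
    if (sc$diversity_spread > 0)
      wmul <- wmul * (max(sh_smooth, 0.05) / log(A))^sc$diversity_spread
    X <- matrix(0, S, A)
    for (a in seq_len(A)) {
      w <- sc$pref_widths[a] * wmul
      g <- if (is.infinite(w)) rep(1, S)
           else exp(-(h - sc$pref_centers[a])^2 / (2 * w^2))
      g <- g * exp(-(Tfield[t, ] - Topt[a])^2 / (2 * sc$temp_tolerance^2))
      g <- g / sum(g)
      X[, a] <- sc$catchability * N_obs[t, a] * g
    }
    noise <- if (sc$obs_noise_sd > 0)
      matrix(exp(rnorm(S * A, 0, sc$obs_noise_sd) - sc$obs_noise_sd^2 / 2), S, A)
      else 1
    cpue[t, , ] <- X * noise
    tot_s <- rowSums(X)
    mu <- mean(tot_s); vx <- var(tot_s)
    truth$abundance[t] <- sum(X)
    truth$shannon[t] <- sh_t
    truth$spatial_cv_noisefree[t] <- if (mu > 0) sqrt(vx) / mu else NA_real_
    v_obs <- vx + mean(rowSums(X^2)) * tau2  # independent noise per class
    truth$spatial_cv[t] <- if (mu > 0) sqrt(v_obs) / mu else NA_real_
  }

  rec <- expand.grid(subarea = sprintf("g%02d", seq_len(S)),
                     class_id = seq_len(A) - 1L,
                     step = seq_len(n_steps), KEEP.OUT.ATTRS = FALSE)
  rec <- rec[order(rec$step, rec$subarea, rec$class_id), ]
  df <- data.frame(year = years[rec$step],
                   quarter = ifelse(q3[rec$step], 3L, 1L),
                   subarea = as.character(rec$subarea),
                   class_id = rec$class_id,
                   cpue = cpue[cbind(rec$step, match(rec$subarea,
                                                     sprintf("g%02d", seq_len(S))),
                               rec$class_id + 1L)])
  age_table <- survey_table(df, "age")
  dfl <- df
  dfl$class_id <- paste0("L", dfl$class_id)
  length_table <- survey_table(dfl, "length")

  tmean <- rowMeans(Tfield)
  tcv <- apply(Tfield, 1, sd) / tmean
  steps0 <- seq_len(n_steps) - 1L
  env <- list(
    temperature = quarter_series(steps0, tmean, years,
                                 ifelse(q3, "Q3", "Q1"), name = "temperature"),
    temperature_cv = quarter_series(steps0, tcv, years,
                                    ifelse(q3, "Q3", "Q1"),
                                    name = "temperature_cv"),
    climate_index = quarter_series(steps0, climate, years,
                                   ifelse(q3, "Q3", "Q1"),
                                   name = "climate_index"),
    fishing_mortality = quarter_series(sc$start_year + seq_len(sc$n_years) - 1L,
                                       sc$fishing_F,
                                       year = sc$start_year + seq_len(sc$n_years) - 1L,
                                       name = "fishing_mortality",
                                       grid = "yearly"))
  list(age_table = age_table, length_table = length_table, env = env,
       truth = list(metrics = truth, scenario = sc, N = N_obs,
                    N_ref = N_ref))
}
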