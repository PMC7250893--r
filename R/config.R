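#' Analysis configuration
#'
#' Collects the tunable constants of the pipeline in one validated object.
#' Defaults follow the protocol used throughout the package: embedding
#' dimensions scanned from 1 to `E_max`, S-map nonlinearity tuned over
#' `theta_grid`, cross-map lags up to `lag_max_quarterly` biquarterly steps
#' (or `lag_max_yearly` years for annual analyses), 200 cross-map replicates
#' with a 95% convergence pass rule at `alpha_ccm`, and a `min_grids`
#' spatial-coverage floor for survey quarters.
#'
#' @param E_max maximum embedding dimension scanned by simplex projection.
#' @param theta_grid candidate S-map nonlinearity parameters (all >= 0).
#' @param lag_max_quarterly maximum cross-map lag, in biquarterly steps.
#' @param lag_max_yearly maximum cross-map lag for yearly analyses, in years.
#' @param n_ccm_replicates number of random-library CCM replicates.
#' @param ccm_pass_fraction fraction of replicates that must pass both
#'   convergence tests for a causal verdict (in (0, 1]).
#' @param alpha_ccm significance level of the per-replicate convergence tests.
#' @param alpha_smap significance level of the S-map skill test.
#' @param alpha_trend significance level of the linear detrending test.
#' @param min_grids minimum number of surveyed subareas per retained quarter.
#' @param L_grid_size number of library sizes in the cross-map convergence scan.
#' @param rng_seed integer seed used by [run_pipeline()].
#'
#' @return a `run_config` list.
#' @export
#' @examples
#' cfg <- run_config(n_ccm_replicates = 50)
#' cfg$ccm_pass_fraction
run_config <- function(E_max = 10L,
                       theta_grid = 0:8,
                       lag_max_quarterly = 8L,
                       lag_max_yearly = 4L,
                       n_ccm_replicates = 200L,
                       ccm_pass_fraction = 0.95,
                       alpha_ccm = 0.05,
                       alpha_smap = 0.10,
                       alpha_trend = 0.05,
                       min_grids = 10L,
                       L_grid_size = 15L,
                       rng_seed = 1L) {
  stopifnot(E_max >= 2, n_ccm_replicates >= 1, L_grid_size >= 3,
            all(theta_grid >= 0), lag_max_quarterly >= 0, lag_max_yearly >= 0,
            min_grids >= 1)
  for (a in c(ccm_pass_fraction, alpha_ccm, alpha_smap, alpha_trend))
    if (!(a > 0 && a <= 1)) stop("thresholds must lie in (0, 1]", call. = FALSE)
  structure(list(E_max = as.integer(E_max),
                 theta_grid = as.numeric(theta_grid),
                 lag_max_quarterly = as.integer(lag_max_quarterly),
                 lag_max_yearly = as.integer(lag_max_yearly),
                 n_ccm_replicates = as.integer(n_ccm_replicates),
                 ccm_pass_fraction = ccm_pass_fraction,
                 alpha_ccm = alpha_ccm,
                 alpha_smap = alpha_smap,
                 alpha_trend = alpha_trend,
                 min_grids = as.integer(min_grids),
                 L_grid_size = as.integer(L_grid_size),
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}
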