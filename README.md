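# spatcv

Causal drivers of fish population spatial variability, quantified with
empirical dynamic modeling (EDM).

## The problem

A fish population that is spread broadly and evenly across its habitat can
absorb local environmental shocks; one concentrated in a few cells cannot.
The **spatial variability** of a population — the coefficient of variation
(CV) of its survey abundance index (CPUE, individuals per hauling hour)
across spatial grid cells — is therefore a stability indicator, and the
question of what drives it (age structure, abundance, temperature,
fishing) is a causal question about a nonlinear, feedback-ridden system.
Correlation-based tools are unreliable in such systems, so `spatcv`
implements the state-space-reconstruction toolkit from first principles:

* **Survey statistics** from long-format CPUE tables: per-quarter spatial
  CV (`spatial_cv`), Shannon age diversity (`age_diversity`), total
  abundance (`total_abundance`), with the standard coverage filters
  (`filter_survey`) and preprocessing (`preprocess_series`).
* **Taylor's power law** `V = aM^b` across quarters (`fit_taylor`), and
  the implied direction of the CV-abundance relation via
  `CV = a'M^(b/2-1)`: negative for `b < 2`, positive for `b > 2`
  (`cv_abundance_direction`).
* **Simplex projection** for embedding-dimension selection
  (`simplex_forecast`, `select_E`).
* **Convergent cross mapping (CCM)** with the full convergence protocol —
  library-size scan, one-sided Kendall and t tests per replicate,
  200 replicates with a 95% pass rule, and lag scanning
  (`ccm_with_replicates`, `lag_scan`).
* **Multivariate S-map** estimation of time-varying influence strengths
  (local Jacobians) with SVD-regularized weighted solves
  (`smap_solve`, `tune_theta`, `estimate_influence`), sensitivity
  re-embeddings (`sensitivity_combinations`), and the yearly
  fishing-mortality sub-analysis (`fishing_analysis`).
* **Synthetic data with known causal structure** for validation: coupled
  logistic/VAR systems (`gen_coupled_system`) and an age-structured
  spatial survey simulator (`gen_survey`).

The compute-heavy neighbour searches and weighted solves are in C++
(Rcpp/RcppArmadillo); the test suite checks them against brute-force R
implementations.

## Worked example

Simulate a 25-year survey in which ramping, old-age-selective fishing
truncates the age structure, and ask the pipeline who drives the spatial
CV:

```r
library(spatcv)

cfg <- run_config(rng_seed = 1, n_ccm_replicates = 100, L_grid_size = 8)
sim <- gen_survey(survey_scenario("age_truncation", seed = 1))
report <- run_pipeline(cfg, sim$age_table, sim$length_table,
                       sim$env[c("temperature", "temperature_cv",
                                 "climate_index")])
print(report)
```

Output from this exact call:

```
spatial-variability attribution report (E* = 10)
CCM scan age_diversity -> spatial_cv: causal, best lag 4, rho = 0.9123
CCM scan abundance -> spatial_cv: causal, best lag 8, rho = 0.9289
CCM scan temperature -> spatial_cv: n.s.
CCM scan temperature_cv -> spatial_cv: n.s.
CCM scan climate_index -> spatial_cv: causal, best lag 8, rho = 0.7935
S-map attribution for 'spatial_cv': theta = 0, rho = 0.8020, p = 2.158e-12 (significant)
mean influences:
    abundance age_diversity climate_index
   0.07798295   -0.87405987    0.12084842
Taylor power law: V = 1.263 * M^1.993  (r^2 = 0.881, n = 50)
implied CV-abundance direction: negative
```

Reading it: the manifold of the spatial-CV series cross-maps age
diversity with skill 0.91 and passes the convergence protocol (a causal
verdict), and the tuned S-map attributes a mean influence of **-0.87** to
age diversity — eroding age structure raises spatial variability, which
is exactly the mechanism built into this scenario.  The fitted Taylor
exponent (b = 1.99, essentially the neutral point 2, as this scenario
imposes no abundance-aggregation feedback) implies spatial variability is
nearly independent of abundance here.
`fit_taylor`, `lag_scan`, `estimate_influence` and the rest are equally
usable on your own `read_survey_table()` data; see the vignette
(`vignettes/spatial-variability-edm.Rmd`) for the model and every
convention.

A thin command-line wrapper over the same functions is in
`inst/cli/spatcv-cli.R` (subcommands `simulate`, `metrics`, `ccm`, `smap`,
`taylor`, `report`).

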