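## Shared fixtures. The heavy default-scale compendium + NMF fit is built once
## per test run and memoised; small fixtures are rebuilt cheaply.

.fixture_env <- new.env(parent = emptyenv())

## Default-scale study conditions: seed 1, rank = number of planted factors,
## 30 restarts. Used by the acceptance suite.
full_fixture <- function() {
  if (!is.null(.fixture_env$full)) return(.fixture_env$full)
  comp <- simulate_compendium(sim_config(seed = 1))
  model <- nmf_fit(log_tpm(comp$expression), k = nrow(comp$truth$H_true),
                   n_restarts = 30, seed = 1)
  cyt <- cyt_score(comp$expression)
  attribution <- attribute_compartments(model, comp$clinical,
                                        comp$truth$subtype, cyt)
  model <- normalize_fractions(
    model, attribution$factor[startsWith(attribution$label, "cohort_specific")])
  model$attribution <- attribution
  .fixture_env$full <- list(comp = comp, model = model, cyt = cyt)
  .fixture_env$full
}

## Small compendium for cheap module tests.
small_comp <- function(seed = 2) {
  simulate_compendium(sim_config(
    seed = seed, n_tumor_A = 30L, n_tumor_B = 30L, n_adjacent = 8L,
    n_healthy = 6L, n_cell_line = 8L, markers_per_factor = 10L,
    n_background_genes = 60L))
}

## Map fitted factor names to planted factor names via Hungarian matching.
fitted_to_truth <- function(model, truth) {
  m <- match_factors(model$H, truth$H_true)
  stats::setNames(rownames(truth$H_true)[m$pairs$ref],
                  rownames(model$H)[m$pairs$fit])
}
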