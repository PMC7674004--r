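# Shared fixtures, built in code.

# Small, fast phantom: quiet background, no noise unless asked.
quiet_config <- function(noise_sd = 0, seed = 1L, ...) {
  phantom_config(noise_sd = noise_sd, seed = seed, ...)
}

# Uniform constant-field phantom: background 100 everywhere, no tree.
flat_config <- function(seed = 1L, laterality = "OD") {
  phantom_config(background = stats::setNames(rep(100, 6), octa_layers()),
                 macro_tree = NULL, noise_sd = 0, fovea_disc_angle = 0,
                 laterality = laterality, seed = seed)
}

# Zero effect map / single- and multi-feature deficits.
zero_effect <- function() {
  stats::setNames(rep(0, 42), feature_columns())
}

deficit_effect <- function(features, shift) {
  em <- zero_effect()
  em[features] <- shift
  em
}

# Reduced linear-SVM grid for desk-scale nested runs (the package default
# grid is the full reference grid; tests scale the search down, not the data).
linear_grid <- function(C = c(0.01, 1)) {
  data.frame(kernel = "linear", C = C, gamma = NA_real_)
}

tiny_rf_grid <- function() {
  data.frame(n_trees = 25L, split_quality = "gini", bootstrap = TRUE,
             min_leaf_pct = 10, min_split_pct = 10, max_depth = Inf,
             stringsAsFactors = FALSE)
}

tiny_xgb_grid <- function() {
  data.frame(min_child_weight = 1, learning_rate = 0.1,
             min_loss_reduction = 0.1, subsample = 0.8, colsample = 0.8,
             min_leaf_pct = 10, max_depth = 5)
}

# Evaluate expr under a temporary seeded RNG state.
with_seed_local <- function(seed, expr) octamls:::with_seed(seed, expr)

# Binary diagnosis cohort with the glaucoma group one severity step away.
binary_cohort <- function(n_control = 20, n_glaucoma = 20,
                          effect_map = zero_effect(), seed = 1L, ...) {
  generate_cohort_feature_table(cohort_effect_spec(
    n_per_group = c(control = n_control, glaucoma = n_glaucoma),
    effect_map = effect_map, severity_steps = c(glaucoma = 1),
    seed = seed, ...))
}
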