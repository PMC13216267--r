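# Shared fixtures, built lazily once per test run and memoised.
# The model fixtures are the expensive ones (two 20-member process
# ensembles plus the FFC regressor); everything downstream (formulator,
# closed loop, acceptance) reuses them.

.tl_cache <- new.env(parent = emptyenv())

tl_memo <- function(key, build) {
  if (is.null(.tl_cache[[key]])) .tl_cache[[key]] <- build()
  .tl_cache[[key]]
}

tl_lib <- function() tl_memo("lib", function() synthetic_material_library())

noiseless <- function() plant_noise(0, 0, 0)

# 602-tablet noisy corpus: 86 random formulations x 7 pressures
tl_corpus <- function() tl_memo("corpus", function() {
  generate_training_corpus(tl_lib(), 86L, seq(100, 400, by = 50), seed = 42L)
})

tl_held_out <- c("API_E", "API_K")

tl_split <- function() tl_memo("split", function() {
  leave_api_out_split(tl_corpus()$records, tl_held_out)
})

tl_eps_ensemble <- function() tl_memo("eps_ens", function() {
  train_ensemble(tl_split()$train, "porosity", seed = 1L)
})

tl_sigma_ensemble <- function() tl_memo("sigma_ens", function() {
  train_ensemble(tl_split()$train, "log_tensile", seed = 2L)
})

tl_ffc_model <- function() tl_memo("ffc", function() {
  train_ffc_surrogate(tl_lib(), n = 400L, seed = 43L)
})

tl_models <- function() tl_memo("models", function() {
  corpus <- tl_corpus()
  ensemble_tablet_models(tl_eps_ensemble(), tl_sigma_ensemble(), tl_ffc_model(),
                         corpus$psd_basis, corpus$ard_basis)
})

r2_of <- function(y, pred) 1 - sum((y - pred)^2) / sum((y - mean(y))^2)

# a mid-strength demo formulation reused across PIBO/plant tests
tl_demo_formulation <- function() {
  make_formulation("API_C", 0.2, c(MCC_A = 0.5, LAC_A = 0.5))
}

# a hand-built ensemble whose members output fixed constants: weights are
# zero so only the output biases act. Exercises the prediction path with
# known member values.
constant_ensemble <- function(values, p = 3L) {
  members <- lapply(values, function(v) {
    list(W = list(matrix(0, 2, p), matrix(0, 1, 2)),
         b = list(rep(0, 2), v), ok = TRUE)
  })
  structure(list(members = members, n_members = length(values),
                 hidden = 2L, x_mean = rep(0, p), x_sd = rep(1, p),
                 y_mean = 0, y_sd = 1, seed = 0L, n_train = 10L),
            class = "ff_ensemble")
}
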