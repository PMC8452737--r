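# Shared fixtures.  Expensive artifacts (the reference phantom and models
# trained on it) are built once per test run and memoized, so several test
# files can reuse them without retraining.

.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a small, fast phantom for structural tests
small_phantom <- function(seed = 5) {
  generate_phantom(phantom_spec(width = 16, height = 16, d = 500,
                                n_regions = 3, peaks_per_region = 4,
                                shared_peaks = 3, seed = seed))
}

tiny_dataset <- function() {
  msi_dataset(mz = c(100, 150, 200, 250),
              intensities = rbind(c(0, 5, 1, 2), c(2, 0, 3, 1)),
              coords = cbind(1:2, 1L, 1L))
}

# the frozen reference phantom and its preprocessed (reduced + normalized)
# training data
ref_phantom <- function() {
  memoize("ref_phantom", generate_phantom(reference_phantom_spec()))
}

ref_training_data <- function() {
  memoize("ref_training", {
    ph <- ref_phantom()
    red <- reduce_to_local_maxima(ph$dataset)
    list(norm = tic_normalize(red$dataset), axis_map = red$axis_map,
         truth = ph$truth)
  })
}

# a model trained on the reference phantom with the default configuration
ref_model <- function(seed = 1) {
  memoize(paste0("ref_model_seed", seed), {
    msi_vae(ref_training_data()$norm, seed = seed)
  })
}

# small multi-section phantom for the train/test and CV workflows
cv_phantom <- function() {
  memoize("cv_phantom", generate_3d_phantom(
    phantom_spec(width = 24, height = 24, n_sections = 10, d = 800,
                 n_regions = 4, peaks_per_region = 6, shared_peaks = 6,
                 seed = 3)))
}

# the multi-section counterpart of the reference phantom: same spectral
# parameters, 10 thinner sections for train/test and cross-validation
ref3d_phantom <- function() {
  memoize("ref3d_phantom", generate_3d_phantom(
    reference_phantom_spec(width = 20, height = 20, n_sections = 10)))
}

# moderate architecture for workflow tests where full scale is not the point
fast_vae_args <- function() {
  list(hidden_dim = 64, latent_dim = 4, epochs = 30, batch_size = 128)
}

adjusted_rand_index <- function(a, b) mclust::adjustedRandIndex(a, b)
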