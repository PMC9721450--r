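# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# canonical signal-bearing study conditions: calibrated so the tumoral model
# scores in the clinically typical AUC range rather than at ceiling
signal_phantom_config <- function(n_patients = 40, seed = 42, ...) {
  phantom_config(n_patients = n_patients, core_effect = 0.25,
                 rim_effect = 0.30, noise_sd = 20, seed = seed, ...)
}

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# small mixed dataset used across region / feature / cnn tests
small_phantom <- function() {
  fixture("small_phantom", function()
    generate_dataset(signal_phantom_config(n_patients = 12, seed = 42)))
}

small_region_sets <- function() {
  fixture("small_region_sets", function() {
    ds <- small_phantom()
    lapply(seq_along(ds$images), function(i)
      build_region_set(ds$images[[i]], ds$masks[[i]], 1:5))
  })
}

mammogram_from_matrix <- function(px, spacing = 1, label = "benign",
                                  view = "CC", id = "T1") {
  structure(list(pixels = px, spacing_mm = rep(spacing, 2), patient_id = id,
                 view = view, label = label), class = "mammogram_image")
}

disk_mask <- function(n, center, radius) {
  r <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  (r - center[1])^2 + (cc - center[2])^2 <= radius^2
}
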