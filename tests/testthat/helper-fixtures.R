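# Shared small fixtures; heavier objects are built lazily and memoised so a
# test run trains each small network only once.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, .fixture_env)) assign(name, expr, .fixture_env)
  get(name, .fixture_env)
}

tiny_mosaic <- function(seed = 11, modality = "confocal") {
  generate_mosaic(mosaic_params(seed = seed, modality = modality))
}

# two-image training set, used by several CNN tests
tiny_patchset <- function() memo("tiny_patchset", {
  ms <- lapply(c(21, 22), function(s) tiny_mosaic(s))
  build_training_set(lapply(ms, `[[`, "image"), lapply(ms, `[[`, "cones"),
                     seed = 5)
})

# a quickly trained network: 3 epochs on the two-image set
tiny_net <- function() memo("tiny_net", {
  cone_cnn(tiny_patchset(),
           cnn_config(epochs = 3, lr_drop_epochs = integer(0), seed = 7))
})

random_cones <- function(n, H = 100, W = 100, source = "manual") {
  marked_cones(runif(n, 0, W - 1), runif(n, 0, H - 1), source)
}

# full end-to-end pipeline runs at the documented desk scale, shared across
# test files (memoised; the first caller pays the cost)
fixture_run <- function(modality) {
  memo(paste0("pipeline_", modality), {
    suite <- make_fixture_suite(seed = 1, modality = modality)
    run_pipeline(suite,
                 cnn_config(epochs = 4, lr_drop_epochs = 3L, seed = 100L),
                 tune_n = 1L)
  })
}
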