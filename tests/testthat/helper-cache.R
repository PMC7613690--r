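# shared, lazily built artifacts for the expensive simulation-based tests;
# everything is seeded so repeated runs are identical
.cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .cache)) assign(name, builder(), envir = .cache)
  get(name, envir = .cache)
}

# reduced-grid ball-and-stick family: 24 angles x 8 AIS positions x 2 offsets
reduced_family <- function() cached("reduced_family", function() {
  suppressWarnings(run_family(sim_config("bas", "reduced", seed = 11)))
})

reduced_dataset <- function() cached("reduced_dataset", function() {
  build_delta_dataset(reduced_family(), sham_ratio = 1, seed = 12)
})

reduced_nca <- function() cached("reduced_nca", function() {
  ds <- reduced_dataset()
  nca_feature_weights(ds$X, ds$valid, nca_config(seed = 13))
})

reduced_library <- function() cached("reduced_library", function() {
  build_kernel_library(reduced_family(), L = 25)
})

# target pairs from the canonical synthetic-detailed neuron (generator
# default, seed 1 -- a fixed study morphology) at one orientation/offset
detailed_targets <- function() cached("detailed_targets", function() {
  cfg <- sim_config("detailed", "reduced",
                    soma_offsets = matrix(c(0, 0), 1),
                    rotation_step_deg = 360,
                    ais_positions = c(5, 10, 15, 20, 25, 30), seed = 1)
  run_family(cfg)$groups[[1]]
})

# one default ball-and-stick simulation, reused by several physics tests
default_sim <- function() cached("default_sim", function() {
  m <- assign_biophysics(build_ball_and_stick(ais_spec(15)))
  simulate_neuron(m, build_probe(), sim_config("bas", "reduced"))
})
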