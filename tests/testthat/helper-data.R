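# Shared fixtures, built in code.

# Canonical dataset shaped like the reference study: 351 building rows
# (117 triplicate sampling points across 12 experiments) + 117 validation
# rows = 468 measurements.
canonical_dataset <- function(noise_sd = 0.1, seed = 11L) {
  design <- build_storage_design(
    temperatures = c(12, 18, 24, 30),
    water_activities = c(0.75, 0.78, 0.81),   # all on the 72-day branch
    sampling_interval = 6, replicates = 3,
    validation_conditions = rbind(c(30, 0.75), c(30, 0.78), c(30, 0.81))
  )
  simulate_degradation(design, noise_sd = noise_sd, seed = seed)
}

# small fast dataset (single replicate) for network tests
small_dataset <- function(noise_sd = 0.1, seed = 21L, split_seed = 22L) {
  design <- build_storage_design(replicates = 1)
  ds <- simulate_degradation(design, noise_sd = noise_sd, seed = seed)
  split_learning_test(ds, seed = split_seed)
}

# hand-buildable trained MLP for forward-pass oracles
manual_mlp <- function(hidden_weights, hidden_biases, output_weights,
                       output_bias, scaling,
                       activation = "logistic") {
  spec <- network_spec("mlp", n_hidden = length(hidden_biases), activation)
  structure(list(spec = spec, scaling = scaling,
                 hidden_weights = hidden_weights, hidden_biases = hidden_biases,
                 output_weights = output_weights, output_bias = output_bias,
                 errors = c(learning = NA_real_, test = NA_real_,
                            validation = NA_real_),
                 init_seed = 0L),
            class = "trained_network")
}

identity_scaling <- list(x_min = c(0, 0, 0), x_max = c(1, 1, 1),
                         y_min = 0, y_max = 1)

# random planted 3-H-1 logistic MLP over the default condition ranges
planted_mlp <- function(H, seed) {
  ranges <- list(x_min = c(0.75, 12, 0), x_max = c(0.90, 30, 72),
                 y_min = 2, y_max = 8)
  set.seed(seed)
  manual_mlp(
    hidden_weights = matrix(runif(3 * H, -2, 2), 3, H),
    hidden_biases = runif(H, -1, 1),
    output_weights = runif(H, -1, 1),
    output_bias = 0.5,
    scaling = ranges
  )
}
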