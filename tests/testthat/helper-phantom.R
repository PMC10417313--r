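# Shared fixtures, all generated in code.

# Small, fast architecture for tests of training mechanics (the tuned
# stage architectures are exercised in the acceptance suite).
tiny_arch <- function(input_length = 692L) {
  cnn_architecture(c(16L, 16L), c(3L, 3L), 64L, input_length = input_length)
}

# Quick separable two-class dataset built from zero-noise-ish phantoms.
tiny_stage_data <- function(n_per_class = 24, seed = 99,
                            classes = c("N", "T"), noise_sd = 0.02) {
  cfg <- phantom_config(noise_sd = noise_sd)
  seeds <- matrix(mrsinet:::child_seeds(seed, 2 * n_per_class), ncol = 2)
  x <- rbind(
    t(vapply(seeds[, 1], function(s)
      generate_spectrum(classes[1], cfg, s), numeric(692))),
    t(vapply(seeds[, 2], function(s)
      generate_spectrum(classes[2], cfg, s), numeric(692))))
  y <- rep(c(0L, 1L), each = n_per_class)
  prov <- data.frame(subject = rep(sprintf("S%02d", 1:8),
                                   length.out = 2 * n_per_class),
                     grid = 1L, row = 0L, col = seq_len(2 * n_per_class) - 1L,
                     label = rep(classes, each = n_per_class),
                     stringsAsFactors = FALSE)
  mrsinet:::new_stage_dataset(ul2_normalize(x), y, prov, "N_vs_RT")
}

# Stub probability model for hierarchy tests: returns fixed per-voxel
# probabilities regardless of input.
stub_model <- function(probs) {
  structure(list(probs = probs), class = "stub_model")
}

# An initialised (untrained) CNN fit object for Grad-CAM mechanics.
init_cnn_fit <- function(arch, seed = 1) {
  params <- mrsinet:::with_seed(seed, mrsinet:::init_cnn_params(arch))
  structure(list(arch = arch, params = params, history = NULL,
                 cfg = NULL, best_epoch = 0L),
            class = c("cnn1d_fit", "cnn1d"))
}
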