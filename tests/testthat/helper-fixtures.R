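# Small fixtures shared across test files; everything is generated in code.

tiny_cohort <- function(n_copd = 30L, n_control = 30L, seed = 101L, ...) {
  generate_cohort(cohort_spec(n_copd = n_copd, n_control = n_control,
                              seed = seed, ...))
}

tiny_image_params <- function(...) {
  image_params(height = 32L, width = 32L, ...)
}

# Fast training config for pipeline tests.
tiny_config <- function(epochs = 6L, gate_warmup = 2L, ...) {
  mmdf_config(epochs = epochs, seed = 3L, gan_iters = 30L,
              gate_warmup = gate_warmup, equalize_levels = 32L, ...)
}
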