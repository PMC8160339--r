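# Shared fixture builders. Everything is generated in code; the default
# full-size batch is cached per session because several files reuse it.

.fixture_env <- new.env(parent = emptyenv())

# Small synthetic batch for fast structural tests.
small_dataset <- function(seed = 42, n_freq = 60, separation = 2.5, ...) {
  generate_dataset(generator_config(
    n_train_unripe = 60, n_train_ripe = 30,
    n_test_unripe = 20, n_test_ripe = 20,
    n_freq = n_freq, separation = separation, seed = seed, ...))
}

# Full study-size batch (534/150 train, 128/111 test), cached.
full_dataset <- function(seed = 1) {
  key <- paste0("full", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_dataset(generator_config(seed = seed))
  .fixture_env[[key]]
}

# Pick 5 evenly spaced grid frequencies for each parameter.
fixed_selection <- function(grid) {
  f <- grid[round(seq(1, length(grid), length.out = 5))]
  list(magnitude = f, phase = f, tan_delta = f)
}

# Feature table built directly (no spectra): label-driven informative
# columns plus pure-noise columns, in the canonical 18-name layout.
toy_features <- function(n = 200, informative = "magn_f3", effect = 3,
                         prevalence = 0.5, seed = 1) {
  withr::with_seed(seed, {
    label <- rbinom(n, 1, prevalence)
    ft <- data.frame(fruit_id = sprintf("f%04d", seq_len(n)), label = label)
    for (nm in feature_names())
      ft[[nm]] <- rnorm(n)
    for (nm in informative)
      ft[[nm]] <- ft[[nm]] + effect * label
    ft$a_star <- 20 + 20 * label + rnorm(n)
    ft
  })
}

# Cached default feature tables (screened selection, full batch).
full_features <- function(seed = 1) {
  key <- paste0("feat", seed)
  if (is.null(.fixture_env[[key]])) {
    d <- full_dataset(seed)
    sel <- screen_frequencies(d$train, n_boot = 25, seed = seed)
    .fixture_env[[key]] <- list(
      train = assemble_features(d$train, sel),
      test = assemble_features(d$test, sel),
      sel = sel)
  }
  .fixture_env[[key]]
}
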