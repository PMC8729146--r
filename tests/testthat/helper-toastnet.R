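# Small cohorts and specs used across tests.

tiny_spec <- function(seed = 1L, effect_size = 2, missing_rate = 0,
                      n_features = 16L, n_informative = 8L,
                      class_counts = c(40L, 10L, 20L, 8L, 12L)) {
  cohort_spec(class_counts = class_counts, n_features = n_features,
              n_informative = n_informative, effect_size = effect_size,
              missing_rate = missing_rate, seed = seed)
}

tiny_net_spec <- function(variant = "V4", sequence_length = 12L,
                          seed = 1L) {
  network_spec(variant = variant, sequence_length = sequence_length,
               conv1 = c(filters = 6L, kernel = 3L, stride = 1L),
               conv2 = c(filters = 4L, kernel = 2L, stride = 2L),
               pool = c(window = 2L, stride = 2L),
               head_width = 8L, n_classes = 5L, seed = seed)
}

# Random probability matrix with rows summing to 1.
random_proba <- function(n, k) {
  m <- matrix(rexp(n * k), n, k)
  m / rowSums(m)
}

# A two-class, clearly separable sequence problem: class means -mu / +mu.
separable_toy <- function(n_per_class = 60L, len = 8L, mu = 1.5,
                          seed = 42L) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * len, -mu), n_per_class),
               matrix(rnorm(n_per_class * len, +mu), n_per_class))
    y <- rep(0:1, each = n_per_class)
    idx <- sample(nrow(x))
    list(x = x[idx, ], y = y[idx])
  })
}
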