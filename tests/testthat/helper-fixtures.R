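# Shared fixture builders: everything is generated in code at test time.

# tiny 3-channel / 2-spectrum set for I/O and container tests
tiny_set <- function() {
  spectrum_set(c(100, 200, 300),
               matrix(c(1, 2, 3, 4, 5, 6), nrow = 2, byrow = TRUE,
                      dimnames = list(c("a", "b"), NULL)),
               labels = c("HT1197", "RT112"))
}

# quiet phantom parameters: deterministic weights, no baseline, no cosmic rays
quiet_params <- function(...) {
  spectral_phantom_params(
    baseline_range = matrix(0, 4, 2),
    cr_sdlog = 0, cb_sdlog = 0, cosmic_rate = 0, ...)
}

# camera with every noise source off
silent_camera <- function() camera_model(0, 0, 1)

# small two-class matrix with a planted mean shift at given channels
planted_matrix <- function(n_per_class = 30, p = 40, channels = 7,
                           delta = 3, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(2 * n_per_class * p), 2 * n_per_class, p)
    y <- rep(c("A", "B"), each = n_per_class)
    X[y == "B", channels] <- X[y == "B", channels] + delta
    list(X = X, y = y)
  })
}
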