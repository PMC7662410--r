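# Shared fixtures and independent oracles.

# Two latent variables, one indicator each, known correlation structure.
two_block_table <- function(n = 200, beta = 0.5, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- beta * x + rnorm(n, 0, sqrt(1 - beta^2))
  data.frame(a = x, b = y)
}

two_block_spec <- function() {
  path_model_spec(list(A = "a", B = "b"),
                  data.frame(from = "A", to = "B"))
}

# Brute-force time-domain HRV oracle: direct transcription of the index
# definitions, independent of the package implementation.
oracle_time_domain <- function(nn_ms) {
  d <- diff(nn_ms)
  list(avnn = sum(nn_ms) / length(nn_ms),
       sdnn = sqrt(sum((nn_ms - mean(nn_ms))^2) / (length(nn_ms) - 1)),
       rmssd = sqrt(sum(d^2) / length(d)),
       pnn50 = sum(abs(d) > 50) / length(d))
}

# nn_series from a vector of intervals in ms (beats at cumulative times).
nn_series_from_nn <- function(nn_ms) {
  nn_series(c(0, cumsum(nn_ms)) / 1000)
}

# Random indicator table drawn from the four-construct ground truth.
random_truth_table <- function(n = 300, b = c(0.5, -0.4, 0.3),
                               loadings = 0.9, noise_sd = 0.3, seed = 42) {
  truth <- latent_ground_truth(loadings, b, noise_sd, n, seed = seed)
  generate_indicator_table(truth)
}

expect_no_flips <- function(al) expect_length(al$flipped, 0)
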