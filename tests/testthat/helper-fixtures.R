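# Shared fixtures, built once per test run.

# The default bank and its expanded shift dictionary are used across many
# tests; building them once keeps the suite fast.
default_bank <- build_gabor_bank()
default_expanded <- expand_dictionary(default_bank)

# A deterministic white-noise waveform for periphery tests.
fixture_noise <- function(n = 16000, seed = 404) {
  set.seed(seed)
  stats::rnorm(n)
}

# Small linear-neuron ensemble: white stimulus windows, response = s . w
# (+ optional noise). Returns the ensemble and the true filter vector.
linear_ensemble <- function(n = 400, n_channels = 7, n_frames = 10,
                            noise_sd = 0, seed = 1) {
  set.seed(seed)
  d <- n_channels * n_frames
  S <- matrix(rnorm(n * d), n, d)
  w <- as.vector(Re(gabor_atom(40, 0, b_t = 16, b_s = n_channels,
                               n_channels = n_channels,
                               n_frames = n_frames)$patch))
  r <- as.vector(S %*% w) + rnorm(n, sd = noise_sd)
  list(ensemble = stimulus_ensemble(S, r, n_channels, n_frames), w = w)
}
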