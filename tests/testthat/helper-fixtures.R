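# Small programmatic fixtures shared across test files.

# Minimal epochs object: deterministic pseudo-random data, balanced labels.
tiny_epochs <- function(n_per_class = 2, n_channels = 3, n_samples = 100,
                        sfreq = 500, tmin_ms = -100, seed = 99,
                        channel_names = NULL) {
  n_trials <- 5 * n_per_class
  dat <- phasedecode:::with_seed(seed,
    array(rnorm(n_trials * n_channels * n_samples), c(n_trials, n_channels, n_samples)))
  eeg_epochs(dat, labels = rep(0:4, n_per_class), sfreq = sfreq,
             tmin_ms = tmin_ms, channel_names = channel_names)
}

# Feature matrix of five well-separated Gaussian blobs (one per class).
blob_features <- function(n_per_class = 12, n_features = 4, separation = 50,
                          seed = 1) {
  n <- 5 * n_per_class
  labels <- rep(0:4, each = n_per_class)
  X <- phasedecode:::with_seed(seed, {
    centers <- matrix(rnorm(5 * n_features), 5, n_features) * separation
    centers[labels + 1, ] + matrix(rnorm(n * n_features), n, n_features)
  })
  list(X = X, labels = labels, signal_kind = "synthetic",
       electrode = "blob", window = window_spec(0, 200), band = "none")
}

# Feature matrix with labels independent of the features.
noise_features <- function(n_per_class = 10, n_features = 6, seed = 2) {
  n <- 5 * n_per_class
  phasedecode:::with_seed(seed, list(
    X = matrix(rnorm(n * n_features), n, n_features),
    labels = sample(rep(0:4, n_per_class)),
    signal_kind = "synthetic", electrode = "noise",
    window = window_spec(0, 200), band = "none"))
}

# A small phase-coded synthetic dataset restricted to a few channels.
small_phase_dataset <- function(seed = 5, n_per_class = 10,
                                channels = c("PO8", "Oz", "P7"),
                                target = c("PO8", "Oz"), snr = 1.5) {
  generate_dataset(synth_config(
    n_per_class = n_per_class, coding = "phase", snr = snr,
    channels = channels, target_channels = target, seed = seed))
}
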