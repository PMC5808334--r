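#' Synthetic EEG generator configuration
#'
#' Describes a synthetic epoched-EEG dataset with the statistical structure
#' the decoding analysis assumes: 1/f^alpha background noise with a shared
#' common-mode component across channels, and -- at a set of target
#' parieto-occipital channels, within an informative latency window -- a
#' carrier-band oscillation that codes the trial's class either in its
#' stimulus-locked phase (`coding = "phase"`), in its amplitude
#' (`coding = "power"`), or not at all (`coding = "none"`, labels
#' independent of the data).
#'
#' For phase coding the oscillation is
#' `A * env(t) * cos(2*pi*f0*(t - t_ref) + phi_class + jitter)` with `f0`
#' the carrier-band midpoint, `env` a raised-cosine ramped (50 ms) envelope
#' over the code window, `t_ref` the window midpoint (so the instantaneous
#' phase measured at mid-window equals the class offset), and a per-trial
#' wrapped-normal phase jitter -- phase-locked yet trial-variable, as real
#' stimulus-locked phase concentration is partial. The amplitude envelope is
#' identical across classes, so power carries no class information. For
#' power coding the class-`k` amplitude is scaled by `1 + k * amp_step` and
#' the oscillation phase is random per trial, so phase carries no class
#' information.
#'
#' `snr` is the ratio of the code oscillation's RMS (over the code window)
#' to the background RMS within the carrier band at the target channels;
#' `snr = 1` means the code is as strong as the band-limited background it
#' sits in.
#'
#' @param n_per_class trials per class (default 90; 5 classes, 450 trials).
#' @param coding `"phase"`, `"power"` or `"none"`.
#' @param carrier_band `c(low_hz, high_hz)` of the code oscillation
#'   (default theta, 4-8 Hz).
#' @param target_channels channels carrying the class code (default PO7,
#'   PO8, O1, Oz, O2).
#' @param class_phase_offsets_rad per-class phase offsets (default
#'   `2*pi*k/5`, `k = 0..4`).
#' @param code_window_ms informative latency window, ms (default
#'   `c(100, 600)`).
#' @param snr code-to-background band RMS ratio (> 0, default 1).
#' @param noise_exponent spectral slope alpha of the 1/f^alpha background
#'   (default 1).
#' @param phase_jitter_sd SD of the per-trial phase jitter in radians
#'   (default 0.5).
#' @param amp_step per-class amplitude increment for power coding; default
#'   `0.4 * snr`.
#' @param common_mode mixing weight of the across-channel shared background
#'   component (default 0.3), mimicking volume conduction.
#' @param bg_rms_uv background RMS per channel in microvolts (default 10).
#' @param channels channel names to synthesize (default: the 64-channel
#'   schematic montage of [standard_montage()]).
#' @param sfreq,tmin_ms,tmax_ms sampling rate and epoch extent (defaults
#'   500 Hz, -500..1000 ms).
#' @param seed integer seed; identical seeds give identical datasets.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 90,
                         coding = c("phase", "power", "none"),
                         carrier_band = c(4, 8),
                         target_channels = c("PO7", "PO8", "O1", "Oz", "O2"),
                         class_phase_offsets_rad = 2 * pi * (0:4) / 5,
                         code_window_ms = c(100, 600),
                         snr = 1, noise_exponent = 1, phase_jitter_sd = 0.5,
                         amp_step = NULL, common_mode = 0.3, bg_rms_uv = 10,
                         channels = NULL, sfreq = 500, tmin_ms = -500,
                         tmax_ms = 1000, seed = NULL) {
  coding <- tryCatch(match.arg(coding), error = function(e)
    stop("invalid coding '", paste(coding, collapse = ","),
         "': must be one of phase, power, none"))
  n_classes <- 5L
  if (length(class_phase_offsets_rad) != n_classes)
    stop("class_phase_offsets_rad must have one offset per class (",
         n_classes, ")")
  if (!(snr > 0)) stop("snr must be > 0")
  if (code_window_ms[1] < tmin_ms || code_window_ms[2] > tmax_ms)
    stop("code window must lie within the epoch")
  if (is.null(amp_step)) amp_step <- 0.4 * snr
  if (is.null(channels)) channels <- standard_montage()$name
  missing_t <- setdiff(target_channels, channels)
  if (coding != "none" && length(missing_t))
    stop("target channel(s) not in the montage: ",
         paste(missing_t, collapse = ", "))
  structure(list(n_per_class = n_per_class, n_classes = n_classes,
                 coding = coding, carrier_band = carrier_band,
                 target_channels = target_channels,
                 class_phase_offsets_rad = class_phase_offsets_rad,
                 code_window_ms = code_window_ms, snr = snr,
                 noise_exponent = noise_exponent,
                 phase_jitter_sd = phase_jitter_sd, amp_step = amp_step,
                 common_mode = common_mode, bg_rms_uv = bg_rms_uv,
                 channels = channels, sfreq = sfreq, tmin_ms = tmin_ms,
                 tmax_ms = tmax_ms, seed = seed),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> coding=%s, %d x %d trials, %d channels, snr=%g, carrier %g-%g Hz\n",
              x$coding, x$n_per_class, x$n_classes, length(x$channels),
              x$snr, x$carrier_band[1], x$carrier_band[2]))
  invisible(x)
}

# Spectral weights (one per rFFT bin) shaping white noise to 1/f^alpha,
# normalized so the shaped series has unit variance in expectation.
spectral_weights <- function(n, sfreq, alpha) {
  k <- seq(0, n - 1)
  freqs <- pmin(k, n - k) * sfreq / n  # folded (two-sided) frequencies
  w <- numeric(n)
  w[freqs > 0] <- freqs[freqs > 0]^(-alpha / 2)
  w
}

# One epoch (n x n_series matrix) of 1/f^alpha noise with unit variance.
pink_noise <- function(n, n_series, w) {
  # shape white Gaussian series in the frequency domain; the weights are
  # symmetric over the DFT bins, so the inverse transform is real
  x <- matrix(rnorm(n * n_series), n, n_series)
  xf <- mvfft(x) * w
  y <- Re(mvfft(xf, inverse = TRUE)) / n
  sc <- sqrt(sum(w^2) / n)  # sd of the shaped series in expectation
  y / sc
}

#' Generate a synthetic epoched-EEG dataset
#'
#' Draws the dataset described by a [synth_config()]: `n_per_class * 5`
#' trials in randomized order, with the configured background noise and
#' class code. Identical seeds give identical output; different seeds give
#' different noise realizations of the same class structure. Channels not
#' in `target_channels` carry no class information.
#'
#' @param config a [synth_config()].
#' @return an [eeg_epochs()] object with montage positions attached.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  sf <- config$sfreq
  n <- as.integer(round((config$tmax_ms - config$tmin_ms) / 1000 * sf))
  n_ch <- length(config$channels)
  n_trials <- config$n_per_class * config$n_classes
  t_s <- (seq_len(n) - 1) / sf + config$tmin_ms / 1000  # seconds re onset
  w <- spectral_weights(n, sf, config$noise_exponent)

  # band share of the background: fraction of noise power inside the carrier
  kk <- seq(0, n - 1)
  freqs <- pmin(kk, n - kk) * sf / n
  in_band <- freqs >= config$carrier_band[1] & freqs <= config$carrier_band[2]
  band_share <- sqrt(sum(w[in_band]^2) / sum(w^2))
  band_rms <- config$bg_rms_uv * band_share

  # raised-cosine envelope over the code window (50 ms ramps)
  i1 <- as.integer(round((config$code_window_ms[1] - config$tmin_ms) / 1000 * sf)) + 1L
  i2 <- as.integer(round((config$code_window_ms[2] - config$tmin_ms) / 1000 * sf))
  env <- numeric(n)
  nwin <- i2 - i1 + 1L
  ramp <- min(as.integer(round(0.050 * sf)), nwin %/% 2)
  e <- rep(1, nwin)
  if (ramp > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
    e[seq_len(ramp)] <- up
    e[nwin + 1 - seq_len(ramp)] <- rev(up)
  }
  env[i1:i2] <- e
  # oscillation amplitude giving the requested band-RMS ratio over the window
  rms_unit <- sqrt(mean(env[i1:i2]^2) / 2)  # RMS of env*cos over the window
  A <- config$snr * band_rms / rms_unit
  f0 <- mean(config$carrier_band)
  t_ref <- mean(config$code_window_ms) / 1000

  target_idx <- match(config$target_channels, config$channels)
  mont <- standard_montage()
  pos <- as.matrix(mont[match(config$channels, mont$name), c("x", "y")])
  cmw <- config$common_mode
  norm <- sqrt(1 + cmw^2)

  with_seed(config$seed, {
    labels <- sample(rep(0:4, config$n_per_class))
    data <- array(0, c(n_trials, n_ch, n))
    for (tr in seq_len(n_trials)) {
      noise <- pink_noise(n, n_ch + 1L, w)
      x <- (noise[, seq_len(n_ch), drop = FALSE] + cmw * noise[, n_ch + 1L]) /
        norm * config$bg_rms_uv
      if (config$coding != "none") {
        k <- labels[tr]
        if (config$coding == "phase") {
          phi <- config$class_phase_offsets_rad[k + 1L] +
            rnorm(1, 0, config$phase_jitter_sd)
          osc <- A * env * cos(2 * pi * f0 * (t_s - t_ref) + phi)
        } else {
          phi <- runif(1, -pi, pi)
          scales <- 1 + (0:4) * config$amp_step
          a_k <- A * scales[k + 1L] / mean(scales)
          osc <- a_k * env * cos(2 * pi * f0 * (t_s - t_ref) + phi)
        }
        x[, target_idx] <- x[, target_idx] + osc
      }
      data[tr, , ] <- t(x)
    }
    if (config$coding == "none") labels <- sample(rep(0:4, config$n_per_class))
    eeg_epochs(data, labels, sfreq = sf, tmin_ms = config$tmin_ms,
               channel_names = config$channels, positions = pos)
  })
}
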