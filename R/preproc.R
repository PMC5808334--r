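#' Canonical EEG frequency bands
#'
#' The six rhythm bands used throughout the analysis: delta (1-4 Hz), theta
#' (4-8 Hz), alpha (8-14 Hz), beta (14-30 Hz), low-gamma (30-50 Hz) and
#' high-gamma (50-150 Hz). A wide band (0.5-220 Hz) is available via
#' [band_spec()] for broadband work.
#'
#' @return data.frame with columns `name`, `low_hz`, `high_hz`.
#' @export
canonical_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "low_gamma", "high_gamma"),
    low_hz = c(1, 4, 8, 14, 30, 50),
    high_hz = c(4, 8, 14, 30, 50, 150))
}

#' Frequency band specification
#'
#' @param name band name. One of the canonical names (see
#'   [canonical_bands()]), `"wide"` (0.5-220 Hz), or any label when `low_hz`
#'   and `high_hz` are given explicitly.
#' @param low_hz,high_hz band edges in Hz; taken from the canonical table
#'   when omitted.
#' @return an object of class `band_spec` with fields `name`, `low_hz`,
#'   `high_hz`.
#' @export
band_spec <- function(name, low_hz = NULL, high_hz = NULL) {
  if (is.null(low_hz) || is.null(high_hz)) {
    tab <- canonical_bands()
    if (name == "wide") {
      low_hz <- 0.5; high_hz <- 220
    } else {
      i <- match(name, tab$name)
      if (is.na(i)) stop("unknown band name: ", name)
      low_hz <- tab$low_hz[i]; high_hz <- tab$high_hz[i]
    }
  }
  if (!(low_hz > 0 && low_hz < high_hz))
    stop("band edges must satisfy 0 < low_hz < high_hz")
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz),
            class = "band_spec")
}

as_band <- function(band) {
  if (inherits(band, "band_spec")) band else band_spec(band)
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %g-%g Hz\n", x$name, x$low_hz, x$high_hz))
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the pre-stimulus baseline
#' window from the whole epoch. Idempotent; after correction the mean over
#' the baseline window is 0 to numerical precision.
#'
#' @param epochs an `eeg_epochs` object.
#' @param window_ms baseline interval `(start, end)` in ms (default
#'   `c(-500, 0)`).
#' @return baseline-corrected `eeg_epochs`.
#' @export
baseline_correct <- function(epochs, window_ms = c(-500, 0)) {
  i1 <- sample_at(epochs, window_ms[1])
  i2 <- sample_at(epochs, window_ms[2])
  n <- dim(epochs$data)[3]
  if (i1 < 1L || i2 > n || i1 > i2)
    stop("baseline window ", window_ms[1], "..", window_ms[2],
         " ms outside the epoch")
  i2 <- min(i2, n)
  mu <- apply(epochs$data[, , i1:i2, drop = FALSE], c(1, 2), mean)
  out <- epochs
  out$data <- epochs$data - as.vector(mu)  # recycles over the sample axis
  out
}

# ---- Kaiser FIR design ---------------------------------------------------

# Kaiser window of length n for stopband attenuation A (dB), via the
# standard empirical beta formula and the zeroth-order modified Bessel
# function.
kaiser_window <- function(n, atten_db) {
  beta <- if (atten_db > 50) 0.1102 * (atten_db - 8.7)
  else if (atten_db >= 21) 0.5842 * (atten_db - 21)^0.4 + 0.07886 * (atten_db - 21)
  else 0
  m <- (n - 1) / 2
  k <- seq_len(n) - 1
  besselI(beta * sqrt(pmax(1 - ((k - m) / m)^2, 0)), 0) / besselI(beta, 0)
}

#' Design a Kaiser-window linear-phase FIR bandpass filter
#'
#' Classic windowed-ideal-bandpass design: an ideal bandpass impulse
#' response with cutoffs at the transition-band midpoints, multiplied by a
#' Kaiser window sized from the standard design equations for the requested
#' stopband attenuation and transition width (a 2 dB design margin is added
#' so the attenuation holds at the stop edges, not only asymptotically).
#' The length is forced odd (type-I FIR), so the filter is exactly
#' linear-phase with group delay `(L-1)/2` samples. Passband gain is
#' normalized to 1 at the band's geometric-mean frequency.
#'
#' When `transition_hz` exceeds `low_hz` (only the delta band at the default
#' pipeline transition), a full-attenuation transition cannot fit above 0 Hz;
#' the low cutoff is then placed at `low_hz/2` and the design is flagged
#' `low_relaxed`, with a warning, meaning the stopband specification is
#' guaranteed on the high side only.
#'
#' @param band a `band_spec` or canonical band name.
#' @param sfreq sampling rate in Hz.
#' @param transition_hz transition (edge) band width in Hz; default 1.
#' @param atten_db stopband attenuation in dB; default 30.
#' @return object of class `fir_design`: `coefficients` (odd length,
#'   symmetric), `band`, `sfreq`, `transition_hz`, `atten_db`, `n_taps`,
#'   `delay` (samples), `low_relaxed`.
#' @export
design_band_fir <- function(band, sfreq, transition_hz = 1, atten_db = 30) {
  band <- as_band(band)
  nyq <- sfreq / 2
  high <- band$high_hz
  if (high >= 0.95 * nyq) {
    warning("band high edge ", high, " Hz clipped to 0.95 x Nyquist (",
            0.95 * nyq, " Hz)")
    high <- 0.95 * nyq
  }
  if (high + transition_hz >= nyq)
    stop("transition band crosses Nyquist (", high, " + ", transition_hz,
         " >= ", nyq, " Hz)")
  low_relaxed <- transition_hz > band$low_hz
  if (low_relaxed) {
    warning("transition width ", transition_hz, " Hz exceeds the low edge ",
            band$low_hz, " Hz; low-side stopband attenuation is relaxed")
    c1 <- band$low_hz / 2
  } else {
    c1 <- band$low_hz - transition_hz / 2
  }
  c2 <- high + transition_hz / 2
  a_des <- atten_db + 2  # design margin: meet atten_db at the stop edges
  n_ord <- ceiling((a_des - 7.95) / (2.285 * 2 * pi * transition_hz / sfreq))
  if (n_ord %% 2 == 1) n_ord <- n_ord + 1  # even order => odd length, type I
  L <- n_ord + 1L
  m <- n_ord / 2
  k <- 0:n_ord
  ideal <- function(fc) ifelse(k == m, 2 * fc / sfreq,
                               sin(2 * pi * fc * (k - m) / sfreq) / (pi * (k - m)))
  h <- (ideal(c2) - ideal(c1)) * kaiser_window(L, a_des)
  f0 <- sqrt(band$low_hz * high)
  h <- h / abs(sum(h * exp(-2i * pi * f0 * k / sfreq)))
  structure(list(coefficients = h, band = band, high_eff_hz = high,
                 sfreq = sfreq, transition_hz = transition_hz,
                 atten_db = atten_db, n_taps = L, delay = as.integer(m),
                 low_relaxed = low_relaxed),
            class = "fir_design")
}

#' @export
print.fir_design <- function(x, ...) {
  cat(sprintf("<fir_design> %s %g-%g Hz @ %g Hz: %d taps, %g Hz transition, -%g dB%s\n",
              x$band$name, x$band$low_hz, x$band$high_hz, x$sfreq, x$n_taps,
              x$transition_hz, x$atten_db,
              if (x$low_relaxed) " (low side relaxed)" else ""))
  invisible(x)
}

#' Frequency response of an FIR design
#' @param design a `fir_design`.
#' @param freqs_hz frequencies at which to evaluate.
#' @return complex response `H(f)` at `freqs_hz`.
#' @export
fir_response <- function(design, freqs_hz) {
  k <- seq_along(design$coefficients) - 1
  vapply(freqs_hz, function(f)
    sum(design$coefficients * exp(-2i * pi * f * k / design$sfreq)),
    complex(1))
}

# FFT-based linear convolution of every column of `x` (n x S matrix) with
# kernel h, returning the delay-compensated same-length segment.
fft_filter_cols <- function(x, h, delay) {
  n <- nrow(x); L <- length(h)
  nfft <- 2^ceiling(log2(n + L - 1))
  hf <- fft(c(h, numeric(nfft - L)))
  xf <- mvfft(rbind(x, matrix(0, nfft - n, ncol(x))))
  y <- Re(mvfft(xf * hf, inverse = TRUE)) / nfft
  y[(delay + 1):(delay + n), , drop = FALSE]
}

#' Apply an FIR filter to epochs
#'
#' Single forward pass with group-delay compensation: each trial/channel
#' series is linearly convolved with the filter (zero-padded) and shifted
#' back by `(L-1)/2` samples, so for a linear-phase design the output has no
#' net phase distortion and features stay aligned with the stimulus-locked
#' time axis. The first and last `(L-1)/2` samples are edge-contaminated and
#' are marked invalid via `n_edge`; [extract_window()] refuses windows that
#' overlap them.
#'
#' @param epochs an `eeg_epochs` object.
#' @param design a `fir_design` from [design_band_fir()]; must be shorter
#'   than the epoch.
#' @return filtered `eeg_epochs` (same shape) with updated `n_edge` and a
#'   `band` field recording the filter band.
#' @export
apply_fir <- function(epochs, design) {
  d <- dim(epochs$data)
  if (design$n_taps > d[3])
    stop("filter (", design$n_taps, " taps) longer than epoch (", d[3],
         " samples); widen the transition band or lengthen the epoch")
  if (!isTRUE(all.equal(design$sfreq, epochs$sfreq)))
    stop("filter designed for ", design$sfreq, " Hz but epochs are ",
         epochs$sfreq, " Hz")
  out <- epochs
  if (d[1] > 0) {
    # samples x (trials*channels), filter all series in one FFT batch
    x <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[3])
    y <- fft_filter_cols(x, design$coefficients, design$delay)
    out$data <- aperm(array(y, c(d[3], d[1], d[2])), c(2, 3, 1))
    dimnames(out$data) <- dimnames(epochs$data)
  }
  out$n_edge <- max(epochs$n_edge, design$delay)
  out$band <- design$band$name
  out
}

#' Band-filter epochs in one step
#'
#' Convenience wrapper: designs the band filter and applies it. The default
#' 3 Hz transition keeps the filter (257 taps at 500 Hz) well inside a
#' 1.5 s epoch so that the whole -100..700 ms analysis range stays clear of
#' filter edges; see the package vignette for the trade-off against the
#' canonical 1 Hz transition.
#'
#' @inheritParams apply_fir
#' @param band a `band_spec` or canonical band name.
#' @param transition_hz transition width in Hz (default 3).
#' @param atten_db stopband attenuation in dB (default 30).
#' @export
filter_band <- function(epochs, band, transition_hz = 3, atten_db = 30) {
  apply_fir(epochs, design_band_fir(band, epochs$sfreq,
                                    transition_hz = transition_hz,
                                    atten_db = atten_db))
}

#' Reject high-amplitude epochs
#'
#' Simple automated stand-in for manual artifact screening: trials whose
#' absolute amplitude exceeds `abs_threshold_uv` at any channel/sample are
#' removed, labels filtered consistently.
#'
#' @param epochs an `eeg_epochs` object.
#' @param abs_threshold_uv rejection threshold in microvolts (`Inf` is a
#'   no-op; 0 rejects every non-flat trial).
#' @return list with elements `epochs` (retained trials) and `rejected`
#'   (integer indices of removed trials). If every trial is rejected the
#'   result is an empty (0-trial) object and a warning is raised.
#' @export
reject_epochs <- function(epochs, abs_threshold_uv) {
  if (is.na(abs_threshold_uv) || abs_threshold_uv < 0)
    stop("abs_threshold_uv must be non-negative")
  d <- dim(epochs$data)
  peak <- apply(abs(epochs$data), 1, max)
  bad <- which(peak > abs_threshold_uv)
  keep <- setdiff(seq_len(d[1]), bad)
  if (length(keep) == 0L)
    warning("all ", d[1], " trials exceed ", abs_threshold_uv,
            " uV; returning empty epochs")
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$labels <- epochs$labels[keep]
  list(epochs = out, rejected = bad)
}
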