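#' Analytic signal of epoched EEG
#'
#' Converts each trial/channel series into its complex analytic signal: the
#' real part is the input itself, the imaginary part its Hilbert transform.
#' The instantaneous power (amplitude) sequence is the modulus `A(t)` of the
#' analytic signal and the instantaneous phase sequence its argument `P(t)`
#' in `(-pi, pi]`. Computed per trial/channel over the full epoch with the
#' standard frequency-domain construction (one-sided spectrum doubling), so
#' windows sliced later share a single, minimally edge-affected transform.
#'
#' @param epochs an `eeg_epochs` object (typically band-filtered); values
#'   must be finite.
#' @return object of class `analytic_epochs`: complex `values` array
#'   `[n_trials, n_channels, n_samples]`, plus the labels, timing, channel
#'   and edge-validity (`n_edge`) metadata of the input and a `band`
#'   provenance field.
#' @export
analytic_signal <- function(epochs) {
  d <- dim(epochs$data)
  if (!all(is.finite(epochs$data))) {
    bad <- which(!is.finite(epochs$data), arr.ind = TRUE)[1, ]
    stop("non-finite sample in trial ", bad[1], ", channel ",
         epochs$channel_names[bad[2]])
  }
  values <- array(complex(real = 0), d)
  if (d[1] > 0 && d[3] > 1) {
    n <- d[3]
    w <- numeric(n)
    if (n %% 2 == 0) { w[1] <- 1; w[2:(n / 2)] <- 2; w[n / 2 + 1] <- 1 }
    else { w[1] <- 1; w[2:((n + 1) / 2)] <- 2 }
    x <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n)
    z <- mvfft(mvfft(x) * w, inverse = TRUE) / n
    # force the real part to equal the input exactly
    z <- complex(real = x, imaginary = Im(z))
    values <- aperm(array(z, c(n, d[1], d[2])), c(2, 3, 1))
  }
  structure(list(values = values, labels = epochs$labels,
                 sfreq = epochs$sfreq, tmin_ms = epochs$tmin_ms,
                 channel_names = epochs$channel_names,
                 positions = epochs$positions, n_edge = epochs$n_edge,
                 band = if (is.null(epochs$band)) "unfiltered" else epochs$band),
            class = "analytic_epochs")
}

#' @export
print.analytic_epochs <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<analytic_epochs> %s band: %d trials x %d channels x %d samples @ %g Hz\n",
              x$band, d[1], d[2], d[3], x$sfreq))
  if (x$n_edge > 0)
    cat(sprintf("  %d edge samples invalid per side (%g ms)\n", x$n_edge,
                x$n_edge / x$sfreq * 1000))
  invisible(x)
}

#' Instantaneous amplitude (power sequence)
#' @param analytic an `analytic_epochs` object.
#' @return real array of `Mod(values)`.
#' @export
amplitude_of <- function(analytic) Mod(analytic$values)

#' Instantaneous phase sequence in `(-pi, pi]`
#' @param analytic an `analytic_epochs` object.
#' @export
phase_of <- function(analytic) Arg(analytic$values)

#' Unwrap a phase sequence
#'
#' Removes 2*pi jumps so that successive differences are in `(-pi, pi]`;
#' the slope of the unwrapped phase of an analytic signal is its
#' instantaneous frequency (rad/sample).
#' @param p numeric vector of wrapped phases.
#' @export
unwrap_phase <- function(p) {
  d <- diff(p)
  p + c(0, cumsum(-2 * pi * round(d / (2 * pi))))
}

#' Analysis window specification
#'
#' @param start_ms window start in ms relative to stimulus onset.
#' @param length_ms window length in ms (default 200, i.e. 100 samples at
#'   500 Hz).
#' @return object of class `window_spec`.
#' @export
window_spec <- function(start_ms, length_ms = 200) {
  if (length_ms <= 0) stop("length_ms must be positive")
  structure(list(start_ms = start_ms, length_ms = length_ms),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %g..%g ms (midpoint %g ms)\n", x$start_ms,
              x$start_ms + x$length_ms, x$start_ms + x$length_ms / 2))
  invisible(x)
}

#' Grids of analysis windows
#'
#' `"sliding"`: sixteen 200 ms windows with starts -100, -60, ..., 500 ms
#' (40 ms step), i.e. midpoints 0..600 ms -- the grid used for band-by-time
#' significance maps. `"growing"`: three hundred windows anchored at 0 ms
#' with lengths 2, 4, ..., 600 ms, used to locate when stimulus information
#' first accumulates.
#'
#' @param mode `"sliding"` or `"growing"`.
#' @return list of [window_spec()] objects.
#' @export
make_window_grid <- function(mode = c("sliding", "growing")) {
  mode <- match.arg(mode)
  if (mode == "sliding")
    lapply(seq(-100, 500, by = 40), window_spec, length_ms = 200)
  else
    lapply(seq(2, 600, by = 2), function(l) window_spec(0, l))
}

#' Extract a per-trial feature matrix from one electrode and window
#'
#' Row `t` of the feature matrix holds trial `t`'s per-sample instantaneous
#' power (`signal_kind = "power"`) or phase (`signal_kind = "phase"`) at the
#' chosen electrode over the window. Phase features default to the raw angle
#' in `(-pi, pi]`; `phase_encoding = "sincos"` instead interleaves
#' `cos(P), sin(P)` per sample (2x features), removing the wrap
#' discontinuity at the cost of doubling dimensionality.
#'
#' Windows overlapping the filter-edge region (`n_edge` samples at either
#' end of the epoch) are refused.
#'
#' @param analytic an `analytic_epochs` object.
#' @param window a [window_spec()].
#' @param electrode channel name.
#' @param signal_kind `"phase"` or `"power"`.
#' @param phase_encoding `"angle"` (default) or `"sincos"`.
#' @return object of class `feature_matrix`: `X` (`n_trials x n_features`),
#'   `labels`, `signal_kind`, `electrode`, `window`, `band`, `encoding`.
#' @export
extract_window <- function(analytic, window, electrode,
                           signal_kind = c("phase", "power"),
                           phase_encoding = c("angle", "sincos")) {
  signal_kind <- match.arg(signal_kind)
  phase_encoding <- match.arg(phase_encoding)
  d <- dim(analytic$values)
  ch <- match(electrode, analytic$channel_names)
  if (is.na(ch)) stop("unknown channel name(s): ", electrode)
  i1 <- sample_at(analytic, window$start_ms)
  nw <- as.integer(round(window$length_ms / 1000 * analytic$sfreq))
  i2 <- i1 + nw - 1L
  if (i1 < 1L || i2 > d[3])
    stop("window ", window$start_ms, "..", window$start_ms + window$length_ms,
         " ms outside the epoch")
  if (i1 <= analytic$n_edge || i2 > d[3] - analytic$n_edge)
    stop("window ", window$start_ms, "..", window$start_ms + window$length_ms,
         " ms overlaps the filter edge region (first/last ", analytic$n_edge,
         " samples are invalid)")
  z <- matrix(analytic$values[, ch, i1:i2, drop = FALSE], nrow = d[1], ncol = nw)
  if (signal_kind == "power") {
    X <- Mod(z)
  } else if (phase_encoding == "angle") {
    X <- Arg(z)
  } else {
    P <- Arg(z)
    X <- matrix(0, nrow = d[1], ncol = 2L * nw)
    X[, seq(1, 2 * nw, by = 2)] <- cos(P)
    X[, seq(2, 2 * nw, by = 2)] <- sin(P)
  }
  structure(list(X = X, labels = analytic$labels, signal_kind = signal_kind,
                 electrode = electrode, window = window, band = analytic$band,
                 encoding = if (signal_kind == "phase") phase_encoding else "amplitude"),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s %s @ %s, window %g..%g ms: %d trials x %d features\n",
              x$band, x$signal_kind, x$electrode, x$window$start_ms,
              x$window$start_ms + x$window$length_ms, nrow(x$X), ncol(x$X)))
  invisible(x)
}
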