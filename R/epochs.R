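#' Epoched multichannel EEG
#'
#' Container for stimulus-locked EEG epochs: a real-valued array of
#' `n_trials x n_channels x n_samples` microvolt values plus per-trial class
#' labels and channel metadata. All times in the API are milliseconds
#' relative to stimulus onset (onset = 0 ms); the sample holding time `t` is
#' `round((t - tmin_ms)/1000 * sfreq) + 1` (1-based).
#'
#' @param data numeric array `[n_trials, n_channels, n_samples]`, microvolts.
#' @param labels integer vector, one class index in `0:4` per trial.
#' @param sfreq sampling rate in Hz (default 500).
#' @param tmin_ms epoch start relative to stimulus onset, ms (default -500).
#' @param channel_names unique channel identifiers (10-10 names). Defaults to
#'   the `dimnames` of `data` or `Ch1..ChK`.
#' @param positions optional `n_channels x 2` matrix of schematic scalp-plane
#'   coordinates (arbitrary units) used only for topography.
#' @param n_edge number of samples at each end of the epoch that are
#'   filter-edge contaminated and must not enter analysis windows (0 for
#'   unfiltered data).
#' @return An object of class `eeg_epochs`.
#' @seealso [select_channels()], [write_epochs()], [generate_dataset()]
#' @export
eeg_epochs <- function(data, labels, sfreq = 500, tmin_ms = -500,
                       channel_names = NULL, positions = NULL, n_edge = 0L) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array [trials x channels x samples]")
  storage.mode(data) <- "double"
  if (is.null(channel_names)) {
    channel_names <- dimnames(data)[[2]]
    if (is.null(channel_names)) channel_names <- paste0("Ch", seq_len(dim(data)[2]))
  }
  x <- structure(
    list(data = data, labels = as.integer(labels), sfreq = as.numeric(sfreq),
         tmin_ms = as.numeric(tmin_ms), channel_names = as.character(channel_names),
         positions = if (is.null(positions)) NULL else
           matrix(as.numeric(positions), ncol = 2L),
         n_edge = as.integer(n_edge)),
    class = "eeg_epochs")
  validate_epochs(x)
  x
}

validate_epochs <- function(x) {
  d <- dim(x$data)
  if (length(x$labels) != d[1])
    stop("invalid epochs: length(labels) [", length(x$labels),
         "] != n_trials [", d[1], "]")
  if (d[1] > 0 && (anyNA(x$labels) || any(x$labels < 0L | x$labels > 4L)))
    stop("invalid epochs: labels must be class indices in 0..4")
  if (length(x$channel_names) != d[2])
    stop("invalid epochs: length(channel_names) != n_channels")
  if (anyDuplicated(x$channel_names))
    stop("invalid epochs: channel_names must be unique")
  if (!is.null(x$positions) && nrow(x$positions) != d[2])
    stop("invalid epochs: positions must have one row per channel")
  if (x$sfreq <= 0) stop("invalid epochs: sfreq must be positive")
  if (x$n_edge < 0 || 2L * x$n_edge > d[3])
    stop("invalid epochs: n_edge out of range")
  invisible(x)
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sfreq))
  cat(sprintf("  epoch %g..%g ms re stimulus onset", x$tmin_ms, tmax_ms(x)))
  if (x$n_edge > 0)
    cat(sprintf("; %d edge samples invalid per side", x$n_edge))
  cat("\n")
  if (d[1] > 0)
    cat("  trials/class:", paste(table(factor(x$labels, 0:4)), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.eeg_epochs <- function(object, ...) {
  print(object)
  cat("  channels:", paste(head(object$channel_names, 12), collapse = " "),
      if (length(object$channel_names) > 12) "...", "\n")
  cat(sprintf("  amplitude range: %.2f .. %.2f uV\n",
              min(object$data), max(object$data)))
  invisible(object)
}

#' Epoch end time in ms
#' @param epochs an `eeg_epochs` object.
#' @return end of the epoch in ms relative to stimulus onset.
#' @export
tmax_ms <- function(epochs) {
  epochs$tmin_ms + dim(epochs$data)[3] / epochs$sfreq * 1000
}

#' Sample index of a time point
#'
#' 1-based index of the sample holding time `t_ms`; the zero-based offset is
#' `round((t - tmin)/1000 * sfreq)`.
#' @param epochs an `eeg_epochs` (or `analytic_epochs`) object.
#' @param t_ms time in ms relative to stimulus onset.
#' @export
sample_at <- function(epochs, t_ms) {
  as.integer(round((t_ms - epochs$tmin_ms) / 1000 * epochs$sfreq)) + 1L
}

#' Parieto-occipital analysis channels
#'
#' The 17 parieto-occipital electrode sites over which decoding is evaluated:
#' P7, P5, P3, P1, Pz, P2, P4, P6, P8, PO7, PO3, POz, PO4, PO8, O1, Oz, O2.
#' @return character vector of 17 channel names.
#' @export
posterior_channels <- function() {
  c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2")
}

#' Select and reorder channels
#'
#' @param epochs an `eeg_epochs` object.
#' @param channels ordered character vector of channel names to keep; all
#'   must exist in `epochs`.
#' @return an `eeg_epochs` with the channel axis ordered as `channels`;
#'   trials and samples untouched.
#' @export
select_channels <- function(epochs, channels = posterior_channels()) {
  idx <- match(channels, epochs$channel_names)
  if (anyNA(idx))
    stop("unknown channel name(s): ",
         paste(channels[is.na(idx)], collapse = ", "))
  eeg_epochs(epochs$data[, idx, , drop = FALSE], epochs$labels,
             sfreq = epochs$sfreq, tmin_ms = epochs$tmin_ms,
             channel_names = epochs$channel_names[idx],
             positions = if (is.null(epochs$positions)) NULL else
               epochs$positions[idx, , drop = FALSE],
             n_edge = epochs$n_edge)
}

# ---- serialization -------------------------------------------------------

EPOCH_MAGIC <- charToRaw("EEGEPOC1")

#' Write epochs to a single-file binary container
#'
#' Layout: 8 magic bytes `"EEGEPOC1"`, a 4-byte little-endian integer giving
#' the byte length of a UTF-8 JSON header (fields: `version`, `sfreq`,
#' `tmin_ms`, `tmax_ms`, `dims`, `labels`, `channel_names`, `positions`,
#' `n_edge`), then `prod(dims)` IEEE-754 doubles, little-endian, in R
#' column-major order of the `[trials, channels, samples]` array. The
#' round trip through [read_epochs()] is bit-exact.
#'
#' @param epochs an `eeg_epochs` object (validated before writing).
#' @param path output file path.
#' @export
write_epochs <- function(epochs, path) {
  validate_epochs(epochs)
  hdr <- list(version = 1L, sfreq = epochs$sfreq, tmin_ms = epochs$tmin_ms,
              tmax_ms = tmax_ms(epochs), dims = dim(epochs$data),
              labels = epochs$labels, channel_names = epochs$channel_names,
              positions = epochs$positions, n_edge = epochs$n_edge)
  json <- charToRaw(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA,
                                     null = "null"))
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeBin(EPOCH_MAGIC, con)
  writeBin(length(json), con, size = 4L, endian = "little")
  writeBin(json, con)
  writeBin(as.vector(epochs$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read epochs from the binary container
#'
#' All `eeg_epochs` invariants are validated on load; a malformed or
#' truncated file raises a format error naming the offending field.
#' @param path file written by [write_epochs()] (or conforming to the
#'   documented layout).
#' @return an `eeg_epochs` object.
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 8L)
  if (length(magic) < 8L || !identical(magic, EPOCH_MAGIC))
    stop("format error: bad magic bytes (not an epoch container)")
  hlen <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(hlen) != 1L || is.na(hlen) || hlen <= 0L)
    stop("format error: bad header length")
  json <- readBin(con, "raw", n = hlen)
  if (length(json) < hlen) stop("format error: truncated header")
  hdr <- tryCatch(jsonlite::fromJSON(rawToChar(json)),
                  error = function(e) stop("format error: unparsable header"))
  for (f in c("sfreq", "tmin_ms", "tmax_ms", "dims", "labels", "channel_names"))
    if (is.null(hdr[[f]]))
      stop("format error: missing header field '", f, "'")
  dims <- as.integer(hdr$dims)
  if (length(dims) != 3L || anyNA(dims) || any(dims < 0L))
    stop("format error: field 'dims' must be three non-negative integers")
  expect_n <- round((hdr$tmax_ms - hdr$tmin_ms) / 1000 * hdr$sfreq)
  if (dims[3] != expect_n)
    stop("format error: field 'dims' inconsistent with tmin_ms/tmax_ms/sfreq",
         " (n_samples ", dims[3], ", expected ", expect_n, ")")
  payload <- readBin(con, "double", n = prod(dims), size = 8L,
                     endian = "little")
  if (length(payload) < prod(dims))
    stop("format error: truncated data payload (field 'data')")
  labels <- if (dims[1] == 0L) integer(0) else as.integer(hdr$labels)
  pos <- hdr$positions
  if (!is.null(pos) && length(pos)) pos <- matrix(as.numeric(pos), ncol = 2L)
  else pos <- NULL
  eeg_epochs(array(payload, dims), labels, sfreq = hdr$sfreq,
             tmin_ms = hdr$tmin_ms, channel_names = as.character(hdr$channel_names),
             positions = pos,
             n_edge = if (is.null(hdr$n_edge)) 0L else as.integer(hdr$n_edge))
}

# ---- montage -------------------------------------------------------------

#' Schematic 64-channel 10-10 montage
#'
#' Channel names of a standard 64-electrode 10-10 layout together with
#' schematic 2-D scalp-plane coordinates (head radius ~1, nose up; arbitrary
#' units). The coordinates are a stylized projection -- rows of the 10-10
#' grid at fixed heights, lateral rank spread symmetrically -- sufficient for
#' topographic interpolation, which needs only the relative layout.
#'
#' @return data.frame with columns `name`, `x`, `y` (64 rows).
#' @export
standard_montage <- function() {
  rows <- list(
    Fp = list(y = 0.85, ch = c("Fp1", "Fp2")),
    AF = list(y = 0.68, ch = c("AF7", "AF3", "AF4", "AF8")),
    F  = list(y = 0.50, ch = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8")),
    FC = list(y = 0.28, ch = c("FT9", "FT7", "FC5", "FC3", "FC1", "FC2", "FC4", "FC6", "FT8", "FT10")),
    C  = list(y = 0.00, ch = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8")),
    CP = list(y = -0.28, ch = c("TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10")),
    P  = list(y = -0.50, ch = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8")),
    PO = list(y = -0.68, ch = c("PO9", "PO7", "PO3", "POz", "PO4", "PO8", "PO10")),
    O  = list(y = -0.85, ch = c("O1", "Oz", "O2")))
  out <- do.call(rbind, lapply(rows, function(r) {
    n <- vapply(r$ch, channel_lateral_rank, numeric(1))
    data.frame(name = r$ch, x = n * 0.19, y = r$y)
  }))
  rownames(out) <- NULL
  out
}

# Signed lateral rank of a 10-10 channel name: z -> 0, odd numbers left
# (negative), even right; |rank| = ceil(number/2).
channel_lateral_rank <- function(name) {
  if (grepl("z$", name)) return(0)
  k <- as.integer(sub("^[A-Za-z]+", "", name))
  ceiling(k / 2) * if (k %% 2 == 1) -1 else 1
}
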