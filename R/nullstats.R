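#' Shuffled-label max-statistic permutation null
#'
#' Builds the null distribution of decoding accuracy under the hypothesis of
#' no label information, while accounting for the selection of the best
#' electrode: on each permutation a subject is drawn uniformly at random,
#' that subject's trial labels are shuffled uniformly, the full per-electrode
#' cross-validated decoding is run, and the maximum accuracy across the
#' electrode subset is recorded. Because of the max over electrodes the null
#' mean sits above the 1/5 chance level whenever more than one electrode is
#' in play; thresholds derived from this ensemble therefore control the
#' familywise error of the electrode search.
#'
#' @param datasets a single `analytic_epochs` object or a list of them (one
#'   per subject).
#' @param window a [window_spec()].
#' @param signal_kind `"phase"` or `"power"`.
#' @param channels electrode names (default: the 17 parieto-occipital sites
#'   present in the first dataset).
#' @param config an [svm_config()].
#' @param n_perm number of label permutations (default 100).
#' @param n_folds folds for each decoding run (default 30).
#' @param seed integer seed governing subject draws, shuffles and fold
#'   assignment.
#' @param phase_encoding passed to [extract_window()].
#' @return object of class `null_ensemble` with `values` (`n_perm`
#'   max-over-electrode accuracies) and unset fit fields; see
#'   [fit_null_normal()].
#' @export
permutation_null <- function(datasets, window, signal_kind = "phase",
                             channels = NULL, config = svm_config(),
                             n_perm = 100, n_folds = 30, seed = NULL,
                             phase_encoding = "angle") {
  if (inherits(datasets, "analytic_epochs")) datasets <- list(datasets)
  if (length(datasets) < 1L) stop("need at least one dataset")
  if (is.null(channels))
    channels <- intersect(posterior_channels(), datasets[[1]]$channel_names)
  # slice features once per subject x electrode
  feats <- lapply(datasets, function(d)
    lapply(stats::setNames(channels, channels), function(ch)
      extract_window(d, window, ch, signal_kind, phase_encoding)))
  seeds <- child_seeds(seed, 2L * n_perm)
  values <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    subj <- with_seed(seeds[[p]], sample.int(length(datasets), 1L))
    labs <- feats[[subj]][[1]]$labels
    shuffled <- with_seed(seeds[[n_perm + p]], labs[sample.int(length(labs))])
    acc <- vapply(feats[[subj]], function(fm) {
      fm$labels <- shuffled
      cfg <- config
      cfg$seed <- if (is.null(seed)) NULL else seeds[[n_perm + p]]
      cross_validate(fm, cfg, n_folds = n_folds)$accuracy
    }, 0)
    values[p] <- max(acc)
  }
  structure(list(values = values, n_perm = n_perm, n_electrodes = length(channels),
                 signal_kind = signal_kind, window = window,
                 fit_mean = NA_real_, fit_sd = NA_real_, ks_stat = NA_real_,
                 ks_p = NA_real_, fit_cutoff = NULL),
            class = "null_ensemble")
}

#' Construct a null ensemble from precomputed values
#'
#' For working directly with max-accuracy draws obtained elsewhere (or
#' simulated) without re-running the decoder.
#' @param values numeric vector of accuracies in `[0, 1]`.
#' @param n_electrodes number of electrodes the max was taken over.
#' @export
null_ensemble <- function(values, n_electrodes = NA_integer_) {
  if (any(values < 0 | values > 1)) stop("accuracies must lie in [0, 1]")
  structure(list(values = values, n_perm = length(values),
                 n_electrodes = n_electrodes, signal_kind = NA_character_,
                 window = NULL, fit_mean = NA_real_, fit_sd = NA_real_,
                 ks_stat = NA_real_, ks_p = NA_real_, fit_cutoff = NULL),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %d shuffled-label max accuracies over %s electrodes\n",
              x$n_perm, x$n_electrodes))
  cat(sprintf("  empirical mean %.4f, sd %.4f\n", mean(x$values), sd(x$values)))
  if (!is.na(x$fit_mean))
    cat(sprintf("  normal fit: mean %.4f, sd %.4f (K-S D = %.3f, p = %.3f)%s\n",
                x$fit_mean, x$fit_sd, x$ks_stat, x$ks_p,
                if (!is.null(x$fit_cutoff))
                  sprintf(" [fit on values <= %.3g]", x$fit_cutoff) else ""))
  invisible(x)
}

#' Fit a normal distribution to a null ensemble
#'
#' Sets `fit_mean`/`fit_sd` to the sample mean/SD of the (optionally
#' truncated) ensemble and runs a Kolmogorov-Smirnov test of the retained
#' values against that fitted normal. Note the plain K-S p-value is
#' anti-conservative when the parameters are estimated from the same data;
#' `lilliefors = TRUE` applies the Lilliefors correction instead.
#'
#' @param ensemble a `null_ensemble`.
#' @param cutoff optional upper accuracy cutoff: only values `<= cutoff`
#'   enter the fit (used to fit the normal body while excluding the extreme
#'   right tail).
#' @param lilliefors use the Lilliefors-corrected normality test.
#' @return the ensemble with fit fields populated.
#' @export
fit_null_normal <- function(ensemble, cutoff = NULL, lilliefors = FALSE) {
  v <- ensemble$values
  if (!is.null(cutoff)) v <- v[v <= cutoff]
  if (length(v) < 20L)
    stop("cannot fit: only ", length(v),
         " values retained (need >= 20); raise the cutoff")
  m <- mean(v); s <- sd(v)
  if (!is.finite(s) || s <= 0)
    stop("cannot fit: retained values are degenerate (zero spread)")
  if (lilliefors) {
    kt <- nortest::lillie.test(v)
    ks_stat <- unname(kt$statistic); ks_p <- kt$p.value
  } else {
    kt <- suppressWarnings(stats::ks.test(v, "pnorm", mean = m, sd = s))
    ks_stat <- unname(kt$statistic); ks_p <- kt$p.value
  }
  ensemble$fit_mean <- m
  ensemble$fit_sd <- s
  ensemble$ks_stat <- ks_stat
  ensemble$ks_p <- ks_p
  ensemble$fit_cutoff <- cutoff
  ensemble
}

#' k-sigma significance threshold
#'
#' The accuracy level `mean + k * sd` of the fitted null; with `k = 3` the
#' one-tailed normal exceedance probability is about 0.00135 (the
#' "three-sigma" criterion). Works on whatever scale the inputs share
#' (fractions or percentage points).
#'
#' @param mean,sd null mean and standard deviation.
#' @param k number of standard deviations (default 3).
#' @export
sigma_threshold <- function(mean, sd, k = 3) {
  if (any(sd < 0)) stop("sd must be non-negative")
  mean + k * sd
}

#' Convert an accuracy into a one-tailed p-value and log10(1/p)
#'
#' `p` is the upper-tail probability of the fitted null normal at the given
#' accuracy; `log10(1/p)` is the significance representation used in the
#' band-by-time maps (larger = more significant). `p` is floored at the
#' smallest representable positive double before taking the logarithm.
#'
#' @param accuracy accuracy value(s) on the same scale as the null fit.
#' @param null a fitted `null_ensemble` (see [fit_null_normal()]).
#' @return list with vectors `p` and `log10_inv_p`.
#' @export
accuracy_to_logp <- function(accuracy, null) {
  if (is.na(null$fit_mean) || is.na(null$fit_sd))
    stop("null ensemble is not fitted; call fit_null_normal() first")
  p <- stats::pnorm(accuracy, mean = null$fit_mean, sd = null$fit_sd,
                    lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  list(p = p, log10_inv_p = log10(1 / p))
}

#' Band-by-time decoding significance map
#'
#' For every frequency band and every analysis window, each subject's
#' epochs are band-filtered, Hilbert-transformed and decoded per electrode;
#' the per-subject best-electrode accuracy is averaged across subjects
#' (default) and converted into a one-tailed p-value and `log10(1/p)` under
#' the fitted max-statistic null. `aggregate = "best_of_mean"` instead
#' averages each electrode's accuracy across subjects first and then takes
#' the best electrode.
#'
#' @param datasets a single `eeg_epochs` or list of them (one per subject),
#'   baseline-corrected, unfiltered.
#' @param null a fitted `null_ensemble`.
#' @param bands data.frame like [canonical_bands()] (columns `name`,
#'   `low_hz`, `high_hz`).
#' @param windows list of [window_spec()]s, e.g.
#'   `make_window_grid("sliding")`.
#' @param signal_kind `"phase"` or `"power"`.
#' @param channels electrode names (default: posterior 17 present).
#' @param config an [svm_config()].
#' @param n_folds folds per decoding run (default 30).
#' @param transition_hz FIR transition width used for the per-band filters
#'   (default 3; see [filter_band()]).
#' @param aggregate `"mean_of_best"` (default) or `"best_of_mean"`.
#' @return object of class `significance_map` with `bands x windows`
#'   matrices `accuracy`, `p`, `log10_inv_p`, `best_electrode`, plus the
#'   window midpoints.
#' @export
band_time_significance <- function(datasets, null, bands = canonical_bands(),
                                   windows = make_window_grid("sliding"),
                                   signal_kind = "phase", channels = NULL,
                                   config = svm_config(), n_folds = 30,
                                   transition_hz = 3,
                                   aggregate = c("mean_of_best", "best_of_mean")) {
  aggregate <- match.arg(aggregate)
  if (inherits(datasets, "eeg_epochs")) datasets <- list(datasets)
  if (is.null(channels))
    channels <- intersect(posterior_channels(), datasets[[1]]$channel_names)
  nb <- nrow(bands); nw <- length(windows); ns <- length(datasets)
  acc <- p <- lp <- matrix(NA_real_, nb, nw,
                           dimnames = list(bands$name, NULL))
  best_el <- matrix(NA_character_, nb, nw, dimnames = list(bands$name, NULL))
  for (b in seq_len(nb)) {
    spec <- band_spec(bands$name[b], bands$low_hz[b], bands$high_hz[b])
    analytic <- lapply(datasets, function(e)
      analytic_signal(filter_band(e, spec, transition_hz = transition_hz)))
    for (w in seq_len(nw)) {
      per_subj <- sapply(analytic, function(a)
        accuracies(decode_electrodes(a, windows[[w]], signal_kind,
                                     channels = channels, config = config,
                                     n_folds = n_folds)))
      per_subj <- matrix(per_subj, nrow = length(channels))  # electrodes x subjects
      if (aggregate == "mean_of_best") {
        acc[b, w] <- mean(apply(per_subj, 2, max))
        best_el[b, w] <- channels[which.max(rowMeans(per_subj))]
      } else {
        em <- rowMeans(per_subj)
        acc[b, w] <- max(em)
        best_el[b, w] <- channels[which.max(em)]
      }
    }
  }
  conv <- accuracy_to_logp(acc, null)
  p[] <- conv$p; lp[] <- conv$log10_inv_p
  mids <- vapply(windows, function(w) w$start_ms + w$length_ms / 2, 0)
  structure(list(accuracy = acc, p = p, log10_inv_p = lp,
                 best_electrode = best_el, midpoints_ms = mids,
                 starts_ms = vapply(windows, function(w) w$start_ms, 0),
                 lengths_ms = vapply(windows, function(w) w$length_ms, 0),
                 bands = bands, signal_kind = signal_kind,
                 n_subjects = ns, aggregate = aggregate),
            class = "significance_map")
}

#' @export
print.significance_map <- function(x, ...) {
  cat(sprintf("<significance_map> %s: %d bands x %d windows, %d subject(s)\n",
              x$signal_kind, nrow(x$accuracy), ncol(x$accuracy), x$n_subjects))
  cat("log10(1/p):\n")
  m <- round(x$log10_inv_p, 2)
  colnames(m) <- x$midpoints_ms
  print(m)
  invisible(x)
}

#' @export
plot.significance_map <- function(x, what = c("log10_inv_p", "accuracy"), ...) {
  what <- match.arg(what)
  z <- x[[what]]
  image(x = x$midpoints_ms, y = seq_len(nrow(z)), z = t(z),
        col = hcl.colors(64, "YlOrRd", rev = TRUE), yaxt = "n",
        xlab = "window midpoint (ms)", ylab = "",
        main = sprintf("%s %s", x$signal_kind,
                       if (what == "accuracy") "accuracy" else "log10(1/P)"), ...)
  axis(2, at = seq_len(nrow(z)), labels = rownames(z), las = 2)
  invisible(x)
}

#' Best-performing window per band
#'
#' Per band, the window with the highest significance (`log10(1/p)`,
#' equivalently highest accuracy under a fixed null); ties resolved to the
#' earliest window.
#'
#' @param map a `significance_map`.
#' @return data.frame with one row per band: `band`, `window_index`,
#'   `start_ms`, `midpoint_ms`, `accuracy`, `log10_inv_p`, `best_electrode`.
#' @export
best_window_per_band <- function(map) {
  idx <- apply(map$log10_inv_p, 1, which.max)  # which.max takes first on ties
  data.frame(
    band = rownames(map$accuracy),
    window_index = idx,
    start_ms = map$starts_ms[idx],
    midpoint_ms = map$midpoints_ms[idx],
    accuracy = map$accuracy[cbind(seq_len(nrow(map$accuracy)), idx)],
    log10_inv_p = map$log10_inv_p[cbind(seq_len(nrow(map$accuracy)), idx)],
    best_electrode = map$best_electrode[cbind(seq_len(nrow(map$accuracy)), idx)],
    row.names = NULL)
}

#' Two-way ANOVA comparing phase vs power decoding across electrodes
#'
#' Takes per-subject accuracies for the two signal kinds over a common
#' electrode set (a balanced layout: `n_subjects x n_electrodes` per kind),
#' fits the two-way fixed-effects ANOVA with factors signal kind and
#' electrode (subjects as replicates, including the interaction), and runs
#' Tukey-Kramer studentized-range pairwise comparisons on both factors.
#'
#' @param power_acc,phase_acc numeric matrices `n_subjects x n_electrodes`
#'   with identical dimensions; column names (electrodes) are carried into
#'   the report.
#' @return object of class `phase_power_anova`: the ANOVA table, per-factor
#'   F and p, and `TukeyHSD` pairwise confidence intervals.
#' @export
compare_phase_power <- function(power_acc, phase_acc) {
  power_acc <- as.matrix(power_acc); phase_acc <- as.matrix(phase_acc)
  if (!all(dim(power_acc) == dim(phase_acc)))
    stop("layout error: power and phase matrices must have identical",
         " subjects x electrodes dimensions")
  el <- colnames(power_acc)
  if (is.null(el)) el <- paste0("E", seq_len(ncol(power_acc)))
  long <- data.frame(
    accuracy = c(as.vector(power_acc), as.vector(phase_acc)),
    kind = factor(rep(c("power", "phase"), each = length(power_acc)),
                  levels = c("power", "phase")),
    electrode = factor(rep(rep(el, each = nrow(power_acc)), 2), levels = el))
  fit <- stats::aov(accuracy ~ kind * electrode, data = long)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  tk <- stats::TukeyHSD(fit, which = c("kind", "electrode"))
  structure(list(
    anova_table = tab,
    kind_F = tab["kind", "F value"], kind_p = tab["kind", "Pr(>F)"],
    electrode_F = tab["electrode", "F value"],
    electrode_p = tab["electrode", "Pr(>F)"],
    mean_power = mean(power_acc), mean_phase = mean(phase_acc),
    tukey = tk, n_subjects = nrow(power_acc)),
    class = "phase_power_anova")
}

#' @export
print.phase_power_anova <- function(x, ...) {
  cat(sprintf("<phase_power_anova> %d subjects: phase mean %.4f vs power mean %.4f\n",
              x$n_subjects, x$mean_phase, x$mean_power))
  cat(sprintf("  kind:      F = %.2f, p = %.3g\n", x$kind_F, x$kind_p))
  cat(sprintf("  electrode: F = %.2f, p = %.3g\n", x$electrode_F, x$electrode_p))
  invisible(x)
}

#' One-way ANOVA of best-window accuracies across frequency bands
#'
#' Tests whether the decoding accuracy at each band's best window differs
#' across bands, with optional pairwise two-sample t-tests (equal-variance,
#' matching the conventional `ttest2` defaults) for designated band pairs.
#'
#' @param band_acc numeric matrix `n_subjects x n_bands` (column names =
#'   band names).
#' @param pairs optional list of length-2 character vectors of band names to
#'   compare pairwise.
#' @return list with the ANOVA `F`, `p`, full `anova_table`, and a
#'   data.frame `pairwise` (band1, band2, t, p) when `pairs` is given.
#' @export
band_accuracy_anova <- function(band_acc, pairs = NULL) {
  band_acc <- as.matrix(band_acc)
  if (ncol(band_acc) < 2 || nrow(band_acc) < 2)
    stop("need at least 2 bands and 2 subjects")
  bands <- colnames(band_acc)
  if (is.null(bands)) bands <- paste0("band", seq_len(ncol(band_acc)))
  colnames(band_acc) <- bands
  long <- data.frame(accuracy = as.vector(band_acc),
                     band = factor(rep(bands, each = nrow(band_acc)),
                                   levels = bands))
  if (stats::sd(long$accuracy) == 0)
    stop("degenerate input: zero variance across all cells")
  fit <- stats::aov(accuracy ~ band, data = long)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  out <- list(F = tab["band", "F value"], p = tab["band", "Pr(>F)"],
              anova_table = tab)
  if (!is.null(pairs)) {
    out$pairwise <- do.call(rbind, lapply(pairs, function(pr) {
      tt <- stats::t.test(band_acc[, pr[1]], band_acc[, pr[2]],
                          var.equal = TRUE)
      data.frame(band1 = pr[1], band2 = pr[2],
                 t = unname(tt$statistic), p = tt$p.value)
    }))
  }
  out
}
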