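test_that("k-sigma thresholds are exact and linear", {
  expect_equal(sigma_threshold(23.81, 1.76, 3), 29.09, tolerance = 1e-12)
  expect_equal(sigma_threshold(20, 0, 3), 20)
  expect_equal(sigma_threshold(10, 1, 2), 12)
  # linearity in both arguments
  expect_equal(sigma_threshold(2 * 10, 2 * 1, 3), 2 * sigma_threshold(10, 1, 3))
  expect_equal(sigma_threshold(10 + 5, 1, 3), sigma_threshold(10, 1, 3) + 5)
  expect_error(sigma_threshold(10, -1), "non-negative")
})

test_that("accuracy-to-p conversion follows the fitted normal upper tail", {
  null <- fit_null_normal(null_ensemble(
    phasedecode:::with_seed(8, rnorm(100, 0.238, 0.018))))
  at_mean <- accuracy_to_logp(null$fit_mean, null)
  expect_equal(at_mean$p, 0.5)
  expect_equal(at_mean$log10_inv_p, log10(2), tolerance = 1e-10)
  at_3s <- accuracy_to_logp(sigma_threshold(null$fit_mean, null$fit_sd, 3), null)
  expect_equal(at_3s$p, stats::pnorm(-3), tolerance = 1e-10)
  expect_equal(at_3s$p, 0.00135, tolerance = 1e-3)
  # p strictly decreasing in accuracy
  accs <- seq(0.15, 0.6, by = 0.05)
  expect_true(all(diff(accuracy_to_logp(accs, null)$p) < 0))
  # unfitted ensemble is refused
  expect_error(accuracy_to_logp(0.3, null_ensemble(runif(30, 0.1, 0.3))),
               "not fitted")
})

test_that("normal fit recovers parameters and rejects degenerate input", {
  v <- phasedecode:::with_seed(15, rnorm(100, 0.238, 0.0176))
  fit <- fit_null_normal(null_ensemble(pmin(pmax(v, 0), 1)))
  expect_lt(abs(fit$fit_mean - 0.238), 0.005)
  expect_lt(abs(fit$fit_sd - 0.0176), 0.005)
  expect_true(is.finite(fit$ks_stat) && fit$ks_stat >= 0)
  expect_true(fit$ks_p > 0 && fit$ks_p <= 1)

  # truncated fit uses only values below the cutoff
  cut <- fit_null_normal(null_ensemble(pmin(pmax(v, 0), 1)), cutoff = 0.29)
  expect_lte(cut$fit_mean, fit$fit_mean + 1e-12)
  expect_identical(cut$fit_cutoff, 0.29)

  # Lilliefors variant returns its corrected statistic
  lf <- fit_null_normal(null_ensemble(pmin(pmax(v, 0), 1)), lilliefors = TRUE)
  expect_true(is.finite(lf$ks_p))

  expect_error(fit_null_normal(null_ensemble(rep(0.2, 50))), "degenerate")
  expect_error(fit_null_normal(null_ensemble(v), cutoff = 0.1), ">= 20")
})

test_that("permutation null has the requested size and is seed-deterministic", {
  cfg <- synth_config(n_per_class = 8, coding = "none",
                      channels = c("PO8", "Oz"), seed = 40)
  an <- analytic_signal(filter_band(baseline_correct(generate_dataset(cfg)),
                                    "theta"))
  null <- permutation_null(an, window_spec(150, 200), "phase",
                           channels = "PO8", n_perm = 20, n_folds = 5,
                           seed = 123)
  expect_length(null$values, 20)
  expect_true(all(null$values >= 0 & null$values <= 1))
  # single electrode: no max-inflation, mean near chance
  expect_lt(abs(mean(null$values) - 0.2), 0.05)
  null2 <- permutation_null(an, window_spec(150, 200), "phase",
                            channels = "PO8", n_perm = 20, n_folds = 5,
                            seed = 123)
  expect_identical(null$values, null2$values)
  null3 <- permutation_null(an, window_spec(150, 200), "phase",
                            channels = "PO8", n_perm = 20, n_folds = 5,
                            seed = 124)
  expect_false(identical(null$values, null3$values))
})

test_that("band-by-time map localizes a theta phase code and has grid shape", {
  cfg <- synth_config(n_per_class = 10, coding = "phase", snr = 2,
                      channels = c("PO8", "P7"), target_channels = "PO8",
                      seed = 21)
  ep <- baseline_correct(generate_dataset(cfg))
  null <- fit_null_normal(null_ensemble(
    phasedecode:::with_seed(3, pmin(pmax(rnorm(100, 0.23, 0.02), 0), 1))))
  map <- suppressWarnings(band_time_significance(
    ep, null, channels = c("PO8", "P7"), config = svm_config(seed = 2),
    n_folds = 5))
  expect_identical(dim(map$accuracy), c(6L, 16L))
  expect_identical(rownames(map$accuracy), canonical_bands()$name)
  expect_equal(map$midpoints_ms, seq(0, 600, by = 40))
  # p consistent with accuracy under the fixed null
  expect_true(all((map$p < 0.5) == (map$accuracy > null$fit_mean)))
  # the strongest cell sits in the theta row, inside the code window
  peak <- which(map$log10_inv_p == max(map$log10_inv_p), arr.ind = TRUE)[1, ]
  expect_identical(rownames(map$accuracy)[peak[1]], "theta")
  expect_true(map$midpoints_ms[peak[2]] >= 100 &&
                map$midpoints_ms[peak[2]] <= 600)
  expect_identical(unname(map$best_electrode[peak[1], peak[2]]), "PO8")
})

test_that("best window per band takes the row argmax, earliest on ties", {
  fake <- structure(list(
    accuracy = rbind(theta = c(0.2, 0.25, 0.23), alpha = c(0.3, 0.3, 0.22)),
    log10_inv_p = rbind(theta = c(0.5, 2.0, 1.0), alpha = c(2.0, 2.0, 0.7)),
    best_electrode = matrix("PO8", 2, 3,
                            dimnames = list(c("theta", "alpha"), NULL)),
    midpoints_ms = c(0, 40, 80), starts_ms = c(-100, -60, -20),
    lengths_ms = rep(200, 3)), class = "significance_map")
  best <- best_window_per_band(fake)
  # theta: unique max in column 2; alpha: tie between columns 1 and 2 -> 1
  expect_identical(unname(best$window_index), c(2L, 1L))
  expect_equal(best$midpoint_ms, c(40, 0))
  expect_equal(best$accuracy, c(0.25, 0.3))
})

test_that("two-way ANOVA of kind x electrode matches textbook sums of squares", {
  # 2 kinds x 3 electrodes x 2 replicates, small integer table
  power <- matrix(c(20, 22, 24, 26, 21, 23), nrow = 2,
                  dimnames = list(NULL, c("E1", "E2", "E3")))
  phase <- matrix(c(28, 30, 33, 35, 27, 31), nrow = 2,
                  dimnames = list(NULL, c("E1", "E2", "E3")))
  res <- compare_phase_power(power, phase)

  y <- c(power, phase)
  kind <- rep(c(0, 1), each = 6)
  elec <- rep(rep(1:3, each = 2), 2)
  gm <- mean(y)
  ss_kind <- sum(tapply(y, kind, function(v) length(v) * (mean(v) - gm)^2))
  ss_elec <- sum(tapply(y, elec, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- tapply(y, interaction(kind, elec), mean)
  ss_cells <- 2 * sum((cellm - gm)^2)
  ss_int <- ss_cells - ss_kind - ss_elec
  ss_err <- sum((y - ave(y, interaction(kind, elec)))^2)
  f_kind <- (ss_kind / 1) / (ss_err / 6)
  f_elec <- (ss_elec / 2) / (ss_err / 6)
  f_int <- (ss_int / 2) / (ss_err / 6)
  expect_equal(res$kind_F, f_kind, tolerance = 1e-10)
  expect_equal(res$electrode_F, f_elec, tolerance = 1e-10)
  expect_equal(res$anova_table["kind:electrode", "F value"], f_int,
               tolerance = 1e-10)
  # Tukey-Kramer intervals exist for both factors
  expect_true(all(c("kind", "electrode") %in% names(res$tukey)))

  # identical conditions: kind effect vanishes
  same <- compare_phase_power(power, power)
  expect_lt(same$kind_F, 1e-20)
  expect_lt(max(abs(same$tukey$kind[, "diff"])), 1e-12)

  expect_error(compare_phase_power(power, phase[, 1:2]), "layout")
})

test_that("kind factor is significant when phase genuinely beats power", {
  sim <- phasedecode:::with_seed(55, {
    power <- matrix(rnorm(12 * 17, 0.229, 0.03), 12, 17)
    phase <- matrix(rnorm(12 * 17, 0.284, 0.03), 12, 17)
    list(power = power, phase = phase)
  })
  res <- compare_phase_power(sim$power, sim$phase)
  expect_lt(res$kind_p, 1e-6)
  expect_gt(res$mean_phase, res$mean_power)
})

test_that("band ANOVA and pairwise t-tests behave as closed forms predict", {
  # identical band distributions: F ~ 0, p ~ 1
  base <- phasedecode:::with_seed(9, rnorm(12, 0.3, 0.04))
  same <- cbind(theta = base, alpha = base, beta = base)
  res_same <- band_accuracy_anova(same)
  expect_lt(res_same$F, 1e-20)
  expect_gt(res_same$p, 0.999)

  # a +10-point band is detected essentially always (power simulation)
  hits <- vapply(1:10, function(s) {
    m <- phasedecode:::with_seed(400 + s,
      cbind(theta = rnorm(12, 0.40, 0.04), alpha = rnorm(12, 0.30, 0.04),
            beta = rnorm(12, 0.30, 0.04)))
    band_accuracy_anova(m)$p < 0.01
  }, TRUE)
  expect_gte(sum(hits), 9)

  # two-sample t on a tiny input matches the closed form
  a <- c(0.30, 0.34, 0.32); b <- c(0.24, 0.26, 0.22)
  m <- cbind(theta = a, alpha = b)
  res <- band_accuracy_anova(m, pairs = list(c("theta", "alpha")))
  sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(2 / 3))
  expect_equal(res$pairwise$t, t_hand, tolerance = 1e-12)

  expect_error(band_accuracy_anova(matrix(0.2, 5, 3)), "degenerate")
  expect_error(band_accuracy_anova(matrix(0.2, 1, 3)), "at least 2")
})

test_that("topography interpolation reproduces nodes and barycentric means", {
  pos <- rbind(c(0, 0), c(2, 0), c(1, 2))
  topo <- topography_map(c(0, 0, 3), pos, grid_n = 21)
  # node reproduction
  expect_equal(predict(topo, pos), c(0, 0, 3), tolerance = 1e-12)
  # centroid of a triangle with values (0,0,3) interpolates to 1
  expect_equal(predict(topo, rbind(colMeans(pos))), 1, tolerance = 1e-12)
  # outside the hull: NA
  expect_true(is.na(predict(topo, rbind(c(-1, -1)))))
  # collinear montage is refused
  expect_error(topography_map(1:3, rbind(c(0, 0), c(1, 1), c(2, 2))),
               "collinear")
})

test_that("interpolation agrees with an independent barycentric oracle", {
  mont <- standard_montage()
  idx <- match(posterior_channels(), mont$name)
  pos <- as.matrix(mont[idx, c("x", "y")])
  vals <- phasedecode:::with_seed(17, runif(17, 0.2, 0.5))
  topo <- topography_map(vals, pos, grid_n = 31)

  # oracle: brute-force triangle search + barycentric coords via solve()
  oracle_at <- function(q) {
    for (t in seq_len(nrow(topo$triangles))) {
      v <- topo$triangles[t, ]
      A <- rbind(t(pos[v, ]), rep(1, 3))
      lam <- solve(A, c(q, 1))
      if (all(lam >= -1e-12)) return(sum(lam * vals[v]))
    }
    NA_real_
  }
  qs <- phasedecode:::with_seed(18, cbind(runif(50, min(pos[, 1]), max(pos[, 1])),
                                          runif(50, min(pos[, 2]), max(pos[, 2]))))
  got <- predict(topo, qs)
  want <- apply(qs, 1, oracle_at)
  inside <- !is.na(want)
  expect_gt(sum(inside), 10)
  expect_equal(got[inside], want[inside], tolerance = 1e-9)
  expect_true(all(is.na(got[!inside])))

  # Delaunay property: no electrode lies strictly inside a circumcircle
  for (t in seq_len(nrow(topo$triangles))) {
    v <- topo$triangles[t, ]
    ax <- pos[v[1], 1]; ay <- pos[v[1], 2]
    bx <- pos[v[2], 1]; by <- pos[v[2], 2]
    cx <- pos[v[3], 1]; cy <- pos[v[3], 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ux - ax)^2 + (uy - ay)^2
    others <- setdiff(seq_len(nrow(pos)), v)
    d2 <- (pos[others, 1] - ux)^2 + (pos[others, 2] - uy)^2
    expect_true(all(d2 >= r2 * (1 - 1e-9)))
  }
})
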