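test_that("stratified folds split 450 balanced trials into 30 folds of 15, 3 per class", {
  labels <- rep(0:4, each = 90)
  fold <- phasedecode:::stratified_folds(labels, 30, seed = 4)
  expect_identical(sort(unique(fold)), 1:30)
  expect_true(all(table(fold) == 15))
  per_class <- table(fold, labels)
  expect_true(all(per_class == 3))
  # deterministic under seed
  expect_identical(fold, phasedecode:::stratified_folds(labels, 30, seed = 4))
  expect_false(identical(fold,
                         phasedecode:::stratified_folds(labels, 30, seed = 5)))
  # unbalanced remainders are spread round-robin: fold sizes differ by <= 1
  labels2 <- rep(0:4, times = c(13, 13, 13, 12, 12))
  fold2 <- phasedecode:::stratified_folds(labels2, 5, seed = 1)
  expect_lte(diff(range(table(fold2))), 1)
})

test_that("well-separated class blobs are decoded perfectly", {
  fm <- blob_features(n_per_class = 12, separation = 50)
  res <- cross_validate(fm, svm_config(seed = 1), n_folds = 10)
  expect_equal(res$accuracy, 1.0)
  expect_identical(sum(res$confusion), 60L)
  expect_identical(sum(diag(res$confusion)), 60L)
  expect_length(res$fold_accuracies, 10)
})

test_that("decode_result bookkeeping is internally consistent", {
  fm <- noise_features(n_per_class = 10)
  res <- cross_validate(fm, svm_config(seed = 2), n_folds = 5)
  expect_identical(sum(res$confusion), res$n_trials)
  expect_equal(res$accuracy, sum(diag(res$confusion)) / res$n_trials)
  # equal fold sizes: mean fold accuracy equals pooled accuracy
  expect_equal(mean(res$fold_accuracies), res$accuracy)
  expect_gt(res$sigma_used, 0)
})

test_that("label-independent features decode at chance", {
  accs <- vapply(1:20, function(s) {
    fm <- noise_features(n_per_class = 10, n_features = 6, seed = 100 + s)
    cross_validate(fm, svm_config(seed = s), n_folds = 5)$accuracy
  }, 0)
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.2), 3 * se + 0.01)
})

test_that("cross-validation rejects degenerate class layouts", {
  fm <- noise_features(n_per_class = 10)
  fm$labels[fm$labels == 4] <- 3L
  fm$labels[1] <- 4L  # a single class-4 trial
  expect_error(cross_validate(fm, svm_config(seed = 1), n_folds = 5),
               "at least 2 trials")
  fm2 <- noise_features(n_per_class = 2)
  expect_error(cross_validate(fm2, svm_config(seed = 1), n_folds = 20),
               "too few trials")
})

test_that("sigma ascent never undercuts its start and matches a grid oracle", {
  fm <- blob_features(n_per_class = 10, n_features = 5, separation = 1.2,
                      seed = 31)
  cfg <- svm_config(seed = 9)
  # ascent property on an arbitrary start
  init <- 0.05
  fit <- optimize_sigma(fm, cfg, init_sigma = init, n_folds = 5)
  acc_init <- cross_validate(fm, svm_config(sigma = init, seed = 9),
                             n_folds = 5)$accuracy
  expect_gte(fit$accuracy, acc_init)

  # 30-point log-grid-search oracle over a generous sigma range
  s0 <- phasedecode:::median_pairwise_dist(fm$X)
  grid <- exp(seq(log(s0 / 30), log(s0 * 30), length.out = 30))
  acc_grid <- vapply(grid, function(s)
    cross_validate(fm, svm_config(sigma = s, seed = 9), n_folds = 5)$accuracy,
    0)
  fit2 <- optimize_sigma(fm, cfg, n_folds = 5)
  expect_gte(fit2$accuracy, max(acc_grid) - 0.02)

  # clearly separable blobs reach perfect accuracy at the optimum
  easy <- blob_features(n_per_class = 8, separation = 40, seed = 5)
  fit3 <- optimize_sigma(easy, cfg, n_folds = 4)
  expect_equal(fit3$accuracy, 1.0)
})

test_that("per-electrode decoding is independent of electrode ordering", {
  ds <- small_phase_dataset(seed = 6, n_per_class = 8)
  an <- analytic_signal(filter_band(baseline_correct(ds), "theta"))
  w <- window_spec(150, 200)
  cfg <- svm_config(seed = 3)
  fwd <- decode_electrodes(an, w, "phase", channels = c("PO8", "Oz", "P7"),
                           config = cfg, n_folds = 4)
  rev_ <- decode_electrodes(an, w, "phase", channels = c("P7", "Oz", "PO8"),
                            config = cfg, n_folds = 4)
  expect_equal(accuracies(fwd)[c("P7", "Oz", "PO8")], accuracies(rev_))
  df <- as.data.frame(fwd)
  expect_identical(df$electrode, c("PO8", "Oz", "P7"))
  expect_true(all(df$kind == "phase"))
})

test_that("direct OVO decision computation equals libsvm predict exactly", {
  for (s in 1:6) {
    dat <- phasedecode:::with_seed(200 + s, {
      n <- 80; d <- 7
      X <- matrix(rnorm(n * d), n, d)
      y <- factor(sample(0:4, n, replace = TRUE), levels = 0:4)
      list(X = X + as.integer(y) * 0.4, y = y,
           Xq = matrix(rnorm(40 * d), 40, d))
    })
    fit <- e1071::svm(dat$X, dat$y, type = "C-classification",
                      kernel = "radial", gamma = 1 / (2 * (1 + s / 3)^2),
                      cost = 1, scale = FALSE)
    expect_identical(phasedecode:::svm_predict_fast(fit, dat$Xq),
                     unname(stats::predict(fit, dat$Xq)))
  }
})

test_that("accuracy is invariant to joint trial reordering on separable data", {
  fm <- blob_features(n_per_class = 10, separation = 50, seed = 13)
  perm <- phasedecode:::with_seed(77, sample.int(nrow(fm$X)))
  fm_perm <- fm
  fm_perm$X <- fm$X[perm, , drop = FALSE]
  fm_perm$labels <- fm$labels[perm]
  a1 <- cross_validate(fm, svm_config(seed = 1), n_folds = 10)$accuracy
  a2 <- cross_validate(fm_perm, svm_config(seed = 1), n_folds = 10)$accuracy
  expect_equal(a1, a2)
})
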