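test_that("time-bin grid matches the encoding analysis geometry", {
  g <- make_time_bins()
  expect_length(g$centers_ms, 26)
  expect_equal(g$centers_ms[1], -10)
  expect_equal(g$centers_ms[26], 490)
  expect_equal(diff(g$centers_ms), rep(20, 25))
  expect_equal(g$samples_per_bin, 13L)
  expect_error(make_time_bins(0, 0), "degenerate")
})

test_that("feature extraction flattens channel-major with full bin coverage", {
  ep274 <- noise_epochs(n_trials = 2, n_channels = 274, n_samples = 361,
                        t0 = -100, seed = 1)
  g <- make_time_bins()
  x <- extract_bin_features(ep274, 170, g)
  expect_equal(dim(x), c(2L, 3562L))  # 13 x 274
  x490 <- extract_bin_features(ep274, 490, g)
  expect_equal(ncol(x490), 3562L)
  # zero epochs give zero vectors
  z <- ep274; z$data[] <- 0
  expect_true(all(extract_bin_features(z, 170, g) == 0))
  # documented ordering: features (ch-1)*13 + s
  expect_equal(x[1, 13 * 2 + 1], ep274$data[1, 3, which(ep274$time_ms == 160)])
  # channel permutation + feature remap leaves values identical
  perm <- rev(seq_len(274))
  epp <- ep274; epp$data <- epp$data[, perm, , drop = FALSE]
  xp <- extract_bin_features(epp, 170, g)
  remap <- as.vector(outer(1:13, (perm - 1) * 13, `+`))
  expect_identical(xp, x[, remap])
  expect_error(extract_bin_features(ep274, 600, g), "samples")
})

test_that("t-test feature reduction keeps ~alpha of null features and all strong ones", {
  set.seed(10)
  x <- matrix(rnorm(100 * 1000), 100, 1000)
  y <- rep(c("F", "B"), each = 50)
  mask <- reduce_features(x, y, 0.05)
  # binomial 99% interval around 5% of 1000
  expect_gt(sum(mask), qbinom(0.005, 1000, 0.05))
  expect_lt(sum(mask), qbinom(0.995, 1000, 0.05))
  x[, 17] <- x[, 17] + ifelse(y == "F", 10, 0)  # 10 SD separation
  expect_true(reduce_features(x, y, 0.05)[17])
  expect_true(all(reduce_features(x, y, 1)))
  expect_error(reduce_features(x, rep("F", 100)), "2 classes")
})

test_that("pairwise classifier: separability, balance, orientation, determinism", {
  set.seed(2)
  x <- matrix(rnorm(60 * 20), 60, 20)
  y <- rep(c("F", "B"), each = 30)
  x[y == "F", 1] <- x[y == "F", 1] + 8
  clf <- train_pairwise_classifier(x, y, c("F", "B"), 170)
  dv <- decision_values(clf, x)
  expect_equal(ifelse(dv >= 0, "F", "B"), y)       # separable: 100% training
  expect_true(mean(dv[y == "F"]) > 0)              # positive favors pair[1]
  clf2 <- train_pairwise_classifier(x, y, c("F", "B"), 170)
  expect_identical(clf$weights, clf2$weights)      # deterministic refit
  expect_error(train_pairwise_classifier(x[1:50, ], y[1:50], c("F", "B")),
               "unbalanced")
  expect_error(decision_values(clf, x[, 1:10]), "mismatch")
})

test_that("training state depends only on training rows (no leakage)", {
  set.seed(3)
  x <- matrix(rnorm(40 * 30), 40, 30)
  y <- rep(c("F", "B"), 20)
  tr <- rep(c(TRUE, FALSE), each = 20)
  clf_a <- train_pairwise_classifier(x[tr, ], y[tr], c("F", "B"))
  x2 <- x; x2[!tr, ] <- 1e6  # corrupt held-out rows
  clf_b <- train_pairwise_classifier(x2[tr, ], y[tr], c("F", "B"))
  expect_identical(clf_a$weights, clf_b$weights)
  expect_identical(clf_a$center, clf_b$center)
  expect_identical(clf_a$feature_mask, clf_b$feature_mask)
})

test_that("cross-validation: chance on permuted labels, signal at the evoked peak", {
  d <- enumerate_design(3)[1:54, ]
  p <- quick_params(snr_encoding = 1.5, seed = 7)
  ep <- simulate_encoding_epochs(d, p)
  g <- make_time_bins(160, 250)
  cv <- crossvalidate_bins(ep, g, folds = 10, seed = 1)
  expect_true(all(cv$acc >= 0 & cv$acc <= 1))
  i170 <- which(cv$centers_ms == 170)
  expect_gt(cv$mean_acc[i170], 0.8)
  # reproducible to machine precision under a fixed seed
  cv2 <- crossvalidate_bins(ep, g, folds = 10, seed = 1)
  expect_identical(cv$acc, cv2$acc)
  # label permutation destroys the signal: accuracy within binomial CI of 0.5
  epp <- ep
  set.seed(42)
  epp$trial_meta$category <- sample(epp$trial_meta$category)
  cvp <- crossvalidate_bins(epp, make_time_bins(150, 190), folds = 10, seed = 1)
  n_per_pair <- 2 * min(table(epp$trial_meta$category))
  ci <- qbinom(c(0.025, 0.975), n_per_pair, 0.5) / n_per_pair
  expect_gt(mean(cvp$acc[, 1]), ci[1] - 0.05)
  expect_lt(mean(cvp$acc[, 1]), ci[2] + 0.05)
})

test_that("pre-stimulus bins decode at chance", {
  d <- enumerate_design(9)[1:54, ]
  ep <- simulate_encoding_epochs(d, quick_params(snr_encoding = 3, seed = 8))
  g <- make_time_bins(-20, 40)
  cv <- crossvalidate_bins(ep, g, folds = 10, seed = 2)
  i <- which(cv$centers_ms == -10)
  n_per_pair <- 2 * min(table(ep$trial_meta$category))
  ci <- qbinom(c(0.025, 0.975), n_per_pair, 0.5) / n_per_pair
  expect_true(mean(cv$acc[, i]) > ci[1] - 0.05 && mean(cv$acc[, i]) < ci[2] + 0.05)
})

test_that("group significance: null mask empty, injected effect clustered, p bounded", {
  g <- make_time_bins()
  mk_curve <- function(acc) {
    structure(list(acc = rbind(acc, acc, acc), mean_acc = acc,
                   centers_ms = g$centers_ms, folds = 10), class = "accuracy_curve")
  }
  flat <- lapply(1:14, function(s) mk_curve(rep(0.5, 26)))
  sig0 <- group_accuracy_significance(flat, n_perm = 200, seed = 1)
  expect_false(any(sig0$sig_mask))

  set.seed(5)
  eff_bins <- g$centers_ms >= 90 & g$centers_ms <= 490
  curves <- lapply(1:14, function(s) {
    acc <- rnorm(26, 0.5, 0.02)
    acc[eff_bins] <- rnorm(sum(eff_bins), 0.75, 0.05)
    mk_curve(acc)
  })
  sig <- group_accuracy_significance(curves, n_perm = 500, seed = 2)
  expect_true(all(sig$clusters$p >= 1 / 501 & sig$clusters$p <= 1))
  expect_true(all(sig$sig_mask[eff_bins]))
  expect_false(any(sig$sig_mask[g$centers_ms < 90]))
  expect_error(group_accuracy_significance(flat[1]), "2 subjects")
})

test_that("best-bin selection maximizes mean accuracy with earliest-tie rule", {
  g <- make_time_bins()
  cu <- structure(list(acc = NULL, mean_acc = rep(0.6, 26),
                       centers_ms = g$centers_ms), class = "accuracy_curve")
  expect_equal(select_best_bin(cu)$bin_center_ms, -10)  # constant: earliest
  cu$mean_acc[which(g$centers_ms == 170)] <- 0.78
  expect_equal(select_best_bin(cu)$bin_center_ms, 170)
})
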