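# Time-bin-resolved pairwise linear classification of encoding epochs.
#
# Category pairs are ordered F < B < C throughout; a positive decision value
# always favors the pair's first category under that order.

CATEGORY_PAIRS <- list(c("F", "B"), c("F", "C"), c("B", "C"))

pair_name <- function(pair) paste(pair, collapse = "-")

#' Build the 20 ms time-bin grid
#'
#' Bins are `width` ms wide with centers at `t_start + width/2`, stepping by
#' `width`, the last center below `t_end`. A bin spans both of its edges, so
#' at 600 Hz a 20 ms bin holds `floor(width * fs / 1000) + 1 = 13` samples.
#'
#' @param t_start,t_end Window bounds relative to stimulus onset, ms.
#' @param width Bin width, ms.
#' @param fs Sampling rate, Hz.
#' @return A list of class `time_bin_grid` with `centers_ms`, `width_ms`,
#'   `samples_per_bin`, `fs`.
#' @export
make_time_bins <- function(t_start = -20, t_end = 500, width = 20, fs = 600) {
  if (width <= 0 || fs <= 0) stopf("width and fs must be positive")
  centers <- seq(t_start + width / 2, by = width,
                 length.out = max(0L, floor((t_end - t_start - width / 2) / width) + 1L))
  centers <- centers[centers < t_end]
  if (length(centers) == 0L) stopf("degenerate window: no bin centers in [%g, %g)",
                                   t_start, t_end)
  structure(list(centers_ms = centers, width_ms = width,
                 samples_per_bin = floor(width * fs / 1000) + 1L, fs = fs),
            class = "time_bin_grid")
}

#' Extract one time bin's feature matrix
#'
#' Flattens, per trial, the `samples_per_bin` samples of every channel in the
#' bin `[center - width/2, center + width/2]` (edges included). Ordering is
#' channel-major: features 1..s are channel 1's samples in time order,
#' features s+1..2s channel 2's, and so on.
#'
#' @param epochs A [sensor_epochs] object.
#' @param center Bin center, ms.
#' @param grid A [make_time_bins()] grid (supplies width and sample count).
#' @return A trials x (channels * samples_per_bin) numeric matrix.
#' @export
extract_bin_features <- function(epochs, center, grid) {
  half <- grid$width_ms / 2
  idx <- which(epochs$time_ms >= center - half - 1e-9 &
                 epochs$time_ms <= center + half + 1e-9)
  if (length(idx) != grid$samples_per_bin) {
    stopf("bin centered at %g ms has %d samples in the epoch (need %d)",
          center, length(idx), grid$samples_per_bin)
  }
  d <- dim(epochs$data)
  sub <- aperm(epochs$data[, , idx, drop = FALSE], c(1, 3, 2))
  matrix(sub, nrow = d[1])
}

#' Univariate t-test feature reduction
#'
#' Keeps the features whose two-sample, two-tailed pooled-variance t-test
#' between the two training classes has p < `alpha`. Computed on training
#' data only. If no feature survives, the single smallest-p feature is kept
#' so a classifier can still be fit.
#'
#' @param x Training feature matrix.
#' @param y Training labels (two classes).
#' @param alpha Retention threshold on the p-value (default 0.05).
#' @return Logical mask over features.
#' @export
reduce_features <- function(x, y, alpha = 0.05) {
  y <- as.character(y)
  cls <- unique(y)
  if (length(cls) != 2L) stopf("feature reduction needs exactly 2 classes, got %d",
                               length(cls))
  i1 <- y == cls[1]
  n1 <- sum(i1); n2 <- sum(!i1)
  m1 <- colMeans(x[i1, , drop = FALSE]); m2 <- colMeans(x[!i1, , drop = FALSE])
  v1 <- colSums(sweep(x[i1, , drop = FALSE], 2, m1)^2)
  v2 <- colSums(sweep(x[!i1, , drop = FALSE], 2, m2)^2)
  sp2 <- (v1 + v2) / (n1 + n2 - 2)
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
  p[is.na(p)] <- 1  # zero-variance, equal-mean features carry no signal
  mask <- p < alpha
  if (!any(mask)) mask[which.min(p)] <- TRUE
  mask
}

#' Train one pairwise max-margin classifier
#'
#' Normalizes features (per-feature center/scale learned from the training
#' data only), reduces them with [reduce_features()], and fits a linear
#' support-vector machine. The fitted hyperplane is stored as explicit
#' weights and bias so unseen bins can be scored directly; the sign is
#' oriented so a positive decision value favors `pair[1]`.
#'
#' @param x Training feature matrix (full feature set).
#' @param y Training labels; must contain equally many trials of each of the
#'   two categories in `pair`.
#' @param pair Character pair, ordered under F < B < C.
#' @param bin_center Bin center the features came from, ms.
#' @param alpha Feature-reduction threshold.
#' @param cost SVM soft-margin cost (default 1, the implementation standard).
#' @return A `pairwise_classifier` object.
#' @export
train_pairwise_classifier <- function(x, y, pair, bin_center = NA_real_,
                                      alpha = 0.05, cost = 1) {
  y <- as.character(y)
  if (!setequal(unique(y), pair)) stopf("labels must be exactly the pair %s",
                                        pair_name(pair))
  if (sum(y == pair[1]) != sum(y == pair[2])) {
    stopf("unbalanced classes for pair %s: caller must downsample", pair_name(pair))
  }
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  mask <- reduce_features(z, y, alpha)
  yf <- factor(y, levels = pair)
  fit <- e1071::svm(z[, mask, drop = FALSE], yf, kernel = "linear",
                    cost = cost, scale = FALSE)
  w <- as.vector(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # orient: positive decision value => pair[1]
  dv <- z[, mask, drop = FALSE] %*% w + b
  if (mean(dv[y == pair[1]]) < mean(dv[y == pair[2]])) {
    w <- -w; b <- -b
  }
  structure(list(pair = pair, bin_center_ms = bin_center, feature_mask = mask,
                 center = center, scale = scale, weights = w, bias = b,
                 cost = cost, alpha = alpha),
            class = "pairwise_classifier")
}

#' Signed decision values of a pairwise classifier
#'
#' @param clf A `pairwise_classifier`.
#' @param x Feature matrix in the classifier's full feature space.
#' @return Numeric vector of signed decision values (positive favors
#'   `clf$pair[1]`).
#' @export
decision_values <- function(clf, x) {
  if (ncol(x) != length(clf$feature_mask)) {
    stopf("feature length mismatch: classifier expects %d, got %d",
          length(clf$feature_mask), ncol(x))
  }
  z <- sweep(sweep(x, 2, clf$center), 2, clf$scale, "/")
  as.vector(z[, clf$feature_mask, drop = FALSE] %*% clf$weights + clf$bias)
}

#' @export
print.pairwise_classifier <- function(x, ...) {
  cat(sprintf("<pairwise_classifier> %s @ %g ms, %d/%d features retained\n",
              pair_name(x$pair), x$bin_center_ms, sum(x$feature_mask),
              length(x$feature_mask)))
  invisible(x)
}

balanced_category_index <- function(categories, pair, seed) {
  idx1 <- which(categories == pair[1])
  idx2 <- which(categories == pair[2])
  n <- min(length(idx1), length(idx2))
  with_seed(seed, {
    sort(c(sample(idx1, n), sample(idx2, n)))
  })
}

stratified_folds <- function(y, folds, seed) {
  with_seed(seed, {
    f <- integer(length(y))
    for (cl in unique(y)) {
      i <- which(y == cl)
      f[i] <- sample(rep(seq_len(folds), length.out = length(i)))
    }
    f
  })
}

#' Cross-validate pairwise classifiers over the time-bin grid
#'
#' For each category pair and each bin, runs stratified k-fold
#' cross-validation: classes are first balanced by seeded downsampling to the
#' smaller class, and within every fold the feature normalization and
#' t-test reduction are learned from the training trials only.
#'
#' @param epochs Encoding [sensor_epochs] whose `trial_meta$category` labels
#'   each epoch.
#' @param grid A [make_time_bins()] grid.
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed for balancing and fold assignment.
#' @param alpha Feature-reduction threshold.
#' @param cost SVM cost.
#' @return An `accuracy_curve`: pairwise accuracy matrix (`acc`, pairs x
#'   bins), per-bin mean over pairs (`mean_acc`), bin centers, fold count.
#' @export
crossvalidate_bins <- function(epochs, grid, folds = 10, seed = 1L,
                               alpha = 0.05, cost = 1) {
  cats <- epochs$trial_meta$category
  acc <- matrix(NA_real_, length(CATEGORY_PAIRS), length(grid$centers_ms),
                dimnames = list(vapply(CATEGORY_PAIRS, pair_name, character(1)),
                                grid$centers_ms))
  for (pi in seq_along(CATEGORY_PAIRS)) {
    pair <- CATEGORY_PAIRS[[pi]]
    keep <- balanced_category_index(cats, pair, derive_seed(seed, 100L + pi))
    y <- cats[keep]
    if (min(table(y)) < folds) stopf("need at least %d trials per category", folds)
    fold_id <- stratified_folds(y, folds, derive_seed(seed, 200L + pi))
    for (bi in seq_along(grid$centers_ms)) {
      x <- extract_bin_features(epochs, grid$centers_ms[bi], grid)[keep, , drop = FALSE]
      correct <- 0L
      for (k in seq_len(folds)) {
        tr <- fold_id != k
        clf <- train_pairwise_classifier(x[tr, , drop = FALSE], y[tr], pair,
                                         grid$centers_ms[bi], alpha, cost)
        dv <- decision_values(clf, x[!tr, , drop = FALSE])
        pred <- ifelse(dv >= 0, pair[1], pair[2])
        correct <- correct + sum(pred == y[!tr])
      }
      acc[pi, bi] <- correct / length(y)
    }
  }
  structure(list(acc = acc, mean_acc = colMeans(acc),
                 centers_ms = grid$centers_ms, folds = folds,
                 pairs = CATEGORY_PAIRS),
            class = "accuracy_curve")
}

#' @export
print.accuracy_curve <- function(x, ...) {
  best <- which.max(x$mean_acc)
  cat(sprintf("<accuracy_curve> %d bins, %d-fold CV; peak mean accuracy %.1f%% at %g ms\n",
              length(x$centers_ms), x$folds, 100 * max(x$mean_acc),
              x$centers_ms[best]))
  invisible(x)
}

#' Group-level significance of accuracy curves
#'
#' One-sample t statistics of per-subject mean accuracies against chance at
#' every bin, with familywise error control by sign-flip max-cluster-mass
#' permutation over the 1-D curve: clusters are contiguous runs of bins whose
#' t exceeds the cluster-forming threshold; cluster mass is the summed t; the
#' null distribution is the maximum cluster mass under random per-subject
#' sign flips of the accuracy deviations from chance.
#'
#' @param curves List of per-subject `accuracy_curve` objects on one grid.
#' @param chance Chance level (default 0.5).
#' @param n_perm Number of sign-flip permutations (default 5000).
#' @param cluster_alpha Cluster-forming p threshold (default 0.05, one-sided
#'   above chance).
#' @param seed Integer seed for the permutation draws.
#' @return A list with the t curve, degrees of freedom, cluster table
#'   (`start_ms`, `end_ms`, `mass`, `p`), the FWE-significant bin mask, and
#'   the method label.
#' @export
group_accuracy_significance <- function(curves, chance = 0.5, n_perm = 5000,
                                        cluster_alpha = 0.05, seed = 1L) {
  if (length(curves) < 2L) stopf("need at least 2 subjects")
  accs <- do.call(rbind, lapply(curves, function(cu) cu$mean_acc))
  centers <- curves[[1]]$centers_ms
  n_sub <- nrow(accs)
  dev <- accs - chance
  t_of <- function(d) {
    m <- colMeans(d)
    se <- apply(d, 2, stats::sd) / sqrt(n_sub)
    ifelse(se == 0, 0, m / se)
  }
  t_obs <- t_of(dev)
  t_thr <- stats::qt(1 - cluster_alpha, df = n_sub - 1)
  find_clusters <- function(tv) {
    r <- rle(tv > t_thr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(start = starts[keep], end = ends[keep],
               mass = vapply(which(keep), function(j)
                 sum(tv[starts[j]:ends[j]]), numeric(1)))
  }
  obs <- find_clusters(t_obs)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      flip <- sample(c(-1, 1), n_sub, replace = TRUE)
      cl <- find_clusters(t_of(dev * flip))
      if (nrow(cl)) max(cl$mass) else 0
    }, numeric(1))
  })
  obs$p <- vapply(obs$mass, function(m) (1 + sum(null_max >= m)) / (n_perm + 1),
                  numeric(1))
  sig <- rep(FALSE, length(centers))
  for (j in seq_len(nrow(obs))) {
    if (obs$p[j] < 0.05) sig[obs$start[j]:obs$end[j]] <- TRUE
  }
  list(t = t_obs, df = n_sub - 1,
       clusters = data.frame(start_ms = centers[obs$start],
                             end_ms = centers[obs$end],
                             mass = obs$mass, p = obs$p),
       sig_mask = sig, centers_ms = centers,
       method = "one-sample t vs chance, FWE by sign-flip max-cluster-mass permutation")
}

#' Select the best-performing time bin
#'
#' @param curve An `accuracy_curve`.
#' @return A list with `bin_center_ms` (bin of maximal mean-over-pairs CV
#'   accuracy, earliest on ties), its `mean_accuracy`, and the index.
#' @export
select_best_bin <- function(curve) {
  i <- which.max(curve$mean_acc)  # which.max returns the earliest maximum
  list(bin_center_ms = curve$centers_ms[i],
       mean_accuracy = unname(curve$mean_acc[i]), index = i)
}

#' Retrain the three pairwise classifiers at one bin on all encoding trials
#'
#' @param epochs Encoding [sensor_epochs].
#' @param bin_center Bin center, ms (typically from [select_best_bin()]).
#' @param grid A [make_time_bins()] grid.
#' @param seed Seed for class balancing.
#' @param alpha,cost Passed to [train_pairwise_classifier()].
#' @return Named list of three `pairwise_classifier` objects.
#' @export
train_bin_classifiers <- function(epochs, bin_center, grid, seed = 1L,
                                  alpha = 0.05, cost = 1) {
  cats <- epochs$trial_meta$category
  x <- extract_bin_features(epochs, bin_center, grid)
  out <- lapply(seq_along(CATEGORY_PAIRS), function(pi) {
    pair <- CATEGORY_PAIRS[[pi]]
    keep <- balanced_category_index(cats, pair, derive_seed(seed, 300L + pi))
    train_pairwise_classifier(x[keep, , drop = FALSE], cats[keep], pair,
                              bin_center, alpha, cost)
  })
  names(out) <- vapply(CATEGORY_PAIRS, pair_name, character(1))
  out
}
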