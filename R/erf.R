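# Event-related field contrast between predominantly maintained (PM) and
# non-PM stimuli, with familywise error control by spatio-temporal
# cluster-mass permutation.

#' Synthetic sensor layout and adjacency
#'
#' Places `n_channels` sensors on a sunflower (golden-angle) disc layout and
#' connects each to its `k` nearest neighbors (symmetrized). Used as the
#' channel neighborhood graph for spatio-temporal clustering when no real
#' sensor geometry exists.
#'
#' @param n_channels Number of sensors.
#' @param k Neighbors per sensor (default 4).
#' @return A list with `xy` coordinates and `adjacency` (list of neighbor
#'   index vectors).
#' @export
sensor_layout <- function(n_channels, k = 4) {
  i <- seq_len(n_channels)
  r <- sqrt(i / n_channels)
  th <- i * pi * (3 - sqrt(5))
  xy <- cbind(x = r * cos(th), y = r * sin(th))
  adj <- vector("list", n_channels)
  for (c1 in i) {
    d2 <- (xy[, 1] - xy[c1, 1])^2 + (xy[, 2] - xy[c1, 2])^2
    adj[[c1]] <- setdiff(order(d2)[seq_len(min(k + 1L, n_channels))], c1)
  }
  # symmetrize
  for (c1 in i) for (c2 in adj[[c1]]) {
    if (!(c1 %in% adj[[c2]])) adj[[c2]] <- c(adj[[c2]], c1)
  }
  list(xy = xy, adjacency = adj)
}

# Label connected components of a channels x time logical mask, where cells
# are adjacent along time (t +/- 1, same channel) and across neighboring
# channels (same t). Returns an integer label matrix (0 = background).
cluster_label <- function(mask, adjacency) {
  nc <- nrow(mask); nt <- ncol(mask)
  lab <- matrix(0L, nc, nt)
  cur <- 0L
  for (cell in which(mask)) {
    if (lab[cell] != 0L) next
    cur <- cur + 1L
    stack <- cell
    lab[cell] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ch <- (v - 1L) %% nc + 1L
      t <- (v - 1L) %/% nc + 1L
      nb <- integer(0)
      if (t > 1L) nb <- c(nb, v - nc)
      if (t < nt) nb <- c(nb, v + nc)
      nb <- c(nb, (t - 1L) * nc + adjacency[[ch]])
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      stack <- c(stack, nb)
    }
  }
  lab
}

#' Cluster-permutation contrast on per-subject ERF difference maps
#'
#' Given per-subject PM-minus-non-PM difference maps (channels x time), this
#' computes the pointwise paired F statistic (squared one-sample t of the
#' differences), forms spatio-temporal clusters of cells exceeding the
#' cluster-forming threshold using the channel adjacency graph, and controls
#' familywise error with a max-cluster-mass permutation: under the null the
#' two condition labels are exchangeable within subject, so each permutation
#' randomly flips the sign of whole subject difference maps.
#'
#' @param diffs List of per-subject channels x time difference matrices.
#' @param time_ms Time axis of the maps.
#' @param adjacency Channel neighborhood graph (from [sensor_layout()]).
#' @param n_perm Number of sign-flip permutations (default 2000).
#' @param cluster_alpha Cluster-forming p threshold (default 0.05).
#' @param alpha Familywise cluster significance level (default 0.05).
#' @param seed Integer seed for the permutations.
#' @return An `erf_stat_map`: the F map, forming threshold, cluster table
#'   (`mass`, `p`, `peak_channel`, `peak_time_ms`, extent), significant-cell
#'   mask, and the method label.
#' @export
erf_cluster_contrast <- function(diffs, time_ms, adjacency, n_perm = 2000,
                                 cluster_alpha = 0.05, alpha = 0.05, seed = 1L) {
  n_sub <- length(diffs)
  if (n_sub < 2L) stopf("need at least 2 subjects")
  nc <- nrow(diffs[[1]]); nt <- ncol(diffs[[1]])
  arr <- array(unlist(diffs), dim = c(nc, nt, n_sub))
  f_thr <- stats::qf(1 - cluster_alpha, 1, n_sub - 1)
  fmap_of <- function(a) {
    m <- rowMeans(a, dims = 2)
    v <- rowSums((a - as.vector(m))^2, dims = 2) / (n_sub - 1)
    f <- n_sub * m^2 / v
    f[!is.finite(f)] <- 0
    f
  }
  clusters_of <- function(f) {
    lab <- cluster_label(f > f_thr, adjacency)
    if (!any(lab > 0L)) return(NULL)
    masses <- vapply(seq_len(max(lab)), function(j) sum(f[lab == j]), numeric(1))
    list(lab = lab, masses = masses)
  }
  f_obs <- fmap_of(arr)
  obs <- clusters_of(f_obs)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      flip <- sample(c(-1, 1), n_sub, replace = TRUE)
      fl <- sweep(arr, 3, flip, "*")
      cl <- clusters_of(fmap_of(fl))
      if (is.null(cl)) 0 else max(cl$masses)
    }, numeric(1))
  })
  if (is.null(obs)) {
    clusters <- data.frame(mass = numeric(0), p = numeric(0),
                           peak_channel = integer(0), peak_time_ms = numeric(0),
                           n_cells = integer(0))
    sig <- matrix(FALSE, nc, nt)
  } else {
    clusters <- do.call(rbind, lapply(seq_along(obs$masses), function(j) {
      cells <- which(obs$lab == j)
      peak <- cells[which.max(f_obs[cells])]
      data.frame(mass = obs$masses[j],
                 p = (1 + sum(null_max >= obs$masses[j])) / (n_perm + 1),
                 peak_channel = (peak - 1L) %% nc + 1L,
                 peak_time_ms = time_ms[(peak - 1L) %/% nc + 1L],
                 n_cells = length(cells))
    }))
    clusters <- clusters[order(clusters$p, -clusters$mass), , drop = FALSE]
    rownames(clusters) <- NULL
    sig <- matrix(FALSE, nc, nt)
    for (j in which(clusters$p < alpha)) {
      sig[obs$lab == match(clusters$mass[j], obs$masses)] <- TRUE
    }
  }
  structure(list(f = f_obs, f_threshold = f_thr, time_ms = time_ms,
                 clusters = clusters, sig_mask = sig, n_subjects = n_sub,
                 n_perm = n_perm,
                 method = "paired F map, FWE by sign-flip spatio-temporal max-cluster-mass permutation"),
            class = "erf_stat_map")
}

#' @export
print.erf_stat_map <- function(x, ...) {
  cat(sprintf("<erf_stat_map> %d subjects, %d permutations; %d cluster(s)\n",
              x$n_subjects, x$n_perm, nrow(x$clusters)))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' PM vs non-PM ERF contrast from encoding epochs
#'
#' For each subject, averages the (low-pass filtered, baseline-corrected)
#' encoding epochs of predominantly maintained stimuli and of the remaining
#' stimuli — two disjoint trial sets — and feeds the per-subject difference
#' maps to [erf_cluster_contrast()]. Subjects with no PM (or no non-PM)
#' epochs are excluded and listed.
#'
#' @param epochs_list List of per-subject encoding [sensor_epochs].
#' @param pm_list List of per-subject logical vectors flagging PM epochs.
#' @param adjacency Channel neighborhood graph; defaults to a
#'   [sensor_layout()] of the epochs' channel count.
#' @param ... Passed to [erf_cluster_contrast()].
#' @return An `erf_stat_map` with an `excluded_subjects` field.
#' @export
compute_erf_contrast <- function(epochs_list, pm_list, adjacency = NULL, ...) {
  usable <- vapply(pm_list, function(f) any(f) && any(!f), logical(1))
  if (!all(usable)) {
    warning(sprintf("excluding %d subject(s) with no PM or no non-PM epochs",
                    sum(!usable)))
  }
  diffs <- mapply(function(ep, pm) {
    apply(ep$data[pm, , , drop = FALSE], c(2, 3), mean) -
      apply(ep$data[!pm, , , drop = FALSE], c(2, 3), mean)
  }, epochs_list[usable], pm_list[usable], SIMPLIFY = FALSE)
  if (is.null(adjacency)) {
    adjacency <- sensor_layout(dim(epochs_list[[1]]$data)[2])$adjacency
  }
  out <- erf_cluster_contrast(diffs, epochs_list[[1]]$time_ms, adjacency, ...)
  out$excluded_subjects <- which(!usable)
  out
}
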