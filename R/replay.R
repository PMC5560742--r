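# Replay-epoch run lengths, Markov transition dynamics, directionality,
# and predominance of decoded delay-period sequences.

EPOCH_RANGES_MS <- list(c(20, 140), c(160, 400), c(420, 1100), c(1200, 3000))

#' Extract replay epochs from a decoded label sequence
#'
#' A replay epoch is a maximal run of consecutive 20 ms bins decoded as the
#' same stimulus category; N bins terminate runs and form no epochs.
#'
#' @param labels Character vector over `{F,B,C,N}` (one trial's bins), or a
#'   `decoded_sequences` object (all trials).
#' @param trial_id Trial identifier(s) attached to the output.
#' @param period Period label attached to the output.
#' @param bin_ms Bin duration, ms (default 20).
#' @return A data frame with `trial_id`, `period`, `label`, `start_bin`,
#'   `n_bins`, `length_ms`.
#' @export
extract_replay_epochs <- function(labels, trial_id = 1L, period = "retention",
                                  bin_ms = 20) {
  if (inherits(labels, "decoded_sequences")) {
    out <- lapply(seq_len(nrow(labels$labels)), function(i)
      extract_replay_epochs(labels$labels[i, ], labels$trial_id[i],
                            labels$period, bin_ms))
    return(do.call(rbind, out))
  }
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "N"
  data.frame(trial_id = rep(trial_id, sum(keep)),
             period = rep(period, sum(keep)),
             label = r$values[keep], start_bin = starts[keep],
             n_bins = r$lengths[keep],
             length_ms = bin_ms * r$lengths[keep],
             stringsAsFactors = FALSE)
}

#' Histogram of replay-epoch lengths
#'
#' Counts epochs in the four canonical length ranges 20-140, 160-400,
#' 420-1100, 1200-3000 ms. Assignment is by upper edge (first range whose
#' upper bound is >= the length), so the 20 ms grid values falling between
#' the printed edges (1120-1180 ms) are counted with the longest range —
#' consistent with the > 1100 ms long-replay rule.
#'
#' @param epochs Data frame from [extract_replay_epochs()].
#' @param period Optional period filter.
#' @return A named count vector of class `epoch_length_histogram` (one entry
#'   per range).
#' @export
histogram_epoch_lengths <- function(epochs, period = NULL) {
  if (!is.null(period)) epochs <- epochs[epochs$period == period, , drop = FALSE]
  nm <- vapply(EPOCH_RANGES_MS, function(r) sprintf("%g-%g", r[1], r[2]),
               character(1))
  counts <- stats::setNames(integer(length(EPOCH_RANGES_MS)), nm)
  if (nrow(epochs)) {
    if (any(epochs$length_ms < 20 | epochs$length_ms > 3000)) {
      stopf("epoch length outside 20-3000 ms; impossible under 150-bin windows")
    }
    uppers <- vapply(EPOCH_RANGES_MS, `[`, numeric(1), 2)
    bin <- vapply(epochs$length_ms, function(l) which(uppers >= l)[1], integer(1))
    counts[] <- tabulate(bin, nbins = length(uppers))
    if (sum(counts) != nrow(epochs)) stopf("epoch lengths fell outside all ranges")
  }
  structure(counts, class = c("epoch_length_histogram", class(counts)))
}

#' @export
print.epoch_length_histogram <- function(x, ...) {
  cat("<epoch_length_histogram> epochs per length range (ms):\n")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Compare per-subject summaries between retention and ITI
#'
#' Two-sided Wilcoxon rank-sum test on per-subject values of any decoded
#' summary (epoch counts per length range, replay counts, N counts,
#' transition probabilities). Exact p-values are used for group sizes up to
#' 10 per side with no ties; otherwise the tie-corrected normal
#' approximation.
#'
#' @param x,y Per-subject values for the two periods.
#' @return `htest` result from [stats::wilcox.test()].
#' @export
compare_periods <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stopf("empty group")
  exact <- length(x) <= 10 && length(y) <= 10 && !any(duplicated(c(x, y)))
  stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                     correct = !exact)
}

#' Estimate the replay-state transition matrix
#'
#' Counts one-step transitions between consecutive bins within each trial's
#' window (never across trials) and row-normalizes. With `remap`, each
#' trial's category labels are first converted to that trial's sequence
#' positions 1/2/3, so matrices from different trials share a common
#' position-based state space.
#'
#' @param decoded A `decoded_sequences` object, or a character label matrix
#'   (trials x bins).
#' @param design Trial design (required for `remap`), rows aligned to the
#'   decoded trials.
#' @param remap If `TRUE`, map categories to sequence positions before
#'   counting.
#' @return A `transition_matrix`: `counts` and row-stochastic `probs` (4x4,
#'   states F/B/C/N or 1/2/3/N), `n_transitions`.
#' @export
estimate_transition_matrix <- function(decoded, design = NULL, remap = FALSE) {
  labels <- if (inherits(decoded, "decoded_sequences")) decoded$labels else decoded
  if (!is.matrix(labels)) labels <- matrix(labels, nrow = 1)
  states <- if (remap) c("1", "2", "3", "N") else STATE_LEVELS
  if (remap) {
    if (is.null(design)) stopf("remap requires the trial design")
    if (nrow(design) != nrow(labels)) stopf("design not aligned to decoded trials")
    for (i in seq_len(nrow(labels))) {
      pos <- stats::setNames(c("1", "2", "3"), trial_sequence(design, i))
      m <- labels[i, ] != "N"
      labels[i, m] <- pos[labels[i, m]]
    }
  }
  counts <- matrix(0, 4, 4, dimnames = list(states, states))
  for (i in seq_len(nrow(labels))) {
    from <- factor(labels[i, -ncol(labels)], levels = states)
    to <- factor(labels[i, -1], levels = states)
    counts <- counts + table(from, to)
  }
  counts <- unclass(counts)
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs == 0, 1, rs)
  structure(list(states = states, counts = counts, probs = probs,
                 n_transitions = sum(counts)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> states %s, %d transitions\n",
              paste(x$states, collapse = "/"), x$n_transitions))
  print(round(x$probs, 3))
  invisible(x)
}

#' Test the directionality of replay
#'
#' From per-subject position-remapped transition matrices, computes the
#' forward replay probability p(1->2) p(2->3) p(3->1) and backward
#' probability p(3->2) p(2->1) p(1->3), and runs the four two-sided Wilcoxon
#' rank-sum comparisons: forward vs backward, p(1->2) vs p(1->3),
#' p(2->1) vs p(2->3), and p(3->1) vs p(3->2). Subjects whose matrix never
#' visited a needed row are excluded from the affected comparison.
#'
#' @param matrices List of per-subject `transition_matrix` objects with
#'   position states, or plain 4x4 row-stochastic matrices (rows 1,2,3,N).
#' @return A `directionality_stats` list: per-subject `p_forward` /
#'   `p_backward`, the comparison table with p-values, and any exclusions.
#' @export
directionality_test <- function(matrices) {
  probs <- lapply(matrices, function(m) {
    if (inherits(m, "transition_matrix")) {
      if (!identical(m$states[1:3], c("1", "2", "3"))) {
        stopf("directionality test needs position-remapped matrices")
      }
      list(P = m$probs, visited = rowSums(m$counts) > 0)
    } else {
      list(P = m, visited = rep(TRUE, 4))
    }
  })
  n <- length(probs)
  pf <- vapply(probs, function(x) x$P[1, 2] * x$P[2, 3] * x$P[3, 1], numeric(1))
  pb <- vapply(probs, function(x) x$P[3, 2] * x$P[2, 1] * x$P[1, 3], numeric(1))
  all_rows <- vapply(probs, function(x) all(x$visited[1:3]), logical(1))
  row_ok <- function(r) vapply(probs, function(x) x$visited[r], logical(1))
  comparisons <- list(
    forward_vs_backward = list(x = pf, y = pb, ok = all_rows),
    p12_vs_p13 = list(x = vapply(probs, function(z) z$P[1, 2], numeric(1)),
                      y = vapply(probs, function(z) z$P[1, 3], numeric(1)),
                      ok = row_ok(1)),
    p21_vs_p23 = list(x = vapply(probs, function(z) z$P[2, 1], numeric(1)),
                      y = vapply(probs, function(z) z$P[2, 3], numeric(1)),
                      ok = row_ok(2)),
    p31_vs_p32 = list(x = vapply(probs, function(z) z$P[3, 1], numeric(1)),
                      y = vapply(probs, function(z) z$P[3, 2], numeric(1)),
                      ok = row_ok(3))
  )
  res <- lapply(comparisons, function(cmp) {
    if (sum(cmp$ok) < 2L) {
      return(list(p = NA_real_, n_subjects = sum(cmp$ok),
                  excluded = which(!cmp$ok)))
    }
    ht <- compare_periods(cmp$x[cmp$ok], cmp$y[cmp$ok])
    list(p = ht$p.value, statistic = unname(ht$statistic),
         n_subjects = sum(cmp$ok), excluded = which(!cmp$ok))
  })
  structure(list(p_forward = pf, p_backward = pb, n_subjects = n,
                 comparisons = res),
            class = "directionality_stats")
}

#' Identify the predominantly maintained stimulus of a trial
#'
#' The predominant (PM) category is the one with the most decoded retention
#' bins; ties are broken by the longest single epoch, then by earliest
#' occurrence. The alternative rule `"longest"` uses the longest single
#' epoch directly (count ties broken by bin count). The probe category's
#' longest epoch assigns the replay group: `long` if > 1100 ms, `short` if
#' 20-1100 ms, `none` if it never replayed.
#'
#' @param labels One trial's retention label vector over `{F,B,C,N}`.
#' @param trial One row of the trial design (supplies the probe category and
#'   the sequence for the PM position).
#' @param rule `"bins"` (default, most decoded bins) or `"longest"`.
#' @param bin_ms Bin duration, ms.
#' @return A one-row data frame: `trial_id`, `pm_category`, `pm_position`,
#'   `longest_F/B/C_ms`, `probe_longest_ms`, `replay_group`, `rule`.
#' @export
identify_predominant <- function(labels, trial, rule = c("bins", "longest"),
                                 bin_ms = 20) {
  rule <- match.arg(rule)
  n_bins_cat <- vapply(CATEGORY_LEVELS, function(cc) sum(labels == cc), numeric(1))
  longest <- vapply(CATEGORY_LEVELS, function(cc)
    bin_ms * longest_run_bins(labels, cc), numeric(1))
  first_bin <- vapply(CATEGORY_LEVELS, function(cc) {
    i <- which(labels == cc)
    if (length(i)) i[1] else Inf
  }, numeric(1))
  if (all(n_bins_cat == 0)) {
    pm_cat <- NA_character_
  } else {
    key <- if (rule == "bins")

      order(-n_bins_cat, -longest, first_bin)
    else
      order(-longest, -n_bins_cat, first_bin)
    pm_cat <- CATEGORY_LEVELS[key[1]]
  }
  seq_cats <- trial_sequence(trial, 1)
  pm_pos <- if (is.na(pm_cat)) NA_integer_ else match(pm_cat, seq_cats)
  probe_longest <- longest[trial$probe_category]
  group <- if (probe_longest > 1100) "long" else if (probe_longest >= 20) "short" else "none"
  data.frame(trial_id = trial$trial_id, pm_category = pm_cat,
             pm_position = pm_pos,
             longest_F_ms = longest["F"], longest_B_ms = longest["B"],
             longest_C_ms = longest["C"],
             probe_longest_ms = unname(probe_longest), replay_group = group,
             rule = rule, stringsAsFactors = FALSE)
}

#' Predominance summaries for all trials of a decoded set
#'
#' @param decoded Retention `decoded_sequences`.
#' @param design Trial design aligned to the decoded trials.
#' @param rule Passed to [identify_predominant()].
#' @return Row-bound [identify_predominant()] results.
#' @export
summarize_predominance <- function(decoded, design, rule = c("bins", "longest")) {
  rule <- match.arg(rule)
  do.call(rbind, lapply(seq_len(nrow(design)), function(i)
    identify_predominant(decoded$labels[i, ], design[i, , drop = FALSE], rule)))
}

#' Within-subject ANOVA on predominance proportions
#'
#' Tests whether which stimulus becomes predominant depends on its category
#' or its sequence position: a two-factor (category x position)
#' within-subject ANOVA on per-subject proportions of trials whose PM
#' stimulus falls in each category-by-position cell.
#'
#' @param summaries Data frame of per-trial predominance rows carrying a
#'   `subject` column (rows with no PM stimulus are dropped).
#' @return A list with the cell-proportion table and the ANOVA table
#'   (category, position, and interaction effects).
#' @export
predominance_anova <- function(summaries) {
  s <- summaries[!is.na(summaries$pm_category), , drop = FALSE]
  if (is.null(s$subject)) stopf("summaries must carry a `subject` column")
  cells <- expand.grid(subject = unique(s$subject),
                       category = CATEGORY_LEVELS, position = 1:3,
                       stringsAsFactors = FALSE)
  cells$prop <- mapply(function(su, cc, pp) {
    tr <- s$subject == su
    sum(tr & s$pm_category == cc & s$pm_position == pp) / sum(tr)
  }, cells$subject, cells$category, cells$position)
  if (any(!is.finite(cells$prop))) stopf("a subject has no PM trials")
  cells$subject <- factor(cells$subject)
  cells$category <- factor(cells$category)
  cells$position <- factor(cells$position)
  fit <- stats::aov(prop ~ category * position +
                      Error(subject / (category * position)), data = cells)
  tabs <- summary(fit)
  pull <- function(stratum, term) {
    tt <- tabs[[stratum]][[1]]
    i <- grep(term, trimws(rownames(tt)), fixed = TRUE)[1]
    list(F = tt[i, "F value"], p = tt[i, "Pr(>F)"],
         df1 = tt[i, "Df"], df2 = tt[nrow(tt), "Df"])
  }
  list(cells = cells,
       category = pull("Error: subject:category", "category"),
       position = pull("Error: subject:position", "position"),
       interaction = pull("Error: subject:category:position", "category:position"))
}
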