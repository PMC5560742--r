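test_that("replay epochs are maximal non-N runs", {
  ep <- extract_replay_epochs(c("F", "F", "F", "N", "B", "B"))
  expect_equal(ep$label, c("F", "B"))
  expect_equal(ep$n_bins, c(3L, 2L))
  expect_equal(ep$length_ms, c(60, 40))
  expect_equal(ep$start_bin, c(1L, 5L))
  expect_equal(nrow(extract_replay_epochs(rep("N", 150))), 0L)
  long <- extract_replay_epochs(rep("F", 150))
  expect_equal(long$length_ms, 3000)
  # lossless decomposition: epochs + N gaps reconstruct the sequence
  set.seed(1)
  lab <- sample(c("F", "B", "C", "N"), 80, replace = TRUE)
  eps <- extract_replay_epochs(lab)
  rebuilt <- rep("N", 80)
  for (j in seq_len(nrow(eps))) {
    rebuilt[eps$start_bin[j] + seq_len(eps$n_bins[j]) - 1L] <- eps$label[j]
  }
  expect_identical(rebuilt, lab)
})

test_that("epoch-length histogram partitions the four ranges", {
  ep <- data.frame(trial_id = 1:4, period = "retention",
                   label = "F", start_bin = 1L,
                   n_bins = c(3L, 10L, 25L, 75L),
                   length_ms = c(60, 200, 500, 1500))
  h <- histogram_epoch_lengths(ep)
  expect_equal(unname(unclass(h)), c(1L, 1L, 1L, 1L))
  expect_equal(sum(h), nrow(ep))
  h0 <- histogram_epoch_lengths(ep[0, ])
  expect_true(all(h0 == 0L))
  # random multiples of 20 ms always land in exactly one range
  set.seed(2)
  epr <- data.frame(length_ms = 20 * sample(1:150, 60, replace = TRUE))
  expect_equal(sum(histogram_epoch_lengths(epr)), 60L)
  # grid values between the printed 1100 and 1200 ms edges count as long
  expect_equal(unname(histogram_epoch_lengths(data.frame(length_ms = 1120))[4]), 1L)
  expect_error(histogram_epoch_lengths(data.frame(length_ms = 3020)), "outside")
})

test_that("rank-sum comparison matches exact enumeration and rank properties", {
  # brute-force oracle: enumerate all 70 assignments of 8 ranks to group 1
  x <- c(10, 11, 12, 13); y <- c(1, 2, 3, 4)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[1:4])
  combos <- combn(8, 4)
  w_all <- apply(combos, 2, function(i) sum(rank(c(x, y))[i]))
  p_oracle <- 2 * mean(w_all >= w_obs)  # observed is the maximum
  expect_equal(p_oracle, 2 / 70)
  expect_equal(compare_periods(x, y)$p.value, p_oracle, tolerance = 1e-10)
  # identical samples: exact two-sided p = 1 is unattainable with ties ->
  # shifted-by-nothing case via distinct interleaved values
  expect_equal(compare_periods(c(1, 4, 5, 8), c(2, 3, 6, 7))$p.value, 1)
  # rank statistic invariant under monotone transforms
  expect_equal(compare_periods(exp(x), exp(y))$p.value,
               compare_periods(x, y)$p.value)
  expect_error(compare_periods(numeric(0), y), "empty")
})

test_that("transition matrices count within-trial transitions only", {
  cyc <- matrix(rep(c("F", "B", "C"), length.out = 30), 1, 30)
  tm <- estimate_transition_matrix(cyc)
  expect_equal(tm$probs["F", "B"], 1)
  expect_equal(tm$probs["B", "C"], 1)
  expect_equal(tm$probs["C", "F"], 1)
  const <- matrix("F", 1, 20)
  tmc <- estimate_transition_matrix(const)
  expect_equal(tmc$probs["F", "F"], 1)
  expect_equal(sum(tmc$counts), 19)
  # conservation: total transitions = trials * (bins - 1)
  set.seed(3)
  lab <- matrix(sample(c("F", "B", "C", "N"), 5 * 40, replace = TRUE), 5, 40)
  tm2 <- estimate_transition_matrix(lab)
  expect_equal(tm2$n_transitions, 5 * 39)
  # no cross-trial transitions: a trial ending F before one starting B
  two <- rbind(matrix("F", 1, 10), matrix("B", 1, 10))
  expect_equal(estimate_transition_matrix(two)$counts["F", "B"], 0)
})

test_that("transition estimator is consistent for a known generator", {
  P <- matrix(c(0.5, 0.2, 0.2, 0.1,
                0.1, 0.6, 0.2, 0.1,
                0.3, 0.3, 0.3, 0.1,
                0.2, 0.2, 0.2, 0.4), 4, 4, byrow = TRUE)
  idx <- sample_markov_chains(1, 1e5, P, rep(0.25, 4), seed = 13)
  lab <- matrix(c("F", "B", "C", "N")[idx], 1, 1e5)
  est5 <- estimate_transition_matrix(lab)
  expect_lt(max(abs(est5$probs - P)), 0.02)
  est3 <- estimate_transition_matrix(lab[, 1:1000, drop = FALSE])
  expect_lt(max(abs(est5$probs - P)), max(abs(est3$probs - P)))
})

test_that("position remapping converts categories to sequence positions", {
  d <- enumerate_design(1)[1, , drop = FALSE]
  seqc <- c(d$cat_1, d$cat_2, d$cat_3)
  lab <- matrix(c(seqc[1], seqc[1], seqc[2], seqc[3], "N"), 1, 5)
  tm <- estimate_transition_matrix(lab, d, remap = TRUE)
  expect_equal(tm$states, c("1", "2", "3", "N"))
  expect_equal(tm$counts["1", "1"], 1)
  expect_equal(tm$counts["1", "2"], 1)
  expect_equal(tm$counts["2", "3"], 1)
  expect_equal(tm$counts["3", "N"], 1)
  expect_error(estimate_transition_matrix(lab, remap = TRUE), "design")
})

test_that("directionality is exactly symmetric for symmetric generators", {
  P <- matrix(c(0.4, 0.2, 0.2, 0.2,
                0.2, 0.4, 0.2, 0.2,
                0.2, 0.2, 0.4, 0.2,
                0.2, 0.2, 0.2, 0.4), 4, 4, byrow = TRUE)
  ds <- directionality_test(replicate(6, P, simplify = FALSE))
  expect_identical(ds$p_forward, ds$p_backward)
  expect_true(all(ds$p_forward >= 0 & ds$p_forward <= 1))
})

test_that("predominance rule: majority of bins with documented tie chain", {
  d <- enumerate_design(1)[1, , drop = FALSE]
  lab <- c(rep("F", 80), rep("B", 10), rep("N", 60))
  pm <- identify_predominant(lab, d)
  expect_equal(pm$pm_category, "F")
  expect_equal(pm$pm_position, match("F", c(d$cat_1, d$cat_2, d$cat_3)))
  pmN <- identify_predominant(rep("N", 150), d)
  expect_true(is.na(pmN$pm_category))
  expect_equal(pmN$replay_group, "none")
  # bin-count tie broken by the longest single epoch
  tie <- c(rep("F", 3), "N", rep("F", 3), "N", rep("B", 6), rep("N", 136))
  expect_equal(identify_predominant(tie, d)$pm_category, "B")
  # longest-epoch alternative rule
  expect_equal(identify_predominant(tie, d, rule = "longest")$pm_category, "B")
})

test_that("replay grouping uses the strict 1100 ms boundary", {
  d <- enumerate_design(1)[1:3, ]
  lab_long <- c(rep(d$probe_category[1], 60), rep("N", 90))   # 1200 ms
  expect_equal(identify_predominant(lab_long, d[1, ])$replay_group, "long")
  lab_1100 <- c(rep(d$probe_category[2], 55), rep("N", 95))   # exactly 1100 ms
  expect_equal(identify_predominant(lab_1100, d[2, ])$replay_group, "short")
  lab_1120 <- c(rep(d$probe_category[3], 56), rep("N", 94))   # 1120 ms
  expect_equal(identify_predominant(lab_1120, d[3, ])$replay_group, "long")
})

test_that("predominance ANOVA: closure and sensitivity to a forced position", {
  set.seed(9)
  mk_summaries <- function(force_pos = NULL) {
    do.call(rbind, lapply(1:10, function(su) {
      d <- enumerate_design(su)[1:54, ]
      pos <- if (is.null(force_pos)) sample(1:3, 54, TRUE) else rep(force_pos, 54)
      cat <- vapply(seq_len(54), function(i)
        d[[paste0("cat_", pos[i])]][i], character(1))
      data.frame(subject = su, trial_id = d$trial_id,
                 pm_category = cat, pm_position = pos)
    }))
  }
  res <- predominance_anova(mk_summaries())
  # per-subject proportions over the 9 cells sum to 1
  sums <- tapply(res$cells$prop, res$cells$subject, sum)
  expect_equal(as.vector(sums), rep(1, 10), tolerance = 1e-12)
  res1 <- predominance_anova(mk_summaries(force_pos = 1))
  expect_lt(res1$position$p, 0.001)
  expect_error(predominance_anova(data.frame(pm_category = "F")), "subject")
})
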