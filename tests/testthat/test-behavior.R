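# Simulated trial-level behavior for LMM tests: subjects with true random
# intercepts and a linear effect of replay length on the 0/1 outcome scale.
sim_behavior_data <- function(n_subjects = 10, n_trials = 80, slope = 0,
                              intercept = 0.7, subj_sd = 0.05, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_subjects), function(su) {
    replay <- ifelse(runif(n_trials) < 0.4, 0,
                     20 * sample(1:100, n_trials, replace = TRUE))
    p <- pmin(pmax(intercept + rnorm(1, 0, subj_sd) + slope * replay, 0.02), 0.98)
    data.frame(subject = su, replay_ms = replay,
               hit = as.numeric(runif(n_trials) < p))
  }))
}

test_that("mixed model recovers a known replay-length effect", {
  slope <- 2e-4  # per ms on the probability scale
  d <- sim_behavior_data(n_subjects = 12, slope = slope, seed = 3)
  fit <- fit_replay_behavior_lmm(d, "hit")
  expect_gt(fit$estimate, 0)
  expect_lt(abs(fit$estimate - slope), 2 * fit$se)
  expect_equal(fit$n_observations, nrow(d))
  expect_gt(fit$random_intercept_sd, 0)
  # null slope: estimate within 2 SE of zero
  d0 <- sim_behavior_data(n_subjects = 12, slope = 0, seed = 4)
  fit0 <- fit_replay_behavior_lmm(d0, "hit")
  expect_lt(abs(fit0$estimate), 2 * fit0$se)
  expect_error(fit_replay_behavior_lmm(d[d$subject == 1, ], "hit"), "2 subjects")
})

test_that("singular random intercepts fall back to pooled regression", {
  d <- sim_behavior_data(n_subjects = 8, slope = 1e-4, subj_sd = 0, seed = 5)
  fit <- suppressWarnings(fit_replay_behavior_lmm(d, "hit"))
  lmfit <- lm(hit ~ replay_ms, data = d)
  if (fit$singular) {
    expect_equal(fit$estimate, unname(coef(lmfit)["replay_ms"]), tolerance = 1e-10)
  } else {
    # near-zero variance: LMM estimate matches ordinary regression closely
    expect_equal(fit$estimate, unname(coef(lmfit)["replay_ms"]), tolerance = 1e-6)
  }
})

test_that("logistic variant returns a slope on the log-odds scale", {
  d <- sim_behavior_data(n_subjects = 8, slope = 2e-4, seed = 6)
  fit <- fit_replay_behavior_lmm(d, "hit", family = "binomial")
  expect_gt(fit$estimate, 0)
  expect_true(is.finite(fit$p))
})

test_that("replay grouping partitions probes at the 1100 ms boundary", {
  tr <- data.frame(subject = rep(1:2, each = 4),
                   probe_longest_ms = c(0, 1100, 1120, 2000, 0, 20, 1100, 1200),
                   detail_response = c(TRUE, TRUE, FALSE, TRUE,
                                       FALSE, TRUE, TRUE, TRUE),
                   detail_rt = rep(900, 8))
  g <- group_by_replay_duration(tr)
  expect_equal(as.character(g$trials$replay_group),
               c("none", "short", "long", "long", "none", "short", "short", "long"))
  agg <- g$by_subject
  # group counts sum to each subject's probed-trial count
  expect_equal(as.vector(tapply(agg$n_trials, agg$subject, sum, na.rm = TRUE)),
               c(4, 4))
})

test_that("replay-group ANOVA detects an injected long-group advantage", {
  set.seed(7)
  mk <- function(boost) {
    do.call(rbind, lapply(1:14, function(su) {
      base <- 70 + rnorm(1, 0, 3)
      data.frame(subject = su,
                 probe_longest_ms = rep(c(0, 400, 1500), each = 20),
                 detail_response = c(runif(20) < base / 100,
                                     runif(20) < base / 100,
                                     runif(20) < (base + boost) / 100),
                 detail_rt = 900)
    }))
  }
  res <- behavior_anova_posthoc(group_by_replay_duration(mk(15)))
  expect_lt(res$anova$p, 0.05)
  expect_lt(res$long_vs_short$p, 0.05)
  expect_lt(res$long_vs_none$p, 0.05)
  expect_equal(res$anova$df1, 2)
  # identical paired samples: t = 0, p = 1
  grouped <- group_by_replay_duration(mk(0))
  grouped$by_subject$detail_hit_pct <- 70  # force exact equality
  res0 <- behavior_anova_posthoc(grouped)
  expect_equal(res0$long_vs_short$t, 0)
  expect_equal(res0$long_vs_short$p, 1)
})

test_that("subjects missing a replay group are excluded and reported", {
  tr <- rbind(
    data.frame(subject = 1, probe_longest_ms = c(0, 400, 1500, 0, 500, 1600),
               detail_response = TRUE, detail_rt = 900),
    data.frame(subject = 2, probe_longest_ms = c(0, 400, 1400, 0, 300, 1900),
               detail_response = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
               detail_rt = 900),
    data.frame(subject = 3, probe_longest_ms = c(0, 0, 0, 40, 60, 80),
               detail_response = TRUE, detail_rt = 900))  # no long group
  res <- behavior_anova_posthoc(group_by_replay_duration(tr))
  expect_equal(res$excluded_subjects, 3)
  expect_equal(nrow(res$by_subject), 2)
})
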