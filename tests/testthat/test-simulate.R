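test_that("category patterns are unit-norm, near-orthogonal, deterministic", {
  p <- quick_params(seed = 11)
  m <- simulate_category_patterns(p)
  expect_equal(colnames(m), c("F", "B", "C"))
  expect_equal(unname(sqrt(colSums(m^2))), rep(1, 3), tolerance = 1e-12)
  cc <- abs(crossprod(m))
  expect_true(max(cc[upper.tri(cc)]) <= p$max_pattern_cos)
  expect_identical(m, simulate_category_patterns(p))
  expect_error(simulate_category_patterns(sim_params(n_channels = 2)),
               "n_channels")
})

test_that("encoding epochs: zero-SNR noise, attention identity, bit-reproducibility", {
  d <- enumerate_design(3)[1:12, ]
  p0 <- quick_params(snr_encoding = 0, seed = 4)
  ep <- simulate_encoding_epochs(d, p0)
  expect_equal(dim(ep$data)[1], 36)  # 3 epochs per trial
  expect_equal(range(ep$time_ms), c(-100, 500))
  # pure noise: per-channel means near zero at the noise scale
  ch_means <- apply(ep$data, 2, mean)
  expect_lt(max(abs(ch_means)), 5 * p0$noise_sd / sqrt(36 * 361))
  # same params + seed -> bit-identical output
  expect_identical(ep$data, simulate_encoding_epochs(d, p0)$data)

  # attention_gain_pm = 1: expected early evoked amplitude identical for PM
  # and non-PM stimuli (signal parts equal by construction)
  p1 <- quick_params(snr_encoding = 2, attention_gain_pm = 1, noise_sd = 0, seed = 4)
  ep1 <- simulate_encoding_epochs(d, p1)
  early <- megreplay:::early_component_pattern(p1)
  win <- ep1$time_ms >= 100 & ep1$time_ms <= 150
  proj <- apply(ep1$data[, , win], 1, function(m) mean(crossprod(early, m)))
  is_pm <- ep1$trial_meta$is_pm
  cats <- ep1$trial_meta$category
  for (cc in unique(cats[is_pm])) {
    expect_equal(mean(proj[is_pm & cats == cc]),
                 mean(proj[!is_pm & cats == cc]), tolerance = 1e-10)
  }
})

test_that("attention gain < 1 lowers the PM early evoked amplitude", {
  # ~500 stimulus epochs; one-sided t-test on the early-window projection
  d <- enumerate_design(8)
  p <- quick_params(snr_encoding = 1.2, attention_gain_pm = 0.7, seed = 6)
  ep <- simulate_encoding_epochs(d, p)
  early <- megreplay:::early_component_pattern(p)
  win <- ep$time_ms >= 100 & ep$time_ms <= 150
  proj <- apply(ep$data[, , win], 1, function(m) mean(crossprod(early, m)))
  ht <- t.test(proj[ep$trial_meta$is_pm], proj[!ep$trial_meta$is_pm],
               alternative = "less")
  expect_lt(ht$p.value, 0.01)
})

test_that("hidden-state chains honor degenerate and long-run generators", {
  d <- enumerate_design(1)[1:10, ]
  p <- quick_params(hidden_transition = diag(4), hidden_start = rep(0.25, 4),
                    seed = 2)
  st <- simulate_hidden_state_sequence(d, p, "retention")
  expect_true(all(apply(st, 1, function(r) length(unique(r)) == 1L)))

  # absorbing N with start at N -> all-N sequences
  pN <- quick_params(hidden_transition = diag(4),
                     hidden_start = c(0, 0, 0, 1), seed = 2)
  stN <- simulate_hidden_state_sequence(d, pN, "retention")
  expect_true(all(stN == "N"))

  expect_error(sim_params(hidden_transition = matrix(1, 4, 4)), "sum to 1")
})

test_that("empirical transition frequencies converge to the generator", {
  P <- matrix(c(0.6, 0.2, 0.1, 0.1,
                0.1, 0.7, 0.1, 0.1,
                0.2, 0.1, 0.6, 0.1,
                0.3, 0.2, 0.2, 0.3), 4, 4, byrow = TRUE)
  s <- sample_markov_chains(1, 1e5, P, rep(0.25, 4), seed = 77)[1, ]
  # brute-force counting oracle, independent of estimate_transition_matrix
  emp <- matrix(0, 4, 4)
  for (a in 1:4) for (b in 1:4) {
    emp[a, b] <- sum(s[-length(s)] == a & s[-1] == b)
  }
  emp <- emp / rowSums(emp)
  expect_lt(max(abs(emp - P)), 0.02)
})

test_that("delay epochs embed patterns only where states are non-null", {
  d <- enumerate_design(2)[1:6, ]
  p <- quick_params(snr_replay = 5, seed = 3)
  d <- assign_predominant(d, p)
  stN <- matrix("N", 6, 150)
  ep_allN <- simulate_delay_epochs(d, stN, p, "retention")
  # all-N retention data carries no pattern energy above the noise floor
  expect_lt(abs(sd(ep_allN$data) / p$noise_sd - 1), 0.02)
  expect_equal(dim(ep_allN$data)[3], 150 * 12 + 1)
  expect_equal(range(ep_allN$time_ms), c(1000, 4000))

  st <- simulate_hidden_state_sequence(d, p, "retention")
  ep <- simulate_delay_epochs(d, st, p, "retention")
  expect_gt(sd(ep$data), sd(ep_allN$data))
  expect_identical(ep$data, simulate_delay_epochs(d, st, p, "retention")$data)

  iti <- simulate_delay_epochs(d, stN, p, "iti")
  expect_equal(range(iti$time_ms), c(-3000, 0))
})

test_that("behavioral saturation: huge intercept gives all hits", {
  d <- enumerate_design(4)[1:30, ]
  p <- quick_params(behavior_intercept = 50, seed = 5)
  d <- assign_predominant(d, p)
  st <- simulate_hidden_state_sequence(d, p, "retention")
  b <- simulate_behavior(d, st, p)
  expect_true(all(b$detail_response))
  expect_true(all(b$order_response %in% 1:3))
  expect_true(all(b$probe_replay_ms >= 0))
  # longest-run covariate matches an independent run-length computation
  i <- 7L
  r <- rle(st[i, ])
  expect_equal(b$probe_replay_ms[i],
               20 * max(0, r$lengths[r$values == b$probe_category[i]]))
})
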