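test_that("exclusion filter applies the chi-square and direction rules", {
  expect_false(exclusion_filter(60, 120)$included)
  f <- exclusion_filter(72, 120)
  expect_equal(f$chisq, 4.8)
  expect_true(f$included)
  # significant but below chance stays excluded
  f2 <- exclusion_filter(30, 120)
  expect_lt(f2$p_value, 0.05)
  expect_false(f2$included)
  expect_error(exclusion_filter(121, 120), "wins")
  expect_error(exclusion_filter(5, 0), "positive")
  # monotone: once included, more wins never exclude
  incl <- vapply(0:120, function(w) exclusion_filter(w, 120)$included, TRUE)
  first <- which(incl)[1]
  expect_true(all(incl[first:121]))
})

test_that("participant summaries flag below-chance environments", {
  d <- make_small_dataset(6, 80, 2, seed = 90)
  s <- participant_summary(d$data)
  expect_true(all(s$reward_rate >= 0 & s$reward_rate <= 1))
  expect_equal(nrow(s), 12)
  # the overall flag is the AND over environments
  for (id in unique(s$participant_id)) {
    rows <- s[s$participant_id == id, ]
    expect_equal(unique(rows$included), all(rows$included_env))
  }
})

test_that("lose-switch rates count within-casino loss pairs correctly", {
  base <- data.frame(participant_id = 1, phase = "learning", block = 1,
                     trial = 1:6, environment = "stable",
                     within_casino_trial = 1:6, correct_machine = 0,
                     winning_machine = 0L,
                     choice =  c(0L, 1L, 1L, 0L, 0L, 1L),
                     reward =  c(1L, 0L, 0L, 1L, 1L, 0L))
  # losses on trials 2 and 3; switch after trial 3 only -> rate 1/2
  # (trial 6 loss has no successor)
  r <- lose_switch_rates(base, stable = "stable", volatile = "none")
  expect_equal(r$rates$stable, 0.5)
  # win-stay/lose-shift agent scores 1, always-repeat scores 0
  wsls <- base
  wsls$choice <- c(0L, 0L, 1L, 1L, 1L, 1L)
  wsls$reward <- as.integer(wsls$choice == wsls$winning_machine)
  # choices follow: stay on win (trials 1-2 win), shift after each loss
  wsls$choice <- c(0L, 0L, 1L, 0L, 0L, 0L)
  wsls$reward <- as.integer(wsls$choice == wsls$winning_machine)
  r2 <- lose_switch_rates(wsls, stable = "stable", volatile = "none")
  expect_equal(r2$rates$stable, 1)
  rep_agent <- base
  rep_agent$choice <- rep(1L, 6)
  rep_agent$reward <- as.integer(rep_agent$choice == rep_agent$winning_machine)
  r3 <- lose_switch_rates(rep_agent, stable = "stable", volatile = "none")
  expect_equal(r3$rates$stable, 0)
})

test_that("block-boundary pairs are excluded from lose-switch counting", {
  d <- data.frame(participant_id = 1, phase = "learning",
                  block = c(1, 1, 2, 2), trial = c(1, 2, 1, 2),
                  environment = "stable", within_casino_trial = c(1, 2, 1, 2),
                  correct_machine = 0, winning_machine = 0L,
                  choice = c(1L, 1L, 0L, 0L), reward = c(0L, 0L, 1L, 1L))
  # the only scored loss is trial 1 (stay); trial 2's loss precedes a new block
  r <- lose_switch_rates(d, stable = "stable", volatile = "none")
  expect_equal(r$rates$stable, 0)
})

test_that("lose-switch rate rises with the negative learning rate", {
  set.seed(91)
  cfg <- phase_config("learning", 1, 200,
                      data.frame(environment = c("stable", "volatile"),
                                 p_reward = c(0.8, 0.9),
                                 volatility = c("stable", "volatile")))
  spec <- model_spec("dual")
  rate_at <- function(aneg) {
    ps <- lapply(1:20, function(i)
      param_set(spec, alpha_pos = 0.4, alpha_neg = aneg, beta = 5))
    names(ps) <- 1:20
    sim <- simulate_choices(generate_cohort(cfg, 20), spec, ps)
    r <- lose_switch_rates(sim)
    mean(c(r$rates$stable, r$rates$volatile), na.rm = TRUE)
  }
  r_low <- rate_at(0.1)
  r_mid <- rate_at(0.5)
  r_high <- rate_at(0.9)
  expect_lt(r_low, r_mid)
  expect_lt(r_mid, r_high)
})

test_that("volatile agents out-switch stable agents after losses", {
  set.seed(92)
  d <- make_small_dataset(20, 160, 2, seed = 93)
  r <- lose_switch_rates(d$data)
  expect_gt(r$test$t, 0)
  expect_equal(r$test$df, 19)
  expect_lt(r$test$p_value, 0.05)
})

test_that("post-switch accuracy produces per-position 2x2 chi-squares", {
  # hand-checked table: 80/20 vs 65/35 of n = 100 each gives chisq ~ 5.6
  tab <- matrix(c(80, 65, 20, 35), 2)
  expect_equal(unname(chisq.test(tab, correct = FALSE)$statistic),
               5.643, tolerance = 1e-3)
  set.seed(94)
  cfg <- experiment_profile("exp3")$phases$test
  spec <- model_spec("dual", environment_specific = TRUE)
  ps <- draw_cohort_params(spec, recovery_population(spec), 30)
  data <- simulate_choices(generate_cohort(cfg, 30), spec, ps)
  suppressWarnings(psa <- post_switch_accuracy(data, horizon = 8))
  expect_setequal(unique(psa$switch_no), 1:2)
  expect_true(all(psa$position <= 8))
  expect_true(all(psa$chisq >= 0))
  expect_true(all(psa$prop_stable >= 0 & psa$prop_stable <= 1))
  # label-swap invariance: flipping all machine codes leaves chisq alone
  flipped <- data
  for (col in c("choice", "correct_machine", "winning_machine")) {
    flipped[[col]] <- 1L - flipped[[col]]
  }
  suppressWarnings(psa2 <- post_switch_accuracy(flipped, horizon = 8))
  expect_equal(psa$chisq, psa2$chisq, tolerance = 1e-12)
})

test_that("block contrasts use a paired one-tailed t-test with guards", {
  d <- data.frame(participant_id = rep(1:5, each = 4),
                  phase = "learning",
                  block = rep(c(1, 1, 2, 2), 5), trial = rep(1:4, 5),
                  environment = "stable", within_casino_trial = rep(1:4, 5),
                  correct_machine = 0, winning_machine = 0L,
                  choice = 0L,
                  reward = c(0L, 0L, 1L, 1L,  0L, 1L, 1L, 1L,  1L, 0L, 1L, 0L,
                             0L, 0L, 1L, 0L,  0L, 1L, 1L, 1L))
  res <- block_reward_contrast(d)
  first <- c(0, .5, .5, 0, .5)
  last <- c(1, 1, .5, .5, 1)
  tt <- t.test(last, first, paired = TRUE, alternative = "greater")
  expect_equal(res$t, unname(tt$statistic))
  expect_equal(res$df, 4)
  expect_equal(res$p_value, tt$p.value)
  # identical blocks: t = 0, p = 0.5... but equal-diff zero variance is flagged
  d2 <- d
  d2$reward <- rep(c(0L, 1L, 0L, 1L), 5)
  res2 <- block_reward_contrast(d2)
  expect_true(res2$degenerate)
  expect_error(block_reward_contrast(d[d$block == 1, ]), "2 blocks")
})
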