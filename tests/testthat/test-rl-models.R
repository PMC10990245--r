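test_that("value-update rules match direct arithmetic", {
  expect_equal(delta_update(0.5, 1, 0), 0.5)
  expect_equal(delta_update(0.5, 1, 1), 1.0)
  expect_equal(delta_update(0.5, 0, 0.4), 0.3)
  expect_error(delta_update(0.5, 1, 1.2), "alpha")
  expect_equal(dual_delta_update(0.5, 1, 0.2, 0.9), 0.6)
  expect_equal(dual_delta_update(0.5, 0, 0.2, 0.9), 0.05)
  # dual reduces to single when both rates coincide
  q <- runif(20); r <- rbinom(20, 1, 0.5)
  expect_identical(dual_delta_update(q, r, 0.37, 0.37),
                   delta_update(q, r, 0.37))
  expect_equal(variable_lr_update(0.5, 0.3, 1, 0), 0.5)
  expect_equal(variable_lr_update(0.5, 0.3, 1, 1), 0.7)
  expect_equal(variable_lr_update(0.5, 0.3, 1, 0.1), 0.52)
})

test_that("softmax probabilities are symmetric, bounded and exact", {
  expect_equal(softmax_prob(0.3, 0.9, 0), 0.5)
  expect_equal(softmax_prob(0.7, 0.7, 5), 0.5)
  expect_equal(softmax_prob(0.8, 0.2, 4), 1 / (1 + exp(-2.4)))
  expect_error(softmax_prob(0, 0, 11), "beta")
  # probabilities over the two machines sum to 1
  qa <- runif(50); qb <- runif(50); b <- runif(50, 0, 10)
  expect_equal(softmax_prob(qa, qb, b) + softmax_prob(qb, qa, b),
               rep(1, 50))
})

test_that("model specs carry the declared parameter multiplicities", {
  expect_equal(param_names(model_spec("single")), c("alpha", "beta"))
  expect_equal(param_names(model_spec("dual")),
               c("alpha_pos", "alpha_neg", "beta"))
  expect_equal(param_names(model_spec("variable")), c("alpha", "eta", "beta"))
  pb <- param_bounds(model_spec("dual"))
  expect_equal(pb$upper, c(1, 1, 10))
  expect_length(all_model_specs(), 6)
  # env-specific dual: 2 copies of each of 3 parameters
  m <- build_model(make_small_dataset(2, 20, 1)$data,
                   model_spec("dual", environment_specific = TRUE))
  expect_equal(nrow(m$param_table), 6)
  m2 <- build_model(make_small_dataset(2, 20, 1)$data, model_spec("variable"))
  expect_equal(nrow(m2$param_table), 3)
})

test_that("pointwise log-likelihood matches the hand-worked 3-trial sequence", {
  # stable casino, alpha = 0.5, beta = 2; choices a,a,b; rewards 1,0,-
  # Q-trajectory of machine a: 0, 0.5, 0.25
  trials <- data.frame(participant_id = 1, phase = "learning", block = 1,
                       trial = 1:3, environment = "stable",
                       within_casino_trial = 1:3, correct_machine = 0,
                       winning_machine = c(0, 1, 1), choice = c(0L, 0L, 1L),
                       reward = c(1L, 0L, 0L))
  spec <- model_spec("single")
  ll <- pointwise_loglik(trials, spec, param_set(spec, alpha = 0.5, beta = 2))
  expect_equal(ll[1], log(0.5))
  expect_equal(ll[2], log(exp(2 * 0.5) / (exp(2 * 0.5) + 1)))
  expect_equal(ll[3], log(1 / (1 + exp(2 * 0.25))))
})

test_that("beta = 0 yields log(0.5) on every trial and first trials always do", {
  d <- make_small_dataset(2, 40, 1)
  spec <- model_spec("single")
  ll <- pointwise_loglik(d$data, spec, param_set(spec, alpha = 0.7, beta = 0))
  expect_equal(ll, rep(log(0.5), length(ll)))
  ll2 <- pointwise_loglik(d$data, spec, param_set(spec, alpha = 0.7, beta = 6))
  expect_equal(ll2[1], log(0.5))
})

test_that("compiled likelihood equals the naive enumeration oracle", {
  set.seed(10)
  d <- make_small_dataset(3, 10, 2)
  for (nm in names(all_model_specs())) {
    spec <- all_model_specs()[[nm]]
    pb <- param_bounds(spec)
    vals <- setNames(as.list(runif(nrow(pb), 0.05, 0.9)), pb$param)
    params <- if (spec$environment_specific) {
      param_set(spec, stable = vals,
                volatile = lapply(vals, function(v) min(v * 1.1, 1)))
    } else {
      do.call(param_set, c(list(spec), vals))
    }
    for (id in 1:3) {
      tr <- d$data[d$data$participant_id == id, ]
      tr <- tr[order(tr$block, tr$trial), ]
      ll <- pointwise_loglik(tr, spec, params)
      ora <- oracle_loglik(tr, spec$lr_kind, spec$environment_specific,
                           if (spec$environment_specific) params$sets
                           else params$sets$shared)
      expect_equal(ll, ora, tolerance = 1e-12)
      # product identity: exp(sum) equals product of per-trial probabilities
      expect_equal(exp(sum(ll[1:8])), prod(exp(ora[1:8])), tolerance = 1e-12)
    }
  }
})

test_that("missing choices contribute no likelihood and no update", {
  d <- make_small_dataset(1, 30, 1)
  tr <- d$data[order(d$data$trial), ]
  spec <- model_spec("single")
  ps <- param_set(spec, alpha = 0.4, beta = 3)
  tr2 <- tr
  drop_idx <- which(tr2$environment == "stable")[3]
  tr2$choice[drop_idx] <- NA
  tr2$reward[drop_idx] <- NA
  ll <- pointwise_loglik(tr2, spec, ps)
  expect_true(is.na(ll[drop_idx]))
  # oracle agreement including the skipped-update state evolution
  ora <- oracle_loglik(tr2, "single", FALSE, ps$sets$shared)
  expect_equal(ll, ora, tolerance = 1e-12)
})

test_that("dual with equal rates and variable with eta 0 reproduce the single model bit-for-bit", {
  d <- make_small_dataset(4, 60, 2)
  single <- model_spec("single", environment_specific = TRUE)
  dual <- model_spec("dual", environment_specific = TRUE)
  varm <- model_spec("variable", environment_specific = TRUE)
  pes <- list(stable = list(alpha = 0.31, beta = 2.7),
              volatile = list(alpha = 0.66, beta = 4.1))
  ll_single <- pointwise_loglik(d$data, single,
    param_set(single, stable = pes$stable, volatile = pes$volatile))
  ll_dual <- pointwise_loglik(d$data, dual,
    param_set(dual,
              stable = list(alpha_pos = 0.31, alpha_neg = 0.31, beta = 2.7),
              volatile = list(alpha_pos = 0.66, alpha_neg = 0.66, beta = 4.1)))
  ll_var <- pointwise_loglik(d$data, varm,
    param_set(varm, stable = list(alpha = 0.31, eta = 0, beta = 2.7),
              volatile = list(alpha = 0.66, eta = 0, beta = 4.1)))
  expect_identical(ll_single, ll_dual)
  expect_identical(ll_single, ll_var)
})

test_that("environment isolation: the other casino's data never leaks", {
  d <- make_small_dataset(1, 60, 2)
  tr <- d$data[order(d$data$block, d$data$trial), ]
  spec <- model_spec("dual", environment_specific = TRUE)
  ps <- param_set(spec,
                  stable = list(alpha_pos = 0.3, alpha_neg = 0.4, beta = 3),
                  volatile = list(alpha_pos = 0.6, alpha_neg = 0.7, beta = 5))
  ll <- pointwise_loglik(tr, spec, ps)
  tr2 <- tr
  vol <- tr2$environment == "volatile"
  tr2$choice[vol] <- rbinom(sum(vol), 1, 0.5)
  tr2$reward[vol] <- as.integer(tr2$choice[vol] == tr2$winning_machine[vol])
  ll2 <- pointwise_loglik(tr2, spec, ps)
  expect_identical(ll[tr$environment == "stable"],
                   ll2[tr$environment == "stable"])
})

test_that("simulated choices follow the softmax and the anticorrelated reward rule", {
  set.seed(20)
  d <- make_small_dataset(1, 200, 1)
  task <- d$data
  task$choice <- NA_integer_
  task$reward <- NA_integer_
  spec <- model_spec("single")
  # alpha = 0: Q stays (0,0), choices Bernoulli(0.5)
  sim <- simulate_choices(task, spec, param_set(spec, alpha = 0, beta = 9))
  expect_true(all(sim$reward == (sim$choice == sim$winning_machine)))
  many <- do.call(rbind, lapply(1:60, function(i) {
    t2 <- task
    t2$participant_id <- i
    t2
  }))
  sim2 <- simulate_choices(many, spec, param_set(spec, alpha = 0, beta = 9))
  expect_lt(abs(mean(sim2$choice) - 0.5), 3 * sqrt(0.25 / nrow(sim2)))
})

test_that("simulated reward rate matches an independent brute-force simulator", {
  set.seed(21)
  # single-LR agent, alpha 0.6, beta 4, stable 80/20 block of 120 trials
  n_rep <- 400
  correct <- rep(1L, 120)
  rates_pkg <- rates_ora <- numeric(n_rep)
  spec <- model_spec("single")
  ps <- param_set(spec, alpha = 0.6, beta = 4)
  for (i in seq_len(n_rep)) {
    winning <- ifelse(runif(120) < 0.8, correct, 1L - correct)
    task <- data.frame(participant_id = 1, phase = "learning", block = 1,
                       trial = 1:120, environment = "stable",
                       within_casino_trial = 1:120, correct_machine = correct,
                       winning_machine = winning, choice = NA_integer_,
                       reward = NA_integer_)
    rates_pkg[i] <- mean(simulate_choices(task, spec, ps)$reward)
    rates_ora[i] <- mean(oracle_simulate_single(winning, 0.6, 4))
  }
  se <- sqrt(var(rates_pkg) / n_rep + var(rates_ora) / n_rep)
  expect_lt(abs(mean(rates_pkg) - mean(rates_ora)), 3 * se)
})

test_that("mismatched parameters and unknown environments are rejected", {
  d <- make_small_dataset(1, 20, 1)
  spec <- model_spec("dual", environment_specific = TRUE)
  expect_error(param_set(spec, alpha_pos = 0.5), "named list per environment")
  expect_error(param_set(model_spec("single"), alpha = 1.5, beta = 2),
               "out of bounds")
  ps <- param_set(spec, stable = list(alpha_pos = .5, alpha_neg = .5, beta = 2),
                  other = list(alpha_pos = .5, alpha_neg = .5, beta = 2))
  expect_error(pointwise_loglik(d$data, spec, ps), "volatile")
  ps_single <- param_set(model_spec("single"), alpha = .5, beta = 2)
  expect_error(simulate_choices(d$data, spec, ps_single), "does not match")
})
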