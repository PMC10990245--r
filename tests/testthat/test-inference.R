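test_that("probit transform maps the raw scale onto the bounds", {
  expect_equal(probit_to_bounds(0, 0, 1), 0.5)
  expect_equal(probit_to_bounds(0, 2, 10), 6)
  expect_equal(probit_to_bounds(50, 0, 10), 10)
  expect_equal(probit_to_bounds(qnorm(0.95), 0, 1), 0.95)
  expect_equal(probit_to_bounds(1.6449, 0, 1), 0.95, tolerance = 1e-4)
  expect_error(probit_to_bounds(0, 1, 1), "strictly")
  # strictly increasing
  x <- sort(rnorm(20))
  expect_true(all(diff(probit_to_bounds(x, 0, 10)) > 0))
})

test_that("the joint log-density matches a term-by-term hand composition", {
  d <- make_small_dataset(2, 8, 1, seed = 77)
  for (es in c(TRUE, FALSE)) {
    spec <- model_spec("dual", environment_specific = es)
    m <- build_model(d$data, spec)
    R <- nrow(m$param_table)
    set.seed(78)
    mu <- rnorm(R)
    sigma <- abs(rnorm(R, 0.5, 0.2)) + 0.05
    z <- matrix(rnorm(2 * R), nrow = 2)
    got <- m$log_density(mu, sigma, z)
    trials_by_ppt <- lapply(m$participants, function(id) {
      tr <- m$trials[m$trials$participant_id == id, ]
      tr[order(tr$block, tr$trial), ]
    })
    want <- oracle_joint_density(trials_by_ppt, "dual", es, m$param_table,
                                 mu, sigma, z)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("participants with zero trials in a cell are rejected", {
  d <- make_small_dataset(2, 20, 1, seed = 79)
  dat <- d$data
  dat <- dat[!(dat$participant_id == 2 & dat$environment == "volatile"), ]
  expect_error(build_model(dat, model_spec("dual", environment_specific = TRUE)),
               "zero trials")
  # a shared spec only needs one cell, so the same data build fine
  expect_s3_class(build_model(dat, model_spec("dual")), "rw_hbm")
})

test_that("default sampling schedule retains 12,000 draws and is seed-deterministic", {
  d <- make_small_dataset(2, 8, 1, seed = 80)
  spec <- model_spec("single")
  m <- build_model(d$data, spec)
  fit <- sample_posterior(m, n_chains = 4, n_iter = 4000, n_burn = 1000,
                          seed = 9, store_pointwise = FALSE)
  draws <- sum(vapply(fit$chains, function(c) nrow(c$mu_raw), 0))
  expect_equal(draws, 12000)
  fit2 <- sample_posterior(m, n_chains = 4, n_iter = 4000, n_burn = 1000,
                           seed = 9, store_pointwise = FALSE)
  expect_identical(fit$chains[[1]]$mu_raw, fit2$chains[[1]]$mu_raw)
  expect_identical(fit$chains[[3]]$z, fit2$chains[[3]]$z)
  # chains differ from each other
  expect_false(identical(fit$chains[[1]]$mu_raw, fit$chains[[2]]$mu_raw))
})

test_that("with no observed choices the sampler recovers the prior", {
  # all-missing choices make the likelihood flat, so the marginal posterior
  # of each raw group mean must be its standard normal prior
  d <- make_small_dataset(3, 40, 1, seed = 81)
  dat <- d$data
  dat$choice <- NA_integer_
  dat$reward <- NA_integer_
  spec <- model_spec("single")
  fit <- fit_hbayes(dat, spec, n_chains = 4, n_iter = 3000, n_burn = 500,
                    seed = 10, store_pointwise = FALSE)
  mu <- unlist(lapply(fit$chains, function(c) c$mu_raw[, 1]))
  ess <- coda::effectiveSize(coda::mcmc(matrix(mu)))
  expect_lt(abs(mean(mu) - 0), 3 / sqrt(ess) + 0.05)
  expect_lt(abs(sd(mu) - 1), 0.15)
  z <- unlist(lapply(fit$chains, function(c) c$z[, 1]))
  expect_lt(abs(mean(z)), 0.15)
})

test_that("bounded draws respect their bounds exactly", {
  d <- make_small_dataset(2, 20, 1, seed = 82)
  spec <- model_spec("dual", environment_specific = TRUE)
  fit <- fit_hbayes(d$data, spec, n_chains = 2, n_iter = 300, n_burn = 100,
                    seed = 11, store_pointwise = FALSE)
  for (r in seq_len(nrow(fit$model$param_table))) {
    g <- group_mean_draws(fit, fit$model$param_table$param[r],
                          fit$model$param_table$environment[r])
    expect_true(all(g >= fit$model$param_table$lower[r]))
    expect_true(all(g <= fit$model$param_table$upper[r]))
  }
})

test_that("hierarchical shrinkage pulls a sparse participant toward the group", {
  set.seed(83)
  cfg <- phase_config("learning", 1, 160,
                      data.frame(environment = c("stable", "volatile"),
                                 p_reward = c(0.8, 0.9),
                                 volatility = c("stable", "volatile")))
  spec <- model_spec("single")
  # a cohort with high alpha, plus one participant observed on few trials
  ps <- lapply(1:8, function(i) param_set(spec, alpha = 0.8, beta = 5))
  names(ps) <- 1:8
  data <- simulate_choices(generate_cohort(cfg, 8), spec, ps)
  sparse <- data[data$participant_id == 8, ]
  keep <- sparse$trial <= 16
  data <- rbind(data[data$participant_id != 8, ], sparse[keep, ])
  fit_h <- fit_hbayes(data, spec, n_chains = 2, n_iter = 800, n_burn = 300,
                      seed = 12, store_pointwise = FALSE)
  fit_solo <- fit_hbayes(sparse[keep, ], spec, n_chains = 2, n_iter = 800,
                         n_burn = 300, seed = 13, store_pointwise = FALSE)
  est_h <- individual_means(fit_h)
  est_s <- individual_means(fit_solo)
  a_h <- est_h$estimate[est_h$participant_id == 8 & est_h$param == "alpha"]
  a_s <- est_s$estimate[est_s$param == "alpha"]
  group <- group_mean_summary(fit_h)
  g <- group$mean[group$param == "alpha"]
  expect_lt(abs(a_h - g), abs(a_s - g))
})

test_that("posterior_prob_greater is a strict matched-draw contrast", {
  a <- rnorm(100)
  expect_equal(posterior_prob_greater(a + 1, a), 1.0)
  expect_equal(posterior_prob_greater(a, a + 1), 0.0)
  set.seed(84)
  x <- rnorm(20000); y <- rnorm(20000)
  expect_lt(abs(posterior_prob_greater(x, y) - 0.5), 0.02)
  expect_equal(posterior_prob_greater(x, y) +
                 posterior_prob_greater(y, x), 1)
  expect_error(posterior_prob_greater(1:3, 1:4), "equal length")
})

test_that("blockwise cells replicate the group structure per block", {
  d <- make_small_dataset(3, 40, 2, seed = 85)
  spec <- model_spec("dual", environment_specific = TRUE)
  m <- build_model(d$data, spec, by_block = TRUE)
  expect_equal(nrow(m$cells), 4) # 2 environments x 2 blocks
  expect_equal(nrow(m$param_table), 12)
  # a single-block fit is identical to the plain fit under the same seed
  one <- d$data[d$data$block == 1, ]
  f_plain <- fit_hbayes(one, spec, n_chains = 1, n_iter = 200, n_burn = 50,
                        seed = 14, store_pointwise = FALSE)
  f_block <- fit_hbayes(one, spec, by_block = TRUE, n_chains = 1,
                        n_iter = 200, n_burn = 50, seed = 14,
                        store_pointwise = FALSE)
  expect_identical(f_plain$chains[[1]]$mu_raw, f_block$chains[[1]]$mu_raw)
})

test_that("interaction_contrast detects shifted and null block gaps", {
  d <- make_small_dataset(3, 40, 2, seed = 86)
  spec <- model_spec("dual", environment_specific = TRUE)
  fit <- fit_hbayes(d$data, spec, by_block = TRUE, n_chains = 2,
                    n_iter = 300, n_burn = 100, store_pointwise = FALSE)
  expect_error(interaction_contrast(fit, 1, 5), "not present")
  # craft draws with a known widening gap: contrast must be exactly 1
  pt <- fit$model$param_table
  fake <- fit
  S <- nrow(fit$chains[[1]]$mu_raw)
  for (ch in seq_along(fake$chains)) {
    mu <- fit$chains[[ch]]$mu_raw
    base <- matrix(rnorm(S * nrow(pt), 0, 0.1), S)
    lr <- pt$param %in% c("alpha_pos", "alpha_neg")
    vol <- pt$environment == "volatile"
    b2 <- pt$block == 2
    mu[, lr & vol & b2] <- base[, lr & vol & b2] + 2
    mu[, lr & !vol] <- base[, lr & !vol]
    mu[, lr & vol & !b2] <- base[, lr & vol & !b2]
    fake$chains[[ch]]$mu_raw <- mu
  }
  expect_equal(interaction_contrast(fake, 1, 2), 1.0)
  # identical gaps in both blocks: contrast hovers at 1/2
  for (ch in seq_along(fake$chains)) {
    mu <- fake$chains[[ch]]$mu_raw
    lr <- pt$param %in% c("alpha_pos", "alpha_neg")
    mu[, lr & pt$block == 2] <- mu[, lr & pt$block == 1] +
      matrix(rnorm(S * sum(lr & pt$block == 1), 0, 1e-3), S)
    fake$chains[[ch]]$mu_raw <- mu
  }
  expect_lt(abs(interaction_contrast(fake, 1, 2) - 0.5), 0.1)
})

test_that("fits flag non-convergence instead of hiding it", {
  d <- make_small_dataset(2, 16, 1, seed = 87)
  spec <- model_spec("single")
  fit <- fit_hbayes(d$data, spec, n_chains = 2, n_iter = 60, n_burn = 20,
                    seed = 15, store_pointwise = FALSE)
  expect_true(is.finite(max(fit$rhat, na.rm = TRUE)))
  expect_type(fit$converged, "logical")
  # coda cross-check on a converged longer run of the same model
  fit2 <- fit_hbayes(d$data, spec, n_chains = 2, n_iter = 1500, n_burn = 500,
                     seed = 16, store_pointwise = FALSE)
  gd <- coda::gelman.diag(as_mcmc_list(fit2), autoburnin = FALSE,
                          multivariate = FALSE)
  expect_lt(max(gd$psrf[, 1]), 1.2)
})
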