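# Independent naive reference implementations used as oracles. These follow
# the model definitions directly in plain R, deliberately sharing no code
# with the package's compiled core.

# naive per-trial log-likelihood for any of the six variants; trials must be
# a single participant's table sorted by block and trial
oracle_loglik <- function(trials, lr_kind, env_specific, params) {
  envs <- sort(unique(trials$environment))
  getp <- function(e, nm) {
    if (env_specific) params[[e]][[nm]] else params[[nm]]
  }
  Q <- list()
  acur <- list()
  curblock <- -1
  out <- rep(NA_real_, nrow(trials))
  for (t in seq_len(nrow(trials))) {
    row <- trials[t, ]
    if (row$block != curblock) {
      for (e in envs) {
        Q[[e]] <- c(0, 0)
        acur[[e]] <- NULL
      }
      curblock <- row$block
    }
    if (is.na(row$choice)) next
    e <- row$environment
    beta <- getp(e, "beta")
    p <- exp(beta * Q[[e]]) / sum(exp(beta * Q[[e]]))
    out[t] <- log(p[row$choice + 1])
    a <- switch(lr_kind,
      single = getp(e, "alpha"),
      dual = if (row$reward == 1) getp(e, "alpha_pos") else getp(e, "alpha_neg"),
      variable = {
        if (is.null(acur[[e]])) acur[[e]] <- getp(e, "alpha")
        acur[[e]]
      })
    q <- Q[[e]][row$choice + 1]
    pe <- row$reward - q
    Q[[e]][row$choice + 1] <- q + a * pe
    if (lr_kind == "variable") {
      eta <- getp(e, "eta")
      acur[[e]] <- eta * abs(pe) + (1 - eta) * acur[[e]]
    }
  }
  out
}

# naive forward simulator for the single learning rate model in one casino
# (used as the independent second simulator for reward-rate checks)
oracle_simulate_single <- function(winning, alpha, beta) {
  Q <- c(0, 0)
  rewards <- integer(length(winning))
  for (t in seq_along(winning)) {
    p1 <- exp(beta * Q[2]) / sum(exp(beta * Q))
    ch <- rbinom(1, 1, p1)
    r <- as.integer(ch == winning[t])
    rewards[t] <- r
    Q[ch + 1] <- Q[ch + 1] + alpha * (r - Q[ch + 1])
  }
  rewards
}

# raw (unsmoothed) importance-sampling LOO oracle
oracle_is_loo <- function(log_lik) {
  vapply(seq_len(ncol(log_lik)), function(i) {
    ll <- log_lik[, i]
    lw <- -ll - max(-ll)
    lw <- lw - log(sum(exp(lw)))
    m <- max(lw + ll)
    m + log(sum(exp(lw + ll - m)))
  }, numeric(1))
}

# hand-composed joint log-density of the hierarchical model
oracle_joint_density <- function(trials_by_ppt, lr_kind, env_specific,
                                 param_table, mu_raw, sigma, z) {
  lp <- sum(dnorm(mu_raw, 0, 1, log = TRUE)) +
    sum(log(2) + dcauchy(sigma, 0, 5, log = TRUE)) +
    sum(dnorm(z, 0, 1, log = TRUE))
  N <- length(trials_by_ppt)
  for (i in seq_len(N)) {
    bounded <- param_table$lower + (param_table$upper - param_table$lower) *
      pnorm(mu_raw + sigma * z[i, ])
    if (env_specific) {
      envs <- unique(param_table$environment)
      params <- lapply(envs, function(e) {
        idx <- param_table$environment == e
        as.list(setNames(bounded[idx], param_table$param[idx]))
      })
      names(params) <- envs
    } else {
      params <- as.list(setNames(bounded, param_table$param))
    }
    lp <- lp + sum(oracle_loglik(trials_by_ppt[[i]], lr_kind, env_specific,
                                 params), na.rm = TRUE)
  }
  lp
}

# small labelled learning-phase dataset simulated from the
# environment-specific dual model under the recovery population settings
make_small_dataset <- function(n_participants = 6, trials_per_block = 80,
                               n_blocks = 2, seed = 123) {
  set.seed(seed)
  cfg <- phase_config("learning", n_blocks, trials_per_block,
                      data.frame(environment = c("stable", "volatile"),
                                 p_reward = c(0.8, 0.9),
                                 volatility = c("stable", "volatile")))
  spec <- model_spec("dual", environment_specific = TRUE)
  ps <- draw_cohort_params(spec, recovery_population(spec),
                                       n_participants)
  list(data = simulate_choices(generate_cohort(cfg, n_participants), spec, ps),
       spec = spec, params = ps, config = cfg)
}
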