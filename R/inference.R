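#' Probit map from the unbounded to a bounded scale
#'
#' `lower + (upper - lower) * pnorm(raw)`: strictly increasing, midpoint at
#' `raw = 0`. Group means and individual parameters are sampled on the raw
#' scale and reported on the bounded scale through this map.
#'
#' @param raw unbounded value(s).
#' @param lower,upper bounds with `lower < upper`.
#' @export
probit_to_bounds <- function(raw, lower, upper) {
  if (any(lower >= upper)) stop("lower must be strictly below upper")
  lower + (upper - lower) * pnorm(raw)
}

#' Build the hierarchical Bayesian model over a cohort
#'
#' For every combination of environment (if the spec is
#' environment-specific) and block (if `by_block`), each free parameter gets
#' its own group-level distribution: individual bounded parameters are
#' `probit_to_bounds(mu_raw + sigma * z)` with `z ~ N(0, 1)` (non-centred),
#' a uniform prior on the bounded group mean (equivalently `mu_raw ~ N(0,1)`
#' through the probit change of variables) and a half-Cauchy(0, 5) prior on
#' the group SD. Fit one phase per model: phases are separate runs.
#'
#' @param data observed trial table (one phase, >= 1 participants; missing
#'   choices are tolerated and contribute neither likelihood nor updates).
#' @param spec a [model_spec()].
#' @param by_block replicate the group-level structure per block?
#' @return object of class `rw_hbm` with components `cells`, `param_table`
#'   and `log_density(mu_raw, sigma, z)` (joint log-density with `sigma` on
#'   the natural scale).
#' @export
build_model <- function(data, spec, by_block = FALSE) {
  if (length(unique(data$phase)) > 1) {
    stop("fit one phase at a time; phases are separate model runs")
  }
  arr <- trial_arrays(data, env_specific = spec$environment_specific)
  trials <- arr$trials
  blocks <- sort(unique(trials$block))
  env_cells <- if (spec$environment_specific) arr$env_labels else "shared"
  block_cells <- if (by_block) blocks else NA
  cells <- expand.grid(environment = env_cells, block = block_cells,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  K <- nrow(cells)
  n <- nrow(trials)
  e_vec <- if (spec$environment_specific) arr$env_labels[arr$env + 1L] else
    rep("shared", n)
  b_vec <- if (by_block) arr$block else rep(NA, n)
  cell <- match(paste(e_vec, b_vec),
                paste(cells$environment, cells$block)) - 1L
  ids <- sort(unique(trials$participant_id))
  counts <- table(factor(trials$participant_id, levels = ids), cell)
  if (ncol(counts) < K || any(counts == 0)) {
    bad <- ids[rowSums(counts == 0) > 0]
    if (ncol(counts) < K) bad <- ids
    stop("participant(s) with zero trials in a phase x environment cell: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  pb <- param_bounds(spec)
  P <- nrow(pb)
  param_table <- data.frame(
    row = seq_len(K * P),
    param = rep(pb$param, each = K),
    environment = rep(cells$environment, P),
    block = rep(cells$block, P),
    lower = rep(pb$lower, each = K),
    upper = rep(pb$upper, each = K))
  offs <- c(0L, cumsum(as.integer(table(factor(trials$participant_id,
                                               levels = ids)))))
  m <- list(spec = spec, by_block = by_block, cells = cells,
            param_table = param_table, participants = ids,
            env_labels = arr$env_labels, K = K, P = P,
            arrays = list(env = arr$env, block = arr$block, cell = cell,
                          choice = arr$choice, reward = arr$reward,
                          winning = arr$winning, offs = offs),
            trials = trials)
  m$log_density <- function(mu_raw, sigma, z) {
    z <- matrix(z, nrow = length(ids), ncol = K * P)
    cpp_joint_logdensity(m$arrays$env, m$arrays$block, m$arrays$cell,
                         m$arrays$choice, m$arrays$reward, m$arrays$offs,
                         param_table$lower, param_table$upper, K, P,
                         lr_kind_code(spec), mu_raw, sigma, z)
  }
  class(m) <- "rw_hbm"
  m
}

#' Draw from the hierarchical posterior
#'
#' Adaptive Metropolis-within-Gibbs: scalar random-walk updates of the raw
#' group means, log group SDs and individual deviates, with proposal scales
#' adapted toward 0.44 acceptance during burn-in. Defaults follow the
#' 4-chain, 4000-iteration, 1000-burn-in schedule (12,000 retained draws).
#' Convergence is assessed with the Gelman-Rubin statistic on every scalar;
#' the fit is flagged (not discarded) if any exceeds 1.1.
#'
#' @param model an `rw_hbm` from [build_model()].
#' @param n_chains,n_iter,n_burn sampling schedule per chain (retained draws
#'   per chain = `n_iter - n_burn`).
#' @param seed master seed; each chain uses a derived child seed.
#' @param store_pointwise keep the draws x observations pointwise
#'   log-likelihood matrix (needed for LOOIC comparison)?
#' @return object of class `rw_fit`.
#' @export
sample_posterior <- function(model, n_chains = 4, n_iter = 4000,
                             n_burn = 1000, seed = 1,
                             store_pointwise = TRUE) {
  stopifnot(inherits(model, "rw_hbm"), n_iter > n_burn)
  a <- model$arrays
  pt <- model$param_table
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(child_seed(seed, 7L, ch))
    chains[[ch]] <- cpp_hier_sample(a$env, a$block, a$cell, a$choice,
                                    a$reward, a$offs, pt$lower, pt$upper,
                                    model$K, model$P,
                                    lr_kind_code(model$spec),
                                    as.integer(n_iter), as.integer(n_burn))
  }
  rhat_of <- function(extract) {
    mats <- lapply(chains, extract)
    vapply(seq_len(ncol(mats[[1]])),
           function(j) split_rhat(lapply(mats, function(m) m[, j])),
           numeric(1))
  }
  rhat <- c(rhat_of(function(c) c$mu_raw), rhat_of(function(c) c$log_sigma),
            rhat_of(function(c) c$z))
  fit <- list(model = model, chains = chains,
              n_chains = n_chains, n_iter = n_iter, n_burn = n_burn,
              seed = seed, rhat = rhat,
              converged = all(rhat < 1.1, na.rm = TRUE),
              accept_group = mean(vapply(chains, `[[`, 0, "accept_group")),
              accept_individual = mean(vapply(chains, `[[`, 0,
                                              "accept_individual")))
  class(fit) <- "rw_fit"
  if (store_pointwise) {
    fit$pointwise <- do.call(rbind, lapply(chains, function(c) {
      cpp_pointwise_matrix(a$env, a$block, a$cell, a$choice, a$reward,
                           a$offs, pt$lower, pt$upper, model$K, model$P,
                           lr_kind_code(model$spec), c$mu_raw, c$log_sigma,
                           c$z)
    }))
  }
  fit
}

#' Convenience wrapper: build and fit in one call
#'
#' @inheritParams build_model
#' @inheritParams sample_posterior
#' @export
fit_hbayes <- function(data, spec, by_block = FALSE, n_chains = 4,
                       n_iter = 4000, n_burn = 1000, seed = 1,
                       store_pointwise = TRUE) {
  sample_posterior(build_model(data, spec, by_block = by_block),
                   n_chains = n_chains, n_iter = n_iter, n_burn = n_burn,
                   seed = seed, store_pointwise = store_pointwise)
}

#' @export
print.rw_fit <- function(x, ...) {
  cat(sprintf(paste0("Hierarchical fit: %s %s model, %d participants, ",
                     "%d chains x %d retained draws\n"),
              if (x$model$spec$environment_specific) "environment-specific"
              else "shared",
              x$model$spec$lr_kind, length(x$model$participants),
              x$n_chains, x$n_iter - x$n_burn))
  cat(sprintf("max Gelman-Rubin statistic: %.3f (%s)\n",
              max(x$rhat, na.rm = TRUE),
              if (x$converged) "converged" else "NOT converged"))
  gm <- group_mean_summary(x)
  print(gm, row.names = FALSE)
  invisible(x)
}

#' Persist group-level posterior draws as long-format CSV
#'
#' One row per chain x draw x parameter cell, with the group mean on the
#' bounded scale and the group SD on the raw scale.
#'
#' @param fit an `rw_fit`.
#' @param path output CSV path.
#' @export
write_posterior_draws <- function(fit, path) {
  pt <- fit$model$param_table
  rows <- list()
  for (ch in seq_along(fit$chains)) {
    c_ <- fit$chains[[ch]]
    S <- nrow(c_$mu_raw)
    for (r in seq_len(nrow(pt))) {
      rows[[length(rows) + 1]] <- data.frame(
        chain = ch, draw = seq_len(S),
        parameter = paste0("mu.", pt$param[r], "[", pt$environment[r],
                           ifelse(is.na(pt$block[r]), "",
                                  paste0(",b", pt$block[r])), "]"),
        value = probit_to_bounds(c_$mu_raw[, r], pt$lower[r], pt$upper[r]))
      rows[[length(rows) + 1]] <- data.frame(
        chain = ch, draw = seq_len(S),
        parameter = paste0("sd.", pt$param[r], "[", pt$environment[r],
                           ifelse(is.na(pt$block[r]), "",
                                  paste0(",b", pt$block[r])), "]"),
        value = exp(c_$log_sigma[, r]))
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Sampler diagnostics summary
#'
#' @param fit an `rw_fit`.
#' @return list: retained draw count, max Gelman-Rubin statistic,
#'   convergence flag, mean acceptance rates.
#' @export
fit_diagnostics <- function(fit) {
  list(n_chains = fit$n_chains,
       n_retained = fit$n_chains * (fit$n_iter - fit$n_burn),
       max_rhat = max(fit$rhat, na.rm = TRUE),
       converged = fit$converged,
       accept_group = fit$accept_group,
       accept_individual = fit$accept_individual)
}

#' Convert a fit's group-level draws to a coda `mcmc.list`
#'
#' Exposes the raw-scale group means and log group SDs to coda's diagnostic
#' toolbox (`gelman.diag`, `effectiveSize`, trace plots).
#'
#' @param fit an `rw_fit`.
#' @return a [coda::mcmc.list].
#' @export
as_mcmc_list <- function(fit) {
  pt <- fit$model$param_table
  label <- paste0(pt$param, "[", pt$environment,
                  ifelse(is.na(pt$block), "", paste0(",b", pt$block)), "]")
  coda::mcmc.list(lapply(fit$chains, function(c) {
    m <- cbind(c$mu_raw, c$log_sigma)
    colnames(m) <- c(paste0("mu.", label), paste0("logsd.", label))
    coda::mcmc(m)
  }))
}

# split-chain Gelman-Rubin statistic over a list of per-chain draw vectors
split_rhat <- function(chain_draws) {
  halves <- unlist(lapply(chain_draws, function(v) {
    h <- floor(length(v) / 2)
    list(v[seq_len(h)], v[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior draws of a group-level mean on the bounded scale
#'
#' @param fit an `rw_fit`.
#' @param param parameter name (e.g. `"alpha_pos"`).
#' @param environment,block cell selectors (omit for shared / non-blockwise
#'   fits).
#' @return numeric vector, draws pooled over chains.
#' @export
group_mean_draws <- function(fit, param, environment = NULL, block = NULL) {
  pt <- fit$model$param_table
  sel <- pt$param == param
  if (!is.null(environment)) sel <- sel & pt$environment == environment
  if (!is.null(block)) sel <- sel & !is.na(pt$block) & pt$block == block
  if (sum(sel) != 1) {
    stop("selector matches ", sum(sel), " parameter cells (need exactly 1)")
  }
  r <- which(sel)
  raw <- unlist(lapply(fit$chains, function(c) c$mu_raw[, r]))
  probit_to_bounds(raw, pt$lower[r], pt$upper[r])
}

#' Posterior summary of all group-level means (bounded scale)
#'
#' @param fit an `rw_fit`.
#' @return data frame with one row per parameter cell.
#' @export
group_mean_summary <- function(fit) {
  pt <- fit$model$param_table
  out <- pt[c("param", "environment", "block")]
  out$mean <- out$sd <- NA_real_
  for (r in seq_len(nrow(pt))) {
    d <- probit_to_bounds(unlist(lapply(fit$chains,
                                        function(c) c$mu_raw[, r])),
                          pt$lower[r], pt$upper[r])
    out$mean[r] <- mean(d)
    out$sd[r] <- sd(d)
  }
  out
}

#' Individual-level posterior means on the bounded scale
#'
#' @param fit an `rw_fit`.
#' @return data frame: `participant_id`, `param`, `environment`, `block`,
#'   `estimate` (posterior mean of the bounded individual parameter).
#' @export
individual_means <- function(fit) {
  pt <- fit$model$param_table
  ids <- fit$model$participants
  N <- length(ids)
  rows <- list()
  for (r in seq_len(nrow(pt))) {
    est <- numeric(N)
    for (i in seq_len(N)) {
      d <- unlist(lapply(fit$chains, function(c) {
        probit_to_bounds(c$mu_raw[, r] + exp(c$log_sigma[, r]) *
                           c$z[, i + N * (r - 1)],
                         pt$lower[r], pt$upper[r])
      }))
      est[i] <- mean(d)
    }
    rows[[r]] <- data.frame(participant_id = ids, param = pt$param[r],
                            environment = pt$environment[r],
                            block = pt$block[r], estimate = est)
  }
  do.call(rbind, rows)
}

#' Posterior probability that one group mean exceeds another
#'
#' Fraction of matched posterior draws in which `draws_a > draws_b`
#' (strict). A value above 0.95 corresponds to a one-tailed p-value below
#' 0.05.
#'
#' @param draws_a,draws_b equal-length draw vectors matched by draw index.
#' @export
posterior_prob_greater <- function(draws_a, draws_b) {
  if (length(draws_a) != length(draws_b)) {
    stop("draw vectors must have equal length")
  }
  mean(draws_a > draws_b)
}

#' Environment-by-block interaction contrast on learning rate
#'
#' For a blockwise fit of the environment-specific dual learning rate model,
#' computes per draw the volatile-minus-stable difference in the learning
#' rate averaged over `alpha_pos` and `alpha_neg`, in the last block minus
#' the first block, and returns the fraction of draws in which that
#' interaction is positive (the gap widened).
#'
#' @param fit blockwise `rw_fit` of the environment-specific dual model.
#' @param first_block,last_block block labels to contrast.
#' @param stable,volatile environment labels.
#' @export
interaction_contrast <- function(fit, first_block, last_block,
                                 stable = "stable", volatile = "volatile") {
  spec <- fit$model$spec
  if (spec$lr_kind != "dual" || !spec$environment_specific ||
      !fit$model$by_block) {
    stop("interaction_contrast needs a blockwise environment-specific dual fit")
  }
  if (!all(c(first_block, last_block) %in% fit$model$cells$block)) {
    stop("requested block not present in the fit")
  }
  gap <- function(b) {
    (group_mean_draws(fit, "alpha_pos", volatile, b) +
       group_mean_draws(fit, "alpha_neg", volatile, b)) / 2 -
      (group_mean_draws(fit, "alpha_pos", stable, b) +
         group_mean_draws(fit, "alpha_neg", stable, b)) / 2
  }
  mean(gap(last_block) - gap(first_block) > 0)
}
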