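#' Reward-rate parameter grid for one environment
#'
#' Simulates the learning-phase bandit of a single casino (fresh machine
#' pair per block, reversal schedule per its volatility) for every cell of a
#' parameter grid and records the mean fraction of rewarded trials. For the
#' single learning rate model the grid is `alphas` x `betas`; for the dual
#' model it is `alpha_pos` x `alpha_neg` with `beta` fixed (default 4,
#' a typical group-average inverse temperature). One pool of
#' schedule realizations is shared across cells (common random numbers), so
#' between-cell comparisons are less noisy than independent simulation.
#'
#' @param lr_kind `"single"` or `"dual"`.
#' @param p_reward probability that the correct machine wins.
#' @param volatility `"stable"`, `"volatile"` or `"intermediate"`.
#' @param switch_interval reversal gap range for volatile schedules.
#' @param alphas,betas grid axes for the single model.
#' @param alpha_pos,alpha_neg,beta grid axes / fixed value for the dual model.
#' @param n_blocks,trials_per_casino design size (defaults: 2 blocks of 120
#'   within-casino trials, the learning-phase shape).
#' @param n_replicates schedule realizations averaged per cell.
#' @return object of class `reward_rate_grid`: a data frame of cells with a
#'   `reward_rate` column and a separately stored `smoothed` copy (moving
#'   average over neighbouring cells, for display only).
#' @export
reward_rate_grid <- function(lr_kind = c("single", "dual"),
                             p_reward, volatility = c("stable", "volatile",
                                                      "intermediate"),
                             switch_interval = c(16L, 24L),
                             alphas = seq(0.01, 0.99, by = 0.01),
                             betas = seq(0.1, 9.9, by = 0.1),
                             alpha_pos = seq(0.01, 0.99, by = 0.01),
                             alpha_neg = seq(0.01, 0.99, by = 0.01),
                             beta = 4,
                             n_blocks = 2, trials_per_casino = 120,
                             n_replicates = 100) {
  lr_kind <- match.arg(lr_kind)
  volatility <- match.arg(volatility)
  stopifnot(n_replicates >= 1)
  sched <- replicate(n_replicates, single_casino_schedule(
    p_reward, volatility, switch_interval, n_blocks, trials_per_casino),
    simplify = FALSE)
  offs <- c(0L, cumsum(vapply(sched, function(s) length(s$winning), 0L)))
  block <- unlist(lapply(sched, `[[`, "block"))
  winning <- unlist(lapply(sched, `[[`, "winning"))
  if (lr_kind == "single") {
    cells <- expand.grid(alpha = alphas, beta = betas,
                         KEEP.OUT.ATTRS = FALSE)
    grid <- as.matrix(cells)
  } else {
    cells <- expand.grid(alpha_pos = alpha_pos, alpha_neg = alpha_neg,
                         KEEP.OUT.ATTRS = FALSE)
    cells$beta <- beta
    grid <- as.matrix(cells)
  }
  cells$reward_rate <- cpp_reward_rate_grid(block, winning,
                                            as.integer(offs), grid,
                                            if (lr_kind == "single") 0L else 1L)
  ax <- names(cells)[1:2]
  structure(list(cells = cells, axes = ax, lr_kind = lr_kind,
                 volatility = volatility, p_reward = p_reward,
                 smoothed = smooth_grid(cells, ax),
                 n_replicates = n_replicates),
            class = "reward_rate_grid")
}

# winning-machine schedule of one casino in isolation
single_casino_schedule <- function(p_reward, volatility, switch_interval,
                                   n_blocks, trials_per_casino) {
  block <- winning <- integer(0)
  for (b in seq_len(n_blocks)) {
    pts <- switch(volatility,
      stable = integer(0),
      volatile = generate_switch_points(trials_per_casino, switch_interval),
      intermediate = generate_switch_points(trials_per_casino,
                                            switch_interval, n_switches = 2L))
    init <- sample(0:1, 1)
    w <- seq_len(trials_per_casino)
    corr <- (init + vapply(w, function(t) sum(pts < t), 0L)) %% 2
    win_is_corr <- runif(trials_per_casino) < p_reward
    winning <- c(winning, ifelse(win_is_corr, corr, 1 - corr))
    block <- c(block, rep(b, trials_per_casino))
  }
  list(block = block, winning = winning)
}

# 3 x 3 moving-average smoothing on the grid (reporting only)
smooth_grid <- function(cells, ax) {
  a1 <- sort(unique(cells[[ax[1]]]))
  a2 <- sort(unique(cells[[ax[2]]]))
  m <- matrix(cells$reward_rate[order(cells[[ax[2]]], cells[[ax[1]]])],
              nrow = length(a1))
  sm <- m
  for (i in seq_along(a1)) {
    for (j in seq_along(a2)) {
      ii <- max(1, i - 1):min(length(a1), i + 1)
      jj <- max(1, j - 1):min(length(a2), j + 1)
      sm[i, j] <- mean(m[ii, jj])
    }
  }
  out <- expand.grid(a1, a2, KEEP.OUT.ATTRS = FALSE)
  names(out) <- ax
  out$reward_rate <- as.vector(sm)
  out
}

#' Where on the grid is reward maximised, per environment?
#'
#' Reports the raw-grid argmax cell of each environment and, when two
#' environments share axes, the qualitative ordering of their optimal
#' learning rates (an optimal learner uses a higher learning rate in the
#' volatile environment).
#'
#' @param grids named list of [reward_rate_grid()]s on common axes.
#' @return list with `optima` (data frame, one row per environment) and
#'   `ordering` (named differences of argmax learning rates between the
#'   environments, `NULL` for a single grid).
#' @export
optimal_region_summary <- function(grids) {
  stopifnot(length(grids) >= 1, !is.null(names(grids)))
  ax <- grids[[1]]$axes
  for (g in grids) {
    if (!identical(g$axes, ax)) stop("grids must share axes")
  }
  optima <- do.call(rbind, lapply(names(grids), function(e) {
    cells <- grids[[e]]$cells
    best <- cells[which.max(cells$reward_rate), ]
    cbind(data.frame(environment = e), best)
  }))
  ordering <- NULL
  if (nrow(optima) == 2) {
    lr_ax <- setdiff(ax, "beta")
    ordering <- vapply(lr_ax, function(a) optima[[a]][2] - optima[[a]][1],
                       numeric(1))
  }
  list(optima = optima, ordering = ordering)
}

# ---- recovery-study population settings -----------------------------------

#' Group-level generative settings used in the recovery simulations
#'
#' Environment-specific models: learning-rate group means 0.4 (stable) and
#' 0.6 (volatile), inverse temperatures 3.5 and 4.5, higher-order learning
#' rates 0. Shared models: learning rates 0.5, inverse temperature 4,
#' higher-order rate 0. Group SDs: 0.2 for learning rates, 2 for inverse
#' temperatures, 0.1 for higher-order rates. Individual parameters are drawn
#' from these normals truncated to the parameter bounds.
#'
#' @param spec a [model_spec()].
#' @return data frame with columns `param`, `environment`, `mean`, `sd`,
#'   `lower`, `upper`.
#' @export
recovery_population <- function(spec) {
  pb <- param_bounds(spec)
  envs <- if (spec$environment_specific) c("stable", "volatile") else "shared"
  out <- expand.grid(param = pb$param, environment = envs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- merge(out, pb, by = "param", sort = FALSE)
  pick <- function(param, env) {
    if (param == "beta") {
      if (env == "shared") c(4, 2)
      else if (env == "stable") c(3.5, 2) else c(4.5, 2)
    } else if (param == "eta") {
      c(0, 0.1)
    } else {
      if (env == "shared") c(0.5, 0.2)
      else if (env == "stable") c(0.4, 0.2) else c(0.6, 0.2)
    }
  }
  ms <- t(mapply(pick, out$param, out$environment))
  out$mean <- ms[, 1]
  out$sd <- ms[, 2]
  out[c("param", "environment", "mean", "sd", "lower", "upper")]
}

#' Draw a cohort of individual parameter sets from a population table
#'
#' Samples each participant's parameters from per-parameter normal
#' distributions on the bounded scale, truncated to the bounds.
#'
#' @param spec a [model_spec()].
#' @param population table as returned by [recovery_population()] (columns
#'   `param`, `environment`, `mean`, `sd`, `lower`, `upper`).
#' @param n_participants cohort size.
#' @return list of [param_set()] objects keyed by participant id `1:n`.
#' @export
draw_cohort_params <- function(spec, population, n_participants) {
  sets <- vector("list", n_participants)
  by_env <- split(population, population$environment)
  for (i in seq_len(n_participants)) {
    args <- lapply(by_env, function(pe) {
      v <- as.list(rtruncnorm(nrow(pe), pe$mean, pe$sd, pe$lower, pe$upper))
      names(v) <- pe$param
      v
    })
    sets[[i]] <- if (spec$environment_specific) {
      do.call(param_set, c(list(spec), args))
    } else {
      do.call(param_set, c(list(spec), args$shared))
    }
  }
  names(sets) <- as.character(seq_len(n_participants))
  sets
}

#' Model recovery study
#'
#' Simulates datasets from each of the six model variants under the
#' reference generative settings ([recovery_population()]) on the
#' learning-phase design, fits all six models to every dataset, selects the
#' best by LOOIC ranking, and tabulates how often each generating model
#' (row) is best fitted by each candidate (column).
#'
#' @param n_datasets_per_model datasets simulated per generating model.
#' @param n_participants cohort size per dataset.
#' @param config learning-phase [phase_config()] (default: the Experiment 1
#'   design, 2 blocks of 240 trials with a 75/25 stable casino).
#' @param n_chains,n_iter,n_burn sampling schedule for every fit.
#' @param loo_thin keep every `loo_thin`-th retained draw for the pointwise
#'   LOOIC computation (1 = all draws).
#' @param seed master seed (one child seed per dataset and per fit).
#' @return list of class `recovery_report`: `matrix` (row-normalised
#'   best-fit frequencies), `counts`, `n_unconverged`, and metadata.
#' @export
model_recovery_study <- function(n_datasets_per_model = 10,
                                 n_participants = 36,
                                 config = experiment_profile("exp1")$phases$learning,
                                 n_chains = 4, n_iter = 4000, n_burn = 1000,
                                 loo_thin = 1, seed = 1) {
  specs <- all_model_specs()
  nm <- names(specs)
  counts <- matrix(0L, length(specs), length(specs), dimnames = list(nm, nm))
  n_unconverged <- 0L
  for (g in seq_along(specs)) {
    for (ds in seq_len(n_datasets_per_model)) {
      set.seed(child_seed(seed, 11L, g, ds))
      pop <- recovery_population(specs[[g]])
      ps <- draw_cohort_params(specs[[g]], pop, n_participants)
      task <- generate_cohort(config, n_participants)
      data <- simulate_choices(task, specs[[g]], ps)
      loos <- vector("list", length(specs))
      names(loos) <- nm
      for (f in seq_along(specs)) {
        fit <- fit_hbayes(data, specs[[f]], n_chains = n_chains,
                          n_iter = n_iter, n_burn = n_burn,
                          seed = child_seed(seed, 13L, g, ds, f))
        if (!fit$converged) n_unconverged <- n_unconverged + 1L
        pw <- fit$pointwise[seq(1, nrow(fit$pointwise), by = loo_thin), ,
                            drop = FALSE]
        loos[[f]] <- compute_elpd_loo(pw)
      }
      best <- compare_models(loos)$model[1]
      counts[g, best] <- counts[g, best] + 1L
    }
  }
  structure(list(matrix = counts / rowSums(counts), counts = counts,
                 n_unconverged = n_unconverged,
                 n_datasets_per_model = n_datasets_per_model,
                 n_participants = n_participants, seed = seed),
            class = "recovery_report")
}

#' Parameter recovery study for the dual learning rate model
#'
#' For each environment and each combination of group-mean positive /
#' negative learning rates and inverse temperatures, draws a cohort of true
#' individual parameters (SDs 0.2, 0.2 and 2, truncated to the bounds),
#' simulates the single-casino learning-phase design, fits the dual learning
#' rate model, and correlates all true individual parameters with their
#' individual-level posterior means, per parameter and environment.
#'
#' @param combos data frame with columns `alpha_pos`, `alpha_neg`, `beta`
#'   (default: the full 4 x 4 x 4 grid over \{0.2, 0.4, 0.6, 0.8\} and
#'   \{2, 4, 6, 8\}).
#' @param environments named list of environment settings
#'   (`p_reward`, `volatility`, `switch_interval`).
#' @param n_participants cohort size per dataset.
#' @param n_blocks,trials_per_casino design size per environment.
#' @param n_chains,n_iter,n_burn sampling schedule.
#' @param seed master seed.
#' @return list of class `recovery_report`: `correlations` (per environment
#'   x parameter), `truth` / `estimates` data frame, metadata.
#' @export
parameter_recovery_study <- function(
    combos = expand.grid(alpha_pos = c(0.2, 0.4, 0.6, 0.8),
                         alpha_neg = c(0.2, 0.4, 0.6, 0.8),
                         beta = c(2, 4, 6, 8), KEEP.OUT.ATTRS = FALSE),
    environments = list(
      stable = list(p_reward = 0.75, volatility = "stable"),
      volatile = list(p_reward = 0.9, volatility = "volatile")),
    n_participants = 36, n_blocks = 2, trials_per_casino = 120,
    n_chains = 4, n_iter = 4000, n_burn = 1000, seed = 1) {
  spec <- model_spec("dual", environment_specific = FALSE)
  sds <- c(alpha_pos = 0.2, alpha_neg = 0.2, beta = 2)
  all_rows <- list()
  for (e in names(environments)) {
    env <- environments[[e]]
    for (ci in seq_len(nrow(combos))) {
      set.seed(child_seed(seed, 17L, match(e, names(environments)), ci))
      pop <- data.frame(param = c("alpha_pos", "alpha_neg", "beta"),
                        environment = "shared",
                        mean = as.numeric(combos[ci, c("alpha_pos",
                                                       "alpha_neg", "beta")]),
                        sd = sds,
                        lower = 0, upper = c(1, 1, 10))
      ps <- draw_cohort_params(spec, pop, n_participants)
      task <- single_env_cohort(env, n_participants, n_blocks,
                                trials_per_casino, label = e)
      data <- simulate_choices(task, spec, ps)
      fit <- fit_hbayes(data, spec, n_chains = n_chains, n_iter = n_iter,
                        n_burn = n_burn,
                        seed = child_seed(seed, 19L, match(e, names(environments)), ci),
                        store_pointwise = FALSE)
      est <- individual_means(fit)
      truth <- do.call(rbind, lapply(seq_len(n_participants), function(i) {
        data.frame(participant_id = i,
                   param = c("alpha_pos", "alpha_neg", "beta"),
                   true = unlist(ps[[i]]$sets$shared))
      }))
      mg <- merge(est, truth, by = c("participant_id", "param"))
      mg$environment <- e
      mg$combo <- ci
      all_rows[[paste(e, ci)]] <- mg
    }
  }
  allm <- do.call(rbind, all_rows)
  cors <- do.call(rbind, lapply(split(allm, allm[c("environment", "param")]),
    function(d) data.frame(environment = d$environment[1],
                           param = d$param[1],
                           correlation = cor(d$true, d$estimate),
                           n = nrow(d))))
  rownames(cors) <- NULL
  structure(list(correlations = cors, detail = allm,
                 n_participants = n_participants, combos = combos,
                 seed = seed),
            class = "recovery_report")
}

# cohort trial table in which every trial belongs to one casino
single_env_cohort <- function(env, n_participants, n_blocks,
                              trials_per_casino, label = "casino") {
  do.call(rbind, lapply(seq_len(n_participants), function(i) {
    s <- single_casino_schedule(env$p_reward, env$volatility,
                                env$switch_interval %||% c(16L, 24L),
                                n_blocks, trials_per_casino)
    data.frame(participant_id = i, phase = "learning", block = s$block,
               trial = seq_along(s$block), environment = label,
               within_casino_trial = unlist(lapply(table(s$block), seq_len)),
               correct_machine = NA_integer_, winning_machine = s$winning,
               choice = NA_integer_, reward = NA_integer_,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.recovery_report <- function(x, ...) {
  if (!is.null(x$matrix)) {
    cat("Model recovery (rows: generating model, cols: best-fitting):\n")
    print(round(x$matrix, 3))
    if (x$n_unconverged > 0) {
      cat(x$n_unconverged, "fit(s) flagged as not converged\n")
    }
  }
  if (!is.null(x$correlations)) {
    cat("Parameter recovery correlations (true vs estimated):\n")
    print(x$correlations, row.names = FALSE)
  }
  invisible(x)
}

#' Posterior predictive check
#'
#' For every retained posterior draw, simulates each participant's full
#' choice sequence conditional on the trial sequence (realized
#' winning-machine schedule) they were presented with, averages the
#' simulated reward rate over draws, and correlates the draw-averaged
#' simulated reward rates with the observed ones across participants, per
#' environment.
#'
#' @param fit an `rw_fit`.
#' @param data the observed trial table the model was fitted to (defaults to
#'   the data stored in the fit).
#' @return list: `by_participant` (observed and simulated reward rate per
#'   participant x environment), `correlations` (per environment),
#'   `draw_rates` (draws x participants matrix of simulated overall reward
#'   rates) and `coverage_95` (fraction of participants whose observed
#'   overall reward rate lies inside the central 95% of their simulated
#'   distribution).
#' @export
posterior_predictive_check <- function(fit, data = NULL) {
  model <- fit$model
  trials <- model$trials
  if (!is.null(data)) {
    arr <- trial_arrays(data, model$spec$environment_specific,
                        env_labels = model$env_labels)
    if (!identical(sort(unique(arr$trials$participant_id)),
                   model$participants)) {
      stop("data does not match the participants of the fit")
    }
    trials <- arr$trials
  }
  a <- model$arrays
  pt <- model$param_table
  mu <- do.call(rbind, lapply(fit$chains, `[[`, "mu_raw"))
  ls <- do.call(rbind, lapply(fit$chains, `[[`, "log_sigma"))
  z <- do.call(rbind, lapply(fit$chains, `[[`, "z"))
  sim <- cpp_ppc(a$env, a$block, a$cell, a$winning, a$offs, pt$lower,
                 pt$upper, model$K, model$P, lr_kind_code(model$spec),
                 mu, ls, z)
  ids <- model$participants
  obs <- do.call(rbind, lapply(seq_along(ids), function(i) {
    tr <- trials[trials$participant_id == ids[i], ]
    do.call(rbind, lapply(seq_along(model$env_labels), function(e) {
      sub <- tr[tr$environment == model$env_labels[e] & !is.na(tr$choice), ]
      data.frame(participant_id = ids[i],
                 environment = model$env_labels[e],
                 observed = mean(sub$reward),
                 simulated = sim$rate[i, e])
    }))
  }))
  cors <- vapply(model$env_labels, function(e) {
    d <- obs[obs$environment == e, ]
    cor(d$observed, d$simulated)
  }, numeric(1))
  obs_overall <- vapply(seq_along(ids), function(i) {
    tr <- trials[trials$participant_id == ids[i] & !is.na(trials$choice), ]
    mean(tr$reward)
  }, numeric(1))
  lo <- apply(sim$draw_rate, 2, stats::quantile, 0.025)
  hi <- apply(sim$draw_rate, 2, stats::quantile, 0.975)
  list(by_participant = obs, correlations = cors,
       draw_rates = sim$draw_rate,
       coverage_95 = mean(obs_overall >= lo & obs_overall <= hi))
}
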