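#' Specify one of the six Rescorla-Wagner model variants
#'
#' The model family crosses the kind of learning rate (`single`: one rate
#' `alpha`; `dual`: separate rates `alpha_pos` / `alpha_neg` after rewarded
#' and unrewarded trials; `variable`: a rate that itself tracks recent
#' absolute prediction errors at a higher-order rate `eta`) with whether each
#' free parameter has one copy per environment (`environment_specific`) or a
#' single copy shared across environments. All variants choose via a softmax
#' with inverse temperature `beta` in \[0, 10\]; learning rates and `eta`
#' live in \[0, 1\]; Q-values start at 0 and reset at block boundaries.
#'
#' @param lr_kind `"single"`, `"dual"` or `"variable"`.
#' @param environment_specific logical; one parameter copy per casino?
#' @return object of class `rw_model_spec`.
#' @export
model_spec <- function(lr_kind = c("single", "dual", "variable"),
                       environment_specific = FALSE) {
  lr_kind <- match.arg(lr_kind)
  structure(list(lr_kind = lr_kind,
                 environment_specific = isTRUE(environment_specific)),
            class = "rw_model_spec")
}

#' @export
print.rw_model_spec <- function(x, ...) {
  cat(sprintf("%s %s learning rate model (parameters: %s)\n",
              if (x$environment_specific) "Environment-specific"
              else "Non-environment-specific",
              x$lr_kind, paste(param_names(x), collapse = ", ")))
  invisible(x)
}

#' All six model variants
#'
#' @return named list of [model_spec()] objects, environment-specific
#'   variants first.
#' @export
all_model_specs <- function() {
  kinds <- c("dual", "single", "variable")
  out <- list()
  for (es in c(TRUE, FALSE)) {
    for (k in kinds) {
      nm <- paste0(if (es) "env_" else "shared_", k)
      out[[nm]] <- model_spec(k, environment_specific = es)
    }
  }
  out
}

#' Free parameters and bounds of a model variant
#'
#' @param spec a [model_spec()].
#' @return data frame with columns `param`, `lower`, `upper` in the order
#'   used throughout the package.
#' @export
param_names <- function(spec) {
  switch(spec$lr_kind,
         single = c("alpha", "beta"),
         dual = c("alpha_pos", "alpha_neg", "beta"),
         variable = c("alpha", "eta", "beta"))
}

#' @rdname param_names
#' @export
param_bounds <- function(spec) {
  p <- param_names(spec)
  data.frame(param = p,
             lower = 0,
             upper = ifelse(p == "beta", 10, 1))
}

lr_kind_code <- function(spec) {
  match(spec$lr_kind, c("single", "dual", "variable")) - 1L
}

#' Delta-rule value update
#'
#' `q + alpha * (reward - q)`: the prediction error `reward - q` is weighted
#' by the learning rate.
#'
#' @param q current value in \[0, 1\].
#' @param reward outcome, 0 or 1.
#' @param alpha learning rate in \[0, 1\].
#' @return updated value.
#' @export
delta_update <- function(q, reward, alpha) {
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]")
  q + alpha * (reward - q)
}

#' Dual-rate delta update
#'
#' Uses `alpha_pos` after rewarded and `alpha_neg` after unrewarded trials.
#'
#' @inheritParams delta_update
#' @param alpha_pos,alpha_neg positive/negative learning rates in \[0, 1\].
#' @export
dual_delta_update <- function(q, reward, alpha_pos, alpha_neg) {
  if (any(c(alpha_pos, alpha_neg) < 0 | c(alpha_pos, alpha_neg) > 1)) {
    stop("learning rates must lie in [0, 1]")
  }
  delta_update(q, reward, ifelse(reward == 1, alpha_pos, alpha_neg))
}

#' Variable learning-rate update
#'
#' The effective learning rate drifts toward the absolute prediction error of
#' the trial it was just used on: `eta * |reward - q_chosen| + (1 - eta) * alpha`.
#'
#' @param alpha current effective learning rate in \[0, 1\].
#' @param q_chosen pre-update value of the chosen machine.
#' @param reward outcome, 0 or 1.
#' @param eta higher-order learning rate in \[0, 1\].
#' @return updated learning rate (stays in \[0, 1\]).
#' @export
variable_lr_update <- function(alpha, q_chosen, reward, eta) {
  if (any(c(alpha, eta, q_chosen) < 0 | c(alpha, eta, q_chosen) > 1)) {
    stop("alpha, eta and q_chosen must lie in [0, 1]")
  }
  eta * abs(reward - q_chosen) + (1 - eta) * alpha
}

#' Softmax choice probability
#'
#' Probability of choosing machine a given values `q_a`, `q_b` and inverse
#' temperature `beta`, computed in max-shifted form for numerical stability.
#'
#' @param q_a,q_b machine values.
#' @param beta inverse temperature in \[0, 10\].
#' @return probability of choosing a.
#' @export
softmax_prob <- function(q_a, q_b, beta) {
  if (any(beta < 0 | beta > 10)) stop("beta must lie in [0, 10]")
  m <- pmax(beta * q_a, beta * q_b)
  ea <- exp(beta * q_a - m)
  ea / (ea + exp(beta * q_b - m))
}

# ---- parameter sets -------------------------------------------------------

#' Bundle free parameter values for a model variant
#'
#' For a non-environment-specific spec pass the parameters directly
#' (`param_set(spec, alpha = .5, beta = 4)`); for an environment-specific
#' spec pass one named list per environment
#' (`param_set(spec, stable = list(...), volatile = list(...))`).
#'
#' @param spec a [model_spec()].
#' @param ... parameter values (see Details).
#' @return object of class `rw_param_set`.
#' @export
param_set <- function(spec, ...) {
  args <- list(...)
  pb <- param_bounds(spec)
  check_one <- function(x, where) {
    if (!setequal(names(x), pb$param)) {
      stop("expected parameters {", paste(pb$param, collapse = ", "),
           "} ", where)
    }
    for (j in seq_len(nrow(pb))) {
      v <- x[[pb$param[j]]]
      if (v < pb$lower[j] || v > pb$upper[j]) {
        stop(pb$param[j], " out of bounds [", pb$lower[j], ", ", pb$upper[j], "]")
      }
    }
    x[pb$param]
  }
  if (spec$environment_specific) {
    if (length(args) < 1 || is.null(names(args)) ||
        !all(vapply(args, is.list, TRUE))) {
      stop("environment-specific spec needs one named list per environment")
    }
    sets <- lapply(names(args), function(e) check_one(args[[e]], paste("for", e)))
    names(sets) <- names(args)
  } else {
    sets <- list(shared = check_one(args, "(shared)"))
  }
  structure(list(spec = spec, sets = sets), class = "rw_param_set")
}

# resolve a K x P value matrix given the environment labels of a dataset;
# K = number of environments for env-specific specs, else 1
params_to_matrix <- function(params, env_labels) {
  spec <- params$spec
  pn <- param_names(spec)
  if (spec$environment_specific) {
    missing_env <- setdiff(env_labels, names(params$sets))
    if (length(missing_env) > 0) {
      stop("no parameters supplied for environment(s): ",
           paste(missing_env, collapse = ", "))
    }
    vals <- t(vapply(env_labels,
                     function(e) unlist(params$sets[[e]][pn]),
                     numeric(length(pn))))
  } else {
    vals <- matrix(unlist(params$sets$shared[pn]), nrow = 1)
  }
  dimnames(vals) <- NULL
  vals
}

# shared bookkeeping: order trials, map environments and cells to 0-based
# indices used by the compiled core
trial_arrays <- function(trials, env_specific, env_labels = NULL) {
  req <- c("participant_id", "block", "trial", "environment",
           "winning_machine")
  miss <- setdiff(req, names(trials))
  if (length(miss) > 0) stop("trial table lacks column(s): ",
                             paste(miss, collapse = ", "))
  ord <- order(trials$participant_id, trials$block, trials$trial)
  trials <- trials[ord, ]
  env_labels <- env_labels %||% sort(unique(trials$environment))
  if (length(env_labels) > 2) stop("more than two environment labels present")
  env_idx <- match(trials$environment, env_labels)
  if (anyNA(env_idx)) {
    stop("unknown environment label: ",
         paste(setdiff(unique(trials$environment), env_labels), collapse = ", "))
  }
  cell <- if (env_specific) env_idx - 1L else rep(0L, nrow(trials))
  list(trials = trials, env_labels = env_labels,
       env = env_idx - 1L, cell = cell,
       block = as.integer(trials$block),
       choice = ifelse(is.na(trials$choice), -1L, as.integer(trials$choice)),
       reward = ifelse(is.na(trials$reward), -1L, as.integer(trials$reward)),
       winning = as.integer(trials$winning_machine))
}

#' Simulate agent choices on a generated trial sequence
#'
#' Runs the model forward through the trial table: on each trial the choice
#' is sampled from the softmax over that environment's Q-values, the reward
#' is 1 exactly when the choice equals the realized winning machine, and the
#' state is updated. Q-values (and, for variable models, the effective
#' learning rate) are kept per environment, persist across interleaved trials
#' of the other casino, and reset at block boundaries.
#'
#' @param trials trial table from [generate_phase()] (one or more
#'   participants; each is simulated independently with the same parameters).
#' @param spec a [model_spec()].
#' @param params a [param_set()] matching `spec`, or a list of them keyed by
#'   participant id.
#' @return the trial table with `choice` and `reward` filled in.
#' @export
simulate_choices <- function(trials, spec, params) {
  per_ppt <- !inherits(params, "rw_param_set")
  if (!per_ppt && !identical(params$spec, spec)) {
    stop("parameter set does not match the model spec")
  }
  ids <- sort(unique(trials$participant_id))
  out <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    tr <- trials[trials$participant_id == ids[j], ]
    ps <- if (per_ppt) params[[as.character(ids[j])]] else params
    if (!inherits(ps, "rw_param_set") || !identical(ps$spec, spec)) {
      stop("parameter set does not match the model spec (participant ",
           ids[j], ")")
    }
    arr <- trial_arrays(tr, spec$environment_specific)
    vals <- params_to_matrix(ps, if (spec$environment_specific)
      arr$env_labels else NULL)
    sim <- cpp_simulate(arr$env, arr$block, arr$cell, arr$winning, vals,
                        lr_kind_code(spec))
    tr <- arr$trials
    tr$choice <- sim$choice
    tr$reward <- sim$reward
    out[[j]] <- tr
  }
  do.call(rbind, out)
}

#' Per-trial log-likelihood of observed choices
#'
#' Deterministic counterpart of [simulate_choices()]: the state evolves
#' conditioned on the observed choices and rewards, and each non-missing
#' trial contributes the log softmax probability of the choice actually
#' made. Missing-choice trials contribute `NA` and trigger no value update.
#'
#' @inheritParams simulate_choices
#' @param params a [param_set()] matching `spec`.
#' @return numeric vector aligned with the rows of `trials` (sorted by
#'   participant, block, trial), `NA` at missing choices.
#' @export
pointwise_loglik <- function(trials, spec, params) {
  if (!identical(params$spec, spec)) {
    stop("parameter set does not match the model spec")
  }
  ids <- sort(unique(trials$participant_id))
  out <- numeric(0)
  for (id in ids) {
    tr <- trials[trials$participant_id == id, ]
    arr <- trial_arrays(tr, spec$environment_specific)
    vals <- params_to_matrix(params, if (spec$environment_specific)
      arr$env_labels else NULL)
    out <- c(out, cpp_pointwise_loglik(arr$env, arr$block, arr$cell,
                                       arr$choice, arr$reward, vals,
                                       lr_kind_code(spec)))
  }
  out
}
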