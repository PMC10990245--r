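trial_columns <- c("participant_id", "phase", "block", "trial",
                   "environment", "within_casino_trial", "correct_machine",
                   "winning_machine", "choice", "reward")

#' Read / write trial tables as long-format CSV
#'
#' The on-disk dialect has one row per trial with the documented header;
#' missing choices are empty fields. Unknown extra columns are preserved on
#' read; a wrong or missing required column is an error naming the first
#' offending column.
#'
#' @param path file path.
#' @return `read_trials`: the trial table; `write_trials`: `path`,
#'   invisibly.
#' @export
read_trials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trial_columns, names(df))
  if (length(missing) > 0) {
    stop("missing required column: ", missing[1])
  }
  for (col in c("block", "trial", "within_casino_trial", "correct_machine",
                "winning_machine", "choice", "reward")) {
    df[[col]] <- as.integer(df[[col]])
  }
  bad <- which(!is.na(df$choice) & !(df$choice %in% 0:1))
  if (length(bad) > 0) {
    stop("malformed choice value at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  df
}

#' @rdname read_trials
#' @param trials trial table to write.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing) > 0) stop("missing required column: ", missing[1])
  write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Seeded end-to-end run of an experiment profile
#'
#' Ties the pipeline together: generates the task for a cohort, simulates
#' choices from a generating model (the environment-specific dual learning
#' rate model under the reference recovery-population settings, by
#' default), optionally fits that model, compares all six variants by
#' LOOIC, and computes the behavioral statistics. Every stage derives its
#' own child seed from the master seed, so any subset of stages reruns
#' reproducibly.
#'
#' @param profile one of `"exp1"`, `"exp2"`, `"exp3"`, `"ci_small"`.
#' @param stages subset of `c("simulate", "fit", "compare", "behavior")`;
#'   `fit`/`compare`/`behavior` require `simulate`.
#' @param seed master seed.
#' @param n_chains,n_iter,n_burn sampling schedule for fitting stages.
#' @param out_dir if given, simulated data and summaries are written there
#'   as CSV.
#' @return manifest list: seeds, profile, per-stage outputs.
#' @export
run_experiment_profile <- function(profile = c("exp1", "exp2", "exp3",
                                               "ci_small"),
                                   stages = c("simulate", "behavior"),
                                   seed = 1, n_chains = 4, n_iter = 4000,
                                   n_burn = 1000, out_dir = NULL) {
  profile <- match.arg(profile)
  known <- c("simulate", "fit", "compare", "behavior")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  if (!"simulate" %in% stages && length(setdiff(stages, "simulate")) > 0) {
    stop("stages ", paste(setdiff(stages, "simulate"), collapse = ", "),
         " require the simulate stage")
  }
  prof <- experiment_profile(profile)
  spec <- model_spec("dual", environment_specific = TRUE)
  manifest <- list(profile = profile, seed = seed, stages = stages,
                   package_version = as.character(utils::packageVersion("volbandit")),
                   outputs = list())
  set.seed(child_seed(seed, 1L))
  pop <- recovery_population(spec)
  params <- draw_cohort_params(spec, pop, prof$n_participants)
  data <- list()
  for (ph in names(prof$phases)) {
    task <- generate_cohort(prof$phases[[ph]], prof$n_participants)
    sim_params <- params
    if (ph == "control") {
      # control casinos carry fresh labels; reuse each participant's stable
      # parameters in both
      sim_params <- lapply(params, function(p) {
        param_set(spec, A = p$sets$stable, B = p$sets$stable)
      })
    }
    data[[ph]] <- simulate_choices(task, spec, sim_params)
  }
  manifest$outputs$data <- data
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    for (ph in names(data)) {
      p <- file.path(out_dir, paste0(profile, "_", ph, ".csv"))
      write_trials(data[[ph]], p)
      paths <- c(paths, p)
    }
    manifest$checksums <- tools::md5sum(paths)
  }
  learn <- data$learning
  if ("fit" %in% stages) {
    manifest$outputs$fit <- fit_hbayes(learn, spec, n_chains = n_chains,
                                       n_iter = n_iter, n_burn = n_burn,
                                       seed = child_seed(seed, 2L))
  }
  if ("compare" %in% stages) {
    specs <- all_model_specs()
    loos <- lapply(seq_along(specs), function(f) {
      compute_elpd_loo(fit_hbayes(learn, specs[[f]], n_chains = n_chains,
                                  n_iter = n_iter, n_burn = n_burn,
                                  seed = child_seed(seed, 3L, f)))
    })
    names(loos) <- names(specs)
    manifest$outputs$comparison <- compare_models(loos)
    if (!is.null(out_dir)) {
      write.csv(as.data.frame(manifest$outputs$comparison),
                file.path(out_dir, paste0(profile, "_comparison.csv")),
                row.names = FALSE)
    }
  }
  if ("behavior" %in% stages) {
    beh <- list(summary = participant_summary(learn))
    if (length(unique(learn$environment)) == 2 &&
        all(c("stable", "volatile") %in% learn$environment)) {
      beh$lose_switch <- lose_switch_rates(learn)
    }
    if (length(unique(learn$block)) >= 2) {
      beh$block_contrast <- block_reward_contrast(learn)
    }
    manifest$outputs$behavior <- beh
    if (!is.null(out_dir)) {
      write.csv(beh$summary,
                file.path(out_dir, paste0(profile, "_participants.csv")),
                row.names = FALSE)
    }
  }
  manifest
}
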