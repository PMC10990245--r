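#' Configure one experimental phase
#'
#' A phase is a set of blocks in which the participant alternates
#' trial-by-trial between two casinos (environments). Each casino runs an
#' independent two-armed bandit with anticorrelated binary rewards: on every
#' trial exactly one machine wins, and the machine currently "correct" wins
#' with probability `p_reward`. Stable casinos keep the same correct machine
#' for a whole block; volatile casinos reverse it every
#' `switch_interval[1]`–`switch_interval[2]` within-casino trials;
#' intermediate (test-phase) casinos reverse it exactly `n_switches` times
#' per block.
#'
#' @param phase_kind one of `"learning"`, `"control"`, `"test"`.
#' @param n_blocks number of blocks.
#' @param trials_per_block trials per block (even; split equally between the
#'   two casinos).
#' @param casinos data frame with columns `environment` (label),
#'   `p_reward` (probability in (0.5, 1] that the correct machine wins) and
#'   `volatility` (`"stable"`, `"volatile"` or `"intermediate"`).
#' @param switch_interval integer range (inclusive) of gaps between
#'   contingency reversals, in within-casino trials.
#' @param n_switches exact number of reversals per block for intermediate
#'   casinos (`NULL` for unconstrained).
#' @return An object of class `phase_config`.
#' @examples
#' cfg <- phase_config("learning", n_blocks = 2, trials_per_block = 240,
#'                     casinos = data.frame(
#'                       environment = c("stable", "volatile"),
#'                       p_reward = c(0.75, 0.9),
#'                       volatility = c("stable", "volatile")))
#' @export
phase_config <- function(phase_kind = c("learning", "control", "test"),
                         n_blocks, trials_per_block, casinos,
                         switch_interval = c(16L, 24L), n_switches = NULL) {
  phase_kind <- match.arg(phase_kind)
  stopifnot(is.data.frame(casinos), nrow(casinos) == 2,
            all(c("environment", "p_reward", "volatility") %in% names(casinos)))
  if (trials_per_block %% 2 != 0) {
    stop("trials_per_block must be even (equal counts per casino)")
  }
  if (any(casinos$p_reward <= 0.5) || any(casinos$p_reward > 1)) {
    stop("p_reward of the better machine must lie in (0.5, 1]")
  }
  if (!all(casinos$volatility %in% c("stable", "volatile", "intermediate"))) {
    stop("volatility must be stable, volatile or intermediate")
  }
  if (length(switch_interval) != 2 || switch_interval[1] > switch_interval[2] ||
      switch_interval[1] < 1) {
    stop("switch_interval must be a nonempty integer range with min >= 1")
  }
  structure(list(phase_kind = phase_kind, n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 casinos = casinos,
                 switch_interval = as.integer(switch_interval),
                 n_switches = n_switches),
            class = "phase_config")
}

#' Built-in experiment profiles
#'
#' Returns the phase configurations and included sample size of the three
#' experiments (learning phases of 2 x 240, 4 x 200 and 3 x 200 trials with a
#' 75/25 or 80/20 stable and a 90/10 volatile casino, plus the control and
#' intermediate-volatility test phases) and a minutes-scale `ci_small`
#' profile for smoke runs.
#'
#' @param name profile name.
#' @return list with elements `phases` (named list of [phase_config()]) and
#'   `n_participants`.
#' @export
experiment_profile <- function(name = c("exp1", "exp2", "exp3", "ci_small")) {
  name <- match.arg(name)
  learn_casinos <- function(p_stable) {
    data.frame(environment = c("stable", "volatile"),
               p_reward = c(p_stable, 0.9),
               volatility = c("stable", "volatile"))
  }
  switch(name,
    exp1 = list(
      n_participants = 36L,
      phases = list(
        learning = phase_config("learning", 2, 240, learn_casinos(0.75)),
        control = phase_config("control", 1, 240,
          data.frame(environment = c("A", "B"), p_reward = c(0.75, 0.75),
                     volatility = c("stable", "stable"))))),
    exp2 = list(
      n_participants = 51L,
      phases = list(
        learning = phase_config("learning", 4, 200, learn_casinos(0.8)))),
    exp3 = list(
      n_participants = 129L,
      phases = list(
        learning = phase_config("learning", 3, 200, learn_casinos(0.8)),
        test = phase_config("test", 1, 200,
          data.frame(environment = c("stable", "volatile"),
                     p_reward = c(0.85, 0.85),
                     volatility = c("intermediate", "intermediate")),
          switch_interval = c(29L, 37L), n_switches = 2L))),
    ci_small = list(
      n_participants = 8L,
      phases = list(
        learning = phase_config("learning", 2, 80, learn_casinos(0.8)))))
}

#' Balanced random casino sequence for one block
#'
#' Uniformly random ordering of exactly `trials_per_block / 2` trials of each
#' casino, matching the per-block-exact alternation of the task.
#'
#' @param trials_per_block even trial count.
#' @param labels the two casino labels.
#' @return character vector of environment labels.
#' @export
generate_casino_sequence <- function(trials_per_block,
                                     labels = c("stable", "volatile")) {
  if (trials_per_block %% 2 != 0) stop("trials_per_block must be even")
  stopifnot(length(labels) == 2)
  sample(rep(labels, each = trials_per_block / 2))
}

#' Reversal points of a volatile reward schedule
#'
#' Gaps between successive contingency reversals (and before the first one)
#' are drawn iid uniformly from `interval_range`; a reversal landing after
#' within-casino trial `n_within` is dropped. When `n_switches` is given the
#' gaps are redrawn until exactly that many reversals fall inside the block
#' (the test phase reverses exactly twice per block).
#'
#' @param n_within number of within-casino trials in the block.
#' @param interval_range inclusive integer range of gaps.
#' @param n_switches exact reversal count to condition on, or `NULL`.
#' @return sorted integer vector: a value `s` means the contingency flips
#'   between within-casino trials `s` and `s + 1`.
#' @export
generate_switch_points <- function(n_within, interval_range = c(16L, 24L),
                                   n_switches = NULL) {
  if (length(interval_range) != 2 || interval_range[1] > interval_range[2] ||
      interval_range[1] < 1) {
    stop("interval_range must be a nonempty integer range with min >= 1")
  }
  range_vals <- seq.int(interval_range[1], interval_range[2])
  draw <- function() {
    max_n <- ceiling(n_within / interval_range[1]) + 1
    gaps <- if (length(range_vals) == 1) rep(range_vals, max_n) else
      sample(range_vals, max_n, replace = TRUE)
    pts <- cumsum(gaps)
    pts[pts <= n_within]
  }
  if (is.null(n_switches)) return(draw())
  for (i in 1:10000) {
    pts <- draw()
    if (length(pts) == n_switches) return(pts)
  }
  stop("could not draw a schedule with exactly ", n_switches, " switches")
}

#' Generate the trial sequence of one phase for one participant
#'
#' Produces a long-format trial table with the casino order, the reversal
#' schedule and the realized winning machine of every trial; choices and
#' rewards are left `NA` (they are filled in by an agent or a participant).
#' Each block gets a fresh machine pair per casino: the initially correct
#' machine is a fair coin flip and Q-learning agents reset their values at
#' block boundaries.
#'
#' @param config a [phase_config()].
#' @param participant_id identifier stored in the output.
#' @return data frame with columns `participant_id`, `phase`, `block`,
#'   `trial`, `environment`, `within_casino_trial`, `correct_machine`,
#'   `winning_machine`, `choice`, `reward`. Machines are labelled 0/1.
#' @export
generate_phase <- function(config, participant_id = 1L) {
  stopifnot(inherits(config, "phase_config"))
  out <- vector("list", config$n_blocks)
  labels <- config$casinos$environment
  for (b in seq_len(config$n_blocks)) {
    envs <- generate_casino_sequence(config$trials_per_block, labels)
    n_within <- config$trials_per_block / 2
    correct <- winning <- integer(config$trials_per_block)
    wct <- integer(config$trials_per_block)
    for (ci in 1:2) {
      cas <- config$casinos[ci, ]
      idx <- which(envs == cas$environment)
      pts <- switch(cas$volatility,
        stable = integer(0),
        volatile = generate_switch_points(n_within, config$switch_interval),
        intermediate = generate_switch_points(n_within, config$switch_interval,
                                              n_switches = config$n_switches))
      init <- sample(0:1, 1)
      w <- seq_len(n_within)
      n_flips <- vapply(w, function(t) sum(pts < t), 0L)
      corr <- (init + n_flips) %% 2
      win_is_corr <- runif(n_within) < cas$p_reward
      correct[idx] <- corr
      winning[idx] <- ifelse(win_is_corr, corr, 1 - corr)
      wct[idx] <- w
    }
    out[[b]] <- data.frame(
      participant_id = participant_id, phase = config$phase_kind, block = b,
      trial = seq_len(config$trials_per_block), environment = envs,
      within_casino_trial = wct, correct_machine = correct,
      winning_machine = winning, choice = NA_integer_, reward = NA_integer_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a phase for a cohort of participants
#'
#' @param config a [phase_config()].
#' @param n_participants cohort size.
#' @param ids participant identifiers (default `1:n_participants`).
#' @return row-bound trial table, one [generate_phase()] per participant.
#' @export
generate_cohort <- function(config, n_participants, ids = seq_len(n_participants)) {
  do.call(rbind, lapply(ids, function(i) generate_phase(config, i)))
}

#' Run-length distribution of casino visits
#'
#' Fraction of maximal runs of consecutive same-casino trials at each length,
#' pooled over blocks. For balanced random sequences the pooled fractions
#' approach 2^(-k): about 50% of runs have length 1 and 25% length 2.
#'
#' @param sequences a character vector of environment labels, or a list of
#'   such vectors (one per block).
#' @return data frame with columns `run_length`, `n_runs`, `fraction`
#'   (fractions sum to 1).
#' @export
run_length_distribution <- function(sequences) {
  if (!is.list(sequences)) sequences <- list(sequences)
  if (length(sequences) == 0 || all(lengths(sequences) == 0)) {
    stop("no sequences supplied")
  }
  lens <- unlist(lapply(sequences, function(s) rle(as.character(s))$lengths))
  tab <- table(lens)
  data.frame(run_length = as.integer(names(tab)),
             n_runs = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab))
}
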