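#' Chance-level inclusion decision
#'
#' A participant is retained in an environment only if their reward count is
#' significantly above chance: a one-degree-of-freedom chi-square test of
#' the win count against half the trials at the 0.05 alpha level, combined
#' with the directional requirement that the reward rate exceeds 0.5.
#'
#' @param wins rewarded trial count.
#' @param trials total trial count (> 0).
#' @param alpha_level significance level.
#' @return list: `included`, `chisq`, `p_value`, `reward_rate`.
#' @export
exclusion_filter <- function(wins, trials, alpha_level = 0.05) {
  if (trials <= 0) stop("trials must be positive")
  if (wins > trials || wins < 0) stop("wins must lie in [0, trials]")
  chisq <- (2 * wins - trials)^2 / trials
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  rate <- wins / trials
  list(included = (p < alpha_level) && (rate > 0.5),
       chisq = chisq, p_value = p, reward_rate = rate)
}

#' Per-participant summaries and inclusion flags
#'
#' @param data learning-phase trial table.
#' @param alpha_level significance level for [exclusion_filter()].
#' @return data frame: one row per participant x environment with reward
#'   rate, trial count, and the overall inclusion flag (false if the
#'   chance-level criterion fails in at least one environment).
#' @export
participant_summary <- function(data, alpha_level = 0.05) {
  data <- data[!is.na(data$choice), ]
  out <- do.call(rbind, lapply(split(data, data[c("participant_id",
                                                  "environment")]),
    function(d) {
      f <- exclusion_filter(sum(d$reward), nrow(d), alpha_level)
      data.frame(participant_id = d$participant_id[1],
                 environment = d$environment[1], n_trials = nrow(d),
                 reward_rate = f$reward_rate, included_env = f$included)
    }))
  rownames(out) <- NULL
  incl <- tapply(out$included_env, out$participant_id, all)
  out$included <- as.logical(incl[as.character(out$participant_id)])
  out
}

#' Lose-switch rates per environment
#'
#' Probability of choosing the other machine on the next within-casino trial
#' after an unrewarded choice. Pairs are consecutive within-casino trials
#' inside the same block; pairs spanning block boundaries are excluded (new
#' machines each block). Returns per-participant rates plus a paired
#' one-tailed t-test across participants (volatile > stable).
#'
#' @param data trial table with observed choices.
#' @param stable,volatile environment labels to contrast.
#' @return list: `rates` (participant x environment), `test` (t statistic,
#'   df, one-tailed p), `dropped` (participants without qualifying pairs).
#' @export
lose_switch_rates <- function(data, stable = "stable", volatile = "volatile") {
  data <- data[!is.na(data$choice), ]
  rate_one <- function(d) {
    d <- d[order(d$block, d$trial), ]
    n_sw <- n_loss <- 0L
    for (b in unique(d$block)) {
      db <- d[d$block == b, ]
      if (nrow(db) < 2) next
      consec <- which(diff(db$within_casino_trial) == 1)
      losses <- consec[db$reward[consec] == 0]
      n_loss <- n_loss + length(losses)
      n_sw <- n_sw + sum(db$choice[losses + 1] != db$choice[losses])
    }
    if (n_loss == 0) return(NA_real_)
    n_sw / n_loss
  }
  rates <- do.call(rbind, lapply(split(data, data$participant_id),
    function(dp) data.frame(
      participant_id = dp$participant_id[1],
      stable = rate_one(dp[dp$environment == stable, ]),
      volatile = rate_one(dp[dp$environment == volatile, ]))))
  rownames(rates) <- NULL
  ok <- stats::complete.cases(rates[c("stable", "volatile")])
  dropped <- rates$participant_id[!ok]
  if (length(dropped) > 0) {
    message("dropped from the lose-switch test (no qualifying pairs): ",
            paste(dropped, collapse = ", "))
  }
  test <- NULL
  d <- rates[ok, ]
  if (nrow(d) >= 2 && sd(d$volatile - d$stable) > 0) {
    tt <- t.test(d$volatile, d$stable, paired = TRUE,
                 alternative = "greater")
    test <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value)
  }
  list(rates = rates, test = test, dropped = dropped)
}

#' Choice accuracy on the first trials after a contingency reversal
#'
#' For test-phase data, the proportion of participants choosing the
#' currently correct machine on each of the first `horizon` within-casino
#' trials after each reversal, per environment, with a per-position 2 x 2
#' chi-square (environment x correct/incorrect, no continuity correction,
#' uncorrected for multiple comparisons).
#'
#' @param data test-phase trial table with `correct_machine` filled.
#' @param horizon post-reversal positions to analyse.
#' @return data frame: `switch_no`, `position`, proportions per environment,
#'   `chisq`, `p_value`.
#' @export
post_switch_accuracy <- function(data, horizon = 10) {
  data <- data[!is.na(data$choice), ]
  envs <- sort(unique(data$environment))
  stopifnot(length(envs) == 2)
  # reversal points recovered from the correct-machine schedule
  pos_tab <- do.call(rbind, lapply(
    split(data, data[c("participant_id", "environment", "block")]),
    function(d) {
      if (nrow(d) == 0) return(NULL)
      d <- d[order(d$within_casino_trial), ]
      flips <- which(diff(d$correct_machine) != 0)
      if (length(flips) == 0) return(NULL)
      do.call(rbind, lapply(seq_along(flips), function(s) {
        post <- d[d$within_casino_trial > d$within_casino_trial[flips[s]], ]
        post <- post[seq_len(min(horizon, nrow(post))), , drop = FALSE]
        if (nrow(post) < horizon) {
          warning("fewer than ", horizon, " post-switch trials; truncated")
        }
        data.frame(environment = d$environment[1], switch_no = s,
                   position = seq_len(nrow(post)),
                   correct = post$choice == post$correct_machine)
      }))
    }))
  out <- do.call(rbind, lapply(split(pos_tab,
                                     pos_tab[c("switch_no", "position")]),
    function(d) {
      if (length(unique(d$environment)) < 2) return(NULL)
      tab <- table(factor(d$environment, levels = envs),
                   factor(d$correct, levels = c(TRUE, FALSE)))
      chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
      props <- tab[, "TRUE"] / rowSums(tab)
      res <- data.frame(switch_no = d$switch_no[1],
                        position = d$position[1],
                        chisq = unname(chi$statistic),
                        p_value = chi$p.value)
      res[[paste0("prop_", envs[1])]] <- props[1]
      res[[paste0("prop_", envs[2])]] <- props[2]
      res
    }))
  out <- out[order(out$switch_no, out$position), ]
  rownames(out) <- NULL
  out
}

#' Block-wise reward-rate contrast
#'
#' Paired one-tailed t-test of per-participant reward rates in the last
#' versus the first block (learning should raise reward rates over blocks).
#'
#' @param data trial table with >= 2 blocks of observed choices.
#' @return list: `by_block` (participant x block reward rates), `t`, `df`,
#'   `p_value`; degenerate zero-variance differences are flagged.
#' @export
block_reward_contrast <- function(data) {
  data <- data[!is.na(data$choice), ]
  blocks <- sort(unique(data$block))
  if (length(blocks) < 2) stop("need at least 2 blocks")
  agg <- stats::aggregate(reward ~ participant_id + block, data, mean)
  first <- agg[agg$block == blocks[1], ]
  last <- agg[agg$block == blocks[length(blocks)], ]
  m <- merge(first, last, by = "participant_id", suffixes = c("_first",
                                                              "_last"))
  diffs <- m$reward_last - m$reward_first
  if (sd(diffs) == 0) {
    return(list(by_block = agg, t = NA_real_, df = nrow(m) - 1,
                p_value = NA_real_, degenerate = TRUE))
  }
  tt <- t.test(m$reward_last, m$reward_first, paired = TRUE,
               alternative = "greater")
  list(by_block = agg, t = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value, degenerate = FALSE)
}
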