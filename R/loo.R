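#' Expected log pointwise predictive density by PSIS-LOO
#'
#' Leave-one-out cross-validation approximated by importance sampling over
#' posterior draws, with the largest importance ratios of each observation
#' stabilised by a generalised Pareto fit to the weight tail
#' (Pareto-smoothed importance sampling). The total is reported as "LOOIC"
#' on the elpd scale used in the comparison tables: negative numbers, higher
#' is better. The standard error is
#' `sqrt(n * var(pointwise contributions))`. Observations whose Pareto shape
#' exceeds 0.7 are counted and reported, never silently fixed.
#'
#' @param log_lik draws x observations matrix of pointwise log-likelihoods
#'   (finite entries), or an `rw_fit` with stored pointwise matrix.
#' @return object of class `loo_result` with `elpd`, `se`, `pointwise`,
#'   `pareto_k` and `n_high_k`.
#' @export
compute_elpd_loo <- function(log_lik) {
  if (inherits(log_lik, "rw_fit")) {
    if (is.null(log_lik$pointwise)) {
      stop("fit was sampled with store_pointwise = FALSE")
    }
    log_lik <- log_lik$pointwise
  }
  if (!is.matrix(log_lik) || nrow(log_lik) < 2) {
    stop("need a draws x observations matrix with at least 2 draws")
  }
  if (!all(is.finite(log_lik))) {
    bad <- which(colSums(!is.finite(log_lik)) > 0)
    stop("non-finite log-likelihoods at observation(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  n <- ncol(log_lik)
  ps <- cpp_psis_elpd(log_lik)
  pointwise <- ps$pointwise
  pareto_k <- ps$pareto_k
  structure(list(elpd = sum(pointwise),
                 se = sqrt(n * var(pointwise)),
                 pointwise = pointwise,
                 pareto_k = pareto_k,
                 n_high_k = sum(pareto_k > 0.7, na.rm = TRUE),
                 n_obs = n, n_draws = nrow(log_lik)),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("LOOIC (elpd): %.1f  SE: %.1f  (%d observations, %d draws)\n",
              x$elpd, x$se, x$n_obs, x$n_draws))
  if (x$n_high_k > 0) {
    cat(sprintf("warning: %d observation(s) with Pareto shape > 0.7\n",
                x$n_high_k))
  }
  invisible(x)
}

#' Rank models by out-of-sample predictive fit
#'
#' Comparison tables: models sorted descending by
#' elpd ("LOOIC", higher is better), with the difference to the top-ranked
#' model and the standard error of that difference computed from the paired
#' per-observation elpd contributions. A model is flagged `decisive`ly worse
#' when its deficit exceeds twice the SE of the difference.
#'
#' @param results named list of `loo_result` objects (or `rw_fit`s with
#'   stored pointwise matrices), all fitted to the identical observation set
#'   in identical order.
#' @return data frame of class `rw_comparison` with columns `model`,
#'   `looic`, `se`, `d_looic`, `d_se`, `decisive`.
#' @export
compare_models <- function(results) {
  if (is.null(names(results)) || any(names(results) == "")) {
    stop("results must be a named list")
  }
  loos <- lapply(results, function(r) {
    if (inherits(r, "rw_fit")) compute_elpd_loo(r) else r
  })
  n_obs <- vapply(loos, function(l) l$n_obs, 0)
  if (length(unique(n_obs)) != 1) {
    stop("models were fitted to different observation sets")
  }
  elpd <- vapply(loos, function(l) l$elpd, 0)
  ord <- order(elpd, decreasing = TRUE)
  top <- loos[[ord[1]]]
  rows <- lapply(ord, function(j) {
    l <- loos[[j]]
    dpw <- top$pointwise - l$pointwise
    d <- sum(dpw)
    dse <- if (j == ord[1]) 0 else sqrt(l$n_obs * var(dpw))
    data.frame(model = names(loos)[j], looic = l$elpd, se = l$se,
               d_looic = d, d_se = dse,
               decisive = d > 2 * dse, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rw_comparison", "data.frame")
  out
}

#' @export
print.rw_comparison <- function(x, ...) {
  y <- as.data.frame(x)
  y$looic <- round(y$looic)
  y$se <- round(y$se)
  y$d_looic <- round(y$d_looic)
  y$d_se <- round(y$d_se)
  names(y) <- c("Model", "LOOIC", "SE", "dLOOIC", "dSE", "decisive")
  print(y, row.names = FALSE)
  invisible(x)
}
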