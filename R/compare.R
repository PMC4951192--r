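# Model comparison: chi-square likelihood-ratio tests for nested pairs
# (asymmetric vs classical) and direct per-trial likelihoods for pairs with
# equal parameter counts (asymmetric vs nonlinear utility). The WSLS
# comparison is reported descriptively only: it is nested at the eta = 1
# bound, where the chi-square null is unreliable.

#' Likelihood-ratio test for nested models
#'
#' Refers `2 * (negll_reduced - negll_full)` to the chi-square distribution
#' with `df` degrees of freedom (the difference in free-parameter counts)
#' and returns the upper-tail p-value.
#'
#' @param negll_full,negll_reduced Negative log-likelihoods at the optimum
#'   of the full and reduced models.
#' @param df Degrees of freedom, `df >= 1`.
#' @param tolerance Numerical slack allowed when the full model fits very
#'   slightly worse than the reduced one (the statistic is then clamped
#'   at 0).
#' @return Upper-tail p-value.
#' @export
nested_lrt <- function(negll_full, negll_reduced, df, tolerance = 1e-6) {
  stopifnot(df >= 1, is.finite(negll_full), is.finite(negll_reduced))
  if (negll_full > negll_reduced + tolerance)
    stop("full model fits worse than the reduced model (",
         negll_full - negll_reduced,
         " nats): fitting failure, not a valid LRT")
  stat <- max(0, 2 * (negll_reduced - negll_full))
  pchisq(stat, df = df, lower.tail = FALSE)
}

#' Geometric-mean per-trial choice probability
#'
#' Inverts a session's total negative log-likelihood into the average
#' probability the model assigned per scoreable choice trial:
#' `exp(-negloglik / n_choice_trials)`.
#'
#' @param negloglik Nonnegative total negative log-likelihood (nats).
#' @param n_choice_trials Number of scoreable choice trials, `>= 1`.
#' @return Probability in `(0, 1]`.
#' @export
per_trial_probability <- function(negloglik, n_choice_trials) {
  if (any(n_choice_trials < 1)) stop("`n_choice_trials` must be positive")
  stopifnot(all(is.finite(negloglik)), all(negloglik >= 0))
  exp(-negloglik / n_choice_trials)
}

#' Per-agent and group model-selection summary
#'
#' For every agent: the asymmetric-vs-classical likelihood-ratio test
#' (df = 1, alpha configurable), the asymmetric-vs-utility per-trial
#' probability difference (equal parameter counts, compared directly), and
#' the descriptive asymmetric-vs-WSLS log-likelihood difference. The group
#' summary counts agents favoring each model and runs a paired one-tailed
#' t-test on the asymmetric-vs-utility likelihood differences (on both the
#' total log-likelihood and the per-trial probability scale).
#'
#' @param fits Data frame as produced by [fits_to_table()], holding one row
#'   per `(agent_id, model)` with at least an `ASYMMETRIC` and a
#'   `CLASSICAL` fit per agent; `UTILITY` and `WSLS` rows are used when
#'   present.
#' @param alpha Significance level for the per-agent LRT (default 0.05).
#' @return An object of class `rl_model_selection`: `per_agent` data frame
#'   and `group` list (`NULL` group tests for single-agent input).
#' @export
model_selection_table <- function(fits, alpha = 0.05) {
  stopifnot(is.data.frame(fits),
            all(c("agent_id", "model", "negloglik") %in% names(fits)))
  agents <- unique(fits$agent_id)
  rows <- lapply(agents, function(id) {
    ff <- fits[fits$agent_id == id, ]
    get <- function(m) ff[ff$model == m, , drop = FALSE]
    asym <- get("ASYMMETRIC"); cls <- get("CLASSICAL")
    if (nrow(asym) != 1 || nrow(cls) != 1)
      stop("agent ", id, " is missing an ASYMMETRIC or CLASSICAL fit")
    uti <- get("UTILITY"); wsls <- get("WSLS")
    n_ch <- asym$n_choice_trials
    p_lrt <- nested_lrt(asym$negloglik, cls$negloglik, df = 1)
    ptp_asym <- per_trial_probability(asym$negloglik, n_ch)
    data.frame(
      agent_id = id,
      n_choice_trials = n_ch,
      negloglik_asym = asym$negloglik,
      negloglik_classical = cls$negloglik,
      delta_loglik_asym_classical = cls$negloglik - asym$negloglik,
      lrt_p = p_lrt,
      asym_justified = p_lrt < alpha,
      per_trial_prob_asym = ptp_asym,
      per_trial_prob_utility = if (nrow(uti) == 1)
        per_trial_probability(uti$negloglik, n_ch) else NA_real_,
      delta_loglik_asym_utility = if (nrow(uti) == 1)
        uti$negloglik - asym$negloglik else NA_real_,
      delta_loglik_asym_wsls = if (nrow(wsls) == 1)
        wsls$negloglik - asym$negloglik else NA_real_
    )
  })
  per_agent <- do.call(rbind, rows)
  per_agent$preferred <- ifelse(per_agent$asym_justified, "ASYMMETRIC",
                                "CLASSICAL")
  group <- NULL
  if (length(agents) > 1) {
    du <- per_agent$delta_loglik_asym_utility
    dp <- per_agent$per_trial_prob_asym - per_agent$per_trial_prob_utility
    group <- list(
      n_agents = length(agents),
      n_asym_over_classical = sum(per_agent$asym_justified),
      n_asym_over_utility = if (all(is.na(du))) NA_integer_ else
        sum(du > 0, na.rm = TRUE),
      n_asym_over_wsls = if (all(is.na(per_agent$delta_loglik_asym_wsls)))
        NA_integer_ else
        sum(per_agent$delta_loglik_asym_wsls > 0, na.rm = TRUE),
      paired_t_total = if (!all(is.na(du)) && sd(du, na.rm = TRUE) > 0)
        t.test(du[!is.na(du)], alternative = "greater") else NULL,
      paired_t_per_trial = if (!all(is.na(dp)) && sd(dp, na.rm = TRUE) > 0)
        t.test(dp[!is.na(dp)], alternative = "greater") else NULL
    )
  }
  structure(list(per_agent = per_agent, group = group, alpha = alpha),
            class = "rl_model_selection")
}

#' @export
print.rl_model_selection <- function(x, ...) {
  cat("<rl_model_selection> ", nrow(x$per_agent), " agents; ",
      sum(x$per_agent$asym_justified),
      " favor the asymmetric model over classical (LRT, alpha = ",
      x$alpha, ")\n", sep = "")
  if (!is.null(x$group) && !is.null(x$group$paired_t_per_trial)) {
    tt <- x$group$paired_t_per_trial
    cat(sprintf(
      "  asym vs utility (paired one-tailed t on per-trial prob): t = %.3f, p = %.4g\n",
      tt$statistic, tt$p.value))
  }
  invisible(x)
}
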