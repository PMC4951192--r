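# Per-session maximum-likelihood fitting: bounded quasi-Newton (PORT
# routines via nlminb) on the raw parameters, repeated from several uniform
# random starting points, keeping the best restart.

model_free_params <- function(model) {
  switch(model,
    ASYMMETRIC = c("eta", "kappa", "beta"),
    CLASSICAL = c("eta", "beta"),
    UTILITY = c("eta", "a", "beta"),
    WSLS = "beta",
    stop("unknown model ", model))
}

param_bounds <- function(kappa_limit = 1) {
  list(eta = c(0, 1), kappa = c(-kappa_limit, kappa_limit), beta = c(0, 30),
       a = c(0, 3))
}

params_from_vector <- function(model, x, kappa_limit = 1) {
  full <- c(eta = 1, kappa = 0, beta = 0, a = 1)
  full[names(x)] <- x
  rl_params(model, eta = full[["eta"]], kappa = full[["kappa"]],
            beta = full[["beta"]], a = full[["a"]], kappa_limit = kappa_limit)
}

#' Fit one model to one session by maximum likelihood
#'
#' Minimizes [session_negloglik()] over the model's free parameters within
#' their bounds (eta `[0, 1]`, kappa `[-kappa_limit, kappa_limit]`, beta
#' `[0, 30]`, a `[0, 3]`) with L-BFGS-B, restarting from `n_restarts`
#' starting points drawn uniformly within the bounds, and keeps the best
#' restart (`nlminb`'s PORT quasi-Newton handles the poorly scaled,
#' locally rugged surface better than box-constrained BFGS here).
#' Deterministic given `(session, seed)`.
#'
#' @param model One of `"ASYMMETRIC"`, `"CLASSICAL"`, `"UTILITY"`, `"WSLS"`.
#' @param session An `rl_session` (or aligned records data frame).
#' @param schedule The matching `rl_schedule`.
#' @param n_restarts Number of random restarts (default 5).
#' @param seed Integer seed for the starting points.
#' @param kappa_limit Half-width of the kappa search range. The default 1
#'   keeps effective learning rates nonnegative; up to 10 is accepted, with
#'   a warning once a fitted `|kappa|` exceeds 1.
#' @return An object of class `rl_fit`: `model`, `best_params`
#'   (`rl_params`), `negloglik`, `n_restarts`, `restart_objectives`,
#'   `converged`, `n_choice_trials`, `seed`.
#' @export
fit_model <- function(model, session, schedule, n_restarts = 5, seed = 1,
                      kappa_limit = 1) {
  model <- match.arg(model, MODEL_LEVELS)
  stopifnot(inherits(schedule, "rl_schedule"), n_restarts >= 1)
  prep <- prep_replay(schedule, session)
  if (prep$n_choice < 1)
    stop("degenerate session: no scoreable choice trial")
  free <- model_free_params(model)
  bounds <- param_bounds(kappa_limit)
  lower <- vapply(bounds[free], `[`, 0, 1)
  upper <- vapply(bounds[free], `[`, 0, 2)
  code <- MODEL_CODES[[model]]
  objective <- function(x) {
    full <- c(eta = 1, kappa = 0, beta = 0, a = 1)
    full[free] <- x
    v <- replay_negloglik_cpp(prep$cue_a, prep$cue_b, prep$is_choice,
                              prep$chosen, prep$reward, prep$aborted, code,
                              full[["eta"]], full[["kappa"]], full[["beta"]],
                              full[["a"]])
    if (!is.finite(v)) .Machine$double.xmax else v
  }
  starts <- withr::with_seed(as.integer(seed), {
    matrix(runif(n_restarts * length(free), rep(lower, each = n_restarts),
                 rep(upper, each = n_restarts)),
           nrow = n_restarts, dimnames = list(NULL, free))
  })
  fits <- lapply(seq_len(n_restarts), function(i) {
    tryCatch(
      stats::nlminb(starts[i, ], objective, lower = lower, upper = upper,
                    control = list(iter.max = 500, eval.max = 1000,
                                   abs.tol = 1e-8)),
      error = function(e) list(par = starts[i, ], objective = Inf,
                               convergence = 52L)
    )
  })
  objectives <- vapply(fits, `[[`, 0, "objective")
  if (!any(is.finite(objectives)))
    stop("all restarts failed to evaluate the objective finitely")
  best <- fits[[which.min(objectives)]]
  par <- setNames(best$par, free)
  if (kappa_limit > 1 && "kappa" %in% free && abs(par[["kappa"]]) > 1)
    warning("fitted |kappa| > 1: effective learning rate changes sign")
  structure(
    list(model = model,
         best_params = suppressWarnings(
           params_from_vector(model, par, kappa_limit)),
         negloglik = best$objective, n_restarts = n_restarts,
         restart_objectives = objectives,
         converged = best$convergence == 0,
         n_choice_trials = prep$n_choice, seed = seed),
    class = "rl_fit"
  )
}

#' @export
print.rl_fit <- function(x, ...) {
  p <- x$best_params
  cat(sprintf(
    "<rl_fit> %s: nll = %.4f over %d choice trials (%d restarts%s)\n",
    x$model, x$negloglik, x$n_choice_trials, x$n_restarts,
    if (x$converged) "" else ", NOT converged"))
  print(p)
  invisible(x)
}

#' Flatten fits into a table
#'
#' @param fits List of `rl_fit` objects (one per agent).
#' @param agent_ids Optional agent identifiers (defaults to list position).
#' @return Data frame with one row per fit: `agent_id`, `model`, `eta`,
#'   `kappa`, `beta`, `a`, `negloglik`, `n_choice_trials`, `converged`.
#' @export
fits_to_table <- function(fits, agent_ids = seq_along(fits)) {
  do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    p <- f$best_params
    data.frame(agent_id = agent_ids[i], model = f$model, eta = p$eta,
               kappa = p$kappa, beta = p$beta, a = p$a,
               negloglik = f$negloglik, n_choice_trials = f$n_choice_trials,
               converged = f$converged)
  }))
}

#' Parameter-recovery harness
#'
#' Simulates a cohort from known true parameters, fits `model` to every
#' agent, and reports paired true/recovered parameters with per-parameter
#' bias, RMSE and true-vs-recovered Pearson correlation. Sessions whose
#' fitted inverse temperature lands on a search bound are flagged as
#' low-information (near-deterministic or near-random choices carry little
#' gradient information about the learning parameters).
#'
#' @param spec An `rl_cohort_spec` with at least 2 agents.
#' @param model Model to fit (defaults to the cohort's generating model).
#' @param n_restarts,fit_seed Passed to [fit_model()] (per-agent seeds are
#'   derived from `fit_seed`).
#' @return An object of class `rl_recovery`: `pairs` (data frame of true and
#'   recovered parameters, per-agent negloglik, `low_info` and `fit_error`
#'   flags) and `summary` (per-parameter bias, RMSE, correlation).
#' @export
recover_parameters <- function(spec, model = spec$model, n_restarts = 5,
                               fit_seed = 1) {
  stopifnot(inherits(spec, "rl_cohort_spec"), spec$n_agents >= 2)
  cohort <- simulate_cohort(spec)
  n <- length(cohort$sessions)
  seeds <- withr::with_seed(as.integer(fit_seed),
                            sample.int(.Machine$integer.max, n))
  free <- model_free_params(model)
  rows <- lapply(seq_len(n), function(i) {
    truth <- cohort$manifest[i, ]
    fit <- tryCatch(
      fit_model(model, cohort$sessions[[i]], cohort$schedule,
                n_restarts = n_restarts, seed = seeds[i],
                kappa_limit = spec$kappa_limit),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      row <- data.frame(agent_id = truth$agent_id, negloglik = NA_real_,
                        low_info = NA, fit_error = conditionMessage(fit))
      for (p in free) {
        row[[paste0(p, "_true")]] <- truth[[p]]
        row[[paste0(p, "_hat")]] <- NA_real_
      }
      return(row)
    }
    bp <- fit$best_params
    beta_bounds <- param_bounds(spec$kappa_limit)$beta
    row <- data.frame(
      agent_id = truth$agent_id, negloglik = fit$negloglik,
      low_info = min(abs(bp$beta - beta_bounds)) < 1e-6,
      fit_error = NA_character_)
    for (p in free) {
      row[[paste0(p, "_true")]] <- truth[[p]]
      row[[paste0(p, "_hat")]] <- bp[[p]]
    }
    row
  })
  pairs <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(free, function(p) {
    tru <- pairs[[paste0(p, "_true")]]
    hat <- pairs[[paste0(p, "_hat")]]
    ok <- !is.na(hat)
    data.frame(
      parameter = p,
      bias = mean(hat[ok] - tru[ok]),
      rmse = sqrt(mean((hat[ok] - tru[ok])^2)),
      correlation = if (sum(ok) >= 3 && sd(tru[ok]) > 0 && sd(hat[ok]) > 0)
        stats::cor(tru[ok], hat[ok]) else NA_real_,
      n = sum(ok))
  }))
  structure(list(pairs = pairs, summary = summary, model = model),
            class = "rl_recovery")
}

#' @export
print.rl_recovery <- function(x, ...) {
  cat("<rl_recovery> model ", x$model, ", ", nrow(x$pairs), " agents (",
      sum(!is.na(x$pairs$low_info) & x$pairs$low_info),
      " flagged low-information)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
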