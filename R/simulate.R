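# Synthetic cohorts: agents obeying one of the candidate learning rules,
# with true parameters drawn from truncated normals whose parent moments are
# the fitted group statistics of the two study populations (a DYT1-dystonia-
# like group and a healthy-control-like group), all replaying one canonical
# schedule per cohort.

GROUP_PRESETS <- list(
  DYT = list(eta = c(mean = 0.25, sd = 0.19),
             kappa = c(mean = -0.05, sd = 0.27),
             beta = c(mean = 0.68, sd = 0.37)),
  CTL = list(eta = c(mean = 0.14, sd = 0.11),
             kappa = c(mean = -0.34, sd = 0.27),
             beta = c(mean = 0.93, sd = 0.47))
)

# inverse-CDF truncated normal; parent moments are (mean, sd), support
# clipped to [lower, upper]
r_truncnorm <- function(n, mean, sd, lower, upper) {
  if (!is.finite(sd) || sd < 0) stop("truncated normal needs sd >= 0")
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Severity-link preset
#'
#' Default linear mapping from an agent's true learning asymmetry `kappa` to
#' a synthetic clinical severity score (arbitrary rating-scale units,
#' truncated at 0): `severity = intercept + slope * kappa + N(0, noise_sd)`.
#' The intercept and slope anchor zero severity at the control-like group's
#' mean asymmetry (-0.34), and `noise_sd` is calibrated so the expected
#' sample correlation between severity and `kappa` in a 13-agent
#' patient-like cohort is about 0.62-0.64.
#'
#' @return List with `intercept`, `slope` and `noise_sd`.
#' @export
severity_link_preset <- function() {
  list(intercept = 10.2, slope = 30, noise_sd = 8.5)
}

#' Specify a synthetic cohort
#'
#' Describes a group of simulated agents: how many, which learning model
#' generates their behavior, the truncated-normal distributions their true
#' parameters are drawn from, an optional severity link, and the seeds for
#' the shared schedule and the cohort-level randomness. The `"DYT"` and
#' `"CTL"` presets carry the fitted group moments of the patient and control
#' populations (eta 0.25 +/- 0.19, kappa -0.05 +/- 0.27, beta 0.68 +/- 0.37;
#' and eta 0.14 +/- 0.11, kappa -0.34 +/- 0.27, beta 0.93 +/- 0.47).
#'
#' @param preset `"DYT"`, `"CTL"` or `"custom"`.
#' @param n_agents Number of agents (default 13, the study group size).
#' @param model Generating model for the agents (presets use
#'   `"ASYMMETRIC"`).
#' @param param_dists For `"custom"`: named list with entries `eta`, `kappa`,
#'   `beta` (and optionally `a`), each `c(mean =, sd =)` parent moments of
#'   the truncated normal. `sd = 0` fixes the parameter.
#' @param severity_link Optional list with `intercept`, `slope`, `noise_sd`
#'   (see [severity_link_preset()]); `NULL` disables severity scores.
#' @param schedule_seed,cohort_seed Integer seeds for the canonical schedule
#'   and for parameter/agent-level randomness.
#' @param kappa_limit Truncation half-width for `kappa` (fitting bounds).
#' @return An object of class `rl_cohort_spec`.
#' @export
cohort_spec <- function(preset = c("CTL", "DYT", "custom"), n_agents = 13,
                        model = "ASYMMETRIC", param_dists = NULL,
                        severity_link = NULL, schedule_seed = 1L,
                        cohort_seed = 1L, kappa_limit = 1) {
  preset <- match.arg(preset)
  if (preset != "custom") {
    param_dists <- GROUP_PRESETS[[preset]]
  } else if (is.null(param_dists)) {
    stop("custom cohorts must supply `param_dists`")
  }
  stopifnot(n_agents >= 1)
  for (p in param_dists) {
    if (!all(is.finite(p)) || p[["sd"]] < 0)
      stop("invalid distribution moments (need finite mean and sd >= 0)")
  }
  if (!is.null(severity_link))
    stopifnot(is.finite(severity_link$noise_sd), severity_link$noise_sd >= 0)
  structure(
    list(label = preset, n_agents = as.integer(n_agents), model = model,
         param_dists = param_dists, severity_link = severity_link,
         schedule_seed = as.integer(schedule_seed),
         cohort_seed = as.integer(cohort_seed), kappa_limit = kappa_limit),
    class = "rl_cohort_spec"
  )
}

#' Simulate one agent on a schedule
#'
#' Replays the schedule: on choice trials the agent samples a cue from the
#' softmax over its current values; on forced trials it takes the single
#' offered cue. Sure cues pay their fixed amount; every risky delivery
#' consumes the next entry of the schedule's counterbalanced outcome
#' sequence. The chosen cue's value is updated after every trial under the
#' agent's model. Fully reproducible from `(params, schedule, seed)`; agents
#' never abort.
#'
#' @param params An `rl_params`.
#' @param schedule An `rl_schedule`.
#' @param seed Integer seed.
#' @param agent_id Identifier stored on the session.
#' @return An object of class `rl_session`: list with `agent_id`,
#'   `true_params`, `records` (data frame with `index`, `chosen`, `reward`,
#'   `delta`, `p_chosen`, `v_risky`, `aborted`) and `severity` (`NA` unless
#'   set later).
#' @export
simulate_session <- function(params, schedule, seed, agent_id = NA) {
  stopifnot(inherits(params, "rl_params"), inherits(schedule, "rl_schedule"))
  tr <- schedule$trials
  n <- nrow(tr)
  ca <- match(tr$cue_left, CUE_LEVELS)
  cb <- match(tr$cue_right, CUE_LEVELS)
  forced_cue <- ifelse(is.na(ca), cb, ca)
  is_choice <- tr$kind == "CHOICE"
  ro <- schedule$risky_outcomes
  eta <- params$eta; kappa <- params$kappa; beta <- params$beta
  model <- params$model
  a_curv <- params$a
  risky_code <- match("RISKY", CUE_LEVELS)
  payoff_by_code <- c(0, 5, 10, NA)

  withr::with_seed(as.integer(seed), {
    V <- numeric(4)
    u <- runif(n)  # one draw per trial; forced trials ignore theirs
    chosen <- integer(n); reward <- numeric(n)
    delta <- numeric(n); p_chosen <- numeric(n); v_risky <- numeric(n)
    ri <- 0L
    for (t in seq_len(n)) {
      v_risky[t] <- V[risky_code]
      if (is_choice[t]) {
        aa <- ca[t]; bb <- cb[t]
        x <- beta * (V[aa] - V[bb])
        p_a <- if (x >= 0) 1 / (1 + exp(-x)) else exp(x) / (1 + exp(x))
        if (u[t] < p_a) {
          ch <- aa; p_chosen[t] <- p_a
        } else {
          ch <- bb; p_chosen[t] <- 1 - p_a
        }
      } else {
        ch <- forced_cue[t]
        p_chosen[t] <- 1
      }
      if (ch == risky_code) {
        ri <- ri + 1L
        if (ri > length(ro))
          stop("risky-outcome sequence exhausted: schedule construction defect")
        r <- ro[ri]
      } else {
        r <- payoff_by_code[ch]
      }
      r_eff <- if (model == "UTILITY" && r == 10) 10 * a_curv else r
      d <- r_eff - V[ch]
      fac <- if (model == "ASYMMETRIC") {
        if (d > 0) 1 + kappa else if (d < 0) 1 - kappa else 1
      } else 1
      lr <- if (model == "WSLS") 1 else eta
      V[ch] <- V[ch] + lr * d * fac
      chosen[t] <- ch; reward[t] <- r; delta[t] <- d
    }
    structure(
      list(agent_id = agent_id, true_params = params,
           records = data.frame(
             index = tr$index, chosen = CUE_LEVELS[chosen], reward = reward,
             delta = delta, p_chosen = p_chosen, v_risky = v_risky,
             aborted = FALSE, stringsAsFactors = FALSE),
           severity = NA_real_, n_risky_consumed = ri),
      class = "rl_session"
    )
  })
}

#' @export
print.rl_session <- function(x, ...) {
  cat("<rl_session> agent ", format(x$agent_id), ": ", nrow(x$records),
      " records, ", x$n_risky_consumed %||% sum(x$records$chosen == "RISKY"),
      " risky deliveries\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a cohort of agents
#'
#' Draws each agent's true parameters independently from the cohort's
#' truncated normals (truncation at the fitting bounds: eta `[0, 1]`, kappa
#' `[-kappa_limit, kappa_limit]`, beta `[0, 30]`, a `[0, 3]`), simulates
#' every agent on the cohort's shared canonical schedule, and, when a
#' severity link is set, attaches `severity = intercept + slope * kappa_true
#' + N(0, noise_sd)` truncated at 0. Per-agent seeds derive deterministically
#' from `cohort_seed`.
#'
#' @param spec An `rl_cohort_spec`.
#' @param schedule Optional prebuilt `rl_schedule`; defaults to
#'   `build_schedule(spec$schedule_seed)`.
#' @return An object of class `rl_cohort`: list with `sessions` (list of
#'   `rl_session`), `manifest` (data frame of agent id, true parameters,
#'   severity), `schedule` and `spec`.
#' @export
simulate_cohort <- function(spec, schedule = NULL) {
  stopifnot(inherits(spec, "rl_cohort_spec"))
  if (is.null(schedule)) schedule <- build_schedule(spec$schedule_seed)
  n <- spec$n_agents
  pd <- spec$param_dists
  draws <- withr::with_seed(spec$cohort_seed, {
    eta <- r_truncnorm(n, pd$eta[["mean"]], pd$eta[["sd"]], 0, 1)
    kappa <- if (spec$model == "ASYMMETRIC") {
      r_truncnorm(n, pd$kappa[["mean"]], pd$kappa[["sd"]],
                  -spec$kappa_limit, spec$kappa_limit)
    } else rep(0, n)
    beta <- r_truncnorm(n, pd$beta[["mean"]], pd$beta[["sd"]], 0, 30)
    a <- if (spec$model == "UTILITY") {
      r_truncnorm(n, pd$a[["mean"]], pd$a[["sd"]], 0, 3)
    } else rep(1, n)
    seeds <- sample.int(.Machine$integer.max, n)
    severity <- rep(NA_real_, n)
    if (!is.null(spec$severity_link)) {
      sl <- spec$severity_link
      severity <- pmax(0, sl$intercept + sl$slope * kappa +
                         rnorm(n, 0, sl$noise_sd))
    }
    list(eta = eta, kappa = kappa, beta = beta, a = a, seeds = seeds,
         severity = severity)
  })
  sessions <- lapply(seq_len(n), function(i) {
    p <- rl_params(spec$model, eta = draws$eta[i], kappa = draws$kappa[i],
                   beta = draws$beta[i], a = draws$a[i],
                   kappa_limit = spec$kappa_limit)
    s <- simulate_session(p, schedule, seed = draws$seeds[i], agent_id = i)
    s$severity <- draws$severity[i]
    s
  })
  manifest <- data.frame(
    agent_id = seq_len(n), model = spec$model, eta = draws$eta,
    kappa = draws$kappa, beta = draws$beta, a = draws$a,
    severity = draws$severity, seed = draws$seeds
  )
  structure(list(sessions = sessions, manifest = manifest,
                 schedule = schedule, spec = spec),
            class = "rl_cohort")
}

#' @export
print.rl_cohort <- function(x, ...) {
  cat("<rl_cohort> ", x$spec$label, "-like, ", length(x$sessions),
      " agents (model ", x$spec$model, "), schedule seed ",
      x$spec$schedule_seed, "\n", sep = "")
  invisible(x)
}

#' Mean choice-probability curves at fixed parameters
#'
#' Runs `n_runs` independent sessions at one parameter setting and returns
#' the across-run mean probability of choosing the risky cue on each
#' successive risky-vs-5c choice trial, plus the mean learned value of the
#' risky cue before every trial of the schedule.
#'
#' @param group_params An `rl_params` (e.g. a group's mean parameters).
#' @param schedule An `rl_schedule`.
#' @param n_runs Number of independent runs.
#' @param seed Integer seed.
#' @return List with `p_risky_curve` (length = number of risky-vs-5c choice
#'   trials), `v_risky_curve` (length = number of trials) and `n_runs`.
#' @export
simulate_group_mean_runs <- function(group_params, schedule, n_runs, seed) {
  stopifnot(n_runs >= 1)
  tr <- schedule$trials
  risky5 <- which(tr$kind == "CHOICE" &
                    pair_key(tr$cue_left, tr$cue_right) ==
                    pair_key("SURE5", "RISKY"))
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max, n_runs))
  p_acc <- numeric(length(risky5))
  v_acc <- numeric(nrow(tr))
  for (i in seq_len(n_runs)) {
    s <- simulate_session(group_params, schedule, seeds[i])
    p_acc <- p_acc + (s$records$chosen[risky5] == "RISKY")
    v_acc <- v_acc + s$records$v_risky
  }
  list(p_risky_curve = p_acc / n_runs, v_risky_curve = v_acc / n_runs,
       n_runs = n_runs)
}

#' Write / read sessions and cohorts as TSV
#'
#' `write_session()` stores one session log (`index phase kind cue_left
#' cue_right chosen reward aborted`); `read_session()` restores it against a
#' schedule. `write_cohort()` writes one log per agent plus a manifest
#' (`manifest.tsv`) of agent ids, true parameters and severity.
#'
#' @param session An `rl_session`.
#' @param schedule The matching `rl_schedule`.
#' @param path Output file path (for a session) or directory (for a cohort).
#' @return The written path, invisibly; readers return the restored object.
#' @export
write_session <- function(session, schedule, path) {
  rec <- session$records
  tr <- schedule$trials
  out <- data.frame(index = tr$index, phase = tr$phase, kind = tr$kind,
                    cue_left = tr$cue_left, cue_right = tr$cue_right,
                    chosen = ifelse(rec$aborted, "", rec$chosen),
                    reward = ifelse(rec$aborted, "", as.integer(rec$reward)),
                    aborted = as.integer(rec$aborted))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @param agent_id,severity Metadata attached to the restored session.
#' @rdname write_session
#' @export
read_session <- function(path, schedule, agent_id = NA, severity = NA_real_) {
  log <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "")
  rec <- data.frame(index = log$index, chosen = log$chosen,
                    reward = ifelse(is.na(log$reward), 0, log$reward),
                    aborted = log$aborted == 1, stringsAsFactors = FALSE)
  # fail early if the log does not match the schedule
  invisible(prep_replay(schedule, rec))
  structure(list(agent_id = agent_id, true_params = NULL, records = rec,
                 severity = severity),
            class = "rl_session")
}

#' @param cohort An `rl_cohort`.
#' @param dir Output directory for the cohort.
#' @rdname write_session
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rl_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_schedule(cohort$schedule, dir)
  write.table(cohort$manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (s in cohort$sessions)
    write_session(s, cohort$schedule,
                  file.path(dir, sprintf("agent_%03d.tsv", s$agent_id)))
  invisible(dir)
}
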