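# Candidate learning models. All four share softmax action selection with
# inverse temperature beta (units 1/cent) over learned values initialized at
# 0, and differ only in the value update:
#   ASYMMETRIC  V <- V + eta * delta * (1 + kappa) for delta > 0,
#               V <- V + eta * delta * (1 - kappa) for delta < 0
#   CLASSICAL   V <- V + eta * (r - V)
#   UTILITY     V <- V + eta * (U(r) - V), U(0)=0, U(5)=5, U(10)=10a
#   WSLS        classical with eta fixed at 1 (win-stay-lose-shift)

MODEL_LEVELS <- c("ASYMMETRIC", "CLASSICAL", "UTILITY", "WSLS")
MODEL_CODES <- c(ASYMMETRIC = 1L, CLASSICAL = 2L, UTILITY = 3L, WSLS = 4L)

#' Model parameter sets
#'
#' Bundles a model identifier with its parameters. `CLASSICAL` fixes the
#' asymmetry `kappa` at 0; `WSLS` additionally fixes the learning rate `eta`
#' at 1; `UTILITY` fixes `kappa = 0` and carries the free utility curvature
#' `a` (subjective value of the 10c payoff is `10 * a`).
#'
#' @param model One of `"ASYMMETRIC"`, `"CLASSICAL"`, `"UTILITY"`, `"WSLS"`.
#' @param eta Learning rate in `[0, 1]` (ignored/forced to 1 for `WSLS`).
#' @param kappa Learning asymmetry: the learning rate is scaled by
#'   `(1 + kappa)` after positive and `(1 - kappa)` after negative prediction
#'   errors. Must lie within `[-kappa_limit, kappa_limit]`.
#' @param beta Softmax inverse temperature in `[0, 30]`, units 1/cent.
#' @param a Utility curvature (UTILITY model only), in `[0, 3]`.
#' @param kappa_limit Half-width of the admissible kappa range. The default 1
#'   keeps effective learning rates `eta * (1 +/- kappa)` in `[0, 2 * eta]`;
#'   values up to 10 are accepted but `|kappa| > 1` triggers a warning since
#'   the effective learning rate then changes sign.
#' @return An object of class `rl_params`.
#' @examples
#' rl_params("ASYMMETRIC", eta = 0.25, kappa = -0.05, beta = 0.68)
#' @export
rl_params <- function(model, eta = NULL, kappa = 0, beta, a = 1,
                      kappa_limit = 1) {
  model <- match.arg(model, MODEL_LEVELS)
  if (model == "WSLS") {
    if (is.null(eta)) eta <- 1
    if (eta != 1) stop("WSLS fixes the learning rate at 1")
  }
  if (is.null(eta)) stop("`eta` is required for model ", model)
  stopifnot(is.finite(eta), is.finite(kappa), is.finite(beta), is.finite(a),
            kappa_limit > 0, kappa_limit <= 10)
  if (eta < 0 || eta > 1) stop("`eta` must lie in [0, 1]")
  if (beta < 0 || beta > 30) stop("`beta` must lie in [0, 30]")
  if (a < 0 || a > 3) stop("`a` must lie in [0, 3]")
  if (model != "ASYMMETRIC" && kappa != 0)
    stop("model ", model, " fixes `kappa` at 0")
  if (abs(kappa) > kappa_limit)
    stop("`kappa` outside [-", kappa_limit, ", ", kappa_limit, "]")
  if (abs(kappa) > 1)
    warning("|kappa| > 1: effective learning rate eta * (1 - |kappa|) is ",
            "negative, inverting updates after one sign of prediction error")
  structure(list(model = model, eta = eta, kappa = kappa, beta = beta, a = a),
            class = "rl_params")
}

#' @export
print.rl_params <- function(x, ...) {
  extra <- switch(x$model,
    ASYMMETRIC = sprintf(", kappa = %.4g", x$kappa),
    UTILITY = sprintf(", a = %.4g", x$a),
    "")
  cat(sprintf("<rl_params> %s: eta = %.4g, beta = %.4g%s\n",
              x$model, x$eta, x$beta, extra))
  invisible(x)
}

#' Subjective utility of a task payoff
#'
#' Piecewise utility over the task's three outcomes, anchored at
#' `U(0) = 0` and `U(5) = 5` with `U(10) = 10 * a`. `a < 1` makes the risky
#' cue worth less than its expected value and so produces risk aversion.
#'
#' @param a Utility curvature.
#' @param reward Payoff(s) in cents; must be 0, 5 or 10.
#' @return Utility in the same scale as cents.
#' @export
utility <- function(a, reward) {
  stopifnot(is.finite(a), all(is.finite(reward)))
  if (!all(reward %in% c(0, 5, 10)))
    stop("rewards outside the task's support {0, 5, 10}")
  ifelse(reward == 10, 10 * a, reward)
}

#' Softmax probability of choosing option A
#'
#' Logistic in `beta * (v_a - v_b)`, evaluated via the value difference so it
#' is numerically stable for any magnitude of values.
#'
#' @param beta Inverse temperature, `beta >= 0`.
#' @param v_a,v_b Learned values (cents) of options A and B.
#' @return `P(choose A)`; `choice_prob(beta, v_a, v_b) +
#'   choice_prob(beta, v_b, v_a)` is 1.
#' @export
choice_prob <- function(beta, v_a, v_b) {
  if (any(!is.finite(beta)) || any(beta < 0))
    stop("`beta` must be finite and nonnegative")
  stats::plogis(beta * (v_a - v_b))
}

#' One value update
#'
#' Applies a single learning step for the chosen cue under the given model
#' (see [rl_params()] for the update rules). A zero prediction error leaves
#' the value unchanged under every model.
#'
#' @param params An `rl_params`.
#' @param v_old Current learned value (cents; utility units for UTILITY).
#' @param reward Obtained payoff in cents.
#' @return Updated value (vectorized over `v_old` / `reward`).
#' @export
update_value <- function(params, v_old, reward) {
  stopifnot(inherits(params, "rl_params"))
  if (!all(is.finite(v_old)) || !all(is.finite(reward)))
    stop("non-finite value or reward")
  r_eff <- if (params$model == "UTILITY") utility(params$a, reward) else reward
  delta <- r_eff - v_old
  fac <- if (params$model == "ASYMMETRIC") {
    ifelse(delta > 0, 1 + params$kappa, ifelse(delta < 0, 1 - params$kappa, 1))
  } else 1
  v_old + params$eta * delta * fac
}

# Precompute integer-coded vectors for the C++ replay. Accepts an rl_session
# or a bare records data frame with columns chosen / reward / aborted.
prep_replay <- function(schedule, session) {
  records <- if (inherits(session, "rl_session")) session$records else session
  tr <- schedule$trials
  if (nrow(records) != nrow(tr))
    stop("session has ", nrow(records), " records but the schedule has ",
         nrow(tr), " trials")
  aborted <- as.logical(records$aborted)
  chosen <- match(records$chosen, CUE_LEVELS)
  cue_a <- match(tr$cue_left, CUE_LEVELS)
  cue_b <- match(tr$cue_right, CUE_LEVELS)
  forced <- tr$kind == "FORCED"
  # forced trials: the single cue goes in slot a
  cue_a[forced] <- ifelse(is.na(cue_a[forced]), cue_b[forced], cue_a[forced])
  cue_b[forced] <- 0L
  cue_b[is.na(cue_b)] <- 0L
  live <- !aborted
  if (any(is.na(chosen[live])))
    stop("non-aborted records must carry a chosen cue")
  ok <- chosen[live] == cue_a[live] |
    (cue_b[live] > 0L & chosen[live] == cue_b[live])
  if (!all(ok))
    stop("record chooses a cue not offered on its trial (first at index ",
         tr$index[live][which(!ok)[1]], ")")
  chosen[!live] <- 0L
  reward <- as.numeric(records$reward)
  reward[!live] <- 0
  if (!all(reward[live] %in% c(0, 5, 10)))
    stop("rewards outside the task's support {0, 5, 10}")
  list(cue_a = as.integer(cue_a), cue_b = as.integer(cue_b),
       is_choice = tr$kind == "CHOICE", chosen = as.integer(chosen),
       reward = reward, aborted = aborted,
       n_choice = sum(tr$kind == "CHOICE" & live))
}

nll_from_prep <- function(prep, model, eta, kappa, beta, a) {
  replay_negloglik_cpp(prep$cue_a, prep$cue_b, prep$is_choice, prep$chosen,
                       prep$reward, prep$aborted,
                       MODEL_CODES[[model]], eta, kappa, beta, a)
}

#' Negative log-likelihood of a session
#'
#' Replays the session trial by trial from zero-initialized cue values.
#' Every non-aborted trial updates the chosen cue's value from its observed
#' reward; every non-aborted choice trial (training and test alike)
#' contributes `-log p(chosen)` under the softmax; forced and aborted trials
#' contribute no likelihood (forced trials still drive learning).
#' Probabilities are floored at 1e-12 before the logarithm.
#'
#' @param params An `rl_params`.
#' @param schedule The `rl_schedule` the session was recorded on.
#' @param session An `rl_session`, or a data frame with columns `chosen`,
#'   `reward`, `aborted` aligned with the schedule's trials.
#' @return Nonnegative scalar negative log-likelihood (nats).
#' @export
session_negloglik <- function(params, schedule, session) {
  stopifnot(inherits(params, "rl_params"), inherits(schedule, "rl_schedule"))
  prep <- prep_replay(schedule, session)
  nll_from_prep(prep, params$model, params$eta, params$kappa, params$beta,
                params$a)
}
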