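# Behavioral summaries of session logs: risky-choice proportions (overall,
# binned, and conditioned on the previous risky outcome), learning-curve
# accuracies for the unambiguous cue pairs, and the nonparametric group
# statistics used to compare cohorts.

RISKY5_KEY <- "RISKY:SURE5"

bin_means <- function(x, width) {
  if (length(x) == 0) return(numeric(0))
  unname(vapply(split(x, ceiling(seq_along(x) / width)), mean, 0))
}

# which cue wins an unambiguous pair (higher expected value; the risky cue
# dominates sure 0 and is dominated by sure 10)
correct_cue <- function(cue_left, cue_right) {
  ev <- function(cue) ifelse(cue == "RISKY", 5, SURE_PAYOFF[cue])
  ifelse(ev(cue_left) > ev(cue_right), cue_left, cue_right)
}

#' Summarize one session's choice behavior
#'
#' Computes the standard behavioral measures from a session log: the overall
#' and binned proportion of risky choices on risky-vs-5c test trials (bins
#' of 15 scoreable trials in schedule order), accuracy on sure-cue pairs
#' (bins of 15) and on pairs where the risky cue is dominated (risky-vs-0c
#' and risky-vs-10c, bins of 20), accuracy on the first 5 test-phase
#' sure-pair choice trials, and the probability of choosing the risky cue
#' conditioned on the outcome of the most recent prior risky delivery
#' (forced or choice; 10c counts as a win, 0c as a loss). Risky-vs-5c trials
#' with no prior risky delivery are excluded from the conditional tallies.
#' Aborted trials are skipped entirely.
#'
#' @param session An `rl_session`.
#' @param schedule The matching `rl_schedule`.
#' @return An object of class `rl_behavior`: scalar proportions
#'   (`overall_risky_prop`, `p_risky_after_win`, `p_risky_after_loss`,
#'   `first5_sure_accuracy`), bin vectors (`risky_prop_per_block`,
#'   `sure_pair_accuracy_per_block`, `risky_dominated_accuracy_per_block`)
#'   and the conditional tally counts.
#' @export
summarize_session <- function(session, schedule) {
  stopifnot(inherits(schedule, "rl_schedule"))
  rec <- if (inherits(session, "rl_session")) session$records else session
  tr <- schedule$trials
  if (nrow(rec) != nrow(tr))
    stop("session inconsistent with schedule: ", nrow(rec), " records vs ",
         nrow(tr), " trials")
  live <- !rec$aborted
  is_choice <- tr$kind == "CHOICE"
  pk <- ifelse(is_choice, pair_key(tr$cue_left, tr$cue_right), "")
  chose_risky <- rec$chosen == "RISKY"

  # risky-vs-5c measures (test phase)
  r5_test <- which(pk == RISKY5_KEY & tr$phase == "TEST" & live)
  risky_bins <- bin_means(chose_risky[r5_test], 15)
  overall <- if (length(r5_test)) mean(chose_risky[r5_test]) else NaN

  # sure-pair and dominated-pair learning curves (test phase)
  sure_keys <- c(pair_key("SURE0", "SURE5"), pair_key("SURE5", "SURE10"))
  dom_keys <- c(pair_key("SURE0", "RISKY"), pair_key("SURE10", "RISKY"))
  corr <- rec$chosen == correct_cue(tr$cue_left, tr$cue_right)
  sure_idx <- which(pk %in% sure_keys & tr$phase == "TEST" & live)
  dom_idx <- which(pk %in% dom_keys & tr$phase == "TEST" & live)
  first5 <- if (length(sure_idx))
    mean(corr[sure_idx[seq_len(min(5, length(sure_idx)))]]) else NaN

  # conditional risky choice given the last risky delivery (any phase)
  cond <- conditional_risky_tally(rec, tr)

  structure(
    list(agent_id = if (inherits(session, "rl_session")) session$agent_id
         else NA,
         overall_risky_prop = overall,
         risky_prop_per_block = risky_bins,
         sure_pair_accuracy_per_block = bin_means(corr[sure_idx], 15),
         risky_dominated_accuracy_per_block = bin_means(corr[dom_idx], 20),
         first5_sure_accuracy = first5,
         p_risky_after_win = cond$p_win,
         p_risky_after_loss = cond$p_loss,
         n_after_win = cond$n_win, n_after_loss = cond$n_loss),
    class = "rl_behavior"
  )
}

# Scan the log once, tracking the outcome (and trial kind) of the most
# recent risky delivery; tally risky-vs-5c choices by that conditioning.
conditional_risky_tally <- function(rec, tr, by_context = FALSE) {
  live <- !rec$aborted
  is_choice <- tr$kind == "CHOICE"
  pk <- ifelse(is_choice, pair_key(tr$cue_left, tr$cue_right), "")
  last_out <- NA_real_
  last_ctx <- NA_character_
  hit <- list(win = c(0, 0), loss = c(0, 0),
              win_FORCED = c(0, 0), win_CHOICE = c(0, 0),
              loss_FORCED = c(0, 0), loss_CHOICE = c(0, 0))
  for (t in seq_len(nrow(rec))) {
    if (live[t] && pk[t] == RISKY5_KEY && !is.na(last_out)) {
      out <- if (last_out == 10) "win" else "loss"
      took <- as.numeric(rec$chosen[t] == "RISKY")
      hit[[out]] <- hit[[out]] + c(took, 1)
      key <- paste0(out, "_", last_ctx)
      hit[[key]] <- hit[[key]] + c(took, 1)
    }
    if (live[t] && identical(rec$chosen[t], "RISKY")) {
      last_out <- rec$reward[t]
      last_ctx <- tr$kind[t]
    }
  }
  ratio <- function(v) if (v[2] > 0) v[1] / v[2] else NaN
  out <- list(p_win = ratio(hit$win), p_loss = ratio(hit$loss),
              n_win = hit$win[2], n_loss = hit$loss[2])
  if (by_context) {
    out$by_context <- data.frame(
      outcome = rep(c("win", "loss"), each = 2),
      context = rep(c("FORCED", "CHOICE"), 2),
      p_risky = c(ratio(hit$win_FORCED), ratio(hit$win_CHOICE),
                  ratio(hit$loss_FORCED), ratio(hit$loss_CHOICE)),
      n = c(hit$win_FORCED[2], hit$win_CHOICE[2],
            hit$loss_FORCED[2], hit$loss_CHOICE[2]))
    out$empty_strata <- out$by_context$n == 0
  }
  out
}

#' Conditional risky choice split by conditioning context
#'
#' As the win/loss conditioning of [summarize_session()], additionally split
#' by whether the conditioning risky outcome was delivered on a forced or a
#' choice trial. Strata with no observations are reported as `NaN` and
#' flagged.
#'
#' @inheritParams summarize_session
#' @return List with `by_context` (data frame `outcome`, `context`,
#'   `p_risky`, `n`) and `empty_strata` (logical flags per row).
#' @export
conditional_by_context <- function(session, schedule) {
  rec <- if (inherits(session, "rl_session")) session$records else session
  tr <- schedule$trials
  if (nrow(rec) != nrow(tr))
    stop("session inconsistent with schedule")
  cond <- conditional_risky_tally(rec, tr, by_context = TRUE)
  cond[c("by_context", "empty_strata")]
}

#' Summarize every agent of a cohort
#'
#' @param cohort An `rl_cohort`.
#' @return List with `table` (one row per agent: scalar behavioral measures
#'   plus true parameters and severity from the manifest), and matrices
#'   `risky_prop_per_block`, `sure_pair_accuracy_per_block`,
#'   `risky_dominated_accuracy_per_block` (agents in rows, bins in columns).
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "rl_cohort"))
  sums <- lapply(cohort$sessions, summarize_session, schedule = cohort$schedule)
  table <- data.frame(
    agent_id = vapply(sums, function(s) s$agent_id, 0),
    overall_risky_prop = vapply(sums, `[[`, 0, "overall_risky_prop"),
    p_risky_after_win = vapply(sums, `[[`, 0, "p_risky_after_win"),
    p_risky_after_loss = vapply(sums, `[[`, 0, "p_risky_after_loss"),
    first5_sure_accuracy = vapply(sums, `[[`, 0, "first5_sure_accuracy")
  )
  table$kappa_true <- cohort$manifest$kappa
  table$severity <- cohort$manifest$severity
  list(table = table,
       risky_prop_per_block =
         do.call(rbind, lapply(sums, `[[`, "risky_prop_per_block")),
       sure_pair_accuracy_per_block =
         do.call(rbind, lapply(sums, `[[`, "sure_pair_accuracy_per_block")),
       risky_dominated_accuracy_per_block =
         do.call(rbind, lapply(sums,
                               `[[`, "risky_dominated_accuracy_per_block")),
       summaries = sums)
}

# tie-corrected normal-approximation z for the Mann-Whitney U statistic
mann_whitney_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- if (sigma2 > 0) (U1 - mu) / sqrt(sigma2) else 0
  list(U = U1, z = z)
}

#' Nonparametric comparison of two groups
#'
#' Two-sided Mann-Whitney U test for independent groups (exact enumeration
#' when the combined sample size is at most 20 and the data are tie-free,
#' tie-corrected normal approximation otherwise; the z statistic is always
#' reported), or the Wilcoxon signed-rank test for paired within-group
#' comparisons.
#'
#' @param x,y Numeric measure vectors for the two groups (equal length when
#'   `paired = TRUE`).
#' @param paired Use the Wilcoxon signed-rank test for repeated measures.
#' @param alternative Passed to the test (`"two.sided"` default).
#' @return List with `method`, `statistic` (U or V), `z`, `p`, and group
#'   sizes.
#' @export
group_compare <- function(x, y, paired = FALSE,
                          alternative = "two.sided") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations")
  if (paired) {
    if (length(x) != length(y)) stop("paired groups must have equal length")
    wt <- suppressWarnings(
      wilcox.test(x, y, paired = TRUE, alternative = alternative))
    d <- x - y; d <- d[d != 0]
    n <- length(d)
    V <- unname(wt$statistic)
    mu <- n * (n + 1) / 4
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    z <- if (sigma > 0) (V - mu) / sigma else 0
    return(list(method = "wilcoxon_signed_rank", statistic = V, z = z,
                p = wt$p.value, n = length(x)))
  }
  mw <- mann_whitney_z(x, y)
  exact <- (length(x) + length(y)) <= 20 &&
    !any(duplicated(c(x, y)))
  p <- if (exact) {
    wilcox.test(x, y, exact = TRUE, alternative = alternative)$p.value
  } else if (alternative == "two.sided") {
    2 * pnorm(-abs(mw$z))
  } else if (alternative == "greater") {
    pnorm(mw$z, lower.tail = FALSE)
  } else {
    pnorm(mw$z)
  }
  list(method = if (exact) "mann_whitney_exact" else "mann_whitney_normal",
       statistic = mw$U, z = mw$z, p = min(p, 1), n1 = length(x),
       n2 = length(y))
}

#' Pearson correlation with a severity covariate
#'
#' @param x Behavioral measure or fitted asymmetry per agent.
#' @param severities Paired severity scores.
#' @return List with `r`, `df` (`n - 2`) and the two-sided `p` from the t
#'   transform.
#' @export
severity_correlation <- function(x, severities) {
  ok <- !is.na(x) & !is.na(severities)
  x <- x[ok]; severities <- severities[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(severities) == 0)
    stop("zero variance: correlation undefined")
  ct <- cor.test(x, severities, method = "pearson")
  list(r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value)
}

#' Assemble the report tables for one analysis run
#'
#' Writes the learning-curve tables, the risky-choice-by-block table, the
#' conditional win/loss table, the true/fitted parameter table, the
#' model-comparison table, and the schedule-validation summary as TSV files
#' under `dir`. Sections whose inputs are absent are skipped and noted in
#' `MANIFEST.tsv`. Re-running with the same inputs reproduces the files
#' byte for byte.
#'
#' @param cohort An `rl_cohort`.
#' @param summaries Optional output of [summarize_cohort()] (recomputed when
#'   `NULL`).
#' @param fits Optional data frame from [fits_to_table()].
#' @param comparisons Optional `rl_model_selection`.
#' @param dir Output directory.
#' @return Invisibly, the manifest data frame of written/skipped sections.
#' @export
build_report <- function(cohort, summaries = NULL, fits = NULL,
                         comparisons = NULL, dir) {
  stopifnot(inherits(cohort, "rl_cohort"))
  if (is.null(summaries)) summaries <- summarize_cohort(cohort)
  if (!all(summaries$table$agent_id %in% cohort$manifest$agent_id))
    stop("mismatched manifests: summaries cover unknown agents")
  if (!is.null(fits) &&
      !all(fits$agent_id %in% cohort$manifest$agent_id))
    stop("mismatched manifests: fits cover unknown agents")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  emit <- function(section, file, df) {
    write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
    manifest[[length(manifest) + 1]] <<- data.frame(
      section = section, file = file, status = "written")
  }
  skip <- function(section) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      section = section, file = "", status = "skipped: no input")
  }

  curves <- function(m) data.frame(
    bin = seq_len(ncol(m)), mean = colMeans(m, na.rm = TRUE),
    sd = apply(m, 2, sd, na.rm = TRUE))
  emit("learning_curves_sure", "learning_curves_sure.tsv",
       curves(summaries$sure_pair_accuracy_per_block))
  emit("learning_curves_dominated", "learning_curves_dominated.tsv",
       curves(summaries$risky_dominated_accuracy_per_block))
  rb <- summaries$risky_prop_per_block
  emit("risky_by_block", "risky_by_block.tsv",
       data.frame(agent_id = rep(summaries$table$agent_id, ncol(rb)),
                  bin = rep(seq_len(ncol(rb)), each = nrow(rb)),
                  p_risky = as.vector(rb)))
  emit("conditional", "conditional.tsv",
       summaries$table[, c("agent_id", "p_risky_after_win",
                           "p_risky_after_loss")])
  params <- cohort$manifest[, c("agent_id", "model", "eta", "kappa", "beta",
                                "a", "severity")]
  if (!is.null(fits)) {
    emit("parameters", "parameters.tsv",
         merge(params, fits, by = "agent_id",
               suffixes = c("_true", "_hat")))
  } else {
    emit("parameters", "parameters.tsv", params)
  }
  if (!is.null(comparisons)) {
    emit("model_comparison", "model_comparison.tsv", comparisons$per_agent)
  } else {
    skip("model_comparison")
  }
  viol <- validate_schedule(cohort$schedule)
  emit("validation", "validation.tsv",
       data.frame(check = "schedule",
                  status = if (length(viol) == 0) "ok" else "violated",
                  detail = paste(viol, collapse = "; ")))
  manifest <- do.call(rbind, manifest)
  write.table(manifest, file.path(dir, "MANIFEST.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
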