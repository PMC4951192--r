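test_that("conditional win/loss proportions match hand enumeration on a toy log", {
  sch <- toy_schedule(list(
    fo_trial("RISKY"),
    ch_trial("RISKY", "SURE5"),
    ch_trial("RISKY", "SURE5"),
    ch_trial("RISKY", "SURE5")
  ))
  # forced risky wins 10; then risky chosen (pays 0), sure chosen, risky chosen
  rec <- data.frame(index = 0:3,
                    chosen = c("RISKY", "RISKY", "SURE5", "RISKY"),
                    reward = c(10, 0, 5, 0), aborted = FALSE)
  b <- summarize_session(rec, sch)
  expect_equal(b$p_risky_after_win, 1)    # trial 2 conditions on the forced win
  expect_equal(b$p_risky_after_loss, 0.5) # trials 3 and 4 condition on the loss
  expect_identical(b$n_after_win, 1)
  expect_identical(b$n_after_loss, 2)
})

test_that("context split separates forced- and choice-conditioned trials", {
  sch <- toy_schedule(list(
    fo_trial("RISKY"),            # forced win
    ch_trial("RISKY", "SURE5"),   # conditioned on forced win; chooses risky, wins
    ch_trial("RISKY", "SURE5")    # conditioned on a chosen win
  ))
  rec <- data.frame(index = 0:2, chosen = c("RISKY", "RISKY", "SURE5"),
                    reward = c(10, 10, 5), aborted = FALSE)
  cc <- conditional_by_context(rec, sch)
  tab <- cc$by_context
  expect_equal(tab$p_risky[tab$outcome == "win" & tab$context == "FORCED"], 1)
  expect_equal(tab$p_risky[tab$outcome == "win" & tab$context == "CHOICE"], 0)
  expect_true(all(cc$empty_strata[tab$outcome == "loss"]))

  # risky outcomes only on forced trials leave the choice-context cells empty
  sch2 <- toy_schedule(list(fo_trial("RISKY"), ch_trial("RISKY", "SURE5")))
  rec2 <- data.frame(index = 0:1, chosen = c("RISKY", "SURE5"),
                     reward = c(0, 5), aborted = FALSE)
  cc2 <- conditional_by_context(rec2, sch2)
  expect_true(all(cc2$empty_strata[cc2$by_context$context == "CHOICE"]))
})

test_that("a sure-only policy has zero risky proportion", {
  sch <- full_schedule()
  tr <- sch$trials
  chosen <- ifelse(tr$kind == "FORCED",
                   ifelse(is.na(tr$cue_left), tr$cue_right, tr$cue_left),
                   ifelse(tr$cue_left == "RISKY", tr$cue_right, tr$cue_left))
  reward <- ifelse(chosen == "RISKY", 0, rsrl:::SURE_PAYOFF[chosen])
  # forced risky trials still deliver outcomes from the sequence
  risky_idx <- which(chosen == "RISKY")
  reward[risky_idx] <- sch$risky_outcomes[seq_along(risky_idx)]
  rec <- data.frame(index = tr$index, chosen = chosen,
                    reward = unname(reward), aborted = FALSE)
  b <- summarize_session(rec, sch)
  expect_equal(b$overall_risky_prop, 0)
  expect_true(all(b$risky_prop_per_block == 0))
})

test_that("overall risky proportion is the weighted mean of its bins", {
  sch <- full_schedule()
  p <- rl_params("ASYMMETRIC", eta = 0.25, kappa = -0.1, beta = 0.7)
  for (i in 1:5) {
    b <- summarize_session(simulate_session(p, sch, seed = 800 + i), sch)
    counts <- c(rep(15, length(b$risky_prop_per_block) - 1),
                60 - 15 * (length(b$risky_prop_per_block) - 1))
    expect_equal(b$overall_risky_prop,
                 sum(b$risky_prop_per_block * counts) / sum(counts))
    expect_length(b$risky_prop_per_block, 4)
    expect_length(b$sure_pair_accuracy_per_block, 4)
    expect_length(b$risky_dominated_accuracy_per_block, 4)
    expect_true(all(unlist(b[c("overall_risky_prop", "p_risky_after_win",
                               "p_risky_after_loss",
                               "first5_sure_accuracy")]) >= 0))
  }
})

test_that("conditional proportions agree with a brute-force re-scan", {
  sch <- full_schedule()
  tr <- sch$trials
  p <- rl_params("ASYMMETRIC", eta = 0.3, kappa = 0.3, beta = 0.8)
  for (i in 1:4) {
    s <- simulate_session(p, sch, seed = 850 + i)
    b <- summarize_session(s, sch)
    # brute force: for each risky-vs-5 choice, scan backwards for the last
    # risky delivery
    rec <- s$records
    is_r5 <- tr$kind == "CHOICE" &
      (tr$cue_left == "SURE5" & tr$cue_right == "RISKY" |
         tr$cue_left == "RISKY" & tr$cue_right == "SURE5")
    wins <- c(); losses <- c()
    for (t in which(is_r5)) {
      prior <- which(rec$chosen[seq_len(t - 1)] == "RISKY")
      if (length(prior) == 0) next
      out <- rec$reward[max(prior)]
      took <- rec$chosen[t] == "RISKY"
      if (out == 10) wins <- c(wins, took) else losses <- c(losses, took)
    }
    expect_equal(b$p_risky_after_win, mean(wins))
    expect_equal(b$p_risky_after_loss, mean(losses))
  }
})

test_that("Mann-Whitney comparison matches exact enumeration and handles shifts", {
  # complete separation of 3 vs 3 ranks: exact two-sided p = 2/20
  out <- group_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$p, 0.1)
  expect_identical(out$method, "mann_whitney_exact")

  # identical groups: z near 0, p near 1
  x <- c(0.1, 0.25, 0.3, 0.42, 0.5, 0.61, 0.7, 0.77, 0.85, 0.9, 1.1, 1.3, 1.5)
  same <- group_compare(x, x)
  expect_equal(same$z, 0)
  expect_gt(same$p, 0.99)

  # a large shift separates completely
  shifted <- group_compare(x, x + 10)
  expect_lt(shifted$p, 0.001)

  expect_error(group_compare(1, c(1, 2)), "at least 2")
})

test_that("paired Wilcoxon detects a consistent within-agent difference", {
  set.seed(9)
  win <- runif(13, 0.4, 0.8)
  loss <- win - runif(13, 0.05, 0.2)
  out <- group_compare(win, loss, paired = TRUE)
  expect_identical(out$method, "wilcoxon_signed_rank")
  expect_lt(out$p, 0.01)
  expect_gt(out$z, 0)
})

test_that("severity correlation returns Pearson r, df and p", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  out <- severity_correlation(x, 2 + 3 * x)
  expect_equal(out$r, 1)
  expect_equal(out$df, 3)
  out2 <- severity_correlation(x, 2 - 3 * x)
  expect_equal(out2$r, -1)
  expect_error(severity_correlation(x, rep(1, 5)), "variance")
})

test_that("the report bundle writes every declared table deterministically", {
  co <- simulate_cohort(cohort_spec("CTL", n_agents = 3, cohort_seed = 8),
                        schedule = full_schedule())
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  man <- build_report(co, dir = dir1)
  expect_true(all(c("learning_curves_sure.tsv", "risky_by_block.tsv",
                    "conditional.tsv", "parameters.tsv", "validation.tsv",
                    "MANIFEST.tsv") %in% list.files(dir1)))
  expect_true("skipped: no input" %in%
                man$status[man$section == "model_comparison"])
  build_report(co, dir = dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), info = f)
  }
  # mismatched manifests are rejected
  bad_fits <- data.frame(agent_id = 99, model = "ASYMMETRIC", negloglik = 1)
  expect_error(build_report(co, fits = bad_fits, dir = dir1), "mismatch")
})
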