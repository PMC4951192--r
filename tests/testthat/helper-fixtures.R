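# Fixtures built in code: toy schedules and arbitrary (policy-free) session
# records for likelihood tests.

# A miniature schedule from a compact spec: each row of `rows` is
# list(kind, cue_left, cue_right, phase, block).
toy_schedule <- function(rows, risky_outcomes = rep(c(0L, 10L), 8)) {
  trials <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(index = i - 1L, phase = r$phase %||% "TEST",
               kind = r$kind,
               cue_left = r$cue_left %||% NA_character_,
               cue_right = r$cue_right %||% NA_character_,
               block = r$block %||% 1L, stringsAsFactors = FALSE)
  }))
  rl_schedule(trials, risky_outcomes)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

ch_trial <- function(a, b, phase = "TEST", block = 1L)
  list(kind = "CHOICE", cue_left = a, cue_right = b, phase = phase,
       block = block)
fo_trial <- function(cue, phase = "TEST", block = 1L)
  list(kind = "FORCED", cue_left = cue, phase = phase, block = block)

# Records with uniformly random choices among the offered cues and rewards
# drawn from each cue's payoff schedule; not tied to any learning policy.
random_records <- function(schedule, seed) {
  tr <- schedule$trials
  withr::with_seed(seed, {
    chosen <- vapply(seq_len(nrow(tr)), function(t) {
      offered <- stats::na.omit(c(tr$cue_left[t], tr$cue_right[t]))
      if (length(offered) == 1) offered else sample(offered, 1)
    }, "")
    reward <- ifelse(chosen == "RISKY",
                     sample(c(0, 10), nrow(tr), replace = TRUE),
                     rsrl:::SURE_PAYOFF[chosen])
    data.frame(index = tr$index, chosen = chosen, reward = unname(reward),
               aborted = FALSE, stringsAsFactors = FALSE)
  })
}

# shared full-size schedule for the slower suites
full_schedule <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_schedule(5)
    cache
  }
})
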