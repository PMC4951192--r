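# Task schedule: four cues (sure 0, 5, 10 cents and a risky 0/10 cue),
# 16 forced training trials, 10 choice training trials, then 300 test trials
# in two blocks of 150 with a fixed per-block composition. Risky payoffs come
# from a counterbalanced sequence: every epoch of 8 deliveries holds exactly
# four 0s and four 10s.

#' Cue identifiers used throughout the package
#'
#' The four payoff schedules of the task: sure 0, 5 and 10 cents, and the
#' risky cue paying 0 or 10 cents with equal probability (expected value 5).
#'
#' @format Character vector of length 4.
#' @export
CUE_LEVELS <- c("SURE0", "SURE5", "SURE10", "RISKY")

SURE_PAYOFF <- c(SURE0 = 0, SURE5 = 5, SURE10 = 10)

# canonical training / test pair types, in a fixed reference order
PAIR_TYPES <- list(
  c("SURE0", "SURE5"), c("SURE5", "SURE10"),
  c("SURE0", "RISKY"), c("SURE5", "RISKY"), c("SURE10", "RISKY")
)
TEST_CHOICE_COUNTS <- c(15L, 15L, 20L, 30L, 20L)
TEST_FORCED_COUNTS <- c(SURE0 = 12L, SURE5 = 12L, SURE10 = 12L, RISKY = 14L)

# balanced left/right assignment: half left, half right, odd remainder random
balanced_sides <- function(n) {
  n_left <- n %/% 2L + if (n %% 2L == 1L) rbinom(1L, 1L, 0.5) else 0L
  sample(c(rep(TRUE, n_left), rep(FALSE, n - n_left)))
}

make_choice_trials <- function(pairs, counts) {
  rows <- lapply(seq_along(pairs), function(i) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]; n <- counts[i]
    a_left <- balanced_sides(n)
    data.frame(
      kind = rep("CHOICE", n),
      cue_left = ifelse(a_left, a, b),
      cue_right = ifelse(a_left, b, a),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

make_forced_trials <- function(cues, counts) {
  rows <- lapply(seq_along(cues), function(i) {
    n <- counts[i]
    left <- balanced_sides(n)
    data.frame(
      kind = rep("FORCED", n),
      cue_left = ifelse(left, cues[i], NA_character_),
      cue_right = ifelse(left, NA_character_, cues[i]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# upper bound on risky deliveries: every forced risky trial plus every choice
# trial offering the risky cue (a session can at most choose risky on all)
max_risky_deliveries <- function(trials) {
  forced_risky <- trials$kind == "FORCED" &
    (trials$cue_left %in% "RISKY" | trials$cue_right %in% "RISKY")
  choice_risky <- trials$kind == "CHOICE" &
    (trials$cue_left == "RISKY" | trials$cue_right == "RISKY")
  sum(forced_risky, na.rm = TRUE) + sum(choice_risky, na.rm = TRUE)
}

#' Construct a task schedule
#'
#' Builds the full 326-trial session: 16 forced training trials (four per
#' cue), 10 training choice trials (two of each pair type), then two test
#' blocks of 150 trials. Each test block holds 30 risky-vs-5c, 20 risky-vs-0c,
#' 20 risky-vs-10c, 15 0c-vs-5c and 15 5c-vs-10c choice trials, 14 forced
#' risky trials and 12 forced trials per sure cue. Trial order is a seeded
#' shuffle within each phase/block; left/right cue placement is seeded and
#' balanced. A counterbalanced risky-outcome sequence long enough to cover
#' every possible risky delivery is attached.
#'
#' @param seed Nonnegative integer; the same seed always yields an identical
#'   schedule.
#' @return An object of class `rl_schedule`: a list with elements `trials`
#'   (data frame with columns `index`, `phase`, `kind`, `cue_left`,
#'   `cue_right`, `block`), `risky_outcomes` (integer payoff vector in cents)
#'   and `seed`.
#' @examples
#' sch <- build_schedule(7)
#' nrow(sch$trials)            # 326
#' validate_schedule(sch)      # character(0)
#' @export
build_schedule <- function(seed) {
  stopifnot(length(seed) == 1, is.finite(seed), seed >= 0,
            seed == as.integer(seed))
  seed <- as.integer(seed)
  built <- withr::with_seed(seed, {
    tf <- make_forced_trials(CUE_LEVELS, rep(4L, 4L))
    tf <- tf[sample(nrow(tf)), ]
    tf$phase <- "TRAINING_FORCED"; tf$block <- 0L
    tc <- make_choice_trials(PAIR_TYPES, rep(2L, 5L))
    tc <- tc[sample(nrow(tc)), ]
    tc$phase <- "TRAINING_CHOICE"; tc$block <- 0L
    blocks <- lapply(1:2, function(b) {
      blk <- rbind(
        make_choice_trials(PAIR_TYPES, TEST_CHOICE_COUNTS),
        make_forced_trials(names(TEST_FORCED_COUNTS), TEST_FORCED_COUNTS)
      )
      blk <- blk[sample(nrow(blk)), ]
      blk$phase <- "TEST"; blk$block <- as.integer(b)
      blk
    })
    trials <- rbind(tf, tc, blocks[[1]], blocks[[2]])
    rownames(trials) <- NULL
    trials$index <- seq_len(nrow(trials)) - 1L
    trials <- trials[, c("index", "phase", "kind", "cue_left", "cue_right",
                         "block")]
    n_epochs <- as.integer(ceiling(max_risky_deliveries(trials) / 8))
    risky <- draw_risky_outcome_sequence(n_epochs,
                                         sample.int(.Machine$integer.max, 1L))
    list(trials = trials, risky = risky)
  })
  out <- rl_schedule(built$trials, built$risky, seed = seed)
  viol <- validate_schedule(out)
  if (length(viol) > 0)
    stop("internal schedule construction defect: ",
         paste(viol, collapse = "; "))
  out
}

#' Low-level schedule constructor
#'
#' Wraps a trial table and risky-outcome sequence as an `rl_schedule` without
#' enforcing the full task composition, so that reduced schedules (toy
#' examples, ingested logs) can reuse the replay, simulation and summary
#' machinery. Use [validate_schedule()] to check the canonical composition.
#'
#' @param trials Data frame with columns `index`, `phase`, `kind`,
#'   `cue_left`, `cue_right`, `block`.
#' @param risky_outcomes Integer vector of risky payoffs in cents.
#' @param seed Integer stored for provenance (may be `NA`).
#' @return An `rl_schedule` object.
#' @export
rl_schedule <- function(trials, risky_outcomes, seed = NA_integer_) {
  need <- c("index", "phase", "kind", "cue_left", "cue_right", "block")
  stopifnot(is.data.frame(trials), all(need %in% names(trials)))
  structure(
    list(trials = trials[, need],
         risky_outcomes = as.integer(risky_outcomes),
         seed = seed),
    class = "rl_schedule"
  )
}

#' @export
print.rl_schedule <- function(x, ...) {
  cat("<rl_schedule> ", nrow(x$trials), " trials (",
      sum(x$trials$phase != "TEST"), " training, ",
      sum(x$trials$phase == "TEST"), " test), ",
      length(x$risky_outcomes), " counterbalanced risky outcomes, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

#' Draw a counterbalanced risky-outcome sequence
#'
#' Every consecutive epoch of eight payoffs is an independent seeded
#' permutation of four 0c and four 10c outcomes, so any prefix of whole
#' epochs has mean exactly 5 cents.
#'
#' @param n_epochs Positive integer; number of epochs of eight payoffs.
#' @param seed Integer seed.
#' @return Integer vector of length `8 * n_epochs` with values 0 or 10.
#' @export
draw_risky_outcome_sequence <- function(n_epochs, seed) {
  if (length(n_epochs) != 1 || !is.finite(n_epochs) || n_epochs < 1 ||
      n_epochs != as.integer(n_epochs))
    stop("`n_epochs` must be a positive integer")
  withr::with_seed(as.integer(seed), {
    as.integer(unlist(lapply(seq_len(n_epochs), function(i)
      sample(rep(c(0L, 10L), each = 4L)))))
  })
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = ":")
}

#' Validate a schedule against the task composition
#'
#' Checks trial counts per phase and block, the per-block pair composition,
#' choice/forced cue arity, the 4-in-8 risky counterbalance, and that the
#' risky-outcome sequence covers the maximum possible number of deliveries.
#'
#' @param schedule An `rl_schedule`.
#' @return Character vector of human-readable violations; empty when the
#'   schedule satisfies every invariant.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "rl_schedule"))
  tr <- schedule$trials
  ro <- schedule$risky_outcomes
  bad <- character(0)
  note <- function(...) bad <<- c(bad, paste0(...))

  if (nrow(tr) != 326)
    note("expected 326 trials, found ", nrow(tr))
  if (sum(tr$phase == "TRAINING_FORCED") != 16)
    note("expected 16 forced training trials, found ",
         sum(tr$phase == "TRAINING_FORCED"))
  if (sum(tr$phase == "TRAINING_CHOICE") != 10)
    note("expected 10 training choice trials, found ",
         sum(tr$phase == "TRAINING_CHOICE"))
  if (sum(tr$phase == "TEST") != 300)
    note("expected 300 test trials, found ", sum(tr$phase == "TEST"))

  is_choice <- tr$kind == "CHOICE"
  n_cues <- (!is.na(tr$cue_left)) + (!is.na(tr$cue_right))
  if (any(is_choice & n_cues != 2))
    note("choice trials must carry exactly two cues (",
         sum(is_choice & n_cues != 2), " violations)")
  if (any(is_choice & tr$cue_left == tr$cue_right, na.rm = TRUE))
    note("choice trials must offer two distinct cues")
  if (any(!is_choice & n_cues != 1))
    note("forced trials must carry exactly one cue (",
         sum(!is_choice & n_cues != 1), " violations)")

  tf <- tr[tr$phase == "TRAINING_FORCED", ]
  tf_cue <- ifelse(is.na(tf$cue_left), tf$cue_right, tf$cue_left)
  for (cue in CUE_LEVELS)
    if (sum(tf_cue == cue) != 4)
      note("training phase must force each cue 4 times (", cue, ": ",
           sum(tf_cue == cue), ")")

  tc <- tr[tr$phase == "TRAINING_CHOICE", ]
  want_pairs <- vapply(PAIR_TYPES, function(p) pair_key(p[1], p[2]), "")
  tc_pairs <- pair_key(tc$cue_left, tc$cue_right)
  for (pk in want_pairs)
    if (sum(tc_pairs == pk) != 2)
      note("training choice must hold 2 trials of pair ", pk, ", found ",
           sum(tc_pairs == pk))

  for (b in 1:2) {
    blk <- tr[tr$phase == "TEST" & tr$block == b, ]
    if (nrow(blk) != 150) {
      note("test block ", b, " must hold 150 trials, found ", nrow(blk))
      next
    }
    ch <- blk[blk$kind == "CHOICE", ]
    fo <- blk[blk$kind == "FORCED", ]
    if (nrow(ch) != 100)
      note("test block ", b, " must hold 100 choice trials, found ", nrow(ch))
    if (nrow(fo) != 50)
      note("test block ", b, " must hold 50 forced trials, found ", nrow(fo))
    ch_pairs <- pair_key(ch$cue_left, ch$cue_right)
    for (i in seq_along(PAIR_TYPES)) {
      pk <- want_pairs[i]
      if (sum(ch_pairs == pk) != TEST_CHOICE_COUNTS[i])
        note("test block ", b, " must hold ", TEST_CHOICE_COUNTS[i],
             " choice trials of pair ", pk, ", found ", sum(ch_pairs == pk))
    }
    fo_cue <- ifelse(is.na(fo$cue_left), fo$cue_right, fo$cue_left)
    for (cue in names(TEST_FORCED_COUNTS))
      if (sum(fo_cue == cue) != TEST_FORCED_COUNTS[[cue]])
        note("test block ", b, " must hold ", TEST_FORCED_COUNTS[[cue]],
             " forced ", cue, " trials, found ", sum(fo_cue == cue))
  }

  if (length(ro) %% 8 != 0) {
    note("risky-outcome sequence length must be a multiple of 8, found ",
         length(ro))
  } else {
    epoch <- matrix(ro, nrow = 8)
    bad_epochs <- which(colSums(epoch == 0) != 4 | colSums(epoch == 10) != 4)
    for (e in bad_epochs)
      note("risky-outcome epoch ", e,
           " must hold four 0c and four 10c payoffs")
  }
  if (length(ro) < max_risky_deliveries(tr))
    note("risky-outcome sequence (", length(ro),
         ") shorter than the maximum possible deliveries (",
         max_risky_deliveries(tr), ")")

  bad
}

#' Write / read a schedule as TSV
#'
#' `write_schedule()` stores the trial table as `schedule.tsv` and the
#' risky-outcome sequence as `risky_outcomes.tsv` (single column `payoff`)
#' under `dir`; `read_schedule()` restores them losslessly.
#'
#' @param schedule An `rl_schedule`.
#' @param dir Directory path (created if missing).
#' @return `write_schedule()` returns `dir` invisibly; `read_schedule()`
#'   returns an `rl_schedule`.
#' @export
write_schedule <- function(schedule, dir) {
  stopifnot(inherits(schedule, "rl_schedule"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(schedule$trials, file.path(dir, "schedule.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  write.table(data.frame(payoff = schedule$risky_outcomes),
              file.path(dir, "risky_outcomes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @param seed Seed recorded on the restored schedule (not re-derivable from
#'   the files).
#' @rdname write_schedule
#' @export
read_schedule <- function(dir, seed = NA_integer_) {
  tr <- read.delim(file.path(dir, "schedule.tsv"), sep = "\t",
                   stringsAsFactors = FALSE, na.strings = "")
  ro <- read.delim(file.path(dir, "risky_outcomes.tsv"), sep = "\t")$payoff
  rl_schedule(tr, ro, seed = seed)
}
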