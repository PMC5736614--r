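#' Task configuration for the three-stimulus sorting task
#'
#' Builds the configuration of one session of the feedback-learning task: a
#' series of sequences, each presenting three novel stimuli that must be sorted
#' into three squares. A sequence ends after `max_trials_per_sequence` trials
#' or as soon as every stimulus has been placed correctly at least
#' `criterion_correct_per_stimulus` times, whichever comes first.
#'
#' The standard session has 15 sequences of at most 12 trials (180 trials
#' maximum) at the first two measurement waves and 10 sequences (120 trials
#' maximum) at the third; use [task_config_wave()] for those presets. Trial
#' timing is fixation cross (500 ms), stimulus plus response window (2500 ms),
#' feedback (1000 ms), with inter-trial intervals jittered uniformly on
#' `jitter_range_s` seconds.
#'
#' @param n_sequences Number of sequences in a session.
#' @param max_trials_per_sequence Trial cap per sequence.
#' @param criterion_correct_per_stimulus Correct placements per stimulus needed
#'   to end a sequence early.
#' @param fixation_ms,stim_response_ms,feedback_ms Within-trial event durations
#'   in milliseconds.
#' @param jitter_range_s Length-2 numeric, bounds of the uniform inter-trial
#'   jitter in seconds.
#' @return A list of class `"task_config"`.
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$n_sequences * cfg$max_trials_per_sequence # 180-trial cap
task_config <- function(n_sequences = 15L,
                        max_trials_per_sequence = 12L,
                        criterion_correct_per_stimulus = 2L,
                        fixation_ms = 500,
                        stim_response_ms = 2500,
                        feedback_ms = 1000,
                        jitter_range_s = c(0, 6)) {
  stopifnot(
    n_sequences >= 1, max_trials_per_sequence >= 1,
    criterion_correct_per_stimulus >= 1,
    fixation_ms >= 0, stim_response_ms >= 0, feedback_ms >= 0,
    length(jitter_range_s) == 2, all(jitter_range_s >= 0),
    jitter_range_s[1] <= jitter_range_s[2]
  )
  structure(
    list(
      n_sequences = as.integer(n_sequences),
      max_trials_per_sequence = as.integer(max_trials_per_sequence),
      criterion_correct_per_stimulus = as.integer(criterion_correct_per_stimulus),
      fixation_ms = fixation_ms,
      stim_response_ms = stim_response_ms,
      feedback_ms = feedback_ms,
      jitter_range_s = as.numeric(jitter_range_s)
    ),
    class = "task_config"
  )
}

#' @rdname task_config
#' @param wave Measurement wave (1, 2 or 3). Waves 1-2 use 15 sequences; wave 3
#'   uses 10.
#' @export
task_config_wave <- function(wave) {
  stopifnot(wave %in% 1:3)
  task_config(n_sequences = if (wave == 3) 10L else 15L)
}

#' Squares used by the sorting task
#' @keywords internal
task_squares <- function() c("A", "B", "C")

#' Stimulus-to-square rule set
#'
#' A rule set maps the three stimuli of one sequence bijectively onto the three
#' squares.
#'
#' @param assignment Named character vector of length 3: names are stimulus
#'   identifiers, values are squares (a permutation of `"A"`, `"B"`, `"C"`).
#' @return Named character vector of class `"rule_set"`.
#' @export
#' @examples
#' rule_set(c(s1 = "B", s2 = "A", s3 = "C"))
rule_set <- function(assignment) {
  if (length(assignment) != 3 || is.null(names(assignment)) ||
      anyDuplicated(names(assignment)) > 0) {
    stop("assignment must map exactly 3 distinct stimuli", call. = FALSE)
  }
  if (!setequal(unname(assignment), task_squares())) {
    stop("assignment must use each of squares ", paste(task_squares(), collapse = ", "),
         " exactly once", call. = FALSE)
  }
  structure(as.character(assignment), names = names(assignment), class = "rule_set")
}

#' @rdname rule_set
#' @param stimuli Character vector of 3 stimulus identifiers.
#' @details `random_rule_set()` draws a uniformly random bijection using the
#'   current RNG state.
#' @export
random_rule_set <- function(stimuli = c("s1", "s2", "s3")) {
  rule_set(stats::setNames(sample(task_squares()), stimuli))
}

# criterion counters for one sequence
new_sequence_state <- function(stimuli) {
  list(correct_counts = stats::setNames(integer(length(stimuli)), stimuli),
       trials_elapsed = 0L)
}

#' Has the sequence criterion been reached?
#'
#' The criterion ends a sequence early: every stimulus must have been placed in
#' its correct square at least `criterion_correct_per_stimulus` times
#' (default 2).
#'
#' @param state Sequence state as kept by [run_sequence()]: a list with a named
#'   integer vector `correct_counts`.
#' @param config A [task_config()].
#' @return `TRUE` iff every stimulus's correct count meets the criterion.
#' @export
is_criterion_met <- function(state, config) {
  stopifnot(is.list(state), !is.null(state$correct_counts))
  all(state$correct_counts >= config$criterion_correct_per_stimulus)
}

# trial duration in seconds (fixation + stimulus/response + feedback)
trial_duration_s <- function(config) {
  (config$fixation_ms + config$stim_response_ms + config$feedback_ms) / 1000
}

#' Run one sequence of the sorting task
#'
#' Presents the three stimuli of one rule set in permuted blocks (each block is
#' a random permutation of the three stimuli, so no stimulus appears twice
#' before the others appear once), querying `policy` for a square on every
#' trial. The sequence stops at the first trial after which the criterion holds
#' ([is_criterion_met()]), or at `max_trials_per_sequence`.
#'
#' @param rules A [rule_set()].
#' @param policy Function `(stimulus_id, history)` returning a square
#'   identifier, or `NA` for a too-late (omitted) response. `history` is a
#'   data frame of this stimulus's prior trials in the sequence with columns
#'   `chosen_square` and `feedback`.
#' @param config A [task_config()].
#' @param sequence_id Integer sequence label stored in the records.
#' @param t0 Session time (seconds) at which the first trial starts.
#' @return Data frame of trial records with columns `sequence_id`,
#'   `trial_index` (0-based within sequence), `stimulus_id`, `chosen_square`,
#'   `correct_square`, `accuracy`, `feedback` (`"positive"`, `"negative"` or
#'   `"none"`), `too_late`, `onset_s` (trial start) and `feedback_onset_s`.
#'   Too-late trials have `feedback = "none"`, count toward the trial cap but
#'   not toward the criterion.
#' @export
run_sequence <- function(rules, policy, config = task_config(),
                         sequence_id = 1L, t0 = 0) {
  stopifnot(inherits(rules, "rule_set"), is.function(policy))
  stimuli <- names(rules)
  squares <- task_squares()
  max_t <- config$max_trials_per_sequence

  # presentation order: permuted blocks of the 3 stimuli
  n_blocks <- ceiling(max_t / length(stimuli))
  order_all <- unlist(lapply(seq_len(n_blocks), function(i) sample(stimuli)))

  state <- new_sequence_state(stimuli)
  dur <- trial_duration_s(config)
  fb_offset <- (config$fixation_ms + config$stim_response_ms) / 1000

  rec <- vector("list", max_t)
  t_now <- t0
  n_done <- 0L
  hist <- stats::setNames(
    rep(list(data.frame(chosen_square = character(), feedback = character(),
                        stringsAsFactors = FALSE)), length(stimuli)),
    stimuli
  )

  for (i in seq_len(max_t)) {
    stim <- order_all[i]
    choice <- policy(stim, hist[[stim]])
    too_late <- length(choice) == 0 || is.na(choice)
    if (!too_late && !(choice %in% squares)) {
      stop("policy returned invalid square '", choice, "'", call. = FALSE)
    }
    correct_sq <- unname(rules[stim])
    acc <- if (too_late) NA else identical(as.character(choice), correct_sq)
    feedback <- if (too_late) "none" else if (acc) "positive" else "negative"
    if (isTRUE(acc)) {
      state$correct_counts[stim] <- state$correct_counts[stim] + 1L
    }
    state$trials_elapsed <- state$trials_elapsed + 1L

    rec[[i]] <- data.frame(
      sequence_id = as.integer(sequence_id),
      trial_index = i - 1L,
      stimulus_id = stim,
      chosen_square = if (too_late) NA_character_ else as.character(choice),
      correct_square = correct_sq,
      accuracy = acc,
      feedback = feedback,
      too_late = too_late,
      onset_s = t_now,
      feedback_onset_s = t_now + fb_offset,
      stringsAsFactors = FALSE
    )
    hist[[stim]] <- rbind(hist[[stim]],
                          data.frame(chosen_square = rec[[i]]$chosen_square,
                                     feedback = feedback,
                                     stringsAsFactors = FALSE))
    n_done <- i
    t_now <- t_now + dur + stats::runif(1, config$jitter_range_s[1],
                                        config$jitter_range_s[2])
    if (is_criterion_met(state, config)) break
  }
  do.call(rbind, rec[seq_len(n_done)])
}

#' Run a full session of the sorting task
#'
#' Runs `config$n_sequences` sequences back to back, each with a fresh rule set
#' over three new stimuli, concatenating trial records with jittered
#' inter-trial intervals on a common session clock. Stimulus identifiers are
#' made unique across sequences (`"q03_s2"` is stimulus 2 of sequence 3).
#'
#' @param policy_factory Function `(rules)` returning a per-sequence policy
#'   `(stimulus_id, history)` (see [run_sequence()]). [policy_always_correct()],
#'   [policy_never_correct()] and [agent_policy()] are such factories.
#' @param config A [task_config()].
#' @param rules_list Optional list of `config$n_sequences` [rule_set()]s; by
#'   default a random bijection is drawn per sequence.
#' @param seed Optional integer; if given, seeds the RNG so the session is
#'   reproducible bit for bit.
#' @return Data frame of trial records (see [run_sequence()]) for the whole
#'   session, onsets strictly increasing.
#' @export
#' @examples
#' s <- run_session(policy_never_correct, task_config_wave(1), seed = 1)
#' nrow(s) # 180: never reaching criterion exhausts 15 x 12 trials
run_session <- function(policy_factory, config = task_config(),
                        rules_list = NULL, seed = NULL) {
  stopifnot(is.function(policy_factory))
  if (!is.null(seed)) set.seed(seed)
  n_seq <- config$n_sequences
  if (is.null(rules_list)) {
    rules_list <- lapply(seq_len(n_seq), function(q) {
      random_rule_set(sprintf("q%02d_s%d", q, 1:3))
    })
  }
  stopifnot(length(rules_list) == n_seq)
  dur <- trial_duration_s(config)
  out <- vector("list", n_seq)
  t0 <- 0
  for (q in seq_len(n_seq)) {
    rules <- rules_list[[q]]
    trials <- run_sequence(rules, policy_factory(rules), config,
                           sequence_id = q, t0 = t0)
    out[[q]] <- trials
    last <- trials[nrow(trials), ]
    t0 <- last$onset_s + dur +
      stats::runif(1, config$jitter_range_s[1], config$jitter_range_s[2])
  }
  do.call(rbind, out)
}

#' Reference policies
#'
#' Policy factories for testing and calibration: `policy_always_correct()`
#' always sorts into the correct square; `policy_never_correct()` always picks
#' a wrong square, so no sequence ever reaches criterion.
#'
#' @param rules A [rule_set()] for the current sequence.
#' @return A policy function `(stimulus_id, history)`.
#' @export
policy_always_correct <- function(rules) {
  function(stimulus_id, history) unname(rules[stimulus_id])
}

#' @rdname policy_always_correct
#' @export
policy_never_correct <- function(rules) {
  function(stimulus_id, history) {
    setdiff(task_squares(), rules[stimulus_id])[1]
  }
}

#' Write a BIDS-style events table for the feedback events
#'
#' One row per trial, time-locked to feedback presentation with duration 0,
#' matching event-related modelling of the feedback moment.
#'
#' @param trials Trial records from [run_session()] or [run_sequence()].
#' @param labels Optional character vector of trial categories (e.g. from
#'   [classify_session()]), aligned with `trials`; when supplied it becomes the
#'   `trial_type` column, otherwise the feedback valence is used.
#' @param file Optional path; when given the table is written as tab-separated
#'   text with a header (BIDS events convention).
#' @return Data frame with columns `onset`, `duration`, `trial_type` (onsets in
#'   seconds from session start), invisibly when written to file.
#' @export
write_events <- function(trials, labels = NULL, file = NULL) {
  if (nrow(trials) == 0) {
    ev <- data.frame(onset = numeric(), duration = numeric(),
                     trial_type = character(), stringsAsFactors = FALSE)
  } else {
    if (!is.null(labels)) {
      if (length(labels) != nrow(trials) || anyNA(labels)) {
        stop("labels must be complete and aligned with trials", call. = FALSE)
      }
      type <- as.character(labels)
    } else {
      type <- paste0("feedback_", trials$feedback)
    }
    ev <- data.frame(onset = trials$feedback_onset_s, duration = 0,
                     trial_type = type, stringsAsFactors = FALSE)
  }
  if (!is.null(file)) {
    utils::write.table(ev, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(ev))
  }
  ev
}

#' Write or read a trial log
#'
#' Tidy CSV, one row per trial record, `trial_index` 0-based within sequence.
#'
#' @param trials Trial records.
#' @param file Path to write to / read from.
#' @return `read_trials()` returns the trial data frame.
#' @export
write_trials <- function(trials, file) {
  utils::write.csv(trials, file, row.names = FALSE)
  invisible(trials)
}

#' @rdname write_trials
#' @export
read_trials <- function(file) {
  tr <- utils::read.csv(file, stringsAsFactors = FALSE)
  needed <- c("sequence_id", "trial_index", "stimulus_id", "chosen_square",
              "correct_square", "accuracy", "feedback", "too_late")
  missing <- setdiff(needed, names(tr))
  if (length(missing) > 0) {
    stop("trial log is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tr
}
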