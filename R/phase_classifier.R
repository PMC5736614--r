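#' Classify every feedback event by informative value and valence
#'
#' Walks a session stimulus by stimulus, in presentation order, and assigns
#' each trial exactly one category:
#'
#' * `learning_pos` / `learning_neg` — the participant had not yet sorted this
#'   stimulus correctly (feedback still carries informative value) and the
#'   feedback was used on the next presentation of the same stimulus: stay
#'   after positive feedback, any switch after negative feedback. A switch that
#'   lands on the other wrong square still counts as used — feedback use is
#'   stay/switch, not success.
#' * `excluded_nonlearning` — a learning-phase trial whose feedback was not
#'   used on the next presentation (stayed after negative, switched after
#'   positive); excluded from the imaging contrasts but still in the
#'   denominator of the performance statistic.
#' * `application` — the stimulus was already sorted correctly on a previous
#'   trial, is sorted correctly now, and continues to be sorted correctly on
#'   its next presentation (or has no next presentation); feedback carries no
#'   new information.
#' * `no_interest` — too-late trials; learning-phase trials with no later
#'   responded presentation (feedback use undecidable); correct post-criterion
#'   trials whose next presentation is incorrect; and relapses (incorrect
#'   responses after a previous correct sort — a prior correct response exists,
#'   so the trial cannot re-enter the learning phase).
#'
#' "Next presentation" means the next presentation of the same stimulus on
#' which a response was given; too-late presentations cannot reveal whether
#' feedback was used and are skipped when looking ahead.
#'
#' @param trials Trial records for one session (see [run_sequence()]), ordered
#'   by onset. Stimulus identifiers must be unique to their sequence.
#' @param include_unevaluable Logical; if `TRUE`, learning-phase trials with no
#'   later responded presentation are added to the denominator of the
#'   performance statistic (they stay labelled `no_interest`). Default `FALSE`:
#'   feedback use on a trial without a next presentation is undecidable.
#' @return An object of class `"classified_session"`: list with `trials` (the
#'   input plus `category` and `used_next` columns), `counts` (named integer
#'   vector over the five categories), `learning_performance` (percent, `NA`
#'   if no evaluable learning trial), `n_learning_evaluable`, and `flagged`
#'   (`TRUE` when the performance statistic is undefined).
#' @export
#' @examples
#' cfg <- task_config(n_sequences = 2)
#' cl <- classify_session(run_session(policy_always_correct, cfg, seed = 1))
#' cl$learning_performance # 100: a perfect learner always uses feedback
classify_session <- function(trials, include_unevaluable = FALSE) {
  required <- c("stimulus_id", "chosen_square", "accuracy", "feedback", "too_late")
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0) {
    stop("trials are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if ("onset_s" %in% names(trials) && nrow(trials) > 1 &&
      any(diff(trials$onset_s) <= 0)) {
    stop("trial onsets must be strictly increasing within a session",
         call. = FALSE)
  }

  n <- nrow(trials)
  category <- rep(NA_character_, n)
  used_next <- rep(NA, n)

  for (s in unique(trials$stimulus_id)) {
    idx <- which(trials$stimulus_id == s)
    for (j in seq_along(idx)) {
      t <- idx[j]
      if (trials$too_late[t]) {
        category[t] <- "no_interest"
        next
      }
      prior <- idx[seq_len(j - 1)]
      prior_correct <- any(trials$accuracy[prior] %in% TRUE)
      later <- idx[idx > t]
      later <- later[!trials$too_late[later]]
      nxt <- if (length(later) > 0) later[1] else NA_integer_

      if (!prior_correct) {
        if (is.na(nxt)) {
          category[t] <- "no_interest" # unevaluable final learning trial
        } else {
          used <- if (trials$feedback[t] == "positive") {
            trials$chosen_square[nxt] == trials$chosen_square[t]
          } else {
            trials$chosen_square[nxt] != trials$chosen_square[t]
          }
          used_next[t] <- used
          category[t] <- if (!used) "excluded_nonlearning"
            else if (trials$feedback[t] == "positive") "learning_pos"
            else "learning_neg"
        }
      } else {
        if (isTRUE(trials$accuracy[t])) {
          category[t] <- if (is.na(nxt) || isTRUE(trials$accuracy[nxt]))
            "application" else "no_interest"
        } else {
          category[t] <- "no_interest" # relapse after an earlier correct sort
        }
      }
    }
  }

  cats <- c("learning_pos", "learning_neg", "application",
            "excluded_nonlearning", "no_interest")
  counts <- stats::setNames(
    vapply(cats, function(k) sum(category == k), integer(1)), cats)

  n_unevaluable <- if (include_unevaluable) {
    sum(category == "no_interest" & !trials$too_late &
          !vapply(seq_len(n), function(t) {
            idx <- which(trials$stimulus_id == trials$stimulus_id[t])
            any(trials$accuracy[idx[idx < t]] %in% TRUE)
          }, logical(1)))
  } else 0L

  denom <- counts[["learning_pos"]] + counts[["learning_neg"]] +
    counts[["excluded_nonlearning"]] + n_unevaluable
  numer <- counts[["learning_pos"]] + counts[["learning_neg"]]
  perf <- if (denom > 0) 100 * numer / denom else NA_real_

  out <- trials
  out$category <- category
  out$used_next <- used_next
  structure(
    list(trials = out, counts = counts,
         learning_performance = perf,
         n_learning_evaluable = as.integer(denom),
         flagged = denom == 0),
    class = "classified_session"
  )
}

#' Learning-performance statistic
#'
#' Percentage of learning-phase feedback events successfully used on the next
#' presentation of the same stimulus (stay after positive feedback, switch
#' after negative), out of all evaluable learning-phase trials:
#' `100 * (learning_pos + learning_neg) /
#'   (learning_pos + learning_neg + excluded_nonlearning)`.
#'
#' @param classified A [classify_session()] result.
#' @return Percent in \[0, 100\].
#' @export
learning_performance <- function(classified) {
  stopifnot(inherits(classified, "classified_session"))
  if (classified$flagged || is.na(classified$learning_performance)) {
    stop("learning performance undefined: no evaluable learning-phase trial",
         call. = FALSE)
  }
  classified$learning_performance
}

#' @export
print.classified_session <- function(x, ...) {
  cat("Classified session:", nrow(x$trials), "trials\n")
  print(x$counts)
  cat(sprintf("learning performance: %s (n evaluable = %d)\n",
              if (is.na(x$learning_performance)) "undefined"
              else sprintf("%.2f%%", x$learning_performance),
              x$n_learning_evaluable))
  invisible(x)
}

#' Per-session category counts
#'
#' Tabulates, for each classified session, the trial counts per category, the
#' learning-phase total (used positive + used negative, the quantity reported
#' as "learning phase trials" in calibration summaries), and the performance
#' statistic.
#'
#' @param sessions A `classified_session` or list of them.
#' @return Data frame with one row per session: `n_trials`, `learning_pos`,
#'   `learning_neg`, `learning` (their sum), `excluded_nonlearning`,
#'   `application`, `no_interest`, `performance`.
#' @export
count_summary <- function(sessions) {
  if (inherits(sessions, "classified_session")) sessions <- list(sessions)
  rows <- lapply(seq_along(sessions), function(i) {
    cl <- sessions[[i]]
    stopifnot(inherits(cl, "classified_session"))
    k <- cl$counts
    data.frame(
      session = i,
      n_trials = nrow(cl$trials),
      learning_pos = k[["learning_pos"]],
      learning_neg = k[["learning_neg"]],
      learning = k[["learning_pos"]] + k[["learning_neg"]],
      excluded_nonlearning = k[["excluded_nonlearning"]],
      application = k[["application"]],
      no_interest = k[["no_interest"]],
      performance = cl$learning_performance
    )
  })
  do.call(rbind, rows)
}

#' Wave-wise behavioral outlier flagging
#'
#' Flags sessions whose learning performance falls more than `sd_threshold`
#' standard deviations below their wave's mean — the rule used to drop
#' participants who did not understand the task before any brain-behavior
#' analysis.
#'
#' @param perf Data frame with columns `wave` and `performance`.
#' @param sd_threshold Number of SDs below the wave mean beyond which a session
#'   is an outlier (default 3).
#' @return Logical vector, `TRUE` for outliers, aligned with `perf` rows.
#' @export
flag_outliers <- function(perf, sd_threshold = 3) {
  stopifnot(all(c("wave", "performance") %in% names(perf)), sd_threshold > 0)
  out <- rep(FALSE, nrow(perf))
  for (w in unique(perf$wave)) {
    i <- which(perf$wave == w & !is.na(perf$performance))
    if (length(i) < 2) next
    m <- mean(perf$performance[i])
    s <- stats::sd(perf$performance[i])
    if (s == 0) next
    out[i] <- perf$performance[i] < m - sd_threshold * s
  }
  out
}
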