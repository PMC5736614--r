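# Independent oracles, written before and apart from the package internals.

# --- trial-record construction -----------------------------------------------

# build a trial data frame for a hand-specified session
make_trials <- function(stimulus, chosen, correct) {
  n <- length(stimulus)
  too_late <- is.na(chosen)
  accuracy <- ifelse(too_late, NA, chosen == correct)
  data.frame(
    sequence_id = 1L, trial_index = seq_len(n) - 1L,
    stimulus_id = stimulus, chosen_square = chosen, correct_square = correct,
    accuracy = accuracy,
    feedback = ifelse(too_late, "none",
                      ifelse(accuracy, "positive", "negative")),
    too_late = too_late,
    onset_s = (seq_len(n) - 1) * 5, feedback_onset_s = (seq_len(n) - 1) * 5 + 3,
    stringsAsFactors = FALSE
  )
}

# a random (possibly adversarial) session: arbitrary stimulus order, choices
# and omissions over a 3-square, up-to-3-stimulus layout
random_session_df <- function(n_trials = sample(1:12, 1), p_too_late = 0.1) {
  squares <- c("A", "B", "C")
  stims <- paste0("s", 1:sample(1:3, 1))
  correct <- setNames(sample(squares, length(stims), replace = TRUE), stims)
  stimulus <- sample(stims, n_trials, replace = TRUE)
  chosen <- ifelse(runif(n_trials) < p_too_late, NA_character_,
                   sample(squares, n_trials, replace = TRUE))
  make_trials(stimulus, chosen, unname(correct[stimulus]))
}

# --- prose-walking classifier oracle -----------------------------------------

# Walks the session trial by trial, literally following the classification
# prose: learning phase = no prior correct for this stimulus; feedback used =
# stay after positive / switch after negative on the next responded
# presentation; application = prior correct, currently correct, and next
# responded presentation (if any) also correct; everything else (too late,
# unevaluable finals, relapses, broken application) is of no interest.
oracle_classify <- function(trials) {
  n <- nrow(trials)
  labels <- character(n)
  for (t in seq_len(n)) {
    if (trials$too_late[t]) { labels[t] <- "no_interest"; next }
    s <- trials$stimulus_id[t]
    before <- trials[seq_len(t - 1), , drop = FALSE]
    before <- before[before$stimulus_id == s & !before$too_late, , drop = FALSE]
    had_correct <- nrow(before) > 0 && any(before$accuracy)
    after <- trials[-seq_len(t), , drop = FALSE]
    after <- after[after$stimulus_id == s & !after$too_late, , drop = FALSE]
    nxt_choice <- if (nrow(after) > 0) after$chosen_square[1] else NA
    nxt_acc <- if (nrow(after) > 0) after$accuracy[1] else NA
    if (!had_correct) {
      if (is.na(nxt_choice)) { labels[t] <- "no_interest"; next }
      if (trials$feedback[t] == "positive") {
        labels[t] <- if (nxt_choice == trials$chosen_square[t])
          "learning_pos" else "excluded_nonlearning"
      } else {
        labels[t] <- if (nxt_choice != trials$chosen_square[t])
          "learning_neg" else "excluded_nonlearning"
      }
    } else if (trials$accuracy[t]) {
      labels[t] <- if (is.na(nxt_acc) || nxt_acc) "application" else "no_interest"
    } else {
      labels[t] <- "no_interest"
    }
  }
  used <- sum(labels %in% c("learning_pos", "learning_neg"))
  denom <- used + sum(labels == "excluded_nonlearning")
  list(labels = labels,
       performance = if (denom > 0) 100 * used / denom else NA_real_)
}

# --- profile-likelihood oracle for the random-intercept ML fit ---------------

# ML log-likelihood of y = X beta + u_subject + e profiled over
# lambda = var(u) / var(e), by direct GLS with the closed-form inverse of
# (I + lambda * J) per subject block; maximised by grid search plus optimize().
oracle_ri_loglik <- function(y, X, subject) {
  subject <- as.character(subject)
  blocks <- split(seq_along(y), subject)
  N <- length(y); p <- ncol(X)
  prof <- function(lambda) {
    XtAX <- matrix(0, p, p); XtAy <- numeric(p); ytAy <- 0; logdet <- 0
    for (idx in blocks) {
      nj <- length(idx)
      Xj <- X[idx, , drop = FALSE]; yj <- y[idx]
      w <- lambda / (1 + nj * lambda)
      cx <- colSums(Xj); cy <- sum(yj)
      XtAX <- XtAX + crossprod(Xj) - w * tcrossprod(cx)
      XtAy <- XtAy + crossprod(Xj, yj) - w * cx * cy
      ytAy <- ytAy + sum(yj^2) - w * cy^2
      logdet <- logdet + log(1 + nj * lambda)
    }
    beta <- solve(XtAX, XtAy)
    rss <- ytAy - 2 * sum(beta * XtAy) + drop(t(beta) %*% XtAX %*% beta)
    sigma2 <- rss / N
    -0.5 * (N * log(2 * pi * sigma2) + logdet + N)
  }
  grid <- c(0, exp(seq(log(1e-6), log(1e3), length.out = 400)))
  ll <- vapply(grid, prof, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(prof, c(lo, max(hi, lo + 1e-8)), maximum = TRUE,
                         tol = 1e-10)
  max(opt$objective, ll[i])
}

# --- misc --------------------------------------------------------------------

# small synthetic longitudinal outcome with known variance components
make_ri_data <- function(n_subj, waves = 3, b = c(0, 0, 0), center = 18.5,
                         sigma_u = 1, sigma_e = 1) {
  age1 <- runif(n_subj, 8, 25)
  d <- expand.grid(subject_id = seq_len(n_subj), wave = seq_len(waves))
  d$age <- age1[d$subject_id] + 2 * (d$wave - 1)
  cc <- d$age - center
  d$y <- b[1] + b[2] * cc + b[3] * cc^2 +
    rnorm(n_subj, sd = sigma_u)[d$subject_id] + rnorm(nrow(d), sd = sigma_e)
  d
}
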