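#' Win-stay / lose-shift agent parameters
#'
#' The behavioral generator is a stochastic win-stay/lose-shift learner with an
#' optional elimination memory. After positive feedback it repeats its previous
#' choice for that stimulus with probability `p_use_positive`; after negative
#' feedback it switches away from the disconfirmed square with probability
#' `p_use_negative`. When it switches and the elimination memory fires
#' (probability `p_elim_memory`), it chooses uniformly among squares never yet
#' disconfirmed for this stimulus; otherwise it chooses uniformly among the two
#' squares other than its last choice. Its session summary under
#' [learning_performance()] is, in expectation, a mixture of `p_use_positive`
#' and `p_use_negative` — precisely the stay/switch feedback-use statistic.
#'
#' @param p_use_positive Probability of staying after positive feedback.
#' @param p_use_negative Probability of switching after negative feedback.
#' @param p_elim_memory Probability a switch avoids all previously
#'   disconfirmed squares (not asserted by any behavioral evidence; a knob).
#' @param p_too_late Per-trial probability of an omitted (too-late) response.
#' @return A list of class `"agent_params"`.
#' @export
agent_params <- function(p_use_positive = 0.95, p_use_negative = 0.95,
                         p_elim_memory = 0.5, p_too_late = 0.02) {
  p <- c(p_use_positive, p_use_negative, p_elim_memory, p_too_late)
  if (any(p < 0 | p > 1)) stop("all probabilities must be in [0, 1]", call. = FALSE)
  structure(
    list(p_use_positive = p_use_positive, p_use_negative = p_use_negative,
         p_elim_memory = p_elim_memory, p_too_late = p_too_late),
    class = "agent_params"
  )
}

#' Agent policy factory
#'
#' Wraps [agent_params()] into a policy factory usable by [run_session()]. The
#' returned factory ignores the rule set (the agent cannot see the answer key)
#' and decides from the stimulus's own feedback history.
#'
#' @param params An [agent_params()].
#' @return Function `(rules)` returning a policy `(stimulus_id, history)`.
#' @export
agent_policy <- function(params) {
  stopifnot(inherits(params, "agent_params"))
  squares <- task_squares()
  function(rules) {
    function(stimulus_id, history) {
      if (stats::runif(1) < params$p_too_late) return(NA_character_)
      responded <- history[!is.na(history$chosen_square), , drop = FALSE]
      if (nrow(responded) == 0) return(sample(squares, 1))
      last_choice <- responded$chosen_square[nrow(responded)]
      last_fb <- responded$feedback[nrow(responded)]
      others <- setdiff(squares, last_choice)
      if (last_fb == "positive") {
        if (stats::runif(1) < params$p_use_positive) return(last_choice)
        return(sample(others, 1))
      }
      # negative feedback: switch with p_use_negative
      if (stats::runif(1) >= params$p_use_negative) return(last_choice)
      if (stats::runif(1) < params$p_elim_memory) {
        disconfirmed <- unique(responded$chosen_square[responded$feedback == "negative"])
        candidates <- setdiff(squares, disconfirmed)
        if (length(candidates) > 0) return(sample(candidates, 1))
      }
      sample(others, 1)
    }
  }
}

#' Developmental profile mapping age to agent parameters
#'
#' Encodes an inverted-U developmental trend in feedback use: on the logit
#' scale, the stay-after-positive and switch-after-negative probabilities
#' follow a downward parabola in age with its vertex at `peak_age`, so
#' simulated learning performance peaks in late adolescence / early adulthood.
#' `logit(p) = logit_peak - curvature * (age - peak_age)^2` for each of the two
#' feedback-use probabilities.
#'
#' Defaults (`peak_age = 20`, `logit_peak = 3.6`, `curvature = 0.008`) are
#' calibrated so that wave-level mean performance of a simulated cohort falls
#' in the mid-90s percent with a spread of a few points, the regime typical of
#' this easy sorting task; they are a calibration reference, not a fit.
#'
#' @param peak_age Age (years) of maximal feedback use.
#' @param logit_peak_pos,logit_peak_neg Logit of the feedback-use probability
#'   at the peak, for positive and negative feedback.
#' @param curvature_pos,curvature_neg Quadratic falloff per squared year on
#'   the logit scale (must be >= 0).
#' @param p_elim_memory,p_too_late Passed through to [agent_params()].
#' @param age_range Ages (years) over which the profile is considered valid.
#' @return A list of class `"developmental_profile"`.
#' @export
developmental_profile <- function(peak_age = 20,
                                  logit_peak_pos = 3.6, curvature_pos = 0.008,
                                  logit_peak_neg = 3.6, curvature_neg = 0.008,
                                  p_elim_memory = 0.5, p_too_late = 0.02,
                                  age_range = c(8, 29)) {
  stopifnot(curvature_pos >= 0, curvature_neg >= 0,
            length(age_range) == 2, age_range[1] < age_range[2])
  structure(
    list(peak_age = peak_age,
         logit_peak_pos = logit_peak_pos, curvature_pos = curvature_pos,
         logit_peak_neg = logit_peak_neg, curvature_neg = curvature_neg,
         p_elim_memory = p_elim_memory, p_too_late = p_too_late,
         age_range = as.numeric(age_range)),
    class = "developmental_profile"
  )
}

#' @rdname developmental_profile
#' @param profile A `developmental_profile`.
#' @param age Age in years.
#' @return `profile_params()` returns the [agent_params()] at `age`.
#' @export
profile_params <- function(profile, age) {
  stopifnot(inherits(profile, "developmental_profile"))
  if (age < profile$age_range[1] || age > profile$age_range[2]) {
    stop("age ", age, " outside the profile's valid range [",
         profile$age_range[1], ", ", profile$age_range[2], "]", call. = FALSE)
  }
  d2 <- (age - profile$peak_age)^2
  agent_params(
    p_use_positive = stats::plogis(profile$logit_peak_pos - profile$curvature_pos * d2),
    p_use_negative = stats::plogis(profile$logit_peak_neg - profile$curvature_neg * d2),
    p_elim_memory = profile$p_elim_memory,
    p_too_late = profile$p_too_late
  )
}

#' Simulate one participant's session
#'
#' Maps `age` through the developmental profile to agent parameters and runs a
#' full session of the sorting task.
#'
#' @param age Age in years (must lie in `profile$age_range`).
#' @param profile A [developmental_profile()].
#' @param config A [task_config()].
#' @param seed Optional integer RNG seed for a reproducible session.
#' @return Trial records as from [run_session()].
#' @export
simulate_participant <- function(age, profile = developmental_profile(),
                                 config = task_config(), seed = NULL) {
  params <- profile_params(profile, age)
  run_session(agent_policy(params), config, seed = seed)
}
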