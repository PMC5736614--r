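#' Configuration of a synthetic accelerated-longitudinal cohort
#'
#' Defines the generative ground truth for a cohort in which subjects enter at
#' staggered ages (uniform on `age_range_tp1` at wave 1) and return for up to
#' `n_waves` biannual waves. Region-of-interest (ROI) contrast values follow a
#' quadratic-in-age fixed trajectory per (ROI, contrast) stratum plus a subject
#' random intercept and a residual; random intercepts and residuals are
#' equicorrelated across strata with correlation `inter_roi_corr`. Learning
#' performance follows its own quadratic age trajectory plus a linear coupling
#' to the true activity residuals of selected strata, a subject random
#' intercept, noise, truncation at 100, and a per-wave fraction of exact-100
#' ceiling scorers.
#'
#' Defaults emulate the published study design: 271 subjects aged 8-25 at wave
#' 1, three waves two years apart, wave-on-wave retention 0.86 (so later waves
#' hold about 233 of 271), mean inter-variable correlation 0.66, performance in
#' the mid-90s percent with a peak near age 20-21, equal between- and
#' within-subject performance variances (intra-class correlation 0.5), and
#' ceiling fractions 15/271, 27/233 and 69/232 at waves 1-3.
#'
#' @param n_subjects Number of subjects entering at wave 1.
#' @param age_range_tp1 Length-2 numeric, uniform age range (years) at wave 1.
#' @param n_waves Number of waves.
#' @param wave_gap Years between waves.
#' @param retention_per_wave Probability a subject is observed at each wave
#'   after the first; waves are dropped independently (attrition need not be
#'   monotone).
#' @param trajectories Data frame with columns `roi`, `contrast`, `b0`, `b1`,
#'   `b2`: fixed trajectory coefficients on the centered-age scale
#'   (`activity = b0 + b1*c + b2*c^2`, `c = age - age_center`).
#' @param random_intercept_sd,residual_sd SDs of the activity random intercept
#'   and residual (common across strata).
#' @param inter_roi_corr Equicorrelation of random intercepts and residuals
#'   across strata; must keep the implied covariance positive definite.
#' @param coupling Data frame `roi`, `contrast`, `coupling`: performance points
#'   per unit of true activity residual in that stratum.
#' @param perf_coef Numeric length 3: performance trajectory `(q0, q1, q2)` on
#'   the centered-age scale.
#' @param perf_random_intercept_sd,perf_residual_sd Performance variance
#'   components.
#' @param ceiling_rate Per-wave probability of an exact-100 ceiling score
#'   (recycled to `n_waves`).
#' @param age_center Centering constant (years) of all polynomials; defaults to
#'   the midpoint of the achievable age span.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 271L,
                          age_range_tp1 = c(8, 25),
                          n_waves = 3L,
                          wave_gap = 2,
                          retention_per_wave = 0.86,
                          trajectories = default_trajectories(),
                          random_intercept_sd = 0.5,
                          residual_sd = 0.5,
                          inter_roi_corr = 0.66,
                          coupling = default_coupling(),
                          perf_coef = c(95, 0.2, -0.05),
                          perf_random_intercept_sd = 3,
                          perf_residual_sd = 3,
                          ceiling_rate = c(15 / 271, 27 / 233, 69 / 232),
                          age_center = NULL) {
  stopifnot(
    n_subjects >= 0, length(age_range_tp1) == 2,
    age_range_tp1[1] < age_range_tp1[2],
    n_waves >= 1, wave_gap > 0,
    retention_per_wave >= 0, retention_per_wave <= 1,
    all(c("roi", "contrast", "b0", "b1", "b2") %in% names(trajectories)),
    random_intercept_sd > 0, residual_sd > 0,
    inter_roi_corr >= -1, inter_roi_corr <= 1,
    all(c("roi", "contrast", "coupling") %in% names(coupling)),
    length(perf_coef) == 3,
    perf_random_intercept_sd > 0, perf_residual_sd > 0,
    all(ceiling_rate >= 0 & ceiling_rate <= 1)
  )
  if (is.null(age_center)) {
    age_center <- mean(c(age_range_tp1[1],
                         age_range_tp1[2] + wave_gap * (n_waves - 1)))
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         age_range_tp1 = as.numeric(age_range_tp1),
         n_waves = as.integer(n_waves), wave_gap = wave_gap,
         retention_per_wave = retention_per_wave,
         trajectories = trajectories,
         random_intercept_sd = random_intercept_sd,
         residual_sd = residual_sd,
         inter_roi_corr = inter_roi_corr,
         coupling = coupling,
         perf_coef = as.numeric(perf_coef),
         perf_random_intercept_sd = perf_random_intercept_sd,
         perf_residual_sd = perf_residual_sd,
         ceiling_rate = rep_len(ceiling_rate, n_waves),
         age_center = age_center),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @details `default_trajectories()` gives every striatal and frontoparietal
#'   ROI an adolescent-peaking quadratic for the informative-value contrast
#'   (vertex at the centering age), a flat or gently sloping valence contrast,
#'   and a flat anterior cingulate, mirroring the qualitative pattern of the
#'   published trajectories.
#' @export
default_trajectories <- function() {
  rois <- c("dorsal_caudate", "ventral_caudate", "nucleus_accumbens",
            "mfg", "sma", "spl", "acc")
  iv <- data.frame(
    roi = rois, contrast = "informative_value",
    b0 = c(0.6, 0.6, 0.8, 0.5, 0.5, 0.5, 0.4),
    b1 = 0,
    b2 = c(-0.012, -0.012, -0.015, -0.010, -0.010, -0.010, 0),
    stringsAsFactors = FALSE
  )
  va <- data.frame(
    roi = rois, contrast = "valence",
    b0 = c(-0.2, 0.1, 0.3, 0, 0, 0, 0),
    b1 = c(0, -0.02, -0.02, 0, 0, 0, 0),
    b2 = c(0, 0, -0.008, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
  rbind(iv, va)
}

#' @rdname cohort_config
#' @details `default_coupling()` couples performance to the informative-value
#'   residuals of dorsal and ventral caudate (0.5 and 0.44 performance points
#'   per residual unit) and to nothing else.
#' @export
default_coupling <- function() {
  data.frame(
    roi = c("dorsal_caudate", "ventral_caudate"),
    contrast = "informative_value",
    coupling = c(0.5, 0.44),
    stringsAsFactors = FALSE
  )
}

# n draws of an m-variate standard normal with equicorrelation rho
rmvn_equicorr <- function(n, m, rho) {
  if (m == 1) return(matrix(stats::rnorm(n), n, 1))
  sigma <- matrix(rho, m, m)
  diag(sigma) <- 1
  ch <- tryCatch(chol(sigma), error = function(e) {
    stop("inter_roi_corr = ", rho,
         " implies a non-positive-definite covariance for ", m, " strata",
         call. = FALSE)
  })
  matrix(stats::rnorm(n * m), n, m) %*% ch
}

#' Sample the accelerated-longitudinal design frame
#'
#' Draws wave-1 ages uniformly on the configured range; every subject is
#' observed at wave 1 and retained at each later wave independently with
#' probability `retention_per_wave`. Age at wave w is
#' `age_tp1 + wave_gap * (w - 1)`.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer RNG seed.
#' @return Data frame `subject_id`, `wave`, `age` (one row per observed
#'   subject-wave); empty with a warning when `n_subjects` is 0.
#' @export
sample_design <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  if (config$n_subjects == 0) {
    warning("n_subjects = 0: empty design")
    return(data.frame(subject_id = integer(), wave = integer(), age = numeric()))
  }
  age1 <- stats::runif(config$n_subjects,
                       config$age_range_tp1[1], config$age_range_tp1[2])
  rows <- lapply(seq_len(config$n_waves), function(w) {
    keep <- if (w == 1) rep(TRUE, config$n_subjects)
      else stats::runif(config$n_subjects) < config$retention_per_wave
    data.frame(subject_id = which(keep), wave = w,
               age = age1[keep] + config$wave_gap * (w - 1))
  })
  out <- do.call(rbind, rows)
  out[order(out$subject_id, out$wave), , drop = FALSE]
}

#' Generate ROI contrast values over a design frame
#'
#' For each (ROI, contrast) stratum, activity is the stratum's fixed quadratic
#' in centered age plus a subject random intercept and a residual; intercepts
#' and residuals are equicorrelated across strata with `inter_roi_corr`. The
#' true stochastic deviation from the fixed curve is returned as
#' `activity_resid_true` — the ground truth against which residualization and
#' coupling recovery are scored.
#'
#' @param design Frame from [sample_design()].
#' @param config A [cohort_config()].
#' @param seed Optional integer RNG seed.
#' @return Long data frame: `subject_id`, `wave`, `age`, `roi`, `contrast`,
#'   `activity`, `activity_resid_true`.
#' @export
generate_activity <- function(design, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  strata <- config$trajectories
  m <- nrow(strata)
  subjects <- sort(unique(design$subject_id))
  u <- rmvn_equicorr(length(subjects), m, config$inter_roi_corr) *
    config$random_intercept_sd
  rownames(u) <- subjects
  e <- rmvn_equicorr(nrow(design), m, config$inter_roi_corr) *
    config$residual_sd

  cc <- design$age - config$age_center
  out <- lapply(seq_len(m), function(k) {
    fixed <- strata$b0[k] + strata$b1[k] * cc + strata$b2[k] * cc^2
    resid_true <- u[as.character(design$subject_id), k] + e[, k]
    data.frame(subject_id = design$subject_id, wave = design$wave,
               age = design$age,
               roi = strata$roi[k], contrast = strata$contrast[k],
               activity = fixed + resid_true,
               activity_resid_true = resid_true,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate learning performance over a design frame
#'
#' Performance is a quadratic in centered age plus the configured couplings to
#' the true activity residuals, a subject random intercept and noise, truncated
#' to \[0, 100\]; a per-wave `ceiling_rate` fraction of subject-waves is then
#' set to exactly 100, emulating ceiling scorers on an easy task.
#'
#' @param design Frame from [sample_design()].
#' @param activity Long rows from [generate_activity()] over the same design.
#' @param config A [cohort_config()].
#' @param seed Optional integer RNG seed.
#' @return `design` plus a `performance` column (percent).
#' @export
generate_performance <- function(design, activity, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  cc <- design$age - config$age_center
  q <- config$perf_coef
  latent <- q[1] + q[2] * cc + q[3] * cc^2

  cp <- config$coupling
  cp <- cp[cp$coupling != 0, , drop = FALSE]
  if (nrow(cp) > 0) {
    key_d <- paste(design$subject_id, design$wave)
    for (k in seq_len(nrow(cp))) {
      a <- activity[activity$roi == cp$roi[k] & activity$contrast == cp$contrast[k], ]
      if (nrow(a) == 0) {
        warning("coupling stratum ", cp$roi[k], ":", cp$contrast[k],
                " absent from the activity table; skipped")
        next
      }
      r <- a$activity_resid_true[match(key_d, paste(a$subject_id, a$wave))]
      latent <- latent + cp$coupling[k] * r
    }
  }

  subjects <- sort(unique(design$subject_id))
  u <- stats::setNames(stats::rnorm(length(subjects),
                                    sd = config$perf_random_intercept_sd),
                       subjects)
  latent <- latent + u[as.character(design$subject_id)] +
    stats::rnorm(nrow(design), sd = config$perf_residual_sd)
  perf <- pmin(pmax(latent, 0), 100)

  at_ceiling <- stats::runif(nrow(design)) <
    config$ceiling_rate[design$wave]
  perf[at_ceiling] <- 100

  out <- design
  out$performance <- unname(perf)
  out
}

#' Generate a complete synthetic cohort
#'
#' Chains [sample_design()], [generate_activity()] and, in the default
#' `"linear"` mode, [generate_performance()]. In `"behavioral"` mode,
#' performance is instead produced end to end by simulating each subject-wave
#' session with the developmental agent ([simulate_participant()]) and scoring
#' it with [classify_session()] — slower, with no closed-form ground truth, but
#' exercising the whole behavioral pipeline. Behavioral-mode performance is not
#' coupled to activity.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer RNG seed (covers all stages).
#' @param mode `"linear"` (default) or `"behavioral"`.
#' @param profile [developmental_profile()] used in behavioral mode.
#' @return List of class `"synthetic_cohort"`: `rows` (long table, one row per
#'   subject-wave-ROI-contrast with `activity` and `performance`), `design`,
#'   `performance` (one row per subject-wave), and `config` (the ground truth).
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL,
                            mode = c("linear", "behavioral"),
                            profile = developmental_profile()) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  design <- sample_design(config)
  activity <- generate_activity(design, config)
  if (mode == "linear") {
    perf <- generate_performance(design, activity, config)
  } else {
    perf <- design
    perf$performance <- vapply(seq_len(nrow(design)), function(i) {
      trials <- simulate_participant(design$age[i], profile,
                                     task_config_wave(design$wave[i]))
      cl <- classify_session(trials)
      if (cl$flagged) NA_real_ else cl$learning_performance
    }, numeric(1))
  }
  rows <- merge(activity, perf[, c("subject_id", "wave", "performance")],
                by = c("subject_id", "wave"), sort = FALSE)
  rows <- rows[order(rows$subject_id, rows$wave, rows$contrast, rows$roi), ]
  rownames(rows) <- NULL
  structure(list(rows = rows, design = design, performance = perf,
                 config = config, mode = mode),
            class = "synthetic_cohort")
}

#' Write a cohort to disk
#'
#' Long-format CSV of the observable columns plus a ground-truth sidecar
#' (JSON-like structured text of the generating parameters).
#'
#' @param cohort A [generate_cohort()] result.
#' @param file CSV path; the sidecar is written next to it as
#'   `<file>.truth.json` when `jsonlite` is available, else as `dput` text.
#' @export
write_cohort <- function(cohort, file) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  obs <- cohort$rows[, c("subject_id", "wave", "age", "roi", "contrast",
                         "activity", "performance")]
  utils::write.csv(obs, file, row.names = FALSE)
  sidecar <- paste0(file, ".truth.json")
  cfg <- cohort$config
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(unclass(cfg), sidecar, auto_unbox = TRUE, digits = NA)
  } else {
    dput(unclass(cfg), file = sidecar)
  }
  invisible(file)
}

#' @rdname write_cohort
#' @param file CSV path written by `write_cohort()` or any file in the same
#'   schema.
#' @export
read_cohort_rows <- function(file) {
  rows <- utils::read.csv(file, stringsAsFactors = FALSE)
  needed <- c("subject_id", "wave", "age", "roi", "contrast", "activity")
  missing <- setdiff(needed, names(rows))
  if (length(missing) > 0) {
    stop("cohort table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows
}
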