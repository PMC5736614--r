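#' Residualize activity against its best age trajectory
#'
#' Subtracts from each observation the fixed-effects prediction of the supplied
#' age-trajectory fit (random intercepts are *not* subtracted: they carry the
#' stable between-subject signal that the brain-behavior test is after).
#'
#' @param rows Long rows for a single (ROI, contrast) stratum with `age` and
#'   the outcome column.
#' @param fit A converged [fit_mixed()] result for this stratum (typically the
#'   selected fit of [compare_ladder()]).
#' @param outcome Activity column name.
#' @return `rows` plus an `activity_residual` column.
#' @export
residualize <- function(rows, fit, outcome = "activity") {
  stopifnot(inherits(fit, "ml_fit"), outcome %in% names(rows))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  pred <- drop(fixed_design(fit, rows$age) %*% fit$coefficients)
  rows$activity_residual <- rows[[outcome]] - pred
  rows
}

#' Residualize every (ROI, contrast) stratum against its selected age model
#'
#' Runs [compare_ladder()] per stratum, takes each stratum's selected fit, and
#' residualizes the stratum's activity against it.
#'
#' @param rows Long cohort rows (`subject_id`, `wave`, `age`, `roi`,
#'   `contrast`, `activity`, ...).
#' @param outcome Activity column name.
#' @param ... Passed to [compare_ladder()].
#' @return List: `rows` (input plus `activity_residual`), `ladders` (named list
#'   of per-stratum [compare_ladder()] results, names `"roi:contrast"`).
#'   Strata whose ladder is incomplete are dropped with a warning.
#' @export
residualize_by_stratum <- function(rows, outcome = "activity", ...) {
  strata <- unique(rows[, c("roi", "contrast")])
  out <- list(); ladders <- list()
  for (k in seq_len(nrow(strata))) {
    key <- paste(strata$roi[k], strata$contrast[k], sep = ":")
    sub <- rows[rows$roi == strata$roi[k] & rows$contrast == strata$contrast[k], ]
    lad <- compare_ladder(sub, outcome, ...)
    if (!lad$complete) {
      warning("stratum ", key, " skipped: ladder incomplete")
      next
    }
    ladders[[key]] <- lad
    out[[key]] <- residualize(sub, lad$fits[[lad$selected + 1L]], outcome)
  }
  list(rows = do.call(rbind, out), ladders = ladders)
}

#' Hierarchical brain-behavior regression
#'
#' Tests whether activity residuals predict learning performance over and above
#' the quadratic age trajectory: the ML random-intercept model
#' `performance ~ age + age^2 + activity_residual + (1 | subject)` is fitted
#' and compared (AIC) against the age-only model. The residual coefficient is
#' reported with its Wald test (normal reference, appropriate at the hundreds
#' of observations this design yields).
#'
#' @param d Data frame with `subject_id`, `age`, `performance` and
#'   `activity_residual`, one row per subject-wave (a single stratum).
#' @param age_degree Degree of the age polynomial retained in both models.
#' @return Object of class `"hierarchical_result"`: `B`, `SE`, `t`, `p` for the
#'   residual term, `aic_age`, `aic_full`, `delta_aic` (full minus age-only),
#'   `n`, `n_subjects`, plus both fitted models.
#' @export
hierarchical_test <- function(d, age_degree = 2) {
  needed <- c("subject_id", "age", "performance", "activity_residual")
  stopifnot(all(needed %in% names(d)))
  d <- d[stats::complete.cases(d[, needed]), , drop = FALSE]
  dd <- data.frame(performance = d$performance,
                   subject = factor(d$subject_id),
                   resid = d$activity_residual)
  if (stats::var(dd$resid) < 1e-12) {
    stop("activity_residual is constant: rank-deficient design ",
         "(collinear column: activity_residual)", call. = FALSE)
  }
  terms <- character()
  if (age_degree > 0) {
    bm <- as.matrix(stats::poly(d$age, age_degree))
    colnames(bm) <- paste0("age_o", seq_len(age_degree))
    dd <- cbind(dd, bm)
    terms <- colnames(bm)
  }
  f_age <- stats::as.formula(paste(
    "performance ~", paste(c("1", terms), collapse = " + "), "+ (1 | subject)"))
  f_full <- stats::as.formula(paste(
    "performance ~", paste(c("1", terms, "resid"), collapse = " + "),
    "+ (1 | subject)"))
  m_age <- lme4::lmer(f_age, data = dd, REML = FALSE)
  m_full <- lme4::lmer(f_full, data = dd, REML = FALSE)
  B <- lme4::fixef(m_full)[["resid"]]
  SE <- sqrt(as.matrix(stats::vcov(m_full))["resid", "resid"])
  tval <- B / SE
  structure(list(B = B, SE = SE, t = tval,
                 p = 2 * stats::pnorm(-abs(tval)),
                 aic_age = stats::AIC(m_age), aic_full = stats::AIC(m_full),
                 delta_aic = stats::AIC(m_full) - stats::AIC(m_age),
                 n = nrow(dd), n_subjects = nlevels(dd$subject),
                 model_age = m_age, model_full = m_full),
            class = "hierarchical_result")
}

#' @export
print.hierarchical_result <- function(x, ...) {
  cat(sprintf("activity residual: B = %.3f, SE = %.3f, t = %.2f, p = %.4g (N = %d)\n",
              x$B, x$SE, x$t, x$p, x$n))
  cat(sprintf("AIC age-only %.1f vs full %.1f (delta %.2f)\n",
              x$aic_age, x$aic_full, x$delta_aic))
  invisible(x)
}

#' Drop ceiling performers
#'
#' Removes every subject-wave with learning performance exactly 100% — the
#' sensitivity analysis guarding against the task being too easy for the
#' oldest participants.
#'
#' @param rows Data frame with `wave` and `performance` (long or one row per
#'   subject-wave).
#' @return Filtered rows; attribute `"removed_per_wave"` is a named count of
#'   removed subject-waves per wave. Warns when nothing survives.
#' @export
ceiling_filter <- function(rows) {
  stopifnot(all(c("wave", "performance") %in% names(rows)))
  at_ceiling <- !is.na(rows$performance) & rows$performance == 100
  if ("subject_id" %in% names(rows)) {
    sw <- unique(rows[at_ceiling, c("subject_id", "wave")])
    removed <- table(factor(sw$wave, levels = sort(unique(rows$wave))))
  } else {
    removed <- table(factor(rows$wave[at_ceiling],
                            levels = sort(unique(rows$wave))))
  }
  out <- rows[!at_ceiling, , drop = FALSE]
  if (nrow(out) == 0) warning("all rows are at ceiling: empty output")
  attr(out, "removed_per_wave") <- removed
  out
}

#' Lagged cross-wave prediction
#'
#' Regresses outcome-wave learning performance on predictor-wave activity, both
#' standardized, over the subjects observed at both waves, asking whether
#' activity foreshadows performance two (or four) years later. By default no
#' age covariate is included; `age_adjust = TRUE` adds age at the predictor
#' wave.
#'
#' @param rows Long cohort rows.
#' @param predictor_wave,outcome_wave Wave numbers.
#' @param roi,contrast Stratum of the predictor activity.
#' @param age_adjust Include age at the predictor wave as a covariate.
#' @return Object of class `"lagged_result"`: `beta` (standardized), `p`, `n`,
#'   and the identifying fields.
#' @export
lagged_prediction <- function(rows, predictor_wave, outcome_wave,
                              roi, contrast, age_adjust = FALSE) {
  pred <- rows[rows$wave == predictor_wave & rows$roi == roi &
                 rows$contrast == contrast, ]
  outc <- unique(rows[rows$wave == outcome_wave,
                      c("subject_id", "performance")])
  m <- merge(pred[, c("subject_id", "age", "activity")], outc,
             by = "subject_id")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 10) {
    stop("only ", nrow(m), " complete predictor/outcome pairs (< 10)",
         call. = FALSE)
  }
  d <- data.frame(y = as.numeric(scale(m$performance)),
                  x = as.numeric(scale(m$activity)),
                  age = m$age)
  fit <- if (age_adjust) stats::lm(y ~ x + age, d) else stats::lm(y ~ x, d)
  s <- summary(fit)$coefficients
  structure(list(beta = s["x", "Estimate"], p = s["x", "Pr(>|t|)"],
                 n = nrow(m), predictor_wave = predictor_wave,
                 outcome_wave = outcome_wave, roi = roi, contrast = contrast,
                 age_adjust = age_adjust),
            class = "lagged_result")
}

#' @export
print.lagged_result <- function(x, ...) {
  cat(sprintf("%s/%s: wave %d activity -> wave %d performance, beta = %.3f, p = %.4g, N = %d\n",
              x$roi, x$contrast, x$predictor_wave, x$outcome_wave,
              x$beta, x$p, x$n))
  invisible(x)
}

#' Bonferroni correction adjusted for correlated variables
#'
#' Softens the Bonferroni division by the effective number of tests
#' `m_eff = k^(1 - r_bar)`, where `r_bar` is the mean pairwise correlation
#' among the test variables: perfectly correlated variables count as one test,
#' independent ones as `k`.
#'
#' @param k Number of tests (>= 1).
#' @param r_bar Mean pairwise correlation among the tested variables, in
#'   \[0, 1\].
#' @param alpha_family Family-wise significance level.
#' @return List of class `"mc_correction"`: `k`, `r_bar`, `m_eff`,
#'   `alpha_family`, `alpha_adjusted` (exact) and `alpha_reported` (rounded to
#'   3 decimals, the conventional reporting precision).
#' @export
#' @examples
#' mc_adjust(6, 0.66)$alpha_reported # 0.027
mc_adjust <- function(k, r_bar, alpha_family = 0.05) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (is.na(r_bar) || r_bar < 0 || r_bar > 1) {
    stop("r_bar must lie in [0, 1]", call. = FALSE)
  }
  m_eff <- k^(1 - r_bar)
  alpha <- alpha_family / m_eff
  structure(list(k = k, r_bar = r_bar, m_eff = m_eff,
                 alpha_family = alpha_family,
                 alpha_adjusted = alpha,
                 alpha_reported = round(alpha, 3)),
            class = "mc_correction")
}

#' @export
print.mc_correction <- function(x, ...) {
  cat(sprintf("k = %d tests, mean r = %.2f -> m_eff = %.3f, adjusted alpha = %.3f\n",
              x$k, x$r_bar, x$m_eff, x$alpha_reported))
  invisible(x)
}

#' Mean pairwise Pearson correlation
#'
#' Average of all pairwise Pearson correlations among the columns of `x`,
#' computed over complete pairs. Pairs involving a constant column are skipped
#' with a warning.
#'
#' @param x Numeric matrix or data frame, one column per variable.
#' @return Mean pairwise correlation.
#' @export
mean_pairwise_correlation <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need >= 2 variables", call. = FALSE)
  const <- apply(x, 2, function(v) stats::var(v, na.rm = TRUE)) < 1e-12
  if (any(const)) {
    warning("skipping constant variable(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
    if (ncol(x) < 2) stop("fewer than 2 non-constant variables", call. = FALSE)
  }
  cm <- stats::cor(x, use = "pairwise.complete.obs")
  mean(cm[upper.tri(cm)])
}

#' Pivot long cohort rows to a subject-wave by stratum matrix
#'
#' One column per (ROI, contrast) stratum, one row per subject-wave; the shape
#' over which [mean_pairwise_correlation()] is computed.
#'
#' @param rows Long cohort rows.
#' @param value Column to pivot (default `"activity"`).
#' @return Numeric matrix with `"roi:contrast"` column names.
#' @export
stratum_matrix <- function(rows, value = "activity") {
  key <- paste(rows$subject_id, rows$wave, sep = "_")
  col <- paste(rows$roi, rows$contrast, sep = ":")
  keys <- unique(key); cols <- unique(col)
  m <- matrix(NA_real_, length(keys), length(cols),
              dimnames = list(keys, cols))
  m[cbind(match(key, keys), match(col, cols))] <- rows[[value]]
  m
}

#' Full brain-behavior analysis over a set of strata
#'
#' For each requested (ROI, contrast) stratum: selects the best age trajectory
#' for activity ([compare_ladder()]), residualizes against it, and runs the
#' hierarchical regression of performance on the residuals over the quadratic
#' age model ([hierarchical_test()]). Results are evaluated against a
#' Bonferroni level adjusted for the correlation among the tested variables
#' ([mc_adjust()]), flagging results significant at the family level but not
#' after correction.
#'
#' @param rows Long cohort rows with `performance`.
#' @param rois,contrasts Strata to test (defaults: the three striatal ROIs,
#'   both contrasts — 6 tests).
#' @param alpha_family Family-wise level before correction.
#' @return List of class `"brain_behavior_result"`: `table` (one row per
#'   stratum: B, SE, t, p, significance flags), `mc` (the [mc_adjust()]
#'   object), `ladders`, `tests`.
#' @export
brain_behavior_analysis <- function(rows,
                                    rois = c("dorsal_caudate",
                                             "ventral_caudate",
                                             "nucleus_accumbens"),
                                    contrasts = c("informative_value",
                                                  "valence"),
                                    alpha_family = 0.05) {
  sel <- rows$roi %in% rois & rows$contrast %in% contrasts
  sub <- rows[sel, , drop = FALSE]
  res <- residualize_by_stratum(sub)
  r_bar <- mean_pairwise_correlation(stratum_matrix(sub))
  k <- length(rois) * length(contrasts)
  mc <- mc_adjust(k, max(0, r_bar), alpha_family)

  keys <- names(res$ladders)
  tests <- list()
  tab <- lapply(keys, function(key) {
    d <- res$rows[paste(res$rows$roi, res$rows$contrast, sep = ":") == key, ]
    ht <- hierarchical_test(d)
    tests[[key]] <<- ht
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    data.frame(roi = parts[1], contrast = parts[2],
               age_degree_selected = res$ladders[[key]]$selected,
               B = ht$B, SE = ht$SE, t = ht$t, p = ht$p, n = ht$n,
               sig_uncorrected = ht$p < alpha_family,
               sig_corrected = ht$p < mc$alpha_adjusted,
               sig_before_not_after = ht$p < alpha_family &
                 ht$p >= mc$alpha_adjusted,
               stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, tab), mc = mc,
                 ladders = res$ladders, tests = tests),
            class = "brain_behavior_result")
}

#' @export
print.brain_behavior_result <- function(x, ...) {
  print(x$mc)
  tb <- x$table
  tb$B <- round(tb$B, 3); tb$SE <- round(tb$SE, 3)
  tb$t <- round(tb$t, 2); tb$p <- signif(tb$p, 3)
  print(tb, row.names = FALSE)
  invisible(x)
}
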