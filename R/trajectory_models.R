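#' Fit a random-intercept age-trajectory model
#'
#' Fits, by maximum likelihood (never REML, so that likelihoods and AICs are
#' comparable across models differing in fixed effects), the model
#' `outcome ~ age polynomial of the given degree + (1 | subject)`. The age
#' polynomial uses an orthonormal basis over the observed ages
#' ([stats::poly()]); printed coefficients therefore depend on the basis, but
#' predicted curves and peak ages do not, and the fit also carries the
#' equivalent raw-age polynomial coefficients (`raw_coef`).
#'
#' @param rows Long data frame with the outcome, an age column and a subject
#'   identifier.
#' @param outcome Name of the outcome column.
#' @param degree Polynomial degree of age: 0 (no age effect), 1 or 2.
#' @param age,subject Column names for age (years) and subject.
#' @return Object of class `"ml_fit"`: list with `degree`, `coefficients`
#'   (fixed effects on the orthonormal basis), `vcov` (their covariance),
#'   `raw_coef` (intercept, age, age^2 on raw years), `sigma_u` and `sigma_e`
#'   (random-intercept and residual SDs), `loglik`, `aic`, `n_obs`,
#'   `n_subjects`, `converged`, `singular`, `basis` (the poly object, `NULL`
#'   for degree 0), `age_range`, and the fitted `model`.
#' @export
fit_mixed <- function(rows, outcome, degree, age = "age",
                      subject = "subject_id") {
  stopifnot(degree %in% 0:2,
            all(c(outcome, age, subject) %in% names(rows)))
  d <- data.frame(y = rows[[outcome]], age = rows[[age]],
                  subject = factor(rows[[subject]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 2 || nlevels(droplevels(d$subject)) < 2) {
    stop("need >= 2 observations from >= 2 subjects (random intercept ",
         "unidentifiable otherwise)", call. = FALSE)
  }
  if (!all(is.finite(d$age))) stop("ages must be finite", call. = FALSE)
  d$subject <- droplevels(d$subject)

  basis <- NULL
  if (degree > 0) {
    basis <- stats::poly(d$age, degree)
    bm <- as.matrix(basis)
    colnames(bm) <- paste0("age_o", seq_len(degree))
    d <- cbind(d, bm)
    form <- stats::as.formula(paste(
      "y ~", paste(colnames(bm), collapse = " + "), "+ (1 | subject)"))
  } else {
    form <- y ~ 1 + (1 | subject)
  }

  degenerate <- stats::var(d$y) < 1e-12
  if (degenerate) {
    # constant outcome: no stochastic component to estimate
    mu <- mean(d$y)
    sd_floor <- 1e-8
    ll <- sum(stats::dnorm(d$y, mu, sd_floor, log = TRUE))
    k <- (degree + 1) + 2
    return(structure(list(
      degree = degree, coefficients = c("(Intercept)" = mu,
        stats::setNames(rep(0, degree), if (degree > 0) paste0("age_o", 1:degree))),
      vcov = matrix(0, degree + 1, degree + 1),
      raw_coef = c(intercept = mu, age = 0, age2 = 0),
      sigma_u = 0, sigma_e = 0, loglik = ll, aic = 2 * k - 2 * ll,
      n_obs = nrow(d), n_subjects = nlevels(d$subject),
      converged = TRUE, singular = TRUE, basis = basis,
      age_range = range(d$age), model = NULL), class = "ml_fit"))
  }

  msgs <- character()
  model <- withCallingHandlers(
    tryCatch(lme4::lmer(form, data = d, REML = FALSE),
             error = function(e) e),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (inherits(model, "error")) {
    warning("mixed-model fit failed: ", conditionMessage(model))
    return(structure(list(degree = degree, converged = FALSE,
                          singular = NA, model = NULL,
                          n_obs = nrow(d), n_subjects = nlevels(d$subject)),
                     class = "ml_fit"))
  }
  conv_ok <- length(model@optinfo$conv$lme4$messages) == 0 &&
    !any(grepl("failed to converge", msgs))

  beta <- lme4::fixef(model)
  vc <- lme4::VarCorr(model)
  sigma_u <- attr(vc$subject, "stddev")[[1]]
  sigma_e <- stats::sigma(model)
  ll <- as.numeric(stats::logLik(model))

  fit <- structure(list(
    degree = degree, coefficients = beta,
    vcov = as.matrix(stats::vcov(model)),
    raw_coef = NULL,
    sigma_u = unname(sigma_u), sigma_e = sigma_e,
    loglik = ll, aic = stats::AIC(model),
    n_obs = nrow(d), n_subjects = nlevels(d$subject),
    converged = conv_ok, singular = lme4::isSingular(model),
    basis = basis, age_range = range(d$age), model = model),
    class = "ml_fit")
  fit$raw_coef <- raw_coefficients(fit)
  fit
}

# design matrix of the fit's fixed effects at the given ages
fixed_design <- function(fit, ages) {
  if (fit$degree == 0) return(matrix(1, length(ages), 1))
  cbind(1, stats::predict(fit$basis, ages))
}

# map the fitted basis coefficients to a raw-age polynomial (intercept, b1, b2)
raw_coefficients <- function(fit) {
  pts <- seq(fit$age_range[1], fit$age_range[2], length.out = 3)
  if (pts[1] == pts[3]) pts <- pts[1] + c(-1, 0, 1)
  pred <- drop(fixed_design(fit, pts) %*% fit$coefficients)
  vander <- cbind(1, pts, pts^2)
  raw <- solve(vander, pred)
  names(raw) <- c("intercept", "age", "age2")
  if (fit$degree < 2) raw["age2"] <- 0
  if (fit$degree < 1) raw["age"] <- 0
  raw
}

#' @export
print.ml_fit <- function(x, ...) {
  cat(sprintf("Random-intercept ML fit, age degree %d (n = %d obs, %d subjects)\n",
              x$degree, x$n_obs, x$n_subjects))
  if (!isTRUE(x$converged)) cat("  ** fit did not converge **\n")
  if (!is.null(x$coefficients)) {
    cat("  fixed effects (orthonormal age basis):\n")
    print(round(x$coefficients, 4))
    cat(sprintf("  sigma_u = %.4f, sigma_e = %.4f, logLik = %.2f, AIC = %.1f\n",
                x$sigma_u, x$sigma_e, x$loglik, x$aic))
  }
  invisible(x)
}

#' Compare the no-age / linear / quadratic age ladder
#'
#' Fits the degree-0, 1 and 2 random-intercept models by maximum likelihood and
#' compares each step with a likelihood-ratio test on chi-squared(1) (one fixed
#' effect added per step; variance components are shared). The selected degree
#' is the highest whose own step-up test is significant at `alpha` — the
#' quadratic can be selected even when the linear step is not significant, as
#' in trajectories that are flat on average but adolescent-peaked. With
#' `rule = "aic"` the minimum-AIC model is selected instead.
#'
#' @inheritParams fit_mixed
#' @param alpha Significance level of the step-up tests.
#' @param rule `"lrt"` (default, LRT-gated selection; AIC reported) or
#'   `"aic"`.
#' @return Object of class `"ladder_comparison"`: `fits` (list of three
#'   [fit_mixed()] results), `table` (degree, logLik, AIC, LRT statistic and
#'   p-value vs the previous degree), `selected` (0, 1 or 2, `NA` when any fit
#'   failed), `rule`, `alpha`, `complete`.
#' @export
compare_ladder <- function(rows, outcome, age = "age",
                           subject = "subject_id",
                           alpha = 0.05, rule = c("lrt", "aic")) {
  rule <- match.arg(rule)
  fits <- lapply(0:2, function(dg)
    fit_mixed(rows, outcome, dg, age = age, subject = subject))
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  ll <- vapply(fits, function(f) if (is.null(f$loglik)) NA_real_ else f$loglik,
               numeric(1))
  aic <- vapply(fits, function(f) if (is.null(f$aic)) NA_real_ else f$aic,
                numeric(1))
  lrt_stat <- c(NA, 2 * pmax(diff(ll), 0))
  lrt_p <- c(NA, stats::pchisq(lrt_stat[-1], df = 1, lower.tail = FALSE))
  tab <- data.frame(degree = 0:2, logLik = ll, AIC = aic,
                    lrt_stat = lrt_stat, lrt_p = lrt_p)
  complete <- all(ok)
  selected <- NA_integer_
  if (complete) {
    if (rule == "aic") {
      selected <- which.min(aic) - 1L
    } else {
      selected <- 0L
      if (!is.na(lrt_p[2]) && lrt_p[2] < alpha) selected <- 1L
      if (!is.na(lrt_p[3]) && lrt_p[3] < alpha) selected <- 2L
    }
  } else {
    warning("ladder comparison incomplete: some fits failed to converge")
  }
  structure(list(fits = fits, table = tab, selected = selected,
                 rule = rule, alpha = alpha, complete = complete),
            class = "ladder_comparison")
}

#' @export
print.ladder_comparison <- function(x, ...) {
  cat("Age-ladder comparison (ML random-intercept models)\n")
  print(transform(x$table, logLik = round(logLik, 2), AIC = round(AIC, 1),
                  lrt_stat = round(lrt_stat, 3), lrt_p = signif(lrt_p, 3)))
  cat("selected degree:", x$selected, sprintf("(rule = %s)\n", x$rule))
  invisible(x)
}

#' Predicted trajectory with 95% confidence band
#'
#' Fixed-effects prediction of the fitted age trajectory on an age grid, with a
#' delta-method pointwise 95% confidence band.
#'
#' @param fit A converged [fit_mixed()] result.
#' @param ages Numeric age grid (years).
#' @param level Confidence level.
#' @return Data frame `age`, `fit`, `lwr`, `upr`; attribute `"extrapolated"`
#'   flags grid points outside the fitted age range.
#' @export
predict_trajectory <- function(fit, ages, level = 0.95) {
  stopifnot(inherits(fit, "ml_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  X <- fixed_design(fit, ages)
  pred <- drop(X %*% fit$coefficients)
  se <- sqrt(pmax(rowSums((X %*% fit$vcov) * X), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(age = ages, fit = pred,
                    lwr = pred - z * se, upr = pred + z * se)
  attr(out, "extrapolated") <-
    ages < fit$age_range[1] | ages > fit$age_range[2]
  out
}

#' Peak age of a quadratic trajectory
#'
#' The vertex `-b1 / (2 * b2)` of the fitted quadratic on the raw-age basis,
#' with a parametric-bootstrap confidence interval: fixed-effect vectors are
#' drawn from their estimated sampling distribution and each draw's vertex is
#' recorded. The estimate is valid only when the fitted curvature is negative
#' (a true peak) and the vertex lies inside the observed age range.
#'
#' @param fit A degree-2 [fit_mixed()] result.
#' @param n_boot Number of bootstrap draws.
#' @param seed Optional integer RNG seed.
#' @param level Confidence level of the percentile interval.
#' @return List of class `"peak_estimate"`: `peak` (years, `NA` when invalid),
#'   `ci`, `valid`, `b1`, `b2` (raw basis), `prop_concave` (share of bootstrap
#'   draws with negative curvature).
#' @export
peak_age <- function(fit, n_boot = 2000, seed = NULL, level = 0.95) {
  stopifnot(inherits(fit, "ml_fit"))
  if (fit$degree != 2) stop("peak age requires a degree-2 fit", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  raw <- fit$raw_coef
  b1 <- raw[["age"]]; b2 <- raw[["age2"]]
  valid <- is.finite(b2) && b2 < 0
  peak <- if (valid) -b1 / (2 * b2) else NA_real_
  if (valid && (peak < fit$age_range[1] || peak > fit$age_range[2])) {
    valid <- FALSE
  }

  # linear map from basis coefficients to raw polynomial coefficients
  pts <- seq(fit$age_range[1], fit$age_range[2], length.out = 3)
  M <- solve(cbind(1, pts, pts^2), fixed_design(fit, pts))
  ch <- chol(fit$vcov + diag(1e-12, nrow(fit$vcov)))
  draws <- matrix(stats::rnorm(n_boot * length(fit$coefficients)),
                  n_boot) %*% ch
  draws <- sweep(draws, 2, fit$coefficients, "+")
  raw_draws <- draws %*% t(M)
  concave <- raw_draws[, 3] < 0
  peaks <- ifelse(concave, -raw_draws[, 2] / (2 * raw_draws[, 3]), NA_real_)
  ci <- if (any(concave)) {
    stats::quantile(peaks[concave], c((1 - level) / 2, 1 - (1 - level) / 2),
                    names = FALSE)
  } else c(NA_real_, NA_real_)

  structure(list(peak = if (valid) unname(peak) else NA_real_,
                 ci = ci, valid = valid,
                 b1 = b1, b2 = b2, prop_concave = mean(concave)),
            class = "peak_estimate")
}

#' @export
print.peak_estimate <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("peak age %.2f y (%.0f%% bootstrap CI %.2f-%.2f)\n",
                x$peak, 95, x$ci[1], x$ci[2]))
  } else {
    cat("no valid peak (curvature >= 0 or vertex outside the data range)\n")
  }
  invisible(x)
}

#' Intra-class correlation from the no-age model
#'
#' Longitudinal reliability: the random-intercept variance divided by the total
#' variance (`sigma_u^2 / (sigma_u^2 + sigma_e^2)`) of the degree-0
#' random-intercept model.
#'
#' @inheritParams fit_mixed
#' @return ICC in \[0, 1\]; `NA` with a warning when the total variance is
#'   zero.
#' @export
icc <- function(rows, outcome, age = "age", subject = "subject_id") {
  fit <- fit_mixed(rows, outcome, 0, age = age, subject = subject)
  tot <- if (is.null(fit$sigma_u)) NA_real_ else fit$sigma_u^2 + fit$sigma_e^2
  if (!is.finite(tot) || tot < 1e-12) {
    warning("ICC undefined: zero total variance or failed fit")
    return(NA_real_)
  }
  fit$sigma_u^2 / tot
}
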