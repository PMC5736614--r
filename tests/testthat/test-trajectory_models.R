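test_that("log-likelihoods are nested and the AIC identity holds", {
  set.seed(21)
  for (i in 1:5) {
    d <- make_ri_data(40, b = c(1, runif(1, -0.1, 0.1), runif(1, -0.02, 0)))
    fits <- lapply(0:2, function(dg) fit_mixed(d, "y", dg))
    ll <- vapply(fits, `[[`, numeric(1), "loglik")
    expect_true(all(diff(ll) >= -1e-6))
    for (f in fits) {
      k <- (f$degree + 1) + 2 # fixed effects + two variance parameters
      expect_equal(f$aic, 2 * k - 2 * f$loglik, tolerance = 1e-10)
    }
  }
})

test_that("fitted likelihood matches a profile-likelihood grid-search oracle", {
  set.seed(22)
  for (i in 1:6) {
    n_subj <- sample(3:5, 1)
    d <- make_ri_data(n_subj, b = c(0.5, 0.05, -0.01),
                      sigma_u = runif(1, 0.3, 2), sigma_e = runif(1, 0.3, 2))
    for (dg in 0:2) {
      fit <- fit_mixed(d, "y", dg)
      X <- if (dg == 0) matrix(1, nrow(d), 1) else cbind(1, poly(d$age, dg))
      ll_oracle <- oracle_ri_loglik(d$y, X, d$subject_id)
      expect_equal(fit$loglik, ll_oracle, tolerance = 1e-4)
    }
  }
})

test_that("predicted curves are identical across polynomial bases", {
  set.seed(23)
  d <- make_ri_data(100, b = c(1, 0.1, -0.02))
  fit_ortho <- fit_mixed(d, "y", 2)
  # same model on the raw centered basis
  d$c1 <- d$age - 18.5; d$c2 <- d$c1^2
  m_raw <- lme4::lmer(y ~ c1 + c2 + (1 | subject_id), data = d, REML = FALSE)
  grid <- seq(9, 28, by = 0.5)
  pred_ortho <- predict_trajectory(fit_ortho, grid)$fit
  b <- lme4::fixef(m_raw)
  pred_raw <- b[1] + b[2] * (grid - 18.5) + b[3] * (grid - 18.5)^2
  expect_equal(pred_ortho, unname(pred_raw), tolerance = 1e-6)
  expect_equal(as.numeric(logLik(m_raw)), fit_ortho$loglik, tolerance = 1e-6)
})

test_that("raw-basis coefficients recover the generating polynomial", {
  set.seed(24)
  reps <- t(replicate(20, {
    d <- make_ri_data(200, b = c(1, 0.08, -0.015), sigma_u = 0.5, sigma_e = 0.5)
    fit <- fit_mixed(d, "y", 2)
    # generating polynomial is in centered age; convert the raw fit back
    b <- fit$raw_coef
    c(b1 = unname(b["age"] + 2 * b["age2"] * 18.5), b2 = unname(b["age2"]))
  }))
  se <- apply(reps, 2, sd) / sqrt(nrow(reps))
  expect_lt(abs(mean(reps[, "b1"]) - 0.08), 2 * se["b1"] + 1e-3)
  expect_lt(abs(mean(reps[, "b2"]) - -0.015), 2 * se["b2"] + 1e-4)
})

test_that("degenerate and undersized inputs are handled as specified", {
  d <- data.frame(subject_id = rep(1:5, each = 3), age = rep(10:12, 5), y = 7)
  fit <- fit_mixed(d, "y", 0)
  expect_equal(fit$sigma_u, 0)
  expect_equal(fit$sigma_e, 0)
  expect_true(is.finite(fit$loglik))

  single <- data.frame(subject_id = 1, age = c(10, 12, 14), y = rnorm(3))
  expect_error(fit_mixed(single, "y", 1), "2 subjects")
})

test_that("the ladder is deterministic and its LRT steps use chi-squared(1)", {
  set.seed(25)
  d <- make_ri_data(80, b = c(0, 0, -0.02))
  c1 <- compare_ladder(d, "y")
  c2 <- compare_ladder(d, "y")
  expect_identical(c1$table, c2$table)
  expect_equal(c1$table$lrt_p[2],
               pchisq(2 * (c1$table$logLik[2] - c1$table$logLik[1]), 1,
                      lower.tail = FALSE))
  expect_equal(c1$selected, 2L)
  # the quadratic can be selected even when the linear step is not significant
  expect_true(c1$table$lrt_p[3] < 0.05)
})

test_that("trajectory curves behave: flat at degree 0, bands shrink with n", {
  set.seed(26)
  d <- make_ri_data(60)
  f0 <- fit_mixed(d, "y", 0)
  tr <- predict_trajectory(f0, c(10, 15, 20))
  expect_true(all(tr$fit == tr$fit[1]))
  expect_true(all(tr$lwr <= tr$fit & tr$fit <= tr$upr))

  d_small <- make_ri_data(100, b = c(0, 0.1, -0.02))
  d_big <- make_ri_data(1000, b = c(0, 0.1, -0.02))
  grid <- seq(10, 26, by = 1)
  w_small <- with(predict_trajectory(fit_mixed(d_small, "y", 2), grid), upr - lwr)
  w_big <- with(predict_trajectory(fit_mixed(d_big, "y", 2), grid), upr - lwr)
  expect_true(all(w_big < w_small))

  tr2 <- predict_trajectory(f0, c(5, 15))
  expect_identical(attr(tr2, "extrapolated"), c(TRUE, FALSE))
})

test_that("peak age is the vertex of the raw quadratic with a bootstrap CI", {
  set.seed(27)
  # nearly noiseless data from y = 2 * age - 0.05 * age^2 -> peak at 20
  d <- make_ri_data(200, sigma_u = 1e-3, sigma_e = 1e-3)
  d$y <- 2 * d$age - 0.05 * d$age^2 + d$y
  pk <- peak_age(fit_mixed(d, "y", 2), seed = 1)
  expect_true(pk$valid)
  expect_equal(pk$peak, 20, tolerance = 0.01)
  expect_true(pk$ci[1] <= pk$peak && pk$peak <= pk$ci[2])

  # convex trajectory: no peak
  d$y <- -2 * d$age + 0.05 * d$age^2 + rnorm(nrow(d), sd = 0.001)
  pk2 <- peak_age(fit_mixed(d, "y", 2), seed = 1)
  expect_false(pk2$valid)
  expect_true(is.na(pk2$peak))

  expect_error(peak_age(fit_mixed(d, "y", 1)), "degree-2")
})

test_that("ICC reflects the variance-component ratio", {
  set.seed(28)
  d_half <- make_ri_data(400, sigma_u = 1, sigma_e = 1)
  expect_lt(abs(icc(d_half, "y") - 0.5), 0.06)

  d_zero <- make_ri_data(200, sigma_u = 1e-6, sigma_e = 1)
  expect_lt(icc(d_zero, "y"), 0.05)

  d_one <- make_ri_data(200, sigma_u = 1, sigma_e = 1e-4)
  expect_gt(icc(d_one, "y"), 0.95)

  d_const <- data.frame(subject_id = rep(1:4, each = 2),
                        age = rep(c(10, 12), 4), y = 3)
  expect_warning(v <- icc(d_const, "y"), "undefined")
  expect_true(is.na(v))
})
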