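make_stratum_cohort <- function(n_subjects, coupling, seed,
                                ceiling_rate = 0, b2 = -0.012,
                                perf_coef = c(95, 0.2, -0.05)) {
  traj <- data.frame(roi = "dorsal_caudate", contrast = "informative_value",
                     b0 = 0.5, b1 = 0, b2 = b2)
  cfg <- cohort_config(
    n_subjects = n_subjects, trajectories = traj,
    coupling = data.frame(roi = "dorsal_caudate",
                          contrast = "informative_value", coupling = coupling),
    ceiling_rate = ceiling_rate, perf_coef = perf_coef
  )
  generate_cohort(cfg, seed = seed)
}

test_that("residuals vanish on the fitted curve and average to zero", {
  set.seed(41)
  co <- make_stratum_cohort(150, coupling = 0, seed = 41)
  sub <- co$rows
  fit <- fit_mixed(sub, "activity", 2)
  res <- residualize(sub, fit)
  # the ML estimating equation zeroes the V^-1-weighted residual mean exactly;
  # the raw mean is only near zero (dropout unbalances the subject weights)
  lambda <- fit$sigma_u^2 / fit$sigma_e^2
  wsum <- 0
  for (s in unique(res$subject_id)) {
    r <- res$activity_residual[res$subject_id == s]
    nj <- length(r)
    wsum <- wsum + sum(r) - (lambda / (1 + nj * lambda)) * nj * sum(r)
  }
  expect_lt(abs(wsum) / nrow(res), 1e-6 * sd(res$activity_residual))
  expect_lt(abs(mean(res$activity_residual)),
            0.05 * sd(res$activity_residual))

  on_curve <- sub[1:5, ]
  on_curve$activity <- drop(
    feedlearn:::fixed_design(fit, on_curve$age) %*% fit$coefficients)
  expect_equal(residualize(on_curve, fit)$activity_residual, rep(0, 5),
               tolerance = 1e-10)
})

test_that("residuals track the generating coupling and survive residualization", {
  co <- make_stratum_cohort(500, coupling = 0.6, seed = 42)
  res <- residualize_by_stratum(co$rows)
  d <- res$rows
  # fitted residuals approximate the true ones
  expect_gt(cor(d$activity_residual, d$activity_resid_true), 0.95)
  ht <- hierarchical_test(d)
  expect_gt(ht$B, 0)
  expect_lt(ht$p, 0.05)
  expect_lt(ht$aic_full, ht$aic_age)
})

test_that("shuffling residuals across rows destroys the brain-behavior effect", {
  co <- make_stratum_cohort(300, coupling = 0.8, seed = 43)
  res <- residualize_by_stratum(co$rows)
  d <- res$rows
  t_real <- abs(hierarchical_test(d)$t)
  set.seed(43)
  t_perm <- replicate(5, {
    d$activity_residual <- sample(d$activity_residual)
    abs(hierarchical_test(d)$t)
  })
  expect_gt(t_real, max(t_perm))
})

test_that("a constant residual column is reported as rank-deficient", {
  co <- make_stratum_cohort(50, coupling = 0, seed = 44)
  d <- co$rows
  d$activity_residual <- 1
  expect_error(hierarchical_test(d), "activity_residual")
})

test_that("ceiling filtering removes exactly the 100% subject-waves", {
  # keep the latent mean far from 100 so truncation adds no extra exact-100s
  co <- make_stratum_cohort(400, coupling = 0, seed = 45, ceiling_rate = 0.1,
                            perf_coef = c(85, 0, 0))
  rows <- co$rows
  out <- ceiling_filter(rows)
  expect_true(all(out$performance < 100))
  removed <- attr(out, "removed_per_wave")
  expect_lt(abs(sum(removed) / nrow(co$performance) - 0.1), 0.03)
  expect_lte(nrow(out), nrow(rows))

  no_ceiling <- rows[rows$performance < 100, ]
  out2 <- ceiling_filter(no_ceiling)
  expect_equal(nrow(out2), nrow(no_ceiling))

  all100 <- transform(rows, performance = 100)
  expect_warning(out3 <- ceiling_filter(all100), "ceiling")
  expect_equal(nrow(out3), 0)
})

test_that("lagged prediction is the identity on duplicated data and null on noise", {
  co <- make_stratum_cohort(60, coupling = 0, seed = 46)
  rows <- co$rows
  # plant wave-2 performance equal to wave-1 activity
  w1 <- rows[rows$wave == 1, c("subject_id", "activity")]
  rows$performance <- ifelse(
    rows$wave == 2, w1$activity[match(rows$subject_id, w1$subject_id)],
    rows$performance)
  # lm warns about the essentially perfect fit; the identity is the point here
  lr <- suppressWarnings(
    lagged_prediction(rows, 1, 2, "dorsal_caudate", "informative_value"))
  expect_equal(lr$beta, 1, tolerance = 1e-10)

  # a genuinely null pairing needs flat age trends in both variables, since
  # the default lagged regression carries no age covariate
  co2 <- make_stratum_cohort(400, coupling = 0, seed = 47, b2 = 0,
                             perf_coef = c(90, 0, 0))
  lr2 <- lagged_prediction(co2$rows, 1, 2, "dorsal_caudate",
                           "informative_value")
  expect_lt(abs(lr2$beta), 0.12)

  co3 <- make_stratum_cohort(600, coupling = 0.8, seed = 48)
  lr3 <- lagged_prediction(co3$rows, 1, 2, "dorsal_caudate",
                           "informative_value")
  expect_gt(lr3$beta, 0) # persistent subject coupling carries across waves

  tiny <- co$rows[co$rows$subject_id <= 5, ]
  expect_error(lagged_prediction(tiny, 1, 2, "dorsal_caudate",
                                 "informative_value"), "< 10")
})

test_that("the correlated-variables Bonferroni correction matches its formula", {
  mc <- mc_adjust(6, 0.66, 0.05)
  expect_equal(mc$m_eff, 6^(1 - 0.66))
  expect_equal(mc$alpha_reported, 0.027)
  expect_equal(mc_adjust(6, 0, 0.05)$alpha_adjusted, 0.05 / 6)
  expect_equal(mc_adjust(6, 1, 0.05)$alpha_adjusted, 0.05)

  # monotone in r_bar, antitone in k
  alphas_r <- sapply(seq(0, 1, 0.1), function(r) mc_adjust(6, r)$alpha_adjusted)
  expect_true(all(diff(alphas_r) > 0))
  alphas_k <- sapply(2:10, function(k) mc_adjust(k, 0.5)$alpha_adjusted)
  expect_true(all(diff(alphas_k) < 0))
  expect_true(all(alphas_k >= 0.05 / (2:10) & alphas_k <= 0.05))

  expect_error(mc_adjust(6, 1.2), "\\[0, 1\\]")
  expect_error(mc_adjust(0, 0.5), ">= 1")
})

test_that("mean pairwise correlation behaves on identical, independent and constant columns", {
  set.seed(49)
  x <- rnorm(200)
  expect_equal(mean_pairwise_correlation(cbind(a = x, b = x)), 1)
  ind <- matrix(rnorm(200 * 4), 200)
  expect_lt(abs(mean_pairwise_correlation(ind)), 0.1)
  withconst <- cbind(a = x, b = x + rnorm(200), c = rep(1, 200))
  expect_warning(r <- mean_pairwise_correlation(withconst), "constant")
  expect_gt(r, 0.5)
  expect_error(mean_pairwise_correlation(cbind(a = x)), ">= 2")
})

test_that("the stratum-level analysis flags only coupled strata after correction", {
  traj <- default_trajectories()
  cfg <- cohort_config(n_subjects = 300,
                       coupling = data.frame(roi = "dorsal_caudate",
                                             contrast = "informative_value",
                                             coupling = 1.2),
                       inter_roi_corr = 0.2, ceiling_rate = 0)
  co <- generate_cohort(cfg, seed = 50)
  bb <- brain_behavior_analysis(co$rows)
  tab <- bb$table
  hit <- tab$roi == "dorsal_caudate" & tab$contrast == "informative_value"
  expect_true(tab$sig_corrected[hit])
  expect_gt(tab$B[hit], 0)
  expect_equal(bb$mc$k, 6)
})
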