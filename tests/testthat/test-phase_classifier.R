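test_that("hand-enumerated sessions classify as the rules dictate", {
  # one stimulus, correct square B; choices A(-), B(+), B(+), B(+)
  tr <- make_trials(rep("s1", 4), c("A", "B", "B", "B"), rep("B", 4))
  cl <- classify_session(tr)
  expect_equal(cl$trials$category,
               c("learning_neg", "learning_pos", "application", "application"))
  expect_equal(cl$learning_performance, 100) # 2 of 2 learning trials used

  # stayed on A after negative feedback: first trial excluded but still counted
  tr2 <- make_trials(rep("s1", 3), c("A", "A", "B"), rep("B", 3))
  cl2 <- classify_session(tr2)
  expect_equal(cl2$trials$category[1:2],
               c("excluded_nonlearning", "learning_neg"))
  # final trial is the first correct with no next presentation: unevaluable
  expect_equal(cl2$trials$category[3], "no_interest")
  expect_equal(cl2$learning_performance, 100 * 1 / 2)

  # relapse: correct, correct, then wrong; the broken application trial and the
  # relapse itself are of no interest, never a return to the learning phase
  tr3 <- make_trials(rep("s1", 4), c("B", "B", "A", "B"), rep("B", 4))
  cl3 <- classify_session(tr3)
  expect_equal(cl3$trials$category,
               c("learning_pos", "no_interest", "no_interest", "application"))
})

test_that("an all-too-late session is flagged and has undefined performance", {
  tr <- make_trials(rep("s1", 3), rep(NA_character_, 3), rep("B", 3))
  cl <- classify_session(tr)
  expect_true(all(cl$trials$category == "no_interest"))
  expect_true(cl$flagged)
  expect_true(is.na(cl$learning_performance))
  expect_error(learning_performance(cl), "undefined")
})

test_that("performance is used learning trials over all evaluable learning trials", {
  # 10 stimuli seen twice, all feedback negative: 9 switch (used), 1 stay -> 90%
  tr <- make_trials(rep(paste0("s", 1:10), each = 2),
                    c(rbind(rep("A", 10), c(rep("B", 9), "A"))),
                    rep("C", 20))
  cl <- classify_session(tr)
  expect_equal(unname(cl$counts["learning_neg"]), 9)
  expect_equal(unname(cl$counts["excluded_nonlearning"]), 1)
  expect_equal(cl$learning_performance, 90)
})

test_that("classification partitions every trial into exactly one category", {
  set.seed(31)
  for (i in 1:100) {
    tr <- random_session_df()
    cl <- classify_session(tr)
    expect_false(anyNA(cl$trials$category))
    expect_equal(sum(cl$counts), nrow(tr))
  }
})

test_that("classifier agrees with the prose-walking oracle on random sessions", {
  set.seed(32)
  for (i in 1:200) {
    tr <- random_session_df()
    cl <- classify_session(tr)
    orc <- oracle_classify(tr)
    expect_identical(cl$trials$category, orc$labels)
    expect_identical(cl$learning_performance, orc$performance)
  }
})

test_that("the first correct placement is never labelled application", {
  set.seed(33)
  for (i in 1:50) {
    tr <- random_session_df(n_trials = 12)
    cl <- classify_session(tr)
    for (s in unique(tr$stimulus_id)) {
      idx <- which(tr$stimulus_id == s & !tr$too_late & tr$accuracy)
      if (length(idx) > 0) {
        expect_false(cl$trials$category[idx[1]] == "application")
      }
    }
  }
})

test_that("the performance statistic ignores application trials", {
  set.seed(34)
  for (i in 1:20) {
    tr <- random_session_df(n_trials = 12, p_too_late = 0)
    cl <- classify_session(tr)
    keep <- cl$trials$category != "application"
    labs <- cl$trials$category[keep]
    used <- sum(labs %in% c("learning_pos", "learning_neg"))
    denom <- used + sum(labs == "excluded_nonlearning")
    recomputed <- if (denom > 0) 100 * used / denom else NA_real_
    expect_identical(recomputed, cl$learning_performance)
  }
})

test_that("unordered onsets are rejected", {
  tr <- make_trials(rep("s1", 2), c("A", "B"), c("B", "B"))
  tr$onset_s <- c(5, 0)
  expect_error(classify_session(tr), "strictly increasing")
})

test_that("including unevaluable finals enlarges only the denominator", {
  tr <- make_trials(rep("s1", 3), c("A", "A", "B"), rep("B", 3))
  base <- classify_session(tr)
  incl <- classify_session(tr, include_unevaluable = TRUE)
  expect_equal(base$n_learning_evaluable, 2L)
  expect_equal(incl$n_learning_evaluable, 3L)
  expect_equal(incl$learning_performance, 100 * 1 / 3)
  expect_identical(incl$trials$category, base$trials$category)
})

test_that("count_summary tabulates sessions and handles empty ones", {
  tr <- make_trials(rep("s1", 4), c("A", "B", "B", "B"), rep("B", 4))
  cs <- count_summary(classify_session(tr))
  expect_equal(cs$learning, 2)
  expect_equal(cs$application, 2)

  empty <- classify_session(tr[0, ])
  cs0 <- count_summary(empty)
  expect_equal(cs0$n_trials, 0)
  expect_true(all(cs0[, c("learning", "application", "excluded_nonlearning")] == 0))

  both <- count_summary(list(classify_session(tr), empty))
  expect_equal(nrow(both), 2)
})

test_that("wave-wise outlier flagging catches extreme low scorers only", {
  set.seed(35)
  perf <- data.frame(wave = rep(1:2, each = 50),
                     performance = c(rnorm(50, 94, 2), rnorm(50, 96, 2)))
  perf$performance[1] <- 40
  flags <- flag_outliers(perf)
  expect_true(flags[1])
  expect_equal(sum(flags), 1)
})
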