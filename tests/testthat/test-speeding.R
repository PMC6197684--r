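test_that("run extraction follows the maximal-streak definition on a toy block", {
  # 0th-order block, predominant symbol 2: ...1,2,2,2,1... yields one run
  # of length 3 whose first trial is the entering 1->2 transition
  stim <- c(3L, 1L, 2L, 2L, 2L, 1L, 3L)
  runs <- extract_runs(toy_trials(stim), task_design())
  expect_equal(unique(runs$run), 1L)
  expect_equal(runs$pos, 1:3)
  expect_equal(runs$trial, 3:5)
  expect_equal(unique(runs$start_trial), 3L)
  expect_equal(unique(runs$half), "first")
})

test_that("runs respect block halves and trials belong to at most one run", {
  d <- task_design()
  # place a run starting at within-block trial 26 of block 1
  stim <- rep(1L, 50)
  stim[26:29] <- 2L
  runs <- extract_runs(toy_trials(stim, matrix_id = 2L), d)
  expect_equal(unique(runs$half), "second")
  set.seed(303)
  s <- simulate_cohort(1, d, placebo_params(), seed = 303)[[1]]
  rr <- extract_runs(s, d)
  expect_false(any(duplicated(rr$trial)))            # partition-consistent
  expect_identical(rr, extract_runs(s, d))           # idempotent
  # no realized predominant transition => zero runs
  none <- toy_trials(c(2L, 1L, 3L, 1L, 4L), matrix_id = 2L)
  expect_equal(nrow(extract_runs(none, d)), 0L)
})

test_that("z-scoring uses only the basis trials but transforms everything", {
  d <- task_design()
  s <- simulate_cohort(1, d, placebo_params(), seed = 311)[[1]]
  z <- zscore_log_rt(s, d)
  runs <- extract_runs(s, d)
  ids <- vapply(d$matrices, `[[`, integer(1), "id")
  dyn <- vapply(d$matrices, `[[`, character(1), "dynamics")
  zb <- s$trials$block[dyn[match(s$trials$matrix_id, ids)] == "zeroth"]
  basis <- s$trials$trial %in% runs$trial[runs$block %in% zb] &
    !is.na(s$trials$rt_ms)
  expect_equal(mean(z[basis]), 0, tolerance = 1e-12)
  expect_equal(sd(z[basis]), 1, tolerance = 1e-12)
  expect_equal(sum(is.na(z)), sum(is.na(s$trials$rt_ms)))
  # subjects transform independently
  s2 <- simulate_cohort(1, d, placebo_params(), seed = 312)[[1]]
  expect_equal(z, zscore_log_rt(s, d))
  expect_false(isTRUE(all.equal(zscore_log_rt(s2, d)[1:10], z[1:10])))
  # model predictions transform under the same standardisation as the
  # data: the data-basis mean and SD
  traj <- fom_filter(s$trials, placebo_params())
  pred <- rep(NA_real_, nrow(s$trials))
  pred[match(traj$trial, s$trials$trial)] <- traj$pred_log_rt
  zp <- zscore_log_rt(s, d, values = pred,
                      reference = log(s$trials$rt_ms))
  m <- mean(log(s$trials$rt_ms[basis])); sd0 <- sd(log(s$trials$rt_ms[basis]))
  expect_equal(zp, (pred - m) / sd0, tolerance = 1e-12)
  expect_error(zscore_log_rt(s, d, values = rep(1, nrow(s$trials))),
               "degenerate")
})

test_that("the halves permutation test detects large shifts and respects invariances", {
  set.seed(321)
  runs <- null_runs(n_subj = 10, n_runs = 12, run_len = 3)
  # inject a 3 SD speeding shift into second-half runs at position 1->2
  shift <- runs$pos == 2 & runs$half == "second"
  runs$zlogrt[shift] <- runs$zlogrt[shift] - 3
  set.seed(1)
  res <- halves_permutation_test(runs, 1, n_iter = 999)
  expect_lt(res$p_value, 0.01)
  expect_lt(res$statistic, 0)
  # invariance: common location and positive scale changes leave p alone
  runs2 <- runs; runs2$zlogrt <- runs2$zlogrt + 5
  set.seed(1)
  res2 <- halves_permutation_test(runs2, 1, n_iter = 999)
  runs3 <- runs; runs3$zlogrt <- runs3$zlogrt * 2.5
  set.seed(1)
  res3 <- halves_permutation_test(runs3, 1, n_iter = 999)
  expect_equal(res2$p_value, res$p_value)
  expect_equal(res3$p_value, res$p_value)
  # a half with no runs at the position is flagged not testable
  one_half <- runs[runs$half == "first", ]
  res4 <- halves_permutation_test(one_half, 1, n_iter = 99)
  expect_false(res4$testable)
  expect_true(is.na(res4$p_value))
})

test_that("mismatch magnitude test is null for self-comparison and detects offsets", {
  set.seed(331)
  data_runs <- null_runs(n_subj = 8, n_runs = 10, run_len = 3)
  model_a <- data_runs                      # model A reproduces the data
  model_b <- data_runs
  set.seed(2)
  res_self <- mismatch_magnitude_test(model_a, model_a, data_runs, 1,
                                      n_iter = 499)
  expect_equal(res_self$statistic, 0)
  expect_equal(res_self$p_value, 1)         # all permuted stats tie at 0
  # model B systematically over-speeds at position 2
  model_b$zlogrt[model_b$pos == 2] <- model_b$zlogrt[model_b$pos == 2] - 2
  set.seed(2)
  res <- mismatch_magnitude_test(model_a, model_b, data_runs, 1,
                                 n_iter = 999)
  expect_lt(res$p_value, 0.01)
  expect_lt(res$statistic, 0)               # A closer to data than B
  expect_gte(res$p_value, 0)
  expect_lte(res$p_value, 1)
})

test_that("speeding curves average runs by half and position", {
  set.seed(341)
  runs <- null_runs(n_subj = 3, n_runs = 4, run_len = 4)
  cur <- speeding_curves(runs, max_pos = 3)
  expect_setequal(cur$pos, 1:3)
  expect_setequal(cur$half, c("first", "second"))
  one <- cur[cur$half == "first" & cur$pos == 2, ]
  manual <- mean(runs$zlogrt[runs$half == "first" & runs$pos == 2])
  expect_equal(one$mean_zlogrt, manual)
})
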