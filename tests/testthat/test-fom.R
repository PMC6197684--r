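test_that("belief initialisation sets every count to gamma", {
  expect_equal(init_beliefs(1), matrix(1, 4, 4))
  expect_equal(init_beliefs(0), matrix(0, 4, 4))
  expect_equal(init_beliefs(2.5), matrix(2.5, 4, 4))
  expect_error(init_beliefs(-0.1), "nonnegative")
  expect_equal(predictive_beliefs(init_beliefs(1), 3), rep(0.25, 4))
})

test_that("the decay-and-count update has the stated algebra", {
  U <- init_beliefs(1)
  # lambda = 0: pure counting, only the observed cell changes
  U1 <- update_beliefs(U, 2, 3, lambda = 0, gamma = 1)
  expect_equal(U1[2, 3], 2)
  expect_equal(U1[-(2 + 4 * 2)], rep(1, 15))
  # lambda = 1: full reset to gamma plus the new count
  U2 <- update_beliefs(matrix(5, 4, 4), 1, 1, lambda = 1, gamma = 1)
  expect_equal(U2[1, 1], 2)
  expect_equal(U2[-1], rep(1, 15))
  # hand-computed cell: 0.7 * (4 - 1) + 1 + 1 = 4.1
  U3 <- matrix(1, 4, 4); U3[2, 3] <- 4
  U4 <- update_beliefs(U3, 2, 3, lambda = 0.3, gamma = 1)
  expect_equal(U4[2, 3], 0.7 * 3 + 1 + 1)
  expect_equal(U4[2, 3], 4.1)
})

test_that("conservation and fixed-point properties of the update hold", {
  # total added count after n observed trials equals n * count_weight
  set.seed(2)
  for (w in c(1, 0.5)) {
    U <- init_beliefs(1)
    n <- 50
    for (k in seq_len(n))
      U <- update_beliefs(U, sample(4, 1), sample(4, 1), lambda = 0,
                          gamma = 1, count_weight = w)
    expect_equal(sum(U) - 16, n * w)
  }
  # gamma is invariant under the decay step (no observation term)
  lam <- 0.4; gam <- 2
  U <- matrix(gam, 4, 4)
  expect_equal((1 - lam) * (U - gam) + gam, U)
  # geometric approach to gamma at rate (1 - lambda)
  U <- matrix(5, 4, 4)
  for (k in 1:20) U <- (1 - lam) * (U - 1) + 1
  expect_equal(U[3, 3] - 1, (5 - 1) * (1 - lam)^20)
})

test_that("with gamma = 0 forgetting preserves within-row count ratios", {
  U <- matrix(c(8, 4, 2, 1), 4, 4, byrow = TRUE)
  lam <- 0.25
  Ud <- update_beliefs(U, 1, 1, lambda = lam, gamma = 0)
  # cells untouched by the observation keep their ratios
  expect_equal(Ud[2, 1] / Ud[2, 2], U[2, 1] / U[2, 2])
  expect_equal(Ud[3, 3] / Ud[3, 4], U[3, 3] / U[3, 4])
})

test_that("predictive beliefs normalise rows or return raw counts", {
  U <- init_beliefs(1); U[2, ] <- c(7, 1, 1, 1)
  expect_equal(predictive_beliefs(U, 2), c(0.7, 0.1, 0.1, 0.1))
  expect_equal(predictive_beliefs(U, 2, "count"), c(7, 1, 1, 1))
  expect_equal(sum(predictive_beliefs(U, 2)), 1, tolerance = 1e-12)
  expect_error(predictive_beliefs(init_beliefs(0), 1), "degenerate belief")
  expect_error(predictive_beliefs(U, 5), "1-4")
})

test_that("the response model is the stated linear combination", {
  p <- placebo_params()
  expect_equal(predict_mean_log_rt(p, 0.25, FALSE), 6.671 - 1.248 * 0.25)
  expect_equal(predict_mean_log_rt(p, 0.25, TRUE) -
                 predict_mean_log_rt(p, 0.25, FALSE), 0.0445)
  # negative beta1: mean log RT strictly decreases as belief increases
  beliefs <- seq(0.1, 0.9, by = 0.1)
  m <- vapply(beliefs, predict_mean_log_rt, numeric(1), params = p)
  expect_true(all(diff(m) < 0))
})

test_that("the filter matches a brute-force Dirichlet counting oracle at lambda = 0", {
  sq <- small_session(4, seed = 21)
  params <- fom_params(lambda = 0, gamma = 1)
  traj <- fom_filter(sq, params)
  # independent oracle: raw transition counts, posterior mean
  # (count + 1) / (row count + 4)
  C <- matrix(0, 4, 4)
  expected <- numeric(0)
  for (t in 2:nrow(sq)) {
    p <- sq$stim[t - 1]; s <- sq$stim[t]
    expected <- c(expected, (C[p, s] + 1) / (sum(C[p, ]) + 4))
    C[p, s] <- C[p, s] + 1
  }
  expect_equal(traj$belief, expected, tolerance = 1e-12)
  expect_equal(nrow(traj), nrow(sq) - 1L)  # one record per predictable trial
})

test_that("unobserved transitions decay to uniform geometrically", {
  # 20 consecutive repeats of stimulus 1: belief in 2->3 approaches 0.25
  stim <- c(2L, 3L, rep(1L, 20L))
  lam <- 0.3
  # row 2 saw one count at trial 2 and then only decays towards gamma,
  # so its predictive is within (1-lam)^20 of uniform after the window
  U <- init_beliefs(1)
  for (t in 2:length(stim))
    U <- update_beliefs(U, stim[t - 1], stim[t], lam, 1)
  expect_lt(abs(predictive_beliefs(U, 2)[3] - 0.25), (1 - lam)^20)
})

test_that("the filter is deterministic and resets beliefs at block starts when asked", {
  sq <- small_session(6, seed = 31)
  p <- placebo_params()
  expect_identical(fom_filter(sq, p), fom_filter(sq, p))
  pr <- placebo_params(reset_at_block = TRUE)
  traj <- fom_filter(sq, pr)
  block_starts <- traj$trial[!duplicated(traj$block)]
  # first predictable trial of each block sees uniform beliefs
  expect_equal(traj$belief[traj$trial %in% block_starts],
               rep(0.25, length(block_starts)))
})

test_that("the Gaussian likelihood matches direct density evaluation", {
  # one predictable trial observed exactly at the predicted mean, sigma = 1
  p <- fom_params(lambda = 0.3, gamma = 1, beta0 = 6, beta1 = -1,
                  beta2 = 0, sigma = 1)
  rt <- exp(6 - 1 * 0.25)
  trials <- toy_trials(c(1L, 2L), rt_ms = c(500, rt))
  expect_equal(fom_log_likelihood(trials, p), -0.5 * log(2 * pi))
})

test_that("invalid trials update beliefs but contribute no likelihood", {
  sq <- small_session(3, seed = 41)
  gen <- placebo_params()
  set.seed(4)
  s <- simulate_subject(sq, gen, sigma = 0.2, p_error = 0.1, p_invalid = 0.2)
  stopifnot(any(!s$trials$valid))
  ll <- fom_log_likelihood(s, gen)
  # oracle: independent per-trial density summation over valid trials
  traj <- fom_filter(s$trials, gen)
  manual <- 0
  for (t in 2:nrow(s$trials)) {
    if (!s$trials$valid[t]) next
    row <- traj[traj$trial == t, ]
    x <- log(s$trials$rt_ms[t])
    manual <- manual - 0.5 * log(2 * pi * gen$sigma^2) -
      (x - row$pred_log_rt)^2 / (2 * gen$sigma^2)
  }
  expect_equal(ll, manual, tolerance = 1e-9)
  # beliefs follow the stimulus stream regardless of validity: trajectories
  # are identical whether or not responses were valid
  expect_equal(traj$belief, fom_filter(sq, gen)$belief)
})
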