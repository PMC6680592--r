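test_that("marginal propagation follows the exact matrix recursion", {
  P <- matrix(c(.5, .5, 0,
                .1, .8, .1,
                0, .3, .7), 3, byrow = TRUE)
  # identity keeps the start distribution forever
  tr_id <- propagate_marginals(c(.2, .3, .5), diag(3), 4)
  expect_equal(unname(tr_id), matrix(rep(c(.2, .3, .5), each = 4), 4))
  # one step from a point mass is the corresponding row
  tr <- propagate_marginals(c(1, 0, 0), P, 2)
  expect_equal(unname(tr[2, ]), c(.5, .5, 0))
  # mass conserved at every phase
  tr5 <- propagate_marginals(c(.6, .3, .1), P, 50)
  expect_equal(rowSums(tr5), rep(1, 50), tolerance = 1e-12)
  expect_error(propagate_marginals(c(.5, .4), P, 3), "distribution")
  expect_error(propagate_marginals(c(1, 0, 0), P - .01, 3), "row-stochastic")
})

test_that("propagated marginals match Monte-Carlo chain frequencies", {
  set.seed(123)
  truth <- default_truth()
  for (g in 0:1) {
    P <- transition_matrix(truth, g)
    tr <- propagate_marginals(truth$pi_init[g + 1, ], P, 5)
    fc <- simulate_forecast(truth, group = g, start_state = 1L,
                            n_chains = 2e5, horizon = 4, seed = 100 + g)
    # forecast starts from a point mass; compare against the same start
    tr_point <- propagate_marginals(c(1, 0, 0), P, 5)
    expect_lt(max(abs(fc$state_freq - unclass(tr_point))), 0.004)
    expect_equal(rowSums(tr), rep(1, 5), tolerance = 1e-12)
  }
})

test_that("absorbing-state detection thresholds the diagonal", {
  expect_equal(detect_absorbing(diag(3)), 1:3)
  P <- matrix(c(.98, .01, .01,
                .0, .995, .005,
                .4, .3, .3), 3, byrow = TRUE)
  expect_equal(detect_absorbing(P), 2L)
  expect_equal(detect_absorbing(matrix(1 / 3, 3, 3)), integer(0))
  # SDI-truth state 2 is near-absorbing by construction
  expect_true(2L %in% detect_absorbing(transition_matrix(default_truth(), 1),
                                       tol = 0.05))
})

test_that("expected hitting times solve the first-passage system", {
  P <- matrix(c(1, 0, 0,
                .9, .1, 0,
                .5, 0, .5), 3, byrow = TRUE)
  expect_equal(expected_hitting_time(P, 1, 1)$expected_steps, 0)
  expect_equal(expected_hitting_time(P, 3, 1)$expected_steps, 2)
  P2 <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3, byrow = TRUE)
  expect_identical(expected_hitting_time(P2, 3, 1)$expected_steps, Inf)
  Pj <- matrix(c(0, 1, 1, 0), 2, byrow = TRUE)
  expect_equal(expected_hitting_time(Pj, 2, 1)$expected_steps, 1)
  # leak into a no-return absorbing state makes the expectation infinite
  Pl <- matrix(c(1, 0, 0,
                 .5, 0, .5,
                 0, 0, 1), 3, byrow = TRUE)
  expect_identical(expected_hitting_time(Pl, 2, 1)$expected_steps, Inf)
})

test_that("analytic hitting times agree with simulation on random chains", {
  set.seed(202)
  for (i in 1:10) {
    P <- matrix(stats::rgamma(9, 1), 3)
    P <- P / rowSums(P)
    h <- expected_hitting_time(P, 3, 1)$expected_steps
    tr <- array(0, c(1, 3, 3)); tr[1, , ] <- P
    p <- lmm_params(matrix(c(1, 0, 0, 1, 0, 0, 1, 0, 0), 3, byrow = TRUE),
                    matrix(c(0, 0, 1), 1), tr)
    fc <- simulate_forecast(p, group = 0, start_state = 3, target = 1,
                            n_chains = 4e4, horizon = 200, seed = 300 + i)
    fp <- fc$first_passage
    expect_true(all(is.finite(fp)))
    se <- stats::sd(fp) / sqrt(length(fp))
    expect_lt(abs(mean(fp) - h), max(3 * se, 0.01))
  }
})

test_that("deterministic permutation chains cycle exactly", {
  P <- matrix(c(0, 1, 0,
                0, 0, 1,
                1, 0, 0), 3, byrow = TRUE)
  tr <- array(0, c(1, 3, 3)); tr[1, , ] <- P
  p <- lmm_params(diag(3), matrix(c(1, 0, 0), 1), tr)
  fc <- simulate_forecast(p, group = 0, start_state = 1, n_chains = 100,
                          horizon = 6, seed = 5)
  expect_equal(fc$state_freq[, 1], c(1, 0, 0, 1, 0, 0, 1))
  expect_equal(fc$state_freq[, 2], c(0, 1, 0, 0, 1, 0, 0))
})

test_that("absorbing mass is non-decreasing under propagation", {
  P <- matrix(c(1, 0, 0,
                .2, .7, .1,
                .1, .3, .6), 3, byrow = TRUE)
  for (start in list(c(0, 1, 0), c(0, 0, 1), c(.2, .5, .3))) {
    tr <- propagate_marginals(start, P, 30)
    expect_true(all(diff(tr[, 1]) >= -1e-12))
  }
})

test_that("tidy trajectory export is long-format and complete", {
  truth <- default_truth()
  traj <- marginal_trajectories(truth, 5)
  expect_named(traj, c("group0", "group1"))
  df <- trajectories_df(traj)
  expect_equal(nrow(df), 2 * 5 * 3)
  expect_equal(sort(unique(df$group)), 0:1)
  agg <- tapply(df$probability, list(df$group, df$phase), sum)
  expect_equal(as.vector(agg), rep(1, 10), tolerance = 1e-12)
})
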