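test_that("window_log_emission matches direct per-trial products", {
  expect_equal(window_log_emission(c(5, 0, 0), c(1, 0, 0)), 0)
  expect_equal(window_log_emission(c(1, 1, 0), c(.5, .5, 0)), 2 * log(.5))
  expect_equal(window_log_emission(c(2, 1, 1), c(.93, .02, .05)),
               log(.93^2 * .02 * .05))
  expect_identical(window_log_emission(c(0, 1, 0), c(1, 0, 0)), -Inf)
  expect_error(window_log_emission(c(1, 1), c(.5, .25, .25)), "lengths differ")
})

test_that("forward-backward matches exhaustive path enumeration", {
  set.seed(42)
  for (rep in 1:10) {
    S <- sample(1:3, 1)
    truth <- random_truth(S = S)
    sim <- generate_wcst(n_per_group = c(2, 2), trials = 20, truth = truth,
                         seed = rep)
    for (j in seq_along(sim$windows)) {
      sub <- sim$windows[[j]]
      fb <- forward_backward(sub, truth)
      or <- oracle_forward_backward(sub$counts, sub$group, truth)
      expect_equal(fb$loglik, or$loglik, tolerance = 1e-10)
      expect_equal(fb$gamma, or$gamma, tolerance = 1e-10)
      expect_equal(rowSums(fb$gamma), rep(1, 5))
      if (S > 1) expect_equal(apply(fb$xi, 1, sum), rep(1, 4))
    }
  }
})

test_that("single-state model reduces to a sum of window emissions", {
  truth <- random_truth(S = 1)
  sim <- generate_wcst(n_per_group = c(1, 1), trials = 30, truth = truth,
                       seed = 5)
  sub <- sim$windows[[1]]
  fb <- forward_backward(sub, truth)
  direct <- sum(vapply(1:5, function(t)
    window_log_emission(sub$counts[t, ], truth$phi[1, ]), numeric(1)))
  expect_equal(fb$loglik, direct, tolerance = 1e-12)
  expect_equal(fb$gamma, matrix(1, 5, 1))
})

test_that("identity transitions with uniform start mix only S diagonal paths", {
  set.seed(14)
  S <- 3
  phi <- matrix(stats::rgamma(S * 3, 1), S, 3)
  phi <- phi / rowSums(phi)
  id_trans <- array(0, c(1, S, S))
  id_trans[1, , ] <- diag(S)
  p <- lmm_params(phi, matrix(rep(1 / S, S), 1), id_trans)
  sim <- generate_wcst(n_per_group = c(1, 1), trials = 25, truth = random_truth(),
                       seed = 9)
  sub <- sim$windows[[1]]
  sub$group <- 0L
  fb <- forward_backward(sub, p)
  per_state <- vapply(seq_len(S), function(s)
    sum(vapply(1:5, function(t)
      window_log_emission(sub$counts[t, ], phi[s, ]), numeric(1))),
    numeric(1))
  expect_equal(fb$loglik, log(mean(exp(per_state - max(per_state)))) +
                 max(per_state), tolerance = 1e-10)
})

test_that("dataset log-likelihood is additive over subjects", {
  truth <- default_truth()
  sim <- sim_small(n = 3, trials = 40, seed = 13)
  ll <- loglik_dataset(sim$windows, truth)
  per <- sum(vapply(seq_along(sim$windows), function(j)
    forward_backward(sim$windows[[j]], truth)$loglik, numeric(1)))
  expect_equal(ll, per, tolerance = 1e-10)
  # duplicated subject doubles its contribution
  one <- sim$windows[1]
  attr(one, "T") <- 5L; attr(one, "categories") <- c("C", "E", "PE")
  class(one) <- "lmm_data"
  two <- sim$windows[c(1, 1)]
  attr(two, "T") <- 5L; attr(two, "categories") <- c("C", "E", "PE")
  class(two) <- "lmm_data"
  expect_equal(loglik_dataset(two, truth), 2 * loglik_dataset(one, truth))
})

test_that("EM log-likelihood trace is non-decreasing", {
  sim <- sim_small(n = 15, trials = 60, seed = 21)
  for (s in 1:5) {
    fit <- em_fit(sim$windows, S = 2,
                  config = em_config(n_starts = 2, seed = s))
    expect_true(all(diff(fit$loglik_trace) >= -1e-8 * abs(fit$loglik)))
  }
})

test_that("S = 1 fit is the pooled multinomial MLE in closed form", {
  sim <- sim_small(n = 10, trials = 50, seed = 31)
  fit <- em_fit(sim$windows, S = 1, config = em_config(seed = 1))
  tot <- Reduce(`+`, lapply(sim$windows, function(s) colSums(s$counts)))
  expect_equal(unname(fit$params$phi[1, ]), unname(tot / sum(tot)))
  expect_equal(fit$n_params, count_params(1, 3, 2))
})

test_that("EM recovers well-separated two-state parameters", {
  phi <- matrix(c(.9, .05, .05, .2, .4, .4), 2, byrow = TRUE)
  trans <- array(0, c(2, 2, 2))
  trans[1, , ] <- matrix(c(.8, .2, .3, .7), 2, byrow = TRUE)
  trans[2, , ] <- matrix(c(.6, .4, .1, .9), 2, byrow = TRUE)
  truth <- lmm_params(phi, matrix(c(.7, .3, .4, .6), 2, byrow = TRUE), trans)
  sim <- generate_wcst(n_per_group = c(250, 250), trials = 125, truth = truth,
                       seed = 8)
  fit <- em_fit(sim$windows, S = 2, config = em_config(n_starts = 5, seed = 88))
  expect_lt(max(abs(fit$params$phi - truth$phi)), 0.03)
  expect_true(fit$converged)
  expect_equal(vapply(fit$posteriors, function(m) rowSums(m),
                      numeric(5))[, 1], rep(1, 5), tolerance = 1e-10)
})

test_that("state relabeling leaves the likelihood and canonical form unchanged", {
  truth <- default_truth()
  sim <- sim_small(n = 10, trials = 60, seed = 55)
  perm <- c(2L, 3L, 1L)
  scrambled <- lmm_params(truth$phi[perm, ], truth$pi_init[, perm],
                          truth$trans[, perm, perm, drop = FALSE])
  # simultaneous relabeling of all blocks is likelihood-invariant
  expect_equal(loglik_dataset(sim$windows, scrambled),
               loglik_dataset(sim$windows, truth), tolerance = 1e-12)
  expect_equal(order_states(scrambled)$phi, order_states(truth)$phi)
  # and independent restart sets land on essentially the same canonical
  # optimum (small EM local-optimum slack on a finite sample)
  fit1 <- em_fit(sim$windows, S = 3, config = em_config(n_starts = 10, seed = 7))
  fit2 <- em_fit(sim$windows, S = 3, config = em_config(n_starts = 10, seed = 70))
  expect_lt(max(abs(fit1$params$phi - fit2$params$phi)), 0.02)
  expect_lt(abs(fit1$loglik - fit2$loglik), 0.1)
})

test_that("pooled fit matches covariate fit when groups share parameters", {
  truth <- default_truth()
  shared <- lmm_params(truth$phi,
                       truth$pi_init[c(1, 1), ],
                       truth$trans[c(1, 1), , , drop = FALSE])
  sim <- generate_wcst(c(150, 150), trials = 125, truth = shared, seed = 99)
  cfg <- em_config(n_starts = 5, seed = 3)
  fit_basic <- em_fit(sim$windows, S = 3, covariate = FALSE, config = cfg)
  fit_cov <- em_fit(sim$windows, S = 3, covariate = TRUE, config = cfg)
  expect_lt(max(abs(fit_basic$params$phi - fit_cov$params$phi)), 0.02)
  expect_lt(max(abs(fit_basic$params$pi_init[1, ] -
                      fit_cov$params$pi_init[1, ])), 0.06)
})

test_that("covariate fit requires both groups and flags degenerate fits", {
  sim <- sim_small(n = 5, trials = 40, seed = 41)
  only0 <- sim$windows[vapply(sim$windows, `[[`, integer(1), "group") == 0]
  attr(only0, "T") <- 5L; attr(only0, "categories") <- c("C", "E", "PE")
  class(only0) <- "lmm_data"
  expect_error(em_fit(only0, S = 2, covariate = TRUE,
                      config = em_config(seed = 1)), "both group levels")
  # all-identical responses cannot support 3 states
  const <- data.frame(subject_id = rep(c("a", "b"), each = 20),
                      group = rep(0:1, each = 20), trial_index = rep(1:20, 2),
                      category = "C")
  ds <- window_dataset(const, 5)
  expect_warning(em_fit(ds, S = 3, config = em_config(n_starts = 2, seed = 2)),
                 "degenerate")
})
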