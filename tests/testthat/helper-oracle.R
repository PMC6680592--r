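# Independent oracles used to cross-check the package's recursions.
# These deliberately use exhaustive enumeration / direct formulas and share
# no code with the implementation under test.

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# emission log-probability of one window by direct per-trial product
oracle_window_logp <- function(counts_row, phi_s) {
  lp <- 0
  for (r in seq_along(counts_row)) {
    if (counts_row[r] == 0) next
    if (phi_s[r] == 0) return(-Inf)
    lp <- lp + counts_row[r] * log(phi_s[r])
  }
  lp
}

# exhaustive path enumeration over S^T latent paths:
# returns loglik and smoothed posteriors gamma (T x S)
oracle_forward_backward <- function(counts, group, params) {
  Tn <- nrow(counts)
  S <- params$S
  g <- if (params$G > 1L) group + 1L else 1L
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), Tn)))
  logp <- apply(paths, 1L, function(s) {
    lp <- log(params$pi_init[g, s[1L]])
    if (Tn > 1L) for (t in 2L:Tn) {
      P <- if (params$homogeneous) params$trans[g, s[t - 1L], s[t]] else
        params$trans[g, t - 1L, s[t - 1L], s[t]]
      lp <- lp + log(P)
    }
    for (t in seq_len(Tn))
      lp <- lp + oracle_window_logp(counts[t, ], params$phi[s[t], ])
    lp
  })
  ll <- log_sum_exp(logp)
  w <- exp(logp - ll)
  gamma <- matrix(0, Tn, S)
  for (t in seq_len(Tn)) for (s in seq_len(S))
    gamma[t, s] <- sum(w[paths[, t] == s])
  list(loglik = ll, gamma = gamma)
}

# truth table for the three-category coding by explicit case analysis
oracle_codify <- function(chosen, active, previous) {
  if (chosen == active) return("C")
  if (!is.na(previous) && chosen == previous) return("PE")
  "E"
}

# random valid parameter set for property tests
random_truth <- function(S = 3L, R = 3L, G = 2L, concentrate = 1) {
  rdir <- function(n, k) {
    m <- matrix(stats::rgamma(n * k, concentrate), n, k)
    m / rowSums(m)
  }
  trans <- array(0, dim = c(G, S, S))
  for (g in seq_len(G)) trans[g, , ] <- rdir(S, S)
  lmm_params(rdir(S, R), rdir(G, S), trans,
             categories = c("C", "E", "PE")[seq_len(R)])
}

# small simulated dataset wrapper with fixed seed
sim_small <- function(n = 20, trials = 50, seed = 1, truth = default_truth()) {
  generate_wcst(n_per_group = c(n, n), trials = trials, truth = truth,
                seed = seed)
}
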