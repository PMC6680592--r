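#' Propagate the marginal latent-state distribution across phases
#'
#' Starting from an initial distribution, the distribution at phase `t + 1`
#' is the phase-`t` distribution right-multiplied by the transition matrix:
#' an exact matrix recursion, no simulation.
#'
#' @param pi1 length-S initial distribution.
#' @param P S x S row-stochastic transition matrix, or a list of `T - 1`
#'   matrices for phase-specific transitions.
#' @param n_phases number of phases `T` (rows of the result).
#' @return a `marginal_trajectory`: T x S matrix, row `t` = distribution of
#'   the latent state at phase `t`.
#' @examples
#' propagate_marginals(c(1, 0), matrix(c(.5, .5, 0, 1), 2, byrow = TRUE), 3)
#' @export
propagate_marginals <- function(pi1, P, n_phases = 5L) {
  pi1 <- as.numeric(pi1)
  if (abs(sum(pi1) - 1) > 1e-8 || any(pi1 < 0))
    stop("pi1 must be a probability distribution", call. = FALSE)
  Plist <- if (is.list(P)) P else rep(list(as.matrix(P)), n_phases - 1L)
  for (M in Plist)
    if (any(M < 0) || any(abs(rowSums(M) - 1) > 1e-8))
      stop("P must be row-stochastic", call. = FALSE)
  out <- matrix(0, n_phases, length(pi1))
  out[1L, ] <- pi1
  if (n_phases > 1L) for (t in 2L:n_phases)
    out[t, ] <- out[t - 1L, ] %*% Plist[[t - 1L]]
  colnames(out) <- paste0("state", seq_along(pi1))
  structure(out, class = c("marginal_trajectory", "matrix"))
}

#' @export
print.marginal_trajectory <- function(x, digits = 3, ...) {
  m <- round(unclass(x), digits)
  rownames(m) <- paste0("phase", seq_len(nrow(m)))
  print(m)
  invisible(x)
}

#' Marginal trajectories for every group of a parameter set
#'
#' Applies [propagate_marginals] to each group's fitted initial vector and
#' transition matrix (or per-phase matrices).
#'
#' @param params an [lmm_params] object.
#' @param n_phases number of phases.
#' @return named list of `marginal_trajectory` matrices, one per group
#'   (`group0`, `group1`, ...).
#' @export
marginal_trajectories <- function(params, n_phases = 5L) {
  out <- lapply(seq_len(params$G), function(g) {
    P <- if (params$homogeneous) {
      matrix(params$trans[g, , ], params$S, params$S)
    } else {
      lapply(seq_len(dim(params$trans)[2]),
             function(t) matrix(params$trans[g, t, , ], params$S, params$S))
    }
    propagate_marginals(params$pi_init[g, ], P, n_phases)
  })
  names(out) <- paste0("group", seq_len(params$G) - 1L)
  out
}

#' Tidy export of marginal trajectories
#'
#' @param trajectories output of [marginal_trajectories].
#' @return data frame with columns `group`, `phase`, `state`, `probability`.
#' @export
trajectories_df <- function(trajectories) {
  rows <- lapply(seq_along(trajectories), function(i) {
    m <- trajectories[[i]]
    data.frame(group = i - 1L,
               phase = rep(seq_len(nrow(m)), ncol(m)),
               state = rep(seq_len(ncol(m)), each = nrow(m)),
               probability = as.vector(m))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group, out$phase, out$state), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect (near-)absorbing states
#'
#' A state whose self-transition probability is at least `1 - tol` is
#' reported as absorbing: once entered, the chain (almost) never leaves it.
#'
#' @param P S x S row-stochastic matrix.
#' @param tol tolerance on the diagonal (default 0.01).
#' @return integer vector of absorbing state indices (possibly empty).
#' @export
detect_absorbing <- function(P, tol = 0.01) {
  P <- as.matrix(P)
  which(diag(P) >= 1 - tol)
}

#' Expected hitting time between latent states
#'
#' Solves the standard first-passage linear system
#' `h[target] = 0`, `h[s] = 1 + sum_{s' != target} P[s, s'] h[s']`.
#' When the target is not reached almost surely from the start state the
#' expectation is infinite and `Inf` is returned rather than an error.
#'
#' @param P S x S row-stochastic transition matrix.
#' @param start,target state indices.
#' @return object of class `hitting_time`: list with `start`, `target`,
#'   `expected_steps`, `by = "analytic"`.
#' @examples
#' P <- matrix(c(1, 0, 0,  .9, .1, 0,  .5, 0, .5), 3, 3, byrow = TRUE)
#' expected_hitting_time(P, start = 3, target = 1)$expected_steps # 2
#' @export
expected_hitting_time <- function(P, start, target) {
  P <- as.matrix(P)
  S <- nrow(P)
  stopifnot(start >= 1, start <= S, target >= 1, target <= S)
  if (start == target)
    return(new_hitting_time(start, target, 0, "analytic"))
  # reachability before absorption: the target is made absorbing so paths
  # through it do not count
  Pz <- P
  Pz[target, ] <- 0
  reach <- reachable_from(Pz, start)
  if (!(target %in% reach))
    return(new_hitting_time(start, target, Inf, "analytic"))
  others <- setdiff(seq_len(S), target)
  # a state visited before absorption from which the target is unreachable
  # makes the expectation infinite (positive probability of never hitting)
  can_reach <- vapply(others, function(s) target %in% reachable_from(Pz, s),
                      logical(1))
  if (any(!can_reach)) {
    bad <- others[!can_reach]
    if (length(intersect(bad, reach)) > 0)
      return(new_hitting_time(start, target, Inf, "analytic"))
    others <- others[can_reach]
  }
  Q <- P[others, others, drop = FALSE]
  h <- tryCatch(solve(diag(length(others)) - Q, rep(1, length(others))),
                error = function(e)
                  stop("singular first-passage system: ",
                       conditionMessage(e), call. = FALSE))
  new_hitting_time(start, target, h[match(start, others)], "analytic")
}

new_hitting_time <- function(start, target, steps, by) {
  structure(list(start = start, target = target,
                 expected_steps = as.numeric(steps), by = by),
            class = "hitting_time")
}

#' @export
print.hitting_time <- function(x, ...) {
  cat(sprintf("Expected first passage %d -> %d: %s steps (%s)\n",
              x$start, x$target,
              if (is.finite(x$expected_steps))
                format(round(x$expected_steps, 4)) else "Inf",
              x$by))
  invisible(x)
}

# states reachable from `from` following positive-probability transitions
reachable_from <- function(P, from) {
  S <- nrow(P)
  seen <- rep(FALSE, S)
  frontier <- from
  repeat {
    nxt <- unique(unlist(lapply(frontier, function(s) which(P[s, ] > 0))))
    nxt <- setdiff(nxt, which(seen))
    if (length(nxt) == 0L) break
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

#' Monte-Carlo forecast of the latent chain
#'
#' Seeded ancestral rollout of a group's latent chain from a fixed start
#' state: simulates `n_chains` trajectories for `horizon` steps and returns
#' the per-step state frequencies plus the sample of first-passage times to
#' a target state (`Inf` when the chain did not reach it within the
#' horizon).
#'
#' @param params an [lmm_params] object.
#' @param group group label (0/1).
#' @param start_state initial state for every chain.
#' @param target target state for first-passage sampling (default 1, the
#'   optimal strategy).
#' @param n_chains number of simulated chains.
#' @param horizon number of steps simulated after the start.
#' @param seed integer seed.
#' @return list with `state_freq` ((horizon + 1) x S matrix, row 1 the
#'   start), `first_passage` (length `n_chains`), `n_chains`, `seed`.
#' @export
simulate_forecast <- function(params, group = 0, start_state, target = 1L,
                              n_chains = 10000L, horizon = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- as.integer(group) + 1L
  S <- params$S
  P <- transition_matrix(params, group)
  cum <- t(apply(P, 1L, cumsum))
  state <- rep(as.integer(start_state), n_chains)
  freq <- matrix(0, horizon + 1L, S)
  freq[1L, ] <- tabulate(state, S) / n_chains
  fp <- rep(Inf, n_chains)
  fp[state == target] <- 0
  for (t in seq_len(horizon)) {
    u <- stats::runif(n_chains)
    state <- max.col(cum[state, , drop = FALSE] >= u, ties.method = "first")
    freq[t + 1L, ] <- tabulate(state, S) / n_chains
    hit <- is.infinite(fp) & state == target
    fp[hit] <- t
  }
  colnames(freq) <- paste0("state", seq_len(S))
  list(state_freq = freq, first_passage = fp, n_chains = n_chains,
       seed = seed)
}
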