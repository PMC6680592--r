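#' Log-likelihood of one window's counts under one state
#'
#' Trials within a window are conditionally i.i.d. given the latent state,
#' so a window's emission log-likelihood is the multinomial kernel
#' `sum_y counts[y] * log(phi_s[y])`. The combinatorial coefficient is
#' constant in the parameters and deliberately omitted everywhere, including
#' reported log-likelihoods.
#'
#' @param counts_row length-R non-negative counts.
#' @param phi_s length-R probability vector for one state.
#' @return log-probability; `-Inf` when a category with positive count has
#'   zero probability.
#' @examples
#' window_log_emission(c(1, 1, 0), c(0.5, 0.5, 0)) # 2 * log(0.5)
#' @export
window_log_emission <- function(counts_row, phi_s) {
  if (length(counts_row) != length(phi_s))
    stop("counts and probability vector lengths differ", call. = FALSE)
  if (any(counts_row < 0)) stop("negative counts", call. = FALSE)
  pos <- counts_row > 0
  if (any(phi_s[pos] == 0)) return(-Inf)
  sum(counts_row[pos] * log(phi_s[pos]))
}

# ---- internal stacked representation -------------------------------------

# Stack an lmm_data object into arrays for vectorized recursions:
# counts (J*T) x R matrix (subject-major, phase within subject),
# g: 1-based group index per subject (all 1 when covariate is ignored).
stack_dataset <- function(dataset, covariate = TRUE) {
  J <- length(dataset)
  Tn <- attr(dataset, "T")
  R <- length(attr(dataset, "categories"))
  counts <- matrix(0, J * Tn, R)
  for (j in seq_len(J))
    counts[(j - 1L) * Tn + seq_len(Tn), ] <- dataset[[j]]$counts
  g <- vapply(dataset, `[[`, integer(1), "group")
  if (covariate) {
    lev <- sort(unique(g))
    gi <- match(g, lev)
    G <- length(lev)
  } else {
    gi <- rep(1L, J)
    G <- 1L
  }
  list(counts = counts, g = gi, J = J, T = Tn, R = R, G = G)
}

# Per-subject, per-phase, per-state emission log-probabilities, stacked as a
# (J*T) x S matrix (subject-major rows). Zero probabilities are floored in
# log space so that a zero count contributes 0 through the matrix product
# while an impossible window stays effectively -Inf.
emis_logp <- function(counts, J, Tn, phi) {
  lphi <- log(phi)
  lphi[!is.finite(lphi)] <- -1e12
  counts %*% t(lphi)                       # (J*T) x S, subject-major rows
}

# Vectorized scaled forward-backward over all subjects.
# Returns per-subject loglik, gamma (J x T x S), and expected transition
# counts per group (G x S x S), plus gamma1 sums per group.
fb_all <- function(stk, params, want_xi = TRUE) {
  J <- stk$J; Tn <- stk$T; S <- params$S; G <- stk$G
  B <- emis_logp(stk$counts, J, Tn, params$phi)     # (J*T) x S
  idx <- function(t) (seq_len(J) - 1L) * Tn + t
  m <- matrix(0, J, Tn)
  b <- vector("list", Tn)                           # J x S scaled emissions
  for (t in seq_len(Tn)) {
    Bt <- B[idx(t), , drop = FALSE]
    m[, t] <- do.call(pmax, as.data.frame(Bt))
    b[[t]] <- exp(Bt - m[, t])
  }
  Pg <- lapply(seq_len(G), function(g)
    if (params$homogeneous) matrix(params$trans[g, , ], S, S) else NULL)
  Pt <- function(g, t)
    if (params$homogeneous) Pg[[g]] else matrix(params$trans[g, t, , ], S, S)

  gsel <- lapply(seq_len(G), function(g) which(stk$g == g))
  alpha <- vector("list", Tn)
  cvec <- matrix(0, J, Tn)
  a <- matrix(params$pi_init[stk$g, ], J, S) * b[[1L]]
  cvec[, 1L] <- rowSums(a)
  if (any(cvec[, 1L] <= 0))
    stop("zero likelihood: all state paths impossible for some subject",
         call. = FALSE)
  alpha[[1L]] <- a / cvec[, 1L]
  if (Tn > 1L) for (t in 2L:Tn) {
    pred <- matrix(0, J, S)
    for (g in seq_len(G)) {
      js <- gsel[[g]]
      pred[js, ] <- alpha[[t - 1L]][js, , drop = FALSE] %*% Pt(g, t - 1L)
    }
    a <- pred * b[[t]]
    cvec[, t] <- rowSums(a)
    if (any(cvec[, t] <= 0))
      stop("zero likelihood: all state paths impossible for some subject",
           call. = FALSE)
    alpha[[t]] <- a / cvec[, t]
  }
  loglik_j <- rowSums(log(cvec)) + rowSums(m)

  beta <- vector("list", Tn)
  beta[[Tn]] <- matrix(1, J, S)
  gamma <- vector("list", Tn)
  gamma[[Tn]] <- alpha[[Tn]]
  xi_g <- if (want_xi) array(0, dim = c(G, S, S)) else NULL
  if (Tn > 1L) for (t in (Tn - 1L):1L) {
    bb <- b[[t + 1L]] * beta[[t + 1L]]               # J x S
    bt <- matrix(0, J, S)
    for (g in seq_len(G)) {
      js <- gsel[[g]]
      P <- Pt(g, t)
      bt[js, ] <- (bb[js, , drop = FALSE] %*% t(P)) / cvec[js, t + 1L]
      if (want_xi) {
        # xi[j,t,s,s'] = alpha_t[j,s] P[s,s'] bb[j,s'] / c_{t+1}[j]
        w <- alpha[[t]][js, , drop = FALSE]
        v <- bb[js, , drop = FALSE] / cvec[js, t + 1L]
        xi_g[g, , ] <- xi_g[g, , ] + (t(w) %*% v) * P
      }
    }
    beta[[t]] <- bt
    gamma[[t]] <- alpha[[t]] * bt
  }
  list(loglik_j = loglik_j, gamma = gamma, xi_g = xi_g,
       gsel = gsel, b = b, B = B)
}

#' Forward-backward recursions for one subject
#'
#' Computes the subject's log-likelihood, the smoothed state posteriors
#' `gamma[t, s] = P(S_t = s | data)`, and the pairwise posteriors
#' `xi[t, s, s'] = P(S_t = s, S_{t+1} = s' | data)`, using scaled
#' recursions that are safe against underflow for long windows.
#'
#' @param subject one element of an `lmm_data` object (list with `counts`
#'   T x R matrix and `group`), or an `lmm_data` of length 1.
#' @param params an [lmm_params] object.
#' @return list with `loglik`, `gamma` (T x S), `xi` ((T-1) x S x S).
#' @export
forward_backward <- function(subject, params) {
  if (inherits(subject, "lmm_data")) subject <- subject[[1L]]
  Tn <- nrow(subject$counts)
  ds <- new_lmm_data(list(subject), Tn, colnames(subject$counts))
  stk <- stack_dataset(ds, covariate = FALSE)
  stk$g <- if (params$G > 1L) subject$group + 1L else 1L
  stk$G <- params$G
  if (stk$g > params$G) stop("subject group exceeds model G", call. = FALSE)
  S <- params$S
  fb <- fb_all(stk, params, want_xi = FALSE)
  gamma <- do.call(rbind, lapply(fb$gamma, function(m) m[1L, ]))
  xi <- array(0, dim = c(max(Tn - 1L, 0L), S, S))
  if (Tn > 1L) xi <- fb_single_xi(stk, params)
  list(loglik = unname(fb$loglik_j[1L]), gamma = gamma, xi = xi)
}

# per-step pairwise posteriors for one stacked subject (J = 1)
fb_single_xi <- function(stk, params) {
  Tn <- stk$T; S <- params$S
  B <- emis_logp(stk$counts, 1L, Tn, params$phi)
  m <- apply(B, 1L, max)
  b <- exp(B - m)                                    # T x S
  P <- function(t) if (params$homogeneous)
    matrix(params$trans[stk$g, , ], S, S) else
      matrix(params$trans[stk$g, t, , ], S, S)
  alpha <- matrix(0, Tn, S); cvec <- numeric(Tn)
  a <- params$pi_init[stk$g, ] * b[1L, ]
  cvec[1L] <- sum(a); alpha[1L, ] <- a / cvec[1L]
  for (t in 2L:Tn) {
    a <- (alpha[t - 1L, ] %*% P(t - 1L)) * b[t, ]
    cvec[t] <- sum(a); alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(1, Tn, S)
  xi <- array(0, dim = c(Tn - 1L, S, S))
  for (t in (Tn - 1L):1L) {
    bb <- b[t + 1L, ] * beta[t + 1L, ]
    xi[t, , ] <- (alpha[t, ] %o% (bb / cvec[t + 1L])) * P(t)
    beta[t, ] <- (P(t) %*% bb) / cvec[t + 1L]
  }
  xi
}

#' Total log-likelihood of a dataset
#'
#' Sum of per-subject forward-pass log-likelihoods.
#'
#' @param dataset an `lmm_data` object.
#' @param params an [lmm_params] object.
#' @param covariate use the group labels (`TRUE`, requires `params$G >= 2`)
#'   or pool all subjects (`FALSE`, uses group-1 parameters).
#' @return scalar log-likelihood.
#' @export
loglik_dataset <- function(dataset, params, covariate = params$G > 1L) {
  stk <- stack_dataset(dataset, covariate = covariate)
  if (max(stk$g) > params$G)
    stop("dataset has more group levels than params$G", call. = FALSE)
  stk$G <- max(stk$g)
  sum(fb_all(stk, params, want_xi = FALSE)$loglik_j)
}

#' EM estimation configuration
#'
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations for the refined run.
#' @param n_starts number of random (flat-Dirichlet) starts.
#' @param start_iter EM iterations allotted to each short exploratory start
#'   before the best start is refined to convergence.
#' @param seed integer seed making the whole fit deterministic; `NULL`
#'   leaves the RNG state alone.
#' @param homogeneous time-constant transition matrices (default) or one
#'   matrix per phase transition.
#' @return list of class `em_config`.
#' @export
em_config <- function(tol = 1e-8, max_iter = 1000L, n_starts = 20L,
                      start_iter = 30L, seed = NULL, homogeneous = TRUE) {
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 n_starts = as.integer(n_starts),
                 start_iter = as.integer(start_iter),
                 seed = seed, homogeneous = isTRUE(homogeneous)),
            class = "em_config")
}

#' Read an EM configuration from a YAML file
#'
#' Recognized keys: `tol`, `max_iter`, `n_starts`, `start_iter`, `seed`,
#' `homogeneous`; missing keys take the [em_config] defaults.
#'
#' @param path YAML file path.
#' @return an `em_config`.
#' @export
read_em_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configs", call. = FALSE)
  x <- yaml::read_yaml(path)
  do.call(em_config, x[intersect(names(x), names(formals(em_config)))])
}

rdirichlet_rows <- function(n, k) {
  m <- matrix(stats::rgamma(n * k, 1), n, k)
  m / rowSums(m)
}

random_params <- function(S, R, G, Tn, homogeneous, categories) {
  phi <- rdirichlet_rows(S, R)
  pi_init <- rdirichlet_rows(G, S)
  if (homogeneous) {
    trans <- array(0, dim = c(G, S, S))
    for (g in seq_len(G)) trans[g, , ] <- rdirichlet_rows(S, S)
  } else {
    trans <- array(0, dim = c(G, Tn - 1L, S, S))
    for (g in seq_len(G)) for (t in seq_len(Tn - 1L))
      trans[g, t, , ] <- rdirichlet_rows(S, S)
  }
  lmm_params(phi, pi_init, trans, homogeneous = homogeneous,
             categories = categories)
}

# One EM run from given params; returns params, trace, convergence flag.
em_run <- function(stk, params, tol, max_iter, floor = 1e-10) {
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  Tn <- stk$T; S <- params$S; G <- stk$G
  for (it in seq_len(max_iter)) {
    fb <- fb_all(stk, params, want_xi = TRUE)
    ll <- sum(fb$loglik_j)
    trace <- c(trace, ll)
    if (it > 1L && abs(ll - ll_old) < tol * (abs(ll_old) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # M-step
    norm_rows <- function(m) {
      m <- pmax(m, floor)
      m / rowSums(m)
    }
    pi_new <- matrix(0, G, S)
    for (g in seq_len(G))
      pi_new[g, ] <- colSums(fb$gamma[[1L]][fb$gsel[[g]], , drop = FALSE])
    pi_new <- norm_rows(pi_new)
    if (params$homogeneous) {
      tr_new <- array(0, dim = c(G, S, S))
      for (g in seq_len(G)) tr_new[g, , ] <- norm_rows(fb$xi_g[g, , ])
    } else {
      stop("time-varying E-step accumulation requires per-phase xi; use em_fit(homogeneous = FALSE)", call. = FALSE)
    }
    # emission counts: sum_j sum_t gamma[j,t,s] * counts[j,t,r]
    Gmat <- matrix(0, stk$J * Tn, S)
    for (t in seq_len(Tn))
      Gmat[(seq_len(stk$J) - 1L) * Tn + t, ] <- fb$gamma[[t]]
    phi_new <- norm_rows(t(Gmat) %*% stk$counts)
    colnames(phi_new) <- colnames(params$phi)
    params <- lmm_params(phi_new, pi_new, tr_new,
                         homogeneous = params$homogeneous,
                         categories = params$categories)
  }
  list(params = params, trace = trace, converged = converged,
       loglik = trace[length(trace)])
}

# EM run with phase-specific transition matrices (kept separate: the xi
# accumulator needs the per-phase slices).
em_run_tv <- function(stk, params, tol, max_iter, floor = 1e-10) {
  Tn <- stk$T; S <- params$S; G <- stk$G; J <- stk$J
  trace <- numeric(0); ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    B <- emis_logp(stk$counts, J, Tn, params$phi)
    idx <- function(t) (seq_len(J) - 1L) * Tn + t
    b <- lapply(seq_len(Tn), function(t) {
      Bt <- B[idx(t), , drop = FALSE]
      mt <- do.call(pmax, as.data.frame(Bt))
      list(b = exp(Bt - mt), m = mt)
    })
    gsel <- lapply(seq_len(G), function(g) which(stk$g == g))
    Pt <- function(g, t) matrix(params$trans[g, t, , ], S, S)
    alpha <- vector("list", Tn); cvec <- matrix(0, J, Tn); m <- sapply(b, `[[`, "m")
    a <- matrix(params$pi_init[stk$g, ], J, S) * b[[1L]]$b
    cvec[, 1L] <- rowSums(a); alpha[[1L]] <- a / cvec[, 1L]
    for (t in 2L:Tn) {
      pred <- matrix(0, J, S)
      for (g in seq_len(G))
        pred[gsel[[g]], ] <- alpha[[t - 1L]][gsel[[g]], , drop = FALSE] %*% Pt(g, t - 1L)
      a <- pred * b[[t]]$b
      cvec[, t] <- rowSums(a); alpha[[t]] <- a / cvec[, t]
    }
    ll <- sum(log(cvec)) + sum(m)
    trace <- c(trace, ll)
    if (it > 1L && abs(ll - ll_old) < tol * (abs(ll_old) + .Machine$double.eps)) {
      converged <- TRUE; break
    }
    ll_old <- ll
    beta <- matrix(1, J, S)
    gamma <- vector("list", Tn); gamma[[Tn]] <- alpha[[Tn]]
    xi <- array(0, dim = c(G, Tn - 1L, S, S))
    for (t in (Tn - 1L):1L) {
      bb <- b[[t + 1L]]$b * beta
      bt <- matrix(0, J, S)
      for (g in seq_len(G)) {
        js <- gsel[[g]]; P <- Pt(g, t)
        bt[js, ] <- (bb[js, , drop = FALSE] %*% t(P)) / cvec[js, t + 1L]
        w <- alpha[[t]][js, , drop = FALSE]
        v <- bb[js, , drop = FALSE] / cvec[js, t + 1L]
        xi[g, t, , ] <- (t(w) %*% v) * P
      }
      beta <- bt
      gamma[[t]] <- alpha[[t]] * bt
    }
    norm_rows <- function(mm) { mm <- pmax(mm, floor); mm / rowSums(mm) }
    pi_new <- matrix(0, G, S)
    for (g in seq_len(G))
      pi_new[g, ] <- colSums(gamma[[1L]][gsel[[g]], , drop = FALSE])
    pi_new <- norm_rows(pi_new)
    tr_new <- array(0, dim = c(G, Tn - 1L, S, S))
    for (g in seq_len(G)) for (t in seq_len(Tn - 1L))
      tr_new[g, t, , ] <- norm_rows(matrix(xi[g, t, , ], S, S))
    Gmat <- matrix(0, J * Tn, S)
    for (t in seq_len(Tn)) Gmat[idx(t), ] <- gamma[[t]]
    phi_new <- norm_rows(t(Gmat) %*% stk$counts)
    colnames(phi_new) <- colnames(params$phi)
    params <- lmm_params(phi_new, pi_new, tr_new, homogeneous = FALSE,
                         categories = params$categories)
  }
  list(params = params, trace = trace, converged = converged,
       loglik = trace[length(trace)])
}

#' Fit the latent Markov model by EM
#'
#' Maximum-likelihood estimation of the covariate-stratified latent Markov
#' model on windowed count data. The measurement model `phi` is shared
#' across groups; initial and transition probabilities are group-specific
#' when `covariate = TRUE`. Estimation uses `n_starts` random starts (flat
#' Dirichlet rows), each run for a bounded number of exploratory iterations;
#' the best start is then refined to convergence. M-step updates are the
#' closed-form expected-count ratios with a small probability floor
#' (1e-10) so no row is trapped at an exact zero. States are returned in
#' canonical order (see [order_states]).
#'
#' @param dataset an `lmm_data` object (all subjects share `T`).
#' @param S number of latent states.
#' @param covariate if `TRUE` (default) stratify the latent process by the
#'   binary group label; if `FALSE` fit the basic model ignoring groups.
#' @param config an [em_config].
#' @return object of class `lmm_fit`: `params` (ordered [lmm_params]),
#'   `loglik`, `loglik_trace` (refined run), `start_logliks`,
#'   `start_traces` (per-start exploratory traces), `n_iter`,
#'   `converged`, `aic`, `bic`, `n_params`, `n_subjects`, `posteriors`
#'   (per-subject T x S smoothed state probabilities), `degenerate`
#'   (TRUE when some state collapsed to near-zero occupancy).
#' @examples
#' sim <- generate_wcst(n_per_group = c(30, 30), trials = 50, seed = 1)
#' fit <- em_fit(sim$windows, S = 2, config = em_config(n_starts = 3, seed = 1))
#' fit$params$phi
#' @export
em_fit <- function(dataset, S, covariate = TRUE, config = em_config()) {
  if (length(dataset) == 0L) stop("empty dataset", call. = FALSE)
  stk <- stack_dataset(dataset, covariate = covariate)
  if (covariate && stk$G < 2L)
    stop("covariate model requires both group levels in the data",
         call. = FALSE)
  Tn <- stk$T
  categories <- attr(dataset, "categories")
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  runner <- if (config$homogeneous) em_run else em_run_tv

  if (S == 1L) {
    # closed form: multinomial MLE, no latent dynamics
    phi <- matrix(colSums(stk$counts) / sum(stk$counts), 1L)
    colnames(phi) <- categories
    tr_dim <- if (config$homogeneous) c(stk$G, 1L, 1L) else c(stk$G, Tn - 1L, 1L, 1L)
    params <- lmm_params(phi, matrix(1, stk$G, 1L), array(1, tr_dim),
                         homogeneous = config$homogeneous,
                         categories = categories)
    ll <- sum(fb_all(stk, params, want_xi = FALSE)$loglik_j)
    best <- list(params = params, trace = ll, converged = TRUE, loglik = ll)
    start_lls <- ll
    start_traces <- list(ll)
  } else {
    starts <- lapply(seq_len(config$n_starts), function(i)
      random_params(S, stk$R, stk$G, Tn, config$homogeneous, categories))
    short <- lapply(starts, function(p)
      runner(stk, p, tol = config$tol, max_iter = config$start_iter))
    start_lls <- vapply(short, `[[`, numeric(1), "loglik")
    start_traces <- lapply(short, `[[`, "trace")
    best0 <- short[[which.max(start_lls)]]
    if (best0$converged) {
      best <- best0
    } else {
      best <- runner(stk, best0$params, tol = config$tol,
                     max_iter = config$max_iter)
      best$trace <- c(best0$trace, best$trace)
    }
  }

  fb <- fb_all(stk, best$params, want_xi = FALSE)
  posteriors <- lapply(seq_len(stk$J), function(j)
    do.call(rbind, lapply(fb$gamma, function(m) m[j, ])))
  ord <- order_states(best$params, posteriors)
  occupancy <- colSums(do.call(rbind, fb$gamma))
  # a state with (near-)zero expected occupancy, or two states with
  # indistinguishable emission rows, signals S beyond what the data identify
  dup <- FALSE
  if (S > 1L) {
    d <- as.matrix(stats::dist(best$params$phi, method = "manhattan"))
    dup <- min(d[upper.tri(d)]) < 1e-3
  }
  degenerate <- any(occupancy < 1) || dup
  if (degenerate)
    warning("degenerate fit: some latent state has near-zero occupancy; ",
            "S may exceed the number of identifiable states", call. = FALSE)
  k <- count_params(S, stk$R, stk$G, Tn, config$homogeneous)
  n <- stk$J
  structure(
    list(params = ord$params, loglik = best$loglik,
         loglik_trace = best$trace, start_logliks = start_lls,
         start_traces = start_traces,
         n_iter = length(best$trace), converged = best$converged,
         aic = -2 * best$loglik + 2 * k,
         bic = -2 * best$loglik + k * log(n),
         n_params = k, n_subjects = n, covariate = covariate && stk$G > 1L,
         posteriors = ord$posteriors, degenerate = degenerate),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Latent Markov model fit: S = %d, %s, %d subjects\n",
              x$params$S,
              if (x$covariate) "group covariate" else "no covariate",
              x$n_subjects))
  cat(sprintf("log-likelihood %.2f (%d EM iterations, %sconverged)\n",
              x$loglik, x$n_iter, if (x$converged) "" else "NOT "))
  cat(sprintf("AIC %.1f   BIC %.1f   (%d free parameters)\n",
              x$aic, x$bic, x$n_params))
  print(x$params, digits = digits)
  invisible(x)
}
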