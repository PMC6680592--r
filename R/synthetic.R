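#' Generative truth for the synthetic WCST study
#'
#' The three-state, two-group parameter set used as ground truth by the
#' synthetic-data generator. The measurement model and the group initial
#' vectors are the fitted values reported for the clinical study this
#' package models (38 substance-dependent individuals vs 44 controls); the
#' transition matrices are stipulated to reproduce the qualitative group
#' dynamics: controls are drawn strongly towards state 1 (optimal strategy)
#' with zero probability of re-entering state 3, while the SDI group has a
#' near-absorbing state 2 (sub-optimal strategy) and a sticky state 3
#' (perseverative non-optimal strategy).
#'
#' @return an [lmm_params] with S = 3 states, R = 3 categories, G = 2
#'   groups.
#' @examples
#' default_truth()$phi[, "C"] # 0.93 0.80 0.44
#' @export
default_truth <- function() {
  phi <- matrix(c(0.93, 0.02, 0.05,
                  0.80, 0.10, 0.10,
                  0.44, 0.38, 0.18), 3, 3, byrow = TRUE)
  pi_init <- matrix(c(0.57, 0.14, 0.29,
                      0.38, 0.21, 0.41), 2, 3, byrow = TRUE)
  trans <- array(0, dim = c(2, 3, 3))
  trans[1, , ] <- matrix(c(0.97, 0.02, 0.01,
                           0.90, 0.08, 0.02,
                           0.95, 0.05, 0.00), 3, 3, byrow = TRUE)
  trans[2, , ] <- matrix(c(0.25, 0.60, 0.15,
                           0.02, 0.96, 0.02,
                           0.05, 0.25, 0.70), 3, 3, byrow = TRUE)
  lmm_params(phi, pi_init, trans)
}

#' Generate a synthetic coded WCST dataset
#'
#' Ancestral sampling from the latent Markov model: for each subject a
#' latent state path is drawn (initial state from the group's initial
#' vector, subsequent states from the group's transition rows), then each
#' phase emits its window of i.i.d. categorical responses from the state's
#' emission row. Per-subject trial totals may be fixed or drawn uniformly
#' from a range, mimicking the unequal task lengths of real
#' administrations; windows are sized by the equal-partition rule of
#' [window_sizes].
#'
#' @param n_per_group length-2 integer vector: subjects in group 0
#'   (controls) and group 1 (SDI). Defaults to the study's 44 and 38.
#' @param n_phases number of task phases `T` (default 5).
#' @param trials per-subject trial total: a single number for a fixed
#'   total, or a length-2 range `c(min, max)` sampled uniformly per subject
#'   (default 80--128).
#' @param truth an [lmm_params] used as generative truth
#'   (default [default_truth()]).
#' @param seed integer seed; the output is fully reproducible from it.
#' @return list of class `wcst_sim` with `trials` (tidy trial-level data
#'   frame: `subject_id`, `group`, `trial_index`, `category`), `windows`
#'   (the corresponding `lmm_data`), `states` (J x T matrix of true latent
#'   states), `truth`, `seed`.
#' @examples
#' sim <- generate_wcst(n_per_group = c(10, 10), trials = 50, seed = 42)
#' head(sim$trials)
#' @export
generate_wcst <- function(n_per_group = c(44L, 38L), n_phases = 5L,
                          trials = c(80L, 128L), truth = default_truth(),
                          seed = NULL) {
  stopifnot(length(n_per_group) == 2L, all(n_per_group >= 1L), n_phases >= 2L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  J <- sum(n_per_group)
  groups <- rep(0:1, n_per_group)
  S <- truth$S
  cats <- truth$categories
  totals <- if (length(trials) == 1L) rep(as.integer(trials), J) else
    sample(seq(trials[1L], trials[2L]), J, replace = TRUE)
  states <- matrix(0L, J, n_phases)
  subj_rows <- vector("list", J)
  windows <- vector("list", J)
  for (j in seq_len(J)) {
    g <- groups[j] + 1L
    P <- transition_matrix(truth, groups[j])
    s <- integer(n_phases)
    s[1L] <- sample.int(S, 1L, prob = truth$pi_init[g, ])
    for (t in 2L:n_phases)
      s[t] <- sample.int(S, 1L, prob = P[s[t - 1L], ])
    states[j, ] <- s
    sizes <- window_sizes(totals[j], n_phases)
    resp <- unlist(lapply(seq_len(n_phases), function(t)
      sample(cats, sizes[t], replace = TRUE, prob = truth$phi[s[t], ])))
    id <- sprintf("S%03d", j)
    subj_rows[[j]] <- data.frame(subject_id = id, group = groups[j],
                                 trial_index = seq_len(totals[j]),
                                 category = resp)
    counts <- partition_windows(resp, n_phases, levels = cats)
    windows[[j]] <- list(subject_id = id, group = groups[j],
                         sizes = counts$sizes, counts = counts$counts)
  }
  structure(
    list(trials = do.call(rbind, subj_rows),
         windows = new_lmm_data(windows, n_phases, cats),
         states = states, truth = truth, seed = seed),
    class = "wcst_sim")
}

#' @export
print.wcst_sim <- function(x, ...) {
  cat(sprintf("Synthetic WCST dataset: %d subjects (seed %s)\n",
              nrow(x$states),
              if (is.null(x$seed)) "unset" else x$seed))
  print(x$windows)
  invisible(x)
}

#' Per-subject scoring totals and group summaries
#'
#' Collapses a simulated (or real) trial-level dataset to the classical
#' summary scores: per-subject totals of correct responses, non-perseverative
#' errors and perseverative errors, plus per-group means and standard errors
#' (SD / sqrt(N)).
#'
#' @param trials trial-level data frame with `subject_id`, `group`,
#'   `category` (e.g. `generate_wcst(...)$trials`).
#' @param levels response category labels.
#' @return list with `scores` (one row per subject: `subject_id`, `group`,
#'   one total per category) and `summary` (per group: N, mean and SE per
#'   category).
#' @export
generate_scores <- function(trials, levels = c("C", "E", "PE")) {
  tab <- table(factor(trials$subject_id, levels = unique(trials$subject_id)),
               factor(trials$category, levels = levels))
  grp <- trials$group[match(rownames(tab), trials$subject_id)]
  scores <- data.frame(subject_id = rownames(tab), group = grp,
                       as.data.frame.matrix(tab))
  rownames(scores) <- NULL
  summ <- do.call(rbind, lapply(split(scores, scores$group), function(d) {
    n <- nrow(d)
    means <- colMeans(d[levels])
    ses <- apply(d[levels], 2, stats::sd) / sqrt(n)
    data.frame(group = d$group[1L], N = n,
               t(stats::setNames(means, paste0("mean_", levels))),
               t(stats::setNames(ses, paste0("se_", levels))))
  }))
  rownames(summ) <- NULL
  list(scores = scores, summary = summ)
}
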