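#' Two-sample t-test from printed summary statistics
#'
#' Reconstructs a pooled-variance (Student) two-sample t statistic from
#' group means, standard errors and sizes, as needed when only a summary
#' table is available: each group SD is `se * sqrt(n)` and the degrees of
#' freedom are `n1 + n2 - 2`. The pooled test (rather than Welch) matches
#' the integer df such tables report.
#'
#' @param mean1,se1,n1 first group's mean, standard error and size.
#' @param mean2,se2,n2 second group's mean, standard error and size.
#' @return list with `t` (signed, `mean2 - mean1` in the numerator), `df`,
#'   `p` (two-sided).
#' @examples
#' summary_ttest(4.65, 0.42, 44, 14.28, 1.52, 38) # t about 6.50, df 80
#' @export
summary_ttest <- function(mean1, se1, n1, mean2, se2, n2) {
  if (any(c(se1, se2) <= 0) || any(c(n1, n2) < 2))
    stop("standard errors must be positive and group sizes at least 2",
         call. = FALSE)
  sd1 <- se1 * sqrt(n1)
  sd2 <- se2 * sqrt(n2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean2 - mean1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Group comparison table from per-subject scores
#'
#' Runs [summary_ttest] per response category on the group summaries of
#' [generate_scores] output (or any table in the same layout).
#'
#' @param score_summary the `summary` element of [generate_scores].
#' @param levels category labels.
#' @return data frame with one row per category: group means/SEs, t, df, p.
#' @export
score_ttests <- function(score_summary, levels = c("C", "E", "PE")) {
  stopifnot(nrow(score_summary) == 2L)
  a <- score_summary[1L, ]
  b <- score_summary[2L, ]
  rows <- lapply(levels, function(l) {
    tt <- summary_ttest(a[[paste0("mean_", l)]], a[[paste0("se_", l)]], a$N,
                        b[[paste0("mean_", l)]], b[[paste0("se_", l)]], b$N)
    data.frame(measure = l,
               mean_g0 = a[[paste0("mean_", l)]], se_g0 = a[[paste0("se_", l)]],
               mean_g1 = b[[paste0("mean_", l)]], se_g1 = b[[paste0("se_", l)]],
               t = tt$t, df = tt$df, p = tt$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- pipeline commands ----------------------------------------------------

write_manifest <- function(out_dir, command, args, seed, outputs) {
  manifest <- list(
    command = command,
    config = args,
    seed = seed,
    package_version = as.character(utils::packageVersion("wcstlmm")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs)
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Pipeline commands
#'
#' Thin command-style wrappers over the package functions. Each writes its
#' outputs (CSV/JSON only) into `out_dir` together with a run manifest
#' (command, configuration, seed, package version, timestamp, output paths)
#' sufficient to reproduce the run. `inst/cli/wcstlmm.R` dispatches to these
#' from a shell.
#'
#' `run_simulate` generates a synthetic dataset and writes the trial-level
#' and windowed CSVs. `run_fit` fits the model to a trial-level CSV and
#' writes the estimated parameters (JSON) and posteriors plus fit summary.
#' `run_select` writes the state-selection and covariate-comparison tables.
#' `run_dynamics` writes tidy marginal trajectories, absorbing states and
#' hitting times for a fitted parameter file. `run_report` writes the
#' scoring summary and group t-tests for a trial-level CSV.
#'
#' @param out_dir output directory (created if missing).
#' @param n_per_group,n_phases,trials,seed see [generate_wcst].
#' @param trials_csv path to a trial-level CSV (see [read_trials_csv]).
#' @param S number of latent states.
#' @param covariate stratify by group?
#' @param config an [em_config].
#' @param candidates state counts for [select_states].
#' @param params_json path to a parameter JSON (see [write_params_json]).
#' @param start_state,target states for the hitting-time query.
#' @return each command returns (invisibly) a list of the objects it wrote.
#' @name pipeline_commands
NULL

#' @rdname pipeline_commands
#' @export
run_simulate <- function(out_dir, n_per_group = c(44L, 38L), n_phases = 5L,
                         trials = c(80L, 128L), seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_wcst(n_per_group, n_phases, trials, seed = seed)
  paths <- c(trials = file.path(out_dir, "trials.csv"),
             windows = file.path(out_dir, "windows.csv"),
             truth = file.path(out_dir, "truth_params.json"))
  write_trials_csv(sim$trials, paths[["trials"]])
  write_windowed_csv(sim$windows, paths[["windows"]])
  write_params_json(sim$truth, paths[["truth"]])
  write_manifest(out_dir, "simulate",
                 list(n_per_group = n_per_group, n_phases = n_phases,
                      trials = trials), seed, as.list(paths))
  invisible(list(sim = sim, paths = paths))
}

#' @rdname pipeline_commands
#' @export
run_fit <- function(trials_csv, out_dir, S = 3L, covariate = TRUE,
                    n_phases = 5L, config = em_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- window_dataset(read_trials_csv(trials_csv), n_phases)
  fit <- em_fit(dataset, S, covariate = covariate, config = config)
  paths <- c(params = file.path(out_dir, "fit_params.json"),
             summary = file.path(out_dir, "fit_summary.json"))
  write_params_json(fit$params, paths[["params"]])
  jsonlite::write_json(
    list(loglik = fit$loglik, aic = fit$aic, bic = fit$bic,
         n_params = fit$n_params, n_subjects = fit$n_subjects,
         n_iter = fit$n_iter, converged = fit$converged,
         degenerate = fit$degenerate),
    paths[["summary"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, "fit",
                 list(trials_csv = trials_csv, S = S, covariate = covariate,
                      n_phases = n_phases,
                      config = unclass(config)), config$seed, as.list(paths))
  invisible(list(fit = fit, paths = paths))
}

#' @rdname pipeline_commands
#' @export
run_select <- function(trials_csv, out_dir, candidates = 1:3,
                       covariate = TRUE, n_phases = 5L,
                       config = em_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- window_dataset(read_trials_csv(trials_csv), n_phases)
  states_tab <- select_states(dataset, candidates, covariate, config)
  best_S <- states_tab$S[1L]
  cov_tab <- compare_covariate(dataset, best_S, config)
  paths <- c(states = file.path(out_dir, "selection_states.csv"),
             covariate = file.path(out_dir, "selection_covariate.csv"))
  write_selection_csv(states_tab, paths[["states"]])
  write_selection_csv(cov_tab, paths[["covariate"]])
  write_manifest(out_dir, "select",
                 list(trials_csv = trials_csv, candidates = candidates,
                      covariate = covariate, n_phases = n_phases,
                      config = unclass(config)), config$seed, as.list(paths))
  invisible(list(states = states_tab, covariate = cov_tab, paths = paths))
}

#' @rdname pipeline_commands
#' @export
run_dynamics <- function(params_json, out_dir, n_phases = 5L,
                         start_state = 3L, target = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- read_params_json(params_json)
  traj <- marginal_trajectories(params, n_phases)
  hit <- lapply(seq_len(params$G), function(g) {
    P <- transition_matrix(params, g - 1L)
    h <- expected_hitting_time(P, start_state, target)
    list(group = g - 1L, start = start_state, target = target,
         expected_steps = h$expected_steps,
         absorbing_states = detect_absorbing(P))
  })
  paths <- c(trajectories = file.path(out_dir, "marginal_trajectories.csv"),
             hitting = file.path(out_dir, "hitting_times.json"))
  utils::write.csv(trajectories_df(traj), paths[["trajectories"]],
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(hit, paths[["hitting"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_manifest(out_dir, "dynamics",
                 list(params_json = params_json, n_phases = n_phases,
                      start_state = start_state, target = target),
                 NULL, as.list(paths))
  invisible(list(trajectories = traj, hitting = hit, paths = paths))
}

#' @rdname pipeline_commands
#' @export
run_report <- function(trials_csv, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trials <- read_trials_csv(trials_csv)
  sc <- generate_scores(trials)
  tt <- score_ttests(sc$summary)
  paths <- c(scores = file.path(out_dir, "subject_scores.csv"),
             summary = file.path(out_dir, "score_summary.csv"),
             ttests = file.path(out_dir, "score_ttests.csv"))
  utils::write.csv(sc$scores, paths[["scores"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(sc$summary, paths[["summary"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(tt, paths[["ttests"]], row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, "report", list(trials_csv = trials_csv), NULL,
                 as.list(paths))
  invisible(list(scores = sc, ttests = tt, paths = paths))
}
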