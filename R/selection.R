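#' Select the number of latent states by information criteria
#'
#' Fits one model per candidate state count and tabulates log-likelihood,
#' parameter count, AIC and BIC. The BIC sample size is the number of
#' subjects, the conventional choice for subject-level longitudinal
#' mixtures. Smaller criterion values indicate a better model.
#'
#' @param dataset an `lmm_data` object.
#' @param candidates integer vector of state counts to try.
#' @param covariate stratify the latent process by group (default `TRUE`).
#' @param config an [em_config]; each candidate is fitted with the same
#'   configuration (per-candidate seeds are derived from `config$seed`).
#' @return a `selection_table` data frame with columns `model`, `S`,
#'   `covariate`, `loglik`, `n_params`, `AIC`, `BIC`, sorted by BIC; the
#'   fitted models are attached as attribute `fits`.
#' @export
select_states <- function(dataset, candidates = 1:3, covariate = TRUE,
                          config = em_config()) {
  stopifnot(length(candidates) >= 1L)
  fits <- vector("list", length(candidates))
  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    S <- candidates[i]
    cfg <- config
    if (!is.null(config$seed)) cfg$seed <- as.integer(config$seed) + S
    res <- tryCatch(em_fit(dataset, S, covariate = covariate, config = cfg),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(model = sprintf("%d-state", S), S = S,
                              covariate = covariate, loglik = NA_real_,
                              n_params = NA_integer_, AIC = NA_real_,
                              BIC = NA_real_, error = conditionMessage(res))
    } else {
      fits[[i]] <- res
      rows[[i]] <- data.frame(model = sprintf("%d-state", S), S = S,
                              covariate = res$covariate, loglik = res$loglik,
                              n_params = res$n_params, AIC = res$aic,
                              BIC = res$bic, error = NA_character_)
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$BIC)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  structure(tab, fits = fits[ord], class = c("selection_table", "data.frame"))
}

#' Compare basic and covariate models at a fixed state count
#'
#' Fits the basic model (group label ignored; one initial vector and one
#' transition matrix) and the covariate model (group-specific latent
#' process, shared measurement model) and tabulates both criteria. The
#' models are nested, so the covariate model's log-likelihood should be at
#' least as high up to EM local-optimum slack.
#'
#' @param dataset an `lmm_data` object containing both group levels.
#' @param S number of latent states.
#' @param config an [em_config].
#' @return a `selection_table` with rows `basic` and `covariate`, sorted by
#'   BIC.
#' @export
compare_covariate <- function(dataset, S, config = em_config()) {
  g <- vapply(dataset, `[[`, integer(1), "group")
  if (length(unique(g)) < 2L)
    stop("both group levels must be present", call. = FALSE)
  fit_b <- em_fit(dataset, S, covariate = FALSE, config = config)
  fit_c <- em_fit(dataset, S, covariate = TRUE, config = config)
  tab <- data.frame(
    model = c("basic", "covariate"), S = S, covariate = c(FALSE, TRUE),
    loglik = c(fit_b$loglik, fit_c$loglik),
    n_params = c(fit_b$n_params, fit_c$n_params),
    AIC = c(fit_b$aic, fit_c$aic), BIC = c(fit_b$bic, fit_c$bic),
    error = NA_character_)
  ord <- order(tab$BIC)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  structure(tab, fits = list(fit_b, fit_c)[ord],
            class = c("selection_table", "data.frame"))
}

#' @export
print.selection_table <- function(x, digits = 1, ...) {
  cat("Model selection (smaller AIC/BIC is better; n = subjects)\n\n")
  d <- as.data.frame(x)
  d$loglik <- round(d$loglik, 2)
  d$AIC <- round(d$AIC, digits)
  d$BIC <- round(d$BIC, digits)
  if (all(is.na(d$error))) d$error <- NULL
  print(d, row.names = FALSE)
  invisible(x)
}

#' Write a selection table as CSV
#'
#' @param table a `selection_table`.
#' @param path file path.
#' @export
write_selection_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
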