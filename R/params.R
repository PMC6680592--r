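#' Latent Markov model parameter set
#'
#' Bundles the three parameter blocks of the covariate-stratified latent
#' Markov model: the measurement model `phi` (per-trial response
#' probabilities given the latent state, shared across groups), the
#' group-specific initial state distributions `pi_init`, and the
#' group-specific transition matrices `trans`.
#'
#' @param phi S x R row-stochastic matrix; `phi[s, r]` is the probability of
#'   emitting response category `r` on a single trial while in latent state
#'   `s`. Columns are the coded categories, by default `C`, `E`, `PE`.
#' @param pi_init G x S row-stochastic matrix; row `g` is the distribution of
#'   the latent state at the first task phase for covariate level `g`
#'   (group 0 in row 1, group 1 in row 2).
#' @param trans transition probabilities. If `homogeneous = TRUE`, a
#'   G x S x S array (`trans[g, s, s']` = P(move from `s` to `s'` in group
#'   `g`), constant over phases); otherwise a G x (T-1) x S x S array with a
#'   per-phase transition matrix.
#' @param homogeneous logical; time-constant transition matrices (default).
#' @param categories response category labels (length R).
#'
#' @return An object of class `lmm_params` with elements `phi`, `pi_init`,
#'   `trans`, `S`, `R`, `G`, `homogeneous`, `categories`.
#' @examples
#' p <- default_truth()
#' p$phi[, "C"]
#' @export
lmm_params <- function(phi, pi_init, trans, homogeneous = TRUE,
                       categories = c("C", "E", "PE")) {
  phi <- as.matrix(phi)
  pi_init <- as.matrix(pi_init)
  S <- nrow(phi)
  R <- ncol(phi)
  G <- nrow(pi_init)
  if (ncol(pi_init) != S)
    stop("pi_init must have one column per latent state", call. = FALSE)
  trans <- as_trans_array(trans, G = G, S = S, homogeneous = homogeneous)
  if (length(categories) != R)
    stop("categories must have length R", call. = FALSE)
  colnames(phi) <- categories
  obj <- structure(
    list(phi = phi, pi_init = pi_init, trans = trans,
         S = S, R = R, G = G, homogeneous = homogeneous,
         categories = categories),
    class = "lmm_params")
  validate_lmm_params(obj)
  obj
}

# Coerce the accepted transition inputs (matrix for G=1, list of matrices,
# or array) to the canonical array layout.
as_trans_array <- function(trans, G, S, homogeneous) {
  if (is.list(trans)) {
    trans <- simplify2array(trans)        # S x S x G
    trans <- aperm(trans, c(3, 1, 2))
  } else if (is.matrix(trans) && G == 1L) {
    trans <- array(trans, dim = c(1L, S, S))
  }
  if (homogeneous) {
    if (!is.array(trans) || length(dim(trans)) != 3L ||
        !all(dim(trans) == c(G, S, S)))
      stop("trans must be a G x S x S array (or list of G matrices)",
           call. = FALSE)
  } else {
    if (!is.array(trans) || length(dim(trans)) != 4L ||
        dim(trans)[1] != G || dim(trans)[3] != S || dim(trans)[4] != S)
      stop("non-homogeneous trans must be a G x (T-1) x S x S array",
           call. = FALSE)
  }
  trans
}

validate_lmm_params <- function(p, tol = 1e-10) {
  stopifnot(inherits(p, "lmm_params"))
  chk_rows <- function(m, what) {
    if (any(m < -tol) || any(m > 1 + tol))
      stop(what, " has entries outside [0, 1]", call. = FALSE)
    rs <- if (is.matrix(m)) rowSums(m) else apply(m, seq_len(length(dim(m)) - 1L), sum)
    if (any(abs(rs - 1) > 1e-8))
      stop(what, " rows must each sum to 1", call. = FALSE)
  }
  chk_rows(p$phi, "phi")
  chk_rows(p$pi_init, "pi_init")
  chk_rows(p$trans, "trans")
  invisible(p)
}

#' Extract the transition matrix for one group (and phase)
#'
#' @param params an [lmm_params] object.
#' @param group group label, 0 or 1 (row `group + 1` of `pi_init`).
#' @param t phase transition index (from phase `t` to `t + 1`); ignored for
#'   homogeneous models.
#' @return S x S transition matrix.
#' @export
transition_matrix <- function(params, group = 0, t = 1L) {
  g <- as.integer(group) + 1L
  if (g < 1L || g > params$G) stop("unknown group level", call. = FALSE)
  if (params$homogeneous) {
    matrix(params$trans[g, , ], params$S, params$S)
  } else {
    matrix(params$trans[g, t, , ], params$S, params$S)
  }
}

#' Canonical state ordering
#'
#' Relabels latent states so that state 1 has the highest probability of a
#' correct response: states are sorted by `phi[, "C"]` descending, ties
#' broken by `phi[, "PE"]` ascending. All dependent structures (`pi_init`,
#' `trans`, and optional posterior matrices) are permuted consistently.
#' Resolves label switching after estimation.
#'
#' @param params an [lmm_params] object.
#' @param posteriors optional list of T x S posterior matrices to permute
#'   alongside.
#' @return The reordered `lmm_params`, or `list(params, posteriors)` when
#'   posteriors are supplied.
#' @export
order_states <- function(params, posteriors = NULL) {
  cc <- params$phi[, 1L]
  pe <- params$phi[, ncol(params$phi)]
  perm <- order(-cc, pe)
  out <- params
  out$phi <- params$phi[perm, , drop = FALSE]
  out$pi_init <- params$pi_init[, perm, drop = FALSE]
  if (params$homogeneous) {
    out$trans <- params$trans[, perm, perm, drop = FALSE]
  } else {
    out$trans <- params$trans[, , perm, perm, drop = FALSE]
  }
  if (is.null(posteriors)) return(out)
  list(params = out,
       posteriors = lapply(posteriors, function(m) m[, perm, drop = FALSE]))
}

#' Number of free parameters of the latent Markov model
#'
#' Counts `S*(R-1)` emission parameters, `G*(S-1)` initial probabilities and
#' `G*S*(S-1)` transition probabilities (times `T-1` if transitions are
#' phase-specific). Used for AIC/BIC.
#'
#' @param S,R,G,T model dimensions (states, response categories, covariate
#'   levels, phases).
#' @param homogeneous time-constant transitions?
#' @return integer parameter count.
#' @examples
#' count_params(S = 3, R = 3, G = 2) # 22
#' @export
count_params <- function(S, R = 3L, G = 1L, T = 5L, homogeneous = TRUE) {
  k <- if (homogeneous) 1L else T - 1L
  as.integer(S * (R - 1) + G * (S - 1) + k * G * S * (S - 1))
}

#' Write / read model parameters as JSON
#'
#' Serializes the probability blocks as plain decimal arrays with keys
#' `phi`, `pi_init`, `trans`, `S`, `R`, `G`, `homogeneous`, `categories`.
#'
#' @param params an [lmm_params] object.
#' @param path file path.
#' @return `read_params_json` returns an [lmm_params]; `write_params_json`
#'   returns `path` invisibly.
#' @export
write_params_json <- function(params, path) {
  x <- list(S = params$S, R = params$R, G = params$G,
            homogeneous = params$homogeneous,
            categories = params$categories,
            phi = unname(params$phi),
            pi_init = unname(params$pi_init),
            trans = params$trans)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  trans <- x$trans
  if (!is.array(trans)) trans <- array(unlist(trans), dim = dims_of(x))
  lmm_params(phi = x$phi, pi_init = x$pi_init, trans = trans,
             homogeneous = isTRUE(x$homogeneous),
             categories = x$categories)
}

dims_of <- function(x) {
  if (isTRUE(x$homogeneous)) c(x$G, x$S, x$S) else c(x$G, -1L, x$S, x$S)
}

#' @export
print.lmm_params <- function(x, digits = 3, ...) {
  cat(sprintf("Latent Markov model parameters: S = %d states, R = %d categories, G = %d group(s)%s\n",
              x$S, x$R, x$G,
              if (x$homogeneous) "" else " (phase-specific transitions)"))
  cat("\nEmission probabilities phi[state, category]:\n")
  print(round(x$phi, digits))
  cat("\nInitial state probabilities (row = group):\n")
  print(round(x$pi_init, digits))
  for (g in seq_len(x$G)) {
    cat(sprintf("\nTransition matrix, group %d:\n", g - 1L))
    if (x$homogeneous) {
      print(round(matrix(x$trans[g, , ], x$S, x$S), digits))
    } else {
      for (t in seq_len(dim(x$trans)[2])) {
        cat(sprintf(" phase %d -> %d\n", t, t + 1L))
        print(round(matrix(x$trans[g, t, , ], x$S, x$S), digits))
      }
    }
  }
  invisible(x)
}
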