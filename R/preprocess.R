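#' Codify a raw WCST trial into C / E / PE
#'
#' Maps a raw card-sorting trial to the three-category coding used by the
#' model: `C` (correct) when the chosen feature matches the active sorting
#' rule; `PE` (perseverative error) when feedback is negative and the chosen
#' feature matches the previously reinforced rule; `E` (non-perseverative
#' error) otherwise, including errors in the first rule block where no
#' previous rule exists.
#'
#' @param chosen_feature,active_rule character vectors over
#'   `c("color", "shape", "number")`.
#' @param previous_rule the previously reinforced rule, or `NA` when none
#'   exists (first rule block).
#' @return character vector over `c("C", "E", "PE")`.
#' @examples
#' codify_trial("color", "color", NA)       # "C"
#' codify_trial("shape", "color", "shape")  # "PE"
#' codify_trial("number", "color", "shape") # "E"
#' @export
codify_trial <- function(chosen_feature, active_rule, previous_rule = NA) {
  feats <- c("color", "shape", "number")
  n <- max(length(chosen_feature), length(active_rule), length(previous_rule))
  chosen_feature <- rep_len(as.character(chosen_feature), n)
  active_rule <- rep_len(as.character(active_rule), n)
  previous_rule <- rep_len(as.character(previous_rule), n)
  bad <- !(chosen_feature %in% feats) | !(active_rule %in% feats) |
    !(is.na(previous_rule) | previous_rule %in% feats)
  if (any(bad))
    stop("unknown feature label(s): ",
         paste(unique(c(chosen_feature, active_rule, previous_rule)[
           rep(bad, 3L)]), collapse = ", "), call. = FALSE)
  out <- ifelse(chosen_feature == active_rule, "C",
                ifelse(!is.na(previous_rule) & chosen_feature == previous_rule,
                       "PE", "E"))
  out
}

#' Codify a raw trial log for one or more subjects
#'
#' Derives the previously reinforced rule from the run structure of
#' `active_rule` (the rule in force before the most recent rule change) and
#' applies [codify_trial] row-wise within each subject. Trials in the first
#' rule block have no previous rule, so their errors are non-perseverative.
#'
#' @param log_df data frame with columns `subject_id`, `chosen_feature`,
#'   `active_rule`, ordered by trial within subject; optional `group`.
#' @return the input with added columns `previous_rule` and `category`.
#' @export
codify_log <- function(log_df) {
  stopifnot(all(c("subject_id", "chosen_feature", "active_rule") %in%
                  names(log_df)))
  parts <- split(seq_len(nrow(log_df)), log_df$subject_id)
  prev <- character(nrow(log_df))
  for (idx in parts) {
    rule <- as.character(log_df$active_rule[idx])
    r <- rle(rule)
    block <- rep(seq_along(r$lengths), r$lengths)
    prev[idx] <- c(NA_character_, r$values)[block]
  }
  log_df$previous_rule <- prev
  log_df$category <- codify_trial(log_df$chosen_feature, log_df$active_rule,
                                  prev)
  log_df
}

#' Equal-sized window lengths
#'
#' Splits `n` trials into `n_windows` contiguous windows whose sizes differ
#' by at most one; when `n = q * n_windows + r`, the first `r` windows get
#' the extra trial.
#'
#' @param n total number of trials.
#' @param n_windows number of windows (task phases).
#' @return integer vector of window sizes summing to `n`.
#' @examples
#' window_sizes(103, 5) # 21 21 21 20 20
#' @export
window_sizes <- function(n, n_windows = 5L) {
  n <- as.integer(n); n_windows <- as.integer(n_windows)
  if (n < n_windows)
    stop("fewer trials (", n, ") than windows (", n_windows, ")",
         call. = FALSE)
  q <- n %/% n_windows
  r <- n %% n_windows
  rep(q, n_windows) + rep(c(1L, 0L), c(r, n_windows - r))
}

#' Partition one subject's coded sequence into phase windows
#'
#' @param categories character vector of coded responses over
#'   `c("C", "E", "PE")` (or the labels in `levels`), in trial order.
#' @param n_windows number of task phases (default 5).
#' @param levels response category labels defining the count columns.
#' @return list with `sizes` (window lengths) and `counts`
#'   (T x R integer matrix of per-window category tallies).
#' @export
partition_windows <- function(categories, n_windows = 5L,
                              levels = c("C", "E", "PE")) {
  categories <- as.character(categories)
  if (!all(categories %in% levels))
    stop("unknown response categories: ",
         paste(setdiff(categories, levels), collapse = ", "), call. = FALSE)
  sizes <- window_sizes(length(categories), n_windows)
  phase <- rep(seq_len(n_windows), sizes)
  counts <- table(factor(phase, levels = seq_len(n_windows)),
                  factor(categories, levels = levels))
  counts <- matrix(as.integer(counts), nrow = n_windows,
                   dimnames = list(NULL, levels))
  list(sizes = sizes, counts = counts)
}

#' Windowed multi-subject dataset
#'
#' Builds the longitudinal data structure the model is fitted to: for each
#' subject, a T x R table of response-category counts per task phase, plus
#' the binary group label. Subjects may contribute unequal numbers of trials;
#' only the number of phases `T` is shared.
#'
#' @param trials data frame with columns `subject_id`, `group` (0/1),
#'   `trial_index`, `category`; one row per trial, ordered within subject by
#'   `trial_index`.
#' @param n_windows number of task phases (default 5).
#' @param levels response category labels.
#' @return an object of class `lmm_data`: a list of subjects, each with
#'   `subject_id`, `group`, `sizes`, `counts`; attributes `T` and
#'   `categories`.
#' @export
window_dataset <- function(trials, n_windows = 5L,
                           levels = c("C", "E", "PE")) {
  stopifnot(all(c("subject_id", "group", "category") %in% names(trials)))
  if ("trial_index" %in% names(trials))
    trials <- trials[order(match(trials$subject_id, unique(trials$subject_id)),
                           trials$trial_index), ]
  parts <- split(seq_len(nrow(trials)), factor(trials$subject_id,
                                               levels = unique(trials$subject_id)))
  subjects <- lapply(parts, function(idx) {
    g <- unique(trials$group[idx])
    if (length(g) != 1L)
      stop("subject with inconsistent group label", call. = FALSE)
    w <- partition_windows(trials$category[idx], n_windows, levels)
    list(subject_id = trials$subject_id[idx[1L]], group = as.integer(g),
         sizes = w$sizes, counts = w$counts)
  })
  new_lmm_data(unname(subjects), n_windows, levels)
}

new_lmm_data <- function(subjects, n_windows, levels) {
  structure(subjects, T = as.integer(n_windows), categories = levels,
            class = "lmm_data")
}

#' @export
print.lmm_data <- function(x, ...) {
  gr <- vapply(x, `[[`, integer(1), "group")
  cat(sprintf("Windowed WCST dataset: %d subjects, %d phases, categories %s\n",
              length(x), attr(x, "T"),
              paste(attr(x, "categories"), collapse = "/")))
  print(table(group = gr))
  invisible(x)
}

#' @export
as.data.frame.lmm_data <- function(x, ...) {
  Tn <- attr(x, "T")
  levels <- attr(x, "categories")
  rows <- lapply(x, function(s) {
    d <- data.frame(subject_id = s$subject_id, group = s$group,
                    phase = seq_len(Tn), window_size = s$sizes)
    cbind(d, as.data.frame(s$counts))
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) %in% levels] <- paste0("n_", levels)
  rownames(out) <- NULL
  out[c("subject_id", "group", "phase",
        paste0("n_", levels), "window_size")]
}

#' Phase slice across subjects
#'
#' Returns the aggregated phase-`t` block: every subject's count row for a
#' single task phase, preserving subject order and group labels.
#'
#' @param dataset an `lmm_data` object.
#' @param t phase index in `1..T`.
#' @return data frame with `subject_id`, `group` and one count column per
#'   response category.
#' @export
aggregate_block <- function(dataset, t) {
  Tn <- attr(dataset, "T")
  t <- as.integer(t)
  if (t < 1L || t > Tn) stop("phase index out of range 1..", Tn, call. = FALSE)
  levels <- attr(dataset, "categories")
  out <- data.frame(
    subject_id = vapply(dataset, function(s) as.character(s$subject_id),
                        character(1)),
    group = vapply(dataset, `[[`, integer(1), "group"))
  cnt <- t(vapply(dataset, function(s) s$counts[t, ], numeric(length(levels))))
  if (length(dataset) == 0L)
    cnt <- matrix(numeric(0), 0L, length(levels), dimnames = list(NULL, levels))
  out <- cbind(out, as.data.frame(cnt))
  names(out)[-(1:2)] <- paste0("n_", levels)
  rownames(out) <- NULL
  out
}

#' Read / write trial-level and windowed CSV files
#'
#' The trial-level format has columns `subject_id`, `group`, `trial_index`
#' (1-based), `category`; the windowed format has `subject_id`, `group`,
#' `phase` (1-based), `n_C`, `n_E`, `n_PE`, `window_size`.
#'
#' @param path file path.
#' @param trials trial-level data frame.
#' @param dataset an `lmm_data` object.
#' @return `read_trials_csv` returns a data frame; `read_windowed_csv`
#'   returns an `lmm_data`; writers return `path` invisibly.
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "trial_index", "category")
  if (!all(need %in% names(df)))
    stop("trial CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_trials_csv
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_trials_csv
#' @export
write_windowed_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname read_trials_csv
#' @export
read_windowed_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cnt_cols <- grep("^n_", names(df), value = TRUE)
  levels <- sub("^n_", "", cnt_cols)
  Tn <- max(df$phase)
  parts <- split(seq_len(nrow(df)), factor(df$subject_id,
                                           levels = unique(df$subject_id)))
  subjects <- lapply(parts, function(idx) {
    d <- df[idx, ][order(df$phase[idx]), ]
    counts <- as.matrix(d[cnt_cols])
    dimnames(counts) <- list(NULL, levels)
    list(subject_id = d$subject_id[1L], group = as.integer(d$group[1L]),
         sizes = as.integer(rowSums(counts)), counts = counts)
  })
  new_lmm_data(unname(subjects), Tn, levels)
}
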