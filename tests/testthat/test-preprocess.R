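test_that("codify_trial agrees with an exhaustive truth table", {
  feats <- c("color", "shape", "number")
  grid <- expand.grid(chosen = feats, active = feats,
                      previous = c(feats, NA), stringsAsFactors = FALSE)
  got <- codify_trial(grid$chosen, grid$active, grid$previous)
  want <- mapply(oracle_codify, grid$chosen, grid$active, grid$previous)
  expect_equal(unname(got), unname(want))
  # spot checks
  expect_equal(codify_trial("color", "color", NA), "C")
  expect_equal(codify_trial("shape", "color", "shape"), "PE")
  expect_equal(codify_trial("number", "color", "shape"), "E")
})

test_that("codify_trial rejects unknown feature labels", {
  expect_error(codify_trial("colour", "color", NA), "unknown feature")
})

test_that("codify_log derives the previous rule from rule-block structure", {
  log_df <- data.frame(
    subject_id = "a",
    chosen_feature = c("shape", "color", "color", "color", "shape"),
    active_rule   = c("color", "color", "shape", "shape", "shape"))
  out <- codify_log(log_df)
  # first block: no previous rule, error is E
  expect_equal(out$category[1], "E")
  expect_equal(out$category[2], "C")
  # after the rule switches to shape, sticking to color is perseverative
  expect_equal(out$category[3], "PE")
  expect_equal(out$category[4], "PE")
  expect_equal(out$category[5], "C")
})

test_that("window sizes are equal up to one, extras first", {
  expect_equal(window_sizes(100, 5), rep(20L, 5))
  expect_equal(window_sizes(103, 5), c(21L, 21L, 21L, 20L, 20L))
  expect_error(window_sizes(4, 5), "fewer trials")
  for (n in 5:40) {
    s <- window_sizes(n, 5)
    expect_equal(sum(s), n)
    expect_lte(max(s) - min(s), 1L)
    expect_true(all(diff(s) <= 0)) # larger windows come first
  }
})

test_that("partition_windows tallies categories per window and is a bijection", {
  w <- partition_windows(c("C", "C", "E", "PE", "C", "C"), 3)
  expect_equal(w$counts,
               matrix(c(2L, 0L, 0L, 0L, 1L, 1L, 2L, 0L, 0L), 3, byrow = TRUE,
                      dimnames = list(NULL, c("C", "E", "PE"))))
  set.seed(7)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    x <- sample(c("C", "E", "PE"), n, replace = TRUE)
    w <- partition_windows(x, 5)
    expect_equal(rowSums(w$counts), as.numeric(w$sizes))
    expect_equal(sum(w$counts), n)
    # re-concatenating windows reproduces the original order
    rebuilt <- unlist(lapply(seq_len(5), function(t) {
      lo <- sum(w$sizes[seq_len(t - 1L)]) + 1L
      x[lo:(lo + w$sizes[t] - 1L)]
    }))
    expect_equal(rebuilt, x)
    expect_equal(colSums(w$counts),
                 c(C = sum(x == "C"), E = sum(x == "E"), PE = sum(x == "PE")))
  }
})

test_that("window_dataset and aggregate_block preserve order and groups", {
  trials <- data.frame(
    subject_id = rep(c("b", "a"), c(10, 12)),
    group = rep(c(1L, 0L), c(10, 12)),
    trial_index = c(1:10, 1:12),
    category = rep("C", 22))
  ds <- window_dataset(trials, 5)
  expect_s3_class(ds, "lmm_data")
  expect_length(ds, 2)
  # subject order of first appearance is preserved
  expect_equal(vapply(ds, `[[`, character(1), "subject_id"), c("b", "a"))
  blk <- aggregate_block(ds, 1)
  expect_equal(blk$subject_id, c("b", "a"))
  expect_equal(blk$group, c(1L, 0L))
  expect_equal(blk$n_C, c(2, 3)) # window_sizes(10,5)=2..., (12,5)=3,3,2,2,2
  expect_error(aggregate_block(ds, 6), "out of range")
  # empty dataset gives an empty slice
  empty <- structure(list(), T = 5L, categories = c("C", "E", "PE"),
                     class = "lmm_data")
  expect_equal(nrow(aggregate_block(empty, 1)), 0L)
})

test_that("trial and windowed CSV round trips are faithful", {
  sim <- sim_small(n = 5, trials = 23, seed = 3)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_trials_csv(sim$trials, tf)
  ds <- window_dataset(read_trials_csv(tf), 5)
  expect_equal(as.data.frame(ds), as.data.frame(sim$windows))
  wf <- withr::local_tempfile(fileext = ".csv")
  write_windowed_csv(ds, wf)
  ds2 <- read_windowed_csv(wf)
  expect_equal(as.data.frame(ds2)$n_C, as.data.frame(ds)$n_C)
  expect_equal(attr(ds2, "T"), 5L)
})
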