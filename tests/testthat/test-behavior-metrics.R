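test_that("criterion learning trial follows the windowed threshold rule", {
  expect_equal(criterion_learning_trial(rep(1, 15)), 1L)
  expect_true(is.na(criterion_learning_trial(rep(0, 15))))
  # 3 opening errors, then all correct: window 1..10 holds 7/10 = 0.70
  expect_equal(criterion_learning_trial(c(0, 0, 0, rep(1, 10))), 1L)
  # 4 opening errors: window 1 fails (6/10), window 2 holds (7/10)
  expect_equal(criterion_learning_trial(c(0, 0, 0, 0, rep(1, 10))), 2L)
  # windows extending past the block end are not evaluated
  expect_true(is.na(criterion_learning_trial(rep(1, 9))))
  # threshold edge cases
  expect_equal(criterion_learning_trial(rep(0, 12), threshold = 0), 1L)
  expect_equal(criterion_learning_trial(c(0, rep(1, 10)), threshold = 1), 2L)
  expect_true(is.na(criterion_learning_trial(c(0, rep(1, 9)), threshold = 1)))
})

test_that("averaged learning curves mean, smooth, and SE correctly", {
  ident <- average_learning_curve(list(c(1, 0, 1, 1, 0), c(1, 0, 1, 1, 0)))
  expect_true(all(ident$se == 0))
  comp <- average_learning_curve(list(rep(1, 8), rep(0, 8)))
  expect_true(all(comp$prop_correct_raw == 0.5))
  # trailing smoothing from trial 4: value at trial 5 = mean of raw 2..5
  set.seed(41)
  blocks <- replicate(5, rbinom(10, 1, 0.7), simplify = FALSE)
  curve <- average_learning_curve(blocks)
  expect_equal(curve$prop_correct[5], mean(curve$prop_correct_raw[2:5]))
  expect_equal(curve$prop_correct[3], curve$prop_correct_raw[3])
  expect_error(average_learning_curve(list()), "no learned blocks")
})

test_that("post-outcome accuracy reproduces hand counts", {
  tr <- flat_trials(7, outcome = c(1L, 0L, 1L, 0L, 0L, 1L, 1L))
  ec <- post_outcome_accuracy(tr, n_after = 2, anchor = "error")
  # errors at 2, 4, 5; lag-1 outcomes: trials 3, 5, 6 -> 1, 0, 1
  expect_equal(ec$prop_correct[1], 2 / 3)
  expect_equal(ec$n[1], 3L)
  # lag-2 outcomes: trials 4, 6, 7 -> 0, 1, 1
  expect_equal(ec$prop_correct[2], 2 / 3)
  allc <- post_outcome_accuracy(flat_trials(6), n_after = 2,
                                anchor = "error")
  expect_true(all(is.na(allc$prop_correct)))
  expect_true(all(allc$n == 0))
  fe <- post_outcome_accuracy(
    flat_trials(5, outcome = c(1L, 1L, 0L, 1L, 0L)),
    n_after = 1, anchor = "first_error"
  )
  expect_equal(fe$prop_correct[1], 1) # outcome of trial 4
})

test_that("block phase restricts the anchor position", {
  out <- c(rep(1L, 4), 0L, rep(1L, 6), 0L, 0L, 1L)
  tr <- flat_trials(length(out), outcome = out)
  early <- post_outcome_accuracy(tr, n_after = 1, anchor = "error",
                                 phase = "early")
  expect_equal(early$n[1], 1L) # only the error at trial 5 is early
  expect_equal(early$prop_correct[1], 1)
  late <- post_outcome_accuracy(tr, n_after = 1, anchor = "error",
                                phase = "late")
  expect_equal(late$n[1], 2L) # errors at trials 12 and 13
  expect_equal(late$prop_correct[1], 0.5)
})

test_that("criterion and EM learning trials agree across simulated blocks", {
  set.seed(42)
  ks <- rep(6:25, each = 10)
  res <- t(vapply(ks, function(k) {
    y <- step_block(k)
    c(k, criterion_learning_trial(y),
      glance(em_learning_curve(y))$learning_trial)
  }, numeric(3)))
  med <- function(x) median(x, na.rm = TRUE)
  cohorts <- stats::aggregate(res[, 2:3], list(k = res[, 1]), med)
  rho <- suppressWarnings(
    cor(cohorts[[2]], cohorts[[3]], method = "spearman",
        use = "complete.obs")
  )
  expect_gt(rho, 0.7)
})

test_that("block summaries and rank-sum comparison run end to end", {
  s <- fixture_session()
  bs <- block_summaries(s$trials)
  expect_equal(nrow(bs), max(s$trials$block_index))
  expect_true(all(bs$criterion_learning_trial <= bs$block_length,
                  na.rm = TRUE))
  expect_true(all(bs$em_learning_trial <= bs$block_length, na.rm = TRUE))
  two <- dplyr::bind_rows(
    dplyr::mutate(bs, condition = "drug"),
    dplyr::mutate(bs, condition = "control")
  )
  cmp <- rank_sum_compare(two, "criterion_learning_trial")
  expect_equal(cmp$median_1, cmp$median_2)
  expect_gt(cmp$p_value, 0.99)
})
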