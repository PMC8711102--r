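test_that("BH step-up rejects the documented sets", {
  expect_equal(sum(bh_fdr(c(0.001, 0.01, 0.02, 0.8), alpha = 0.05)), 3L)
  expect_identical(bh_fdr(c(0.001, 0.01, 0.02, 0.8), alpha = 0.05),
                   c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(bh_fdr(rep(1, 10))))
  expect_true(all(bh_fdr(rep(0, 10))))
  expect_error(bh_fdr(c(0.2, 1.4)), "\\[0, 1\\]")
})

make_ledger <- function(sig_counts, n_iter = 100) {
  # one row per (iteration, variable); importance descending in variable order
  vars <- names(sig_counts)
  rows <- do.call(rbind, lapply(seq_len(n_iter), function(i) {
    data.frame(iteration = i, repetition = 1, fold = i,
               variable = vars,
               importance = rev(seq_along(vars)) / 100,
               p_value = 0.5,
               significant = seq_len(n_iter)[i] <= unlist(sig_counts),
               stringsAsFactors = FALSE)
  }))
  structure(rows, n_iterations = n_iter, alpha = 0.05,
            class = c("importance_ledger", "data.frame"))
}

test_that("consistency selection is inclusive at the 50% boundary", {
  ledger <- make_ledger(c(keep = 50, drop = 49, strong = 100), n_iter = 100)
  sel <- select_consistent_variables(ledger, min_fraction = 0.5)
  expect_setequal(sel$variable, c("keep", "strong"))
  all_vars <- attr(sel, "all_variables")
  expect_equal(all_vars$consistency[all_vars$variable == "drop"], 0.49)
  expect_equal(all_vars$consistency[all_vars$variable == "keep"], 0.50)
  # ordering by mean importance
  expect_equal(sel$variable[1],
               sel$variable[which.max(sel$mean_importance)])
})

test_that("permutation importance separates signal from noise with add-one floor", {
  set.seed(1)
  n <- 240
  labels <- rbinom(n, 1, 0.5)
  x <- cbind(sig = labels + rnorm(n, sd = 0.05),
             noise1 = rnorm(n), noise2 = rnorm(n),
             constant = rep(1, n))
  train <- seq_len(160)
  test <- setdiff(seq_len(n), train)
  model <- rfcourse:::fit_learner(learner_spec(n_trees = 100),
                                  x[train, ], labels[train], seed = 2)
  vp <- variable_permutation_pvalues(model, x[test, ], labels[test],
                                     n_permutations = 60, seed = 3)
  expect_equal(vp$p_value[vp$variable == "sig"], 1 / 61)
  expect_gt(vp$importance[vp$variable == "sig"], 0.2)
  # an unused constant column: permutation is a no-op, p pinned at 1
  expect_equal(vp$p_value[vp$variable == "constant"], 1)
  expect_equal(vp$importance[vp$variable == "constant"], 0)
  # noise p-values are roughly uniform, nowhere near the floor
  expect_gt(min(vp$p_value[vp$variable %in% c("noise1", "noise2")]), 0.05)
})

test_that("duplicated informative columns mask each other's importance", {
  set.seed(4)
  n <- 300
  labels <- rbinom(n, 1, 0.5)
  sig <- labels + rnorm(n, sd = 0.4)
  train <- seq_len(200)
  test <- setdiff(seq_len(n), train)
  x_dup <- cbind(a = sig, b = sig, noise = rnorm(n))
  x_solo <- cbind(a = sig, noise = x_dup[, "noise"])
  m_dup <- rfcourse:::fit_learner(learner_spec(n_trees = 150),
                                  x_dup[train, ], labels[train], seed = 5)
  m_solo <- rfcourse:::fit_learner(learner_spec(n_trees = 150),
                                   x_solo[train, ], labels[train], seed = 5)
  vp_dup <- variable_permutation_pvalues(m_dup, x_dup[test, ], labels[test],
                                         n_permutations = 40, seed = 6)
  vp_solo <- variable_permutation_pvalues(m_solo, x_solo[test, ], labels[test],
                                          n_permutations = 40, seed = 6)
  expect_lt(vp_dup$importance[vp_dup$variable == "a"],
            vp_solo$importance[vp_solo$variable == "a"])
})

test_that("the importance ledger spans iterations and applies per-iteration FDR", {
  set.seed(7)
  n <- 200
  labels <- rbinom(n, 1, 0.5)
  x <- cbind(sig = labels + rnorm(n, sd = 0.3),
             noise1 = rnorm(n), noise2 = rnorm(n))
  plan <- make_fold_plan(labels, 1, 4, seed = 8)
  # 100 permutations: the add-one floor 1/101 clears the harshest BH
  # step-up threshold alpha/3 for three variables
  ledger <- run_cv_importance(x, labels, plan, learner_spec(n_trees = 60, seed = 9),
                              n_permutations = 100, alpha = 0.05)
  expect_s3_class(ledger, "importance_ledger")
  expect_equal(attr(ledger, "n_iterations"), 4L)
  expect_equal(nrow(ledger), 4L * 3L)
  expect_true(all(ledger$p_value > 0 & ledger$p_value <= 1))
  sel <- select_consistent_variables(ledger)
  expect_true("sig" %in% sel$variable)
  expect_false(any(c("noise1", "noise2") %in% sel$variable))
})

test_that("rank differences vanish for identical ledgers and flag planted shifts", {
  ledger <- make_ledger(c(a = 100, b = 100, c = 100), n_iter = 20)
  rd <- rank_difference_analysis(ledger, ledger, n_flips = 500, seed = 1)
  expect_true(all(rd$mean_rank_diff == 0))
  expect_true(all(rd$p_value == 1))
  expect_false(any(rd$significant))

  # shift variable "a" to the bottom of the ranking in the second ledger
  flipped <- make_ledger(c(a = 100, b = 100, c = 100), n_iter = 20)
  flipped$importance[flipped$variable == "a"] <- -1
  rd2 <- rank_difference_analysis(ledger, flipped, n_flips = 2000, seed = 2)
  a_row <- rd2[rd2$variable == "a", ]
  expect_lt(a_row$mean_rank_diff, 0)   # ranks better (lower) for task A
  expect_true(a_row$significant)

  other <- make_ledger(c(a = 1, d = 1), n_iter = 20)
  expect_error(rank_difference_analysis(ledger, other), "different variable")
})
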