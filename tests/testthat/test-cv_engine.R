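test_that("fold plans stratify exactly and are deterministic in the seed", {
  labels <- rep(c(0, 1), each = 10)
  plan <- make_fold_plan(labels, n_repetitions = 3, n_folds = 10, seed = 5)
  for (r in 1:3) {
    fold <- plan$assignment[, r]
    expect_equal(as.vector(table(fold)), rep(2L, 10))
    for (f in 1:10) {
      expect_equal(sum(labels[fold == f]), 1L)  # one positive per fold
    }
  }
  plan2 <- make_fold_plan(labels, 3, 10, seed = 5)
  expect_identical(plan$assignment, plan2$assignment)
  expect_identical(plan_fingerprint(plan), plan_fingerprint(plan2))
  plan3 <- make_fold_plan(rep(c(0, 1), each = 30), 3, 10, seed = 6)
  plan4 <- make_fold_plan(rep(c(0, 1), each = 30), 3, 10, seed = 7)
  expect_false(identical(plan3$assignment, plan4$assignment))
})

test_that("a cohort-scale plan splits 484 positives into folds of 48 or 49", {
  labels <- c(rep(1, 484), rep(0, 403))
  plan <- make_fold_plan(labels, n_repetitions = 2, n_folds = 10, seed = 1)
  for (r in 1:2) {
    fold <- plan$assignment[, r]
    sizes <- as.vector(table(fold))
    expect_lte(diff(range(sizes)), 1)            # fold sizes differ by <= 1
    pos_counts <- vapply(1:10, function(f) sum(labels[fold == f]), numeric(1))
    expect_true(all(pos_counts %in% c(48, 49)))
    expect_equal(sort(unique(fold)), 1:10)       # partition is exhaustive
  }
  expect_error(make_fold_plan(c(rep(0, 50), rep(1, 5)), 1, 10, seed = 1),
               "class 1")
})

test_that("a perfectly separating feature yields near-perfect test AUC", {
  set.seed(2)
  n <- 200
  labels <- rbinom(n, 1, 0.5)
  x <- cbind(sep = labels + rnorm(n, sd = 0.05),
             noise = rnorm(n))
  plan <- make_fold_plan(labels, 1, 5, seed = 3)
  res <- run_cv(x, labels, plan, learner_spec(n_trees = 100, seed = 4))
  expect_gte(mean(per_iteration_auc(res)$all), 0.99)
})

test_that("label-independent features score at chance", {
  set.seed(5)
  n <- 300
  labels <- rbinom(n, 1, 0.5)
  x <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("v", 1:10)))
  plan <- make_fold_plan(labels, 2, 5, seed = 6)
  res <- run_cv(x, labels, plan, learner_spec(n_trees = 100, seed = 7))
  expect_lt(abs(mean(per_iteration_auc(res)$all) - 0.5), 0.05)
})

test_that("cross-validation is reproducible and matched across domain sets", {
  co <- generate_cohort(test_config(n_patients = 150, seed = 41))
  prep <- suppressWarnings(prepare_cohort(co))
  plan <- make_fold_plan(prep$labels$anxiety, 1, 3, seed = 2)
  lrn <- learner_spec(n_trees = 30, seed = 8)
  a <- run_cv(prep$table, prep$labels$anxiety, plan, lrn)
  b <- run_cv(prep$table, prep$labels$anxiety, plan, lrn)
  expect_identical(a$prob, b$prob)
  expect_identical(attr(a, "plan_fingerprint"), attr(b, "plan_fingerprint"))
  # every patient appears in exactly one test fold per repetition/domain set
  for (ds in unique(a$domain_set)) {
    ids <- a$patient_id[a$domain_set == ds & a$repetition == 1]
    expect_setequal(ids, prep$table$patient_ids)
    expect_equal(anyDuplicated(ids), 0L)
  }
})

test_that("degenerate transfer (same labels both roles) equals standard CV", {
  set.seed(9)
  n <- 150
  labels <- rbinom(n, 1, 0.5)
  x <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("v", 1:6)))
  plan <- make_fold_plan(labels, 1, 3, seed = 4)
  lrn <- learner_spec(n_trees = 30, seed = 5)
  std <- run_cv(x, labels, plan, lrn)
  trans <- run_transfer_cv(x, labels, labels, plan, lrn)
  expect_identical(std$prob, trans$prob)
  expect_identical(std$eval_label, trans$eval_label)
})

test_that("transfer against an unrelated outcome scores at chance", {
  set.seed(10)
  n <- 300
  train_lab <- rbinom(n, 1, 0.5)
  eval_lab <- rbinom(n, 1, 0.5)           # independent of features and train
  x <- cbind(sig = train_lab + rnorm(n, sd = 0.3),
             noise = rnorm(n))
  plan <- make_fold_plan(train_lab, 2, 5, seed = 11)
  res <- run_transfer_cv(x, train_lab, eval_lab, plan,
                         learner_spec(n_trees = 50, seed = 12))
  expect_lt(abs(mean(per_iteration_auc(res)$all, na.rm = TRUE) - 0.5), 0.06)
})

test_that("subgroup evaluation restricted to everyone reproduces overall AUCs", {
  set.seed(13)
  n <- 120
  labels <- rbinom(n, 1, 0.5)
  x <- cbind(sig = labels + rnorm(n), noise = rnorm(n))
  plan <- make_fold_plan(labels, 1, 4, seed = 14)
  res <- run_cv(x, labels, plan, learner_spec(n_trees = 30, seed = 15))
  full <- evaluate_subgroup(res, rep(TRUE, n), domain_set = "all")
  expect_equal(full$n_skipped, 0)
  expect_equal(sort(full$per_iteration$auc),
               sort(per_iteration_auc(res)$all))
  expect_error(evaluate_subgroup(res, rep(FALSE, n)), "empty")
  expect_error(evaluate_subgroup(res, TRUE), "every patient")
})

test_that("signal planted within one stratum surfaces in subgroup AUCs", {
  set.seed(16)
  n <- 400
  stratum <- rbinom(n, 1, 0.5)
  sig <- rnorm(n)
  # the feature predicts the outcome only inside the stratum
  eta <- ifelse(stratum == 1, 2.0 * sig, 0)
  labels <- rbinom(n, 1, plogis(eta))
  x <- cbind(sig = sig, noise = rnorm(n))
  plan <- make_fold_plan(labels, 2, 5, seed = 17)
  res <- run_cv(x, labels, plan, learner_spec(n_trees = 100, seed = 18))
  in_grp <- evaluate_subgroup(res, stratum == 1)
  out_grp <- evaluate_subgroup(res, stratum == 0)
  expect_gt(in_grp$mean_auc, out_grp$mean_auc + 0.1)
})
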