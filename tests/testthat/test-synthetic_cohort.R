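test_that("intercept calibration solves the logistic prevalence equation", {
  expect_equal(calibrate_intercept(rep(0, 10), 0.5), 0, tolerance = 1e-6)
  expect_equal(calibrate_intercept(rep(0, 10), 0.546),
               log(0.546 / 0.454), tolerance = 1e-5)
  expect_equal(calibrate_intercept(c(-1, 1), 0.5), 0, tolerance = 1e-6)
  set.seed(4)
  lp <- rnorm(500, sd = 2)
  for (target in c(0.1, 0.408, 0.546, 0.9)) {
    c0 <- calibrate_intercept(lp, target)
    expect_equal(mean(plogis(c0 + lp)), target, tolerance = 1e-6)
  }
  expect_error(calibrate_intercept(c(1, NA), 0.5), "finite")
  expect_error(calibrate_intercept(numeric(0), 0.5), "nonempty")
  expect_error(calibrate_intercept(rnorm(5), 1), "inside")
})

test_that("generator config invariants are enforced", {
  expect_error(generator_config(n_patients = 0), "positive")
  expect_error(generator_config(target_prevalence = c(anxiety = 0, cmd = 0.4)),
               "inside")
  expect_error(generator_config(item_missing_rate_range = c(0.5, 0.2)),
               "interval")
  expect_error(generator_config(item_missing_rate_range = c(0, 1)),
               "interval")
  bad_mix <- list(clinical = c(continuous = 0.5, ordinal = 0.2, nominal = 0.2))
  expect_error(small_generator_config(
    items_per_domain = c(clinical = 10), type_mix = bad_mix), "sum to 1")
})

test_that("generation is deterministic in the seed and sensitive to it", {
  cfg <- test_config(n_patients = 120, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$table$values, b$table$values)
  expect_identical(a$labels_anxiety, b$labels_anxiety)
  expect_identical(a$table$applicable, b$table$applicable)
  c <- generate_cohort(test_config(n_patients = 120, seed = 12))
  expect_false(identical(a$table$values, c$table$values))
})

test_that("prevalences hit their targets and continuous items stay positive", {
  co <- generate_cohort(test_config(n_patients = 2000, seed = 3))
  expect_lt(abs(mean(co$labels_anxiety) - 0.546), 0.03)
  expect_lt(abs(mean(co$labels_cmd) - 0.408), 0.03)
  cont <- co$table$meta$item_id[co$table$meta$kind == "continuous"]
  for (id in cont) {
    v <- co$table$values[[id]]
    expect_true(all(v[!is.na(v)] > 0))
  }
})

test_that("per-item missingness matches the drawn rates", {
  co <- generate_cohort(test_config(n_patients = 2000, seed = 8))
  observed <- item_missing_fraction(co$table)
  drawn <- co$truth$item_missing_rates[names(observed)]
  # inapplicable cells are excluded from the missingness denominator, so
  # compare on the applicable fraction
  applicable_frac <- colMeans(co$table$applicable)
  expect_true(all(abs(observed - drawn * applicable_frac) <= 0.03))
})

test_that("skip-pattern children are inapplicable exactly at the parent off level", {
  co <- generate_cohort(test_config(n_patients = 400, seed = 21))
  rules <- co$truth$skip_rules
  expect_gt(nrow(rules), 0)
  for (i in seq_len(nrow(rules))) {
    parent_v <- co$table$values[[rules$parent[i]]]
    child_app <- co$table$applicable[, rules$child[i]]
    seen <- !is.na(parent_v)
    expect_identical(child_app[seen], parent_v[seen] != rules$off_level[i])
    # inapplicable cells carry no value
    expect_true(all(is.na(co$table$values[[rules$child[i]]][!child_app])))
  }
})

test_that("the two outcomes are positively correlated through the shared factor", {
  co <- generate_cohort(test_config(n_patients = 2000, seed = 5))
  r_coupled <- cor(co$labels_anxiety, co$labels_cmd)
  expect_gt(r_coupled, 0.05)
  # removing the shared factor (and all planted signal) decouples the labels
  co0 <- generate_cohort(test_config(n_patients = 2000, seed = 5,
                                     shared_factor_weight = 0,
                                     effect_scale = list(
                                       anxiety = c(clinical = 0),
                                       cmd = c(clinical = 0))))
  r_null <- cor(co0$labels_anxiety, co0$labels_cmd)
  expect_lt(abs(r_null), 0.06)
  expect_gt(r_coupled, r_null + 0.05)
  # a heavier shared factor couples the labels more strongly
  co2 <- generate_cohort(test_config(n_patients = 2000, seed = 5,
                                     shared_factor_weight = 3))
  expect_gt(cor(co2$labels_anxiety, co2$labels_cmd), r_coupled)
})

test_that("a configured fraction of patients exceeds the 20% missingness bar", {
  co <- generate_cohort(small_generator_config(
    n_patients = 500, seed = 9, patient_high_missing_fraction = 0.108))
  frac <- patient_missing_fraction(co$table)
  high <- co$truth$high_missing_patients
  expect_equal(length(high), round(0.108 * 500))
  expect_true(all(frac[match(high, co$table$patient_ids)] > 0.20))
})

test_that("cohorts round-trip through the delimited text format", {
  co <- generate_cohort(test_config(n_patients = 60, seed = 14))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(
    dir, c("values.tsv", "items.tsv", "applicable.tsv", "labels.tsv",
           "cohort.json")))))
  back <- read_cohort(dir)
  expect_equal(back$table$values, co$table$values)
  expect_identical(back$table$applicable, co$table$applicable)
  expect_identical(back$labels_anxiety, co$labels_anxiety)
  expect_identical(back$labels_cmd, co$labels_cmd)
  expect_identical(back$table$meta$levels, co$table$meta$levels)
  expect_identical(back$table$meta$parent, co$table$meta$parent)
})
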