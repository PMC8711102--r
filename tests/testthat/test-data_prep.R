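test_that("item filter keeps items at the threshold and drops strictly above", {
  set.seed(1)
  tab <- table_with_missing(c(0, 0.10, 0.20, 0.21, 0.50), n = 100)
  out <- filter_items(tab, 0.20)
  expect_equal(n_items(out$table), 3L)
  expect_setequal(out$dropped_items, c("item_04", "item_05"))

  complete <- table_with_missing(c(0, 0, 0), n = 20)
  out2 <- filter_items(complete)
  expect_identical(out2$table$values, complete$values)
  expect_length(out2$dropped_items, 0)

  all_miss <- table_with_missing(c(0, 1), n = 20)
  expect_true("item_02" %in% filter_items(all_miss, 0.99)$dropped_items)
})

test_that("patient filter uses the fraction of retained items, boundary inclusive", {
  set.seed(2)
  values <- as.data.frame(matrix(abs(rnorm(30)) + 1, nrow = 3))
  names(values) <- sprintf("i%02d", 1:10)
  values[2, 1:2] <- NA   # 0.20 missing -> retained
  values[3, 1:3] <- NA   # 0.30 missing -> dropped
  meta <- data.frame(item_id = names(values), domain = "clinical",
                     kind = "continuous", stringsAsFactors = FALSE)
  meta$levels <- rep(list(character()), 10)
  tab <- cohort_table(values, meta)
  out <- filter_patients(tab, 0.20)
  expect_equal(n_patients(out$table), 2L)
  expect_identical(out$dropped_patients, "P0003")

  # both filters are idempotent
  again <- filter_patients(out$table, 0.20)
  expect_identical(again$table$values, out$table$values)
  fi <- filter_items(tab, 0.5)
  expect_identical(filter_items(fi$table, 0.5)$table$values, fi$table$values)
})

test_that("inapplicable cells are recoded to out-of-support sentinels", {
  tab <- mini_mixed_table()
  app <- tab$applicable
  app[1, "cont"] <- FALSE
  app[2, "nom"] <- FALSE
  values <- tab$values
  values$cont[1] <- NA
  values$nom[2] <- NA
  tab <- cohort_table(values, tab$meta, app)

  rec <- recode_inapplicable(tab)
  expect_equal(rec$values$cont[1], 0)
  expect_false(missing_mask(rec)[1, "cont"])
  expect_equal(rec$values$nom[2], "NA_CATEGORY")
  expect_identical(rec$meta$levels[[3]], c("A", "B", "NA_CATEGORY"))

  # fully applicable tables pass through unchanged
  clean <- mini_mixed_table()
  expect_identical(recode_inapplicable(clean)$values, clean$values)

  # an inapplicable cell that carries a value is inconsistent input
  bad <- mini_mixed_table()
  bad_app <- bad$applicable
  bad_app[1, "cont"] <- FALSE
  bad <- cohort_table(bad$values, bad$meta, bad_app)
  expect_error(recode_inapplicable(bad), "inconsistent")
})

test_that("imputer fills are train-set medians and modes with deterministic ties", {
  tab <- mini_mixed_table()
  model <- fit_imputer(tab, train_rows = 1:3)
  expect_equal(model$fills$cont, 2)        # median of {1, 2, 10}
  expect_equal(model$fills$nom, "A")       # mode of {A, A, B}
  expect_equal(model$fills$ord, "mid")     # median rank of {low, mid, high}

  # even-count ordinal median rounds half down to the lower level
  m2 <- fit_imputer(tab, train_rows = 1:4)  # ranks {1,2,3,2} -> median 2
  expect_equal(m2$fills$ord, "mid")
  m3 <- fit_imputer(tab, train_rows = 2:5)  # ranks {2,3,2,1} -> 2
  expect_equal(m3$fills$ord, "mid")

  # nominal modal tie broken by declared level order
  m4 <- fit_imputer(tab, train_rows = c(1, 3))  # {A, B} tie -> A
  expect_equal(m4$fills$nom, "A")

  empty <- mini_mixed_table()
  v <- empty$values
  v$cont[1:2] <- NA
  empty <- cohort_table(v, empty$meta)
  expect_error(fit_imputer(empty, train_rows = 1:2), "no observed training")
})

test_that("imputation fills depend on training rows only (leakage guard)", {
  tab <- mini_mixed_table()
  train <- 1:5
  test <- 6:8
  model_clean <- fit_imputer(tab, train)

  corrupted <- tab
  v <- corrupted$values
  v$cont[test] <- 1e6
  v$ord[test] <- "high"
  v$nom[test] <- "B"
  corrupted <- cohort_table(v, tab$meta, tab$applicable, tab$patient_ids)
  model_corrupt <- fit_imputer(corrupted, train)
  expect_identical(model_clean$fills, model_corrupt$fills)

  # applying the model removes all missingness in the target rows
  holey <- tab
  v <- holey$values
  v$cont[6] <- NA
  v$ord[7] <- NA
  holey <- cohort_table(v, tab$meta)
  imputed <- apply_imputer(holey, model_clean, rows = test)
  expect_equal(imputed$values$cont[6], 4)  # median of train values {1,2,10,4,5}
  expect_false(any(missing_mask(imputed)[test, ]))
  # complete rows pass through untouched
  expect_identical(imputed$values[1:5, ], tab$values[1:5, ])

  other <- table_with_missing(c(0, 0), n = 8)
  expect_error(apply_imputer(other, model_clean), "lacks fill")
})

test_that("learner encoding maps levels to ranks and respects domain filters", {
  tab <- mini_mixed_table()
  enc <- encode_for_learner(tab)
  expect_equal(dim(enc$x), c(8L, 3L))
  expect_true(all(is.finite(enc$x)))
  expect_equal(enc$x[1:3, "ord"], c(0, 1, 2))   # low, mid, high
  expect_identical(enc$map$item_id[enc$map$column], colnames(enc$x))

  bio <- encode_for_learner(tab, domains = "biological")
  expect_equal(colnames(bio$x), "nom")

  holey <- tab
  v <- holey$values
  v$cont[2] <- NA
  holey <- cohort_table(v, tab$meta)
  expect_error(encode_for_learner(holey), "impute before encoding")
  expect_error(encode_for_learner(tab, domains = "proteomic"), "unknown domain")
})

test_that("prepare_cohort chains recode, item filter, patient filter in order", {
  co <- generate_cohort(small_generator_config(
    n_patients = 400, seed = 31, patient_high_missing_fraction = 0.10))
  prep <- suppressWarnings(prepare_cohort(co))
  # recoded sentinel cells survive the filters as observed values
  expect_false(any(item_missing_fraction(prep$table) > 0.20))
  expect_false(any(patient_missing_fraction(prep$table) > 0.20))
  # every heavy-missingness patient is gone
  expect_true(all(co$truth$high_missing_patients %in% prep$dropped_patients))
  # labels follow the retained patients
  expect_length(prep$labels$anxiety, n_patients(prep$table))
  keep <- match(prep$table$patient_ids, co$table$patient_ids)
  expect_identical(prep$labels$cmd, co$labels_cmd[keep])
})
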