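# Fixtures are built in code: tiny cohort tables with controlled
# missingness / applicability, and a hand-rolled cv_result constructor for
# metric-level tests.

# A cohort table of `n` patients with one item per requested missing
# fraction: item i has exactly round(frac * n) missing cells.
table_with_missing <- function(fracs, n = 100, kind = "continuous") {
  values <- lapply(seq_along(fracs), function(i) {
    v <- abs(stats::rnorm(n)) + 1
    k <- round(fracs[i] * n)
    if (k > 0) v[seq_len(k)] <- NA
    v
  })
  names(values) <- sprintf("item_%02d", seq_along(fracs))
  meta <- data.frame(item_id = names(values), domain = "clinical",
                     kind = kind, stringsAsFactors = FALSE)
  meta$levels <- rep(list(character()), length(fracs))
  cohort_table(as.data.frame(values), meta)
}

# Mixed-kind mini table used by the prep tests.
mini_mixed_table <- function(n = 8) {
  values <- data.frame(
    cont = c(1, 2, 10, 4, 5, 3, 7, 9)[seq_len(n)],
    ord = c("low", "mid", "high", "mid", "low", "mid", "high", "low")[seq_len(n)],
    nom = c("A", "A", "B", "A", "B", "A", "B", "A")[seq_len(n)],
    stringsAsFactors = FALSE
  )
  meta <- data.frame(
    item_id = c("cont", "ord", "nom"),
    domain = c("clinical", "psychological", "biological"),
    kind = c("continuous", "ordinal", "nominal"),
    stringsAsFactors = FALSE
  )
  meta$levels <- list(character(), c("low", "mid", "high"), c("A", "B"))
  cohort_table(values, meta)
}

# Build a cv_result by hand from per-fold scores and labels.
make_cv_result <- function(rows, patient_ids = NULL, fp = "testplan") {
  if (is.null(patient_ids)) patient_ids <- unique(rows$patient_id)
  structure(rows,
            plan_fingerprint = fp,
            learner = learner_spec(n_trees = 1),
            patient_ids = patient_ids,
            domain_sets = unique(rows$domain_set),
            class = c("cv_result", "data.frame"))
}

# Brute-force AUC oracle: count positive-negative pairs, ties one half.
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# Small generator configuration shared by pipeline-level tests.
test_config <- function(...) {
  small_generator_config(patient_high_missing_fraction = 0, ...)
}
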