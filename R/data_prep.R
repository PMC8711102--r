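#' Drop items with excessive missingness
#'
#' Removes every item whose fraction of missing values across patients
#' strictly exceeds the threshold (items at exactly the threshold are
#' retained). Structurally inapplicable cells do not count as missing, so
#' this should normally run after [recode_inapplicable()].
#'
#' @param table A [cohort_table()].
#' @param max_missing_fraction Retention threshold; default 0.20.
#' @return List with elements `table` (filtered [cohort_table()]),
#'   `dropped_items` (character vector) and `missing_fraction` (named
#'   vector over the original items).
#' @export
filter_items <- function(table, max_missing_fraction = 0.20) {
  stopifnot(inherits(table, "cohort_table"))
  if (n_items(table) == 0L || n_patients(table) == 0L) {
    stop("cannot filter an empty cohort table")
  }
  frac <- item_missing_fraction(table)
  keep <- frac <= max_missing_fraction
  if (!any(keep)) stop("item filter would drop every item")
  out <- subset_cohort(table, cols = which(keep))
  list(table = out,
       dropped_items = names(frac)[!keep],
       missing_fraction = frac)
}

#' Drop patients with excessive missingness
#'
#' Removes every patient whose fraction of missing values across the
#' (already item-filtered) items strictly exceeds the threshold; patients at
#' exactly the threshold are retained. Run after [filter_items()] so that
#' patient missingness is computed over retained items only.
#'
#' @inheritParams filter_items
#' @return List with elements `table`, `dropped_patients` (patient ids) and
#'   `missing_fraction` (per original patient).
#' @export
filter_patients <- function(table, max_missing_fraction = 0.20) {
  stopifnot(inherits(table, "cohort_table"))
  if (n_items(table) == 0L || n_patients(table) == 0L) {
    stop("cannot filter an empty cohort table")
  }
  frac <- patient_missing_fraction(table)
  keep <- frac <= max_missing_fraction
  if (!any(keep)) stop("patient filter would drop every patient")
  out <- subset_cohort(table, rows = which(keep))
  list(table = out,
       dropped_patients = table$patient_ids[!keep],
       missing_fraction = stats::setNames(frac, table$patient_ids))
}

#' Recode structurally inapplicable cells
#'
#' Wherever an item does not apply to a patient (skip-pattern structure),
#' the cell is filled with an out-of-support sentinel so the item can still
#' be used for classification: 0 for continuous items (all observed
#' continuous values are positive) and a dedicated extra level
#' (`"NA_CATEGORY"`, appended to the level list) for ordinal and nominal
#' items. Recoded cells are no longer missing. Runs before the missingness
#' filters, since inapplicable is distinct from missing.
#'
#' @param table A [cohort_table()].
#' @param sentinel_level Name of the appended level for categorical items.
#' @return The recoded [cohort_table()].
#' @export
recode_inapplicable <- function(table, sentinel_level = "NA_CATEGORY") {
  stopifnot(inherits(table, "cohort_table"))
  values <- table$values
  meta <- table$meta
  for (j in seq_len(n_items(table))) {
    inap <- !table$applicable[, j]
    if (!any(inap)) next
    if (any(!is.na(values[[j]][inap]))) {
      stop("item '", meta$item_id[j],
           "' carries observed values in inapplicable cells; ",
           "inconsistent applicability mask")
    }
    if (meta$kind[j] == "continuous") {
      values[[j]][inap] <- 0
    } else {
      if (!sentinel_level %in% meta$levels[[j]]) {
        meta$levels[[j]] <- c(meta$levels[[j]], sentinel_level)
      }
      values[[j]][inap] <- sentinel_level
    }
  }
  cohort_table(values, meta, table$applicable, table$patient_ids)
}

#' Fit a median/mode imputation model on training rows
#'
#' Computes one fill value per item from the *training rows only*:
#' the median of observed values for continuous items, the median level
#' (by rank, rounding half down to the lower level) for ordinal items, and
#' the modal level for nominal items (ties broken by declared level order).
#'
#' @param table A [cohort_table()] (after inapplicable recoding).
#' @param train_rows Integer indices of the training rows.
#' @return An `imputation_model`: list of per-item fills plus the training
#'   row set it was fitted on.
#' @export
fit_imputer <- function(table, train_rows) {
  stopifnot(inherits(table, "cohort_table"))
  train_rows <- as.integer(train_rows)
  if (length(train_rows) == 0L) stop("train_rows must be nonempty")
  fills <- vector("list", n_items(table))
  names(fills) <- table$meta$item_id
  for (j in seq_len(n_items(table))) {
    v <- table$values[[j]][train_rows]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      stop("item '", table$meta$item_id[j],
           "' has no observed training values; cannot fit imputer")
    }
    kind <- table$meta$kind[j]
    if (kind == "continuous") {
      fills[[j]] <- stats::median(v)
    } else if (kind == "ordinal") {
      lev <- table$meta$levels[[j]]
      med_rank <- floor(stats::median(match(v, lev)))
      fills[[j]] <- lev[med_rank]
    } else {
      lev <- table$meta$levels[[j]]
      counts <- table(factor(v, levels = lev))
      fills[[j]] <- lev[which.max(counts)]   # which.max: first max wins
    }
  }
  structure(list(fills = fills, train_rows = train_rows),
            class = "imputation_model")
}

#' Apply an imputation model
#'
#' Replaces every missing cell in the given rows by the model's fill value.
#'
#' @param table A [cohort_table()].
#' @param model An `imputation_model` from [fit_imputer()].
#' @param rows Rows to impute (default: all).
#' @return The imputed [cohort_table()]; the given rows contain no missing
#'   cells afterwards.
#' @export
apply_imputer <- function(table, model, rows = seq_len(n_patients(table))) {
  stopifnot(inherits(table, "cohort_table"),
            inherits(model, "imputation_model"))
  missing_items <- setdiff(table$meta$item_id, names(model$fills))
  if (length(missing_items)) {
    stop("imputation model lacks fill values for: ",
         paste(utils::head(missing_items, 5), collapse = ", "))
  }
  values <- table$values
  rows <- as.integer(rows)
  for (j in seq_len(n_items(table))) {
    idx <- rows[is.na(values[[j]][rows])]
    if (length(idx)) {
      values[[j]][idx] <- model$fills[[table$meta$item_id[j]]]
    }
  }
  cohort_table(values, table$meta, table$applicable, table$patient_ids)
}

#' Encode a fully imputed cohort table as a numeric matrix
#'
#' Tree learners need numeric input: continuous items pass through, ordinal
#' items map to their level ranks (0-based), nominal items to integer codes
#' in declared level order (the inapplicable sentinel category is its own
#' code). Items are integer-coded rather than one-hot expanded so the
#' column count equals the item count and importances attach to items.
#'
#' @param table A fully imputed [cohort_table()].
#' @param domains Optional character vector restricting the encoding to
#'   items of the given predictor domains.
#' @return List with `x` (numeric matrix, columns named by item id) and
#'   `map` (data.frame item_id / column / domain / kind).
#' @export
encode_for_learner <- function(table, domains = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  meta <- table$meta
  cols <- seq_len(n_items(table))
  if (!is.null(domains)) {
    bad <- setdiff(domains, PREDICTOR_DOMAINS)
    if (length(bad)) stop("unknown domain(s): ", paste(bad, collapse = ", "))
    cols <- which(meta$domain %in% domains)
    if (!length(cols)) stop("no items in the requested domains")
  }
  x <- matrix(NA_real_, n_patients(table), length(cols))
  for (i in seq_along(cols)) {
    j <- cols[i]
    v <- table$values[[j]]
    if (anyNA(v)) {
      stop("item '", meta$item_id[j],
           "' still has missing cells; impute before encoding")
    }
    if (meta$kind[j] == "continuous") {
      x[, i] <- as.numeric(v)
    } else {
      code <- match(v, meta$levels[[j]]) - 1
      if (anyNA(code)) {
        stop("item '", meta$item_id[j], "' has values outside its level list")
      }
      x[, i] <- code
    }
  }
  colnames(x) <- meta$item_id[cols]
  list(x = x,
       map = data.frame(item_id = meta$item_id[cols],
                        column = seq_along(cols),
                        domain = meta$domain[cols],
                        kind = meta$kind[cols],
                        stringsAsFactors = FALSE))
}

#' Prepare a cohort for analysis
#'
#' Convenience wrapper running the standard preparation sequence: recode
#' inapplicable cells, drop items with more than `max_missing_fraction`
#' missing values, then drop patients with more than
#' `max_missing_fraction` missingness over the retained items. A warning is
#' logged (not an error) if any retained item exceeds 10\% missingness, a
#' level of missingness the imputation step is not really meant for.
#'
#' @param cohort A `synthetic_cohort` or [cohort_table()].
#' @param max_missing_fraction Threshold for both filters.
#' @return List with `table`, `labels` (named list of 0/1 vectors, if the
#'   input carried labels, subset to retained patients), `comorbidity_flag`,
#'   `dropped_items`, `dropped_patients`.
#' @export
prepare_cohort <- function(cohort, max_missing_fraction = 0.20) {
  table <- if (inherits(cohort, "synthetic_cohort")) cohort$table else cohort
  stopifnot(inherits(table, "cohort_table"))
  table <- recode_inapplicable(table)
  fi <- filter_items(table, max_missing_fraction)
  fp <- filter_patients(fi$table, max_missing_fraction)
  high <- item_missing_fraction(fp$table)
  if (any(high > 0.10)) {
    warning(sprintf(
      "%d retained item(s) exceed 10%% missingness before imputation",
      sum(high > 0.10)), call. = FALSE)
  }
  keep <- match(fp$table$patient_ids, table$patient_ids)
  labels <- NULL
  comorbidity <- NULL
  if (inherits(cohort, "synthetic_cohort")) {
    labels <- list(anxiety = cohort$labels_anxiety[keep],
                   cmd = cohort$labels_cmd[keep])
    comorbidity <- cohort$comorbidity_flag[keep]
  }
  list(table = fp$table, labels = labels, comorbidity_flag = comorbidity,
       dropped_items = fi$dropped_items,
       dropped_patients = fp$dropped_patients)
}
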