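#' Construct a cohort table of mixed-type baseline items
#'
#' The central data container: a patient-by-item table of baseline
#' predictors together with per-item metadata. Continuous items are numeric
#' columns; ordinal and nominal items are character columns whose admissible
#' values are listed (in order, for ordinal) in the metadata. `NA` encodes a
#' missing value; the `applicable` mask separately records skip-pattern
#' structure ("not applicable" is distinct from missing).
#'
#' @param values A data.frame (patients x items). Numeric columns for
#'   continuous items, character columns for ordinal/nominal items; `NA`
#'   marks a missing cell.
#' @param meta A data.frame with one row per item and columns `item_id`,
#'   `domain` (one of [PREDICTOR_DOMAINS]), `kind` (`"continuous"`,
#'   `"ordinal"` or `"nominal"`), `levels` (list column of character level
#'   vectors, empty for continuous), and optional `parent`,
#'   `parent_off_level` describing the skip pattern that gates the item.
#' @param applicable Logical matrix (patients x items); `FALSE` marks cells
#'   that are structurally inapplicable. Defaults to all-`TRUE`.
#' @param patient_ids Character vector of patient identifiers; defaults to
#'   `P0001`, `P0002`, ...
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(values, meta, applicable = NULL, patient_ids = NULL) {
  stopifnot(is.data.frame(values), is.data.frame(meta))
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  n <- nrow(values)
  p <- ncol(values)
  if (p == 0L || nrow(meta) == 0L) stop("cohort table must be nonempty")
  if (nrow(meta) != p) {
    stop("meta must have exactly one row per item column")
  }
  if (!all(c("item_id", "domain", "kind") %in% names(meta))) {
    stop("meta needs columns item_id, domain, kind")
  }
  if (is.null(meta$levels)) meta$levels <- rep(list(character()), p)
  if (is.null(meta$parent)) meta$parent <- NA_character_
  if (is.null(meta$parent_off_level)) meta$parent_off_level <- NA_character_
  if (anyDuplicated(meta$item_id)) stop("duplicate item ids in meta")
  if (!identical(names(values), meta$item_id)) {
    if (!setequal(names(values), meta$item_id)) {
      stop("column names of values must match meta$item_id")
    }
    meta <- meta[match(names(values), meta$item_id), , drop = FALSE]
  }
  bad_domain <- setdiff(unique(meta$domain), PREDICTOR_DOMAINS)
  if (length(bad_domain)) {
    stop("unknown predictor domain(s): ", paste(bad_domain, collapse = ", "))
  }
  if (!all(meta$kind %in% c("continuous", "ordinal", "nominal"))) {
    stop("item kind must be continuous, ordinal or nominal")
  }
  cont <- meta$kind == "continuous"
  if (any(lengths(meta$levels[cont]) > 0L)) {
    stop("continuous items must have an empty level list")
  }
  if (any(lengths(meta$levels[!cont]) == 0L)) {
    stop("ordinal/nominal items must declare their levels")
  }
  if (any(!is.na(meta$parent) & is.na(meta$parent_off_level))) {
    stop("items with a parent must declare parent_off_level")
  }
  if (is.null(applicable)) {
    applicable <- matrix(TRUE, n, p)
  }
  applicable <- as.matrix(applicable)
  storage.mode(applicable) <- "logical"
  if (!identical(dim(applicable), c(n, p))) {
    stop("applicable mask must match the dimensions of values")
  }
  dimnames(applicable) <- list(NULL, names(values))
  if (is.null(patient_ids)) patient_ids <- sprintf("P%04d", seq_len(n))
  if (length(patient_ids) != n) stop("patient_ids must have one id per row")
  rownames(meta) <- NULL
  structure(
    list(values = values, meta = meta, applicable = applicable,
         patient_ids = as.character(patient_ids)),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d patients x %d items\n",
              n_patients(x), n_items(x)))
  tab <- table(factor(x$meta$domain, levels = PREDICTOR_DOMAINS))
  cat("  items per domain:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  missing cells: %.1f%%; inapplicable cells: %.1f%%\n",
              100 * mean(missing_mask(x)), 100 * mean(!x$applicable)))
  invisible(x)
}

#' Number of patients / items in a cohort table
#' @param table A [cohort_table()].
#' @return Integer count.
#' @export
n_patients <- function(table) nrow(table$values)

#' @rdname n_patients
#' @export
n_items <- function(table) ncol(table$values)

#' Missingness mask of a cohort table
#'
#' A cell is missing when its value is absent *and* the item applies to the
#' patient: structurally inapplicable cells do not count as missing.
#'
#' @param table A [cohort_table()].
#' @return Logical matrix (patients x items).
#' @export
missing_mask <- function(table) {
  m <- is.na(as.matrix(table$values)) & table$applicable
  dimnames(m) <- list(NULL, names(table$values))
  m
}

#' Per-item and per-patient missing fractions
#' @param table A [cohort_table()].
#' @return Named numeric vector of missing fractions.
#' @export
item_missing_fraction <- function(table) colMeans(missing_mask(table))

#' @rdname item_missing_fraction
#' @export
patient_missing_fraction <- function(table) rowMeans(missing_mask(table))

subset_cohort <- function(table, rows = NULL, cols = NULL) {
  values <- table$values
  applicable <- table$applicable
  meta <- table$meta
  ids <- table$patient_ids
  if (!is.null(cols)) {
    values <- values[, cols, drop = FALSE]
    applicable <- applicable[, cols, drop = FALSE]
    meta <- meta[match(names(values), meta$item_id), , drop = FALSE]
  }
  if (!is.null(rows)) {
    values <- values[rows, , drop = FALSE]
    applicable <- applicable[rows, , drop = FALSE]
    ids <- ids[rows]
    rownames(values) <- NULL
  }
  cohort_table(values, meta, applicable, ids)
}
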