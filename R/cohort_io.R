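#' Write a cohort to delimited text files
#'
#' Serializes a cohort as plain-text artifacts in a directory:
#' `values.tsv` (patients x items; empty cell = missing),
#' `items.tsv` (item metadata; levels pipe-joined),
#' `applicable.tsv` (0/1 applicability mask),
#' `labels.tsv` (outcome labels and comorbidity flag, when present), and
#' `cohort.json` (generator config and planted ground truth, when present).
#'
#' @param cohort A `synthetic_cohort` or [cohort_table()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  table <- if (inherits(cohort, "synthetic_cohort")) cohort$table else cohort
  stopifnot(inherits(table, "cohort_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vals <- cbind(patient_id = table$patient_ids, table$values)
  utils::write.table(vals, file.path(dir, "values.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  meta <- table$meta
  meta_out <- data.frame(
    item_id = meta$item_id, domain = meta$domain, kind = meta$kind,
    levels = vapply(meta$levels, paste, character(1), collapse = "|"),
    parent = ifelse(is.na(meta$parent), "", meta$parent),
    parent_off_level = ifelse(is.na(meta$parent_off_level), "",
                              meta$parent_off_level),
    stringsAsFactors = FALSE
  )
  utils::write.table(meta_out, file.path(dir, "items.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  app <- cbind(patient_id = table$patient_ids,
               as.data.frame(table$applicable * 1L))
  utils::write.table(app, file.path(dir, "applicable.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (inherits(cohort, "synthetic_cohort")) {
    labs <- data.frame(patient_id = table$patient_ids,
                       recovery_anxiety = cohort$labels_anxiety,
                       recovery_cmd = cohort$labels_cmd,
                       comorbidity = cohort$comorbidity_flag)
    utils::write.table(labs, file.path(dir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sidecar <- list(config = unclass(cohort$config), truth = cohort$truth)
    jsonlite::write_json(sidecar, file.path(dir, "cohort.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return A `synthetic_cohort` if label/ground-truth files are present,
#'   else a bare [cohort_table()].
#' @export
read_cohort <- function(dir) {
  vals <- utils::read.delim(file.path(dir, "values.tsv"), sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE,
                            na.strings = "")
  meta_in <- utils::read.delim(file.path(dir, "items.tsv"), sep = "\t",
                               stringsAsFactors = FALSE,
                               colClasses = "character")
  patient_ids <- vals$patient_id
  vals$patient_id <- NULL
  meta <- data.frame(item_id = meta_in$item_id, domain = meta_in$domain,
                     kind = meta_in$kind, stringsAsFactors = FALSE)
  meta$levels <- lapply(meta_in$levels, function(s) {
    if (is.na(s) || s == "") character() else strsplit(s, "|", fixed = TRUE)[[1]]
  })
  meta$parent <- ifelse(meta_in$parent == "", NA_character_, meta_in$parent)
  meta$parent_off_level <- ifelse(meta_in$parent_off_level == "",
                                  NA_character_, meta_in$parent_off_level)
  # enforce column types (a fully missing categorical column reads as logical)
  for (j in seq_len(nrow(meta))) {
    id <- meta$item_id[j]
    vals[[id]] <- if (meta$kind[j] == "continuous") {
      as.numeric(vals[[id]])
    } else {
      as.character(vals[[id]])
    }
  }
  app_path <- file.path(dir, "applicable.tsv")
  applicable <- NULL
  if (file.exists(app_path)) {
    app <- utils::read.delim(app_path, sep = "\t", check.names = FALSE)
    app$patient_id <- NULL
    applicable <- as.matrix(app) == 1
  }
  table <- cohort_table(vals, meta, applicable, patient_ids)
  lab_path <- file.path(dir, "labels.tsv")
  if (!file.exists(lab_path)) return(table)
  labs <- utils::read.delim(lab_path, sep = "\t")
  truth <- NULL
  config <- NULL
  json_path <- file.path(dir, "cohort.json")
  if (file.exists(json_path)) {
    sidecar <- jsonlite::read_json(json_path, simplifyVector = TRUE)
    truth <- sidecar$truth
    config <- sidecar$config
  }
  structure(
    list(table = table,
         labels_anxiety = labs$recovery_anxiety,
         labels_cmd = labs$recovery_cmd,
         comorbidity_flag = labs$comorbidity,
         truth = truth, config = config),
    class = "synthetic_cohort"
  )
}
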