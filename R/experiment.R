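#' Configuration of a full experiment
#'
#' Bundles every stage's parameters: cohort generation (or an external
#' cohort directory), preparation thresholds, cross-validation shape,
#' learner hyperparameters, significance testing, variable importance,
#' and the transfer / subgroup toggles. Every source of randomness derives
#' from `master_seed`.
#'
#' @param generator A [generator_config()], or a path to a directory
#'   written by [write_cohort()].
#' @param learner A [learner_spec()].
#' @param cv List: `n_repetitions`, `n_folds` (default 10 x 10).
#' @param tests List: `enabled`, `n_label_permutations`, `scheme`
#'   (`"reduced_rerun"` reruns one `perm_folds`-fold repetition per
#'   permutation, `"full_rerun"` the full plan), `perm_folds`,
#'   `n_sign_flips`, `alpha`.
#' @param importance List: `enabled`, `n_permutations`, `alpha`,
#'   `min_fraction`, `n_iterations` (cap on iterations scored; `NULL` =
#'   all).
#' @param transfer,subgroup Logical toggles.
#' @param threshold Classification threshold for confusion metrics.
#' @param max_missing_fraction Missingness threshold for both filters.
#' @param master_seed Integer master seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(generator = generator_config(),
                              learner = learner_spec(),
                              cv = list(n_repetitions = 10, n_folds = 10),
                              tests = list(),
                              importance = list(),
                              transfer = TRUE,
                              subgroup = TRUE,
                              threshold = 0.5,
                              max_missing_fraction = 0.20,
                              master_seed = 1L) {
  tests <- utils::modifyList(
    list(enabled = TRUE, n_label_permutations = 1000,
         scheme = "reduced_rerun", perm_folds = 10,
         n_sign_flips = 10000, alpha = 0.05),
    tests)
  importance <- utils::modifyList(
    list(enabled = TRUE, n_permutations = 1000, alpha = 0.05,
         min_fraction = 0.5, n_iterations = NULL),
    importance)
  stopifnot(tests$scheme %in% c("reduced_rerun", "full_rerun"),
            cv$n_repetitions >= 1, cv$n_folds >= 2)
  structure(
    list(generator = generator, learner = learner, cv = cv, tests = tests,
         importance = importance, transfer = isTRUE(transfer),
         subgroup = isTRUE(subgroup), threshold = threshold,
         max_missing_fraction = max_missing_fraction,
         master_seed = as.integer(master_seed)),
    class = "experiment_config"
  )
}

#' Run the full experiment
#'
#' Executes the enabled stages in order: simulate (or load) the cohort;
#' recode/filter/prepare; build one matched fold plan per task; run the
#' domain-wise cross-validation for both tasks; summarize scores;
#' label-permutation tests per domain set (Bonferroni over the six sets);
#' pairwise domain comparison by matched-fold sign-flip tests (Bonferroni
#' over all pairs x tasks); permutation variable importance with
#' consistency selection on the all-domain models of both tasks and the
#' between-task rank-difference analysis; transfer-label evaluation; and
#' subgroup evaluation by baseline comorbidity.
#'
#' @param config An [experiment_config()].
#' @return An `experiment_report` list with elements `cohort_summary`,
#'   `cv_results`, `summaries`, `permutation_tests`, `comparison`,
#'   `importance`, `transfer`, `subgroup`, and `manifest`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  seed0 <- config$master_seed

  cohort <- if (is.character(config$generator)) {
    read_cohort(config$generator)
  } else {
    generate_cohort(config$generator)
  }
  prep <- prepare_cohort(cohort, config$max_missing_fraction)
  table <- prep$table
  labels <- prep$labels
  if (is.null(labels)) stop("the cohort carries no outcome labels")
  tasks <- names(labels)

  plans <- lapply(tasks, function(task) {
    make_fold_plan(labels[[task]], config$cv$n_repetitions,
                   config$cv$n_folds, seed = derive_seed(seed0, "plan", task))
  })
  names(plans) <- tasks

  learner <- config$learner
  cv_results <- list()
  summaries <- list()
  for (task in tasks) {
    lrn <- learner
    lrn$seed <- derive_seed(seed0, "learner", task)
    cv_results[[task]] <- run_cv(table, labels[[task]], plans[[task]], lrn)
    summaries[[task]] <- summarize_cv(cv_results[[task]], config$threshold)
  }
  domain_sets_used <- attr(cv_results[[1]], "domain_sets")

  # ---- label-permutation tests ----------------------------------------
  permutation_tests <- NULL
  if (isTRUE(config$tests$enabled)) {
    permutation_tests <- list()
    m_family <- length(domain_sets_used)
    for (task in tasks) {
      per_task <- list()
      for (ds in domain_sets_used) {
        ds_domains <- if (ds == "all") {
          intersect(PREDICTOR_DOMAINS, unique(table$meta$domain))
        } else ds
        stat_fn <- local({
          ds_domains <- ds_domains
          task_c <- task
          function(lab) {
            if (config$tests$scheme == "reduced_rerun") {
              plan1 <- make_fold_plan(lab, 1, config$tests$perm_folds,
                                      seed = derive_seed(seed0, "permplan",
                                                         task_c))
            } else {
              plan1 <- make_fold_plan(lab, config$cv$n_repetitions,
                                      config$cv$n_folds,
                                      seed = derive_seed(seed0, "permplan",
                                                         task_c))
            }
            lrn1 <- learner
            lrn1$seed <- derive_seed(seed0, "permfit", task_c)
            res <- run_cv(table, lab, plan1, lrn1,
                          domain_sets = stats::setNames(list(ds_domains), "s"))
            mean(per_iteration_auc(res)[["s"]], na.rm = TRUE)
          }
        })
        per_task[[ds]] <- label_permutation_test(
          stat_fn, labels[[task]],
          n_permutations = config$tests$n_label_permutations,
          seed = derive_seed(seed0, "labelperm", task, ds),
          m = m_family
        )
      }
      permutation_tests[[task]] <- per_task
    }
  }

  # ---- pairwise domain comparison -------------------------------------
  comparison <- NULL
  if (isTRUE(config$tests$enabled)) {
    comparison <- compare_domains(cv_results,
                                  n_flips = config$tests$n_sign_flips,
                                  alpha = config$tests$alpha,
                                  seed = derive_seed(seed0, "compare"))
  }

  # ---- variable importance --------------------------------------------
  importance_out <- NULL
  if (isTRUE(config$importance$enabled)) {
    ledgers <- list()
    selections <- list()
    for (task in tasks) {
      iters <- NULL
      cap <- config$importance$n_iterations
      if (!is.null(cap)) {
        all_iters <- expand.grid(fold = seq_len(config$cv$n_folds),
                                 repetition = seq_len(config$cv$n_repetitions))
        all_iters <- all_iters[, c("repetition", "fold")]
        iters <- utils::head(all_iters, cap)
      }
      lrn <- learner
      lrn$seed <- derive_seed(seed0, "importance", task)
      ledgers[[task]] <- run_cv_importance(
        table, labels[[task]], plans[[task]], lrn,
        n_permutations = config$importance$n_permutations,
        alpha = config$importance$alpha, iterations = iters
      )
      selections[[task]] <- select_consistent_variables(
        ledgers[[task]], config$importance$min_fraction)
    }
    rank_diff <- NULL
    if (length(tasks) == 2L) {
      rank_diff <- rank_difference_analysis(
        ledgers[[1]], ledgers[[2]],
        n_flips = config$tests$n_sign_flips,
        alpha = config$importance$alpha,
        seed = derive_seed(seed0, "rankdiff"))
    }
    importance_out <- list(ledgers = ledgers, selected = selections,
                           rank_differences = rank_diff)
  }

  # ---- transfer analysis ----------------------------------------------
  transfer_out <- NULL
  if (isTRUE(config$transfer) && length(tasks) == 2L) {
    lrn <- learner
    lrn$seed <- derive_seed(seed0, "transfer")
    transfer_cv <- run_transfer_cv(table, labels[["cmd"]],
                                   labels[["anxiety"]], plans[["cmd"]], lrn)
    transfer_summary <- summarize_cv(transfer_cv, config$threshold)
    base <- summaries[["anxiety"]]$summary
    trans <- transfer_summary$summary
    key <- paste(trans$domain_set, trans$metric)
    base_m <- base$mean[match(key, paste(base$domain_set, base$metric))]
    deltas <- data.frame(domain_set = trans$domain_set, metric = trans$metric,
                         transfer_mean = trans$mean, standard_mean = base_m,
                         delta = trans$mean - base_m,
                         stringsAsFactors = FALSE)
    transfer_out <- list(cv_result = transfer_cv, summary = transfer_summary,
                         deltas = deltas)
  }

  # ---- subgroup analysis ----------------------------------------------
  subgroup_out <- NULL
  if (isTRUE(config$subgroup) && !is.null(prep$comorbidity_flag)) {
    subgroup_out <- lapply(tasks, function(task) {
      list(comorbidity = evaluate_subgroup(cv_results[[task]],
                                           prep$comorbidity_flag == 1),
           no_comorbidity = evaluate_subgroup(cv_results[[task]],
                                              prep$comorbidity_flag == 0))
    })
    names(subgroup_out) <- tasks
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("rfcourse")),
    master_seed = seed0,
    plan_fingerprints = lapply(plans, plan_fingerprint),
    n_patients = n_patients(table),
    n_items = n_items(table),
    dropped_items = prep$dropped_items,
    dropped_patients = prep$dropped_patients,
    domain_sets = domain_sets_used,
    learner = unclass(learner),
    cv = config$cv, tests = config$tests, importance = config$importance,
    threshold = config$threshold
  )

  structure(
    list(cohort_summary = list(
           n_patients = n_patients(table), n_items = n_items(table),
           prevalence = vapply(labels, mean, numeric(1)),
           comorbidity_rate = if (!is.null(prep$comorbidity_flag))
             mean(prep$comorbidity_flag) else NA_real_),
         prepared = prep,
         plans = plans,
         cv_results = cv_results,
         summaries = summaries,
         permutation_tests = permutation_tests,
         comparison = comparison,
         importance = importance_out,
         transfer = transfer_out,
         subgroup = subgroup_out,
         manifest = manifest,
         config = config),
    class = "experiment_report"
  )
}

format_score_table <- function(summary_df, perm_tests = NULL) {
  metrics <- c("auc", "balanced_accuracy", "sensitivity", "specificity",
               "ppv", "npv")
  sets <- unique(summary_df$domain_set)
  out <- data.frame(domain_set = sets, stringsAsFactors = FALSE)
  for (m in metrics) {
    sel <- summary_df[summary_df$metric == m, ]
    out[[m]] <- sprintf("%.3f (%.3f)",
                        sel$mean[match(sets, sel$domain_set)],
                        sel$sd[match(sets, sel$domain_set)])
  }
  if (!is.null(perm_tests)) {
    out$perm_p_adjusted <- vapply(sets, function(s) {
      if (!is.null(perm_tests[[s]])) perm_tests[[s]]$adjusted_p else NA_real_
    }, numeric(1))
  }
  out
}

#' Write an experiment report to delimited files
#'
#' Emits, under `dir`: per-task performance tables (domain sets x metrics
#' as `mean (sd)` with the permutation-test adjusted p per row), the
#' pairwise comparison table, per-task selected-variable tables and
#' importance ledgers, the between-task rank-difference table, the
#' transfer delta table, the subgroup AUC table, the per-task columnar CV
#' results, and a JSON manifest of seeds and settings. Every number in the
#' report is recomputable from the persisted CV result files.
#'
#' @param report An `experiment_report` from [run_experiment()].
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  for (task in names(report$summaries)) {
    put(format_score_table(report$summaries[[task]]$summary,
                           report$permutation_tests[[task]]),
        sprintf("performance_%s.csv", task))
    put(report$cv_results[[task]], sprintf("cv_result_%s.csv", task))
  }
  if (!is.null(report$comparison)) {
    put(as.data.frame(report$comparison), "domain_comparisons.csv")
  }
  if (!is.null(report$importance)) {
    for (task in names(report$importance$ledgers)) {
      put(as.data.frame(report$importance$ledgers[[task]]),
          sprintf("importance_ledger_%s.csv", task))
      put(attr(report$importance$selected[[task]], "all_variables"),
          sprintf("importance_variables_%s.csv", task))
    }
    if (!is.null(report$importance$rank_differences)) {
      put(report$importance$rank_differences, "rank_differences.csv")
    }
  }
  if (!is.null(report$transfer)) {
    put(report$transfer$deltas, "transfer_deltas.csv")
  }
  if (!is.null(report$subgroup)) {
    rows <- list()
    for (task in names(report$subgroup)) {
      for (grp in names(report$subgroup[[task]])) {
        ev <- report$subgroup[[task]][[grp]]
        rows[[length(rows) + 1L]] <- data.frame(
          task = task, subgroup = grp, mean_auc = ev$mean_auc,
          n_iterations = nrow(ev$per_iteration), n_skipped = ev$n_skipped,
          stringsAsFactors = FALSE)
      }
    }
    put(do.call(rbind, rows), "subgroup_auc.csv")
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(report$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, manifest_path)
  invisible(files)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  cat(sprintf("  cohort: %d patients x %d items\n",
              x$cohort_summary$n_patients, x$cohort_summary$n_items))
  for (task in names(x$summaries)) {
    s <- x$summaries[[task]]$summary
    auc <- s[s$metric == "auc", ]
    best <- auc[which.max(auc$mean), ]
    cat(sprintf("  %s: best domain set '%s' AUC %.3f (sd %.3f)\n",
                task, best$domain_set, best$mean, best$sd))
  }
  invisible(x)
}
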