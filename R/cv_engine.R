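#' Build a matched fold plan for repeated stratified cross-validation
#'
#' Assigns every patient to one test fold per repetition, stratified by
#' class: fold sizes differ by at most one patient overall and by at most
#' one within each class. The *same* plan object is reused across every
#' predictor-domain run (and, in transfer mode, for both label sets), which
#' is what licenses paired per-iteration comparisons later.
#'
#' @param labels 0/1 outcome vector (stratification labels).
#' @param n_repetitions Number of repetitions (default 10).
#' @param n_folds Number of folds per repetition (default 10).
#' @param seed Integer seed; the plan is deterministic in it.
#' @return A `fold_plan`: list with `assignment` (patients x repetitions
#'   integer matrix of fold indices), counts and the seed.
#' @export
make_fold_plan <- function(labels, n_repetitions = 10, n_folds = 10, seed = 1L) {
  assert_binary_labels(labels)
  n <- length(labels)
  for (cl in c(0, 1)) {
    if (sum(labels == cl) < n_folds) {
      stop(sprintf("class %d has %d members, fewer than n_folds = %d",
                   cl, sum(labels == cl), n_folds))
    }
  }
  assignment <- withr::with_seed(seed, {
    vapply(seq_len(n_repetitions), function(r) {
      fold <- integer(n)
      sizes <- integer(n_folds)
      # stratify: deal each class out in (near-)equal counts, sending the
      # leftover members of the second class to the currently smallest folds
      for (cl in c(1, 0)) {
        idx <- sample(which(labels == cl))
        k <- length(idx)
        base <- k %/% n_folds
        extra <- k %% n_folds
        extra_folds <- order(sizes, stats::runif(n_folds))[seq_len(extra)]
        counts <- rep(base, n_folds)
        counts[extra_folds] <- counts[extra_folds] + 1L
        fold[idx] <- rep(seq_len(n_folds), counts)
        sizes <- sizes + counts
      }
      fold
    }, integer(n))
  })
  structure(
    list(n_repetitions = as.integer(n_repetitions),
         n_folds = as.integer(n_folds),
         assignment = assignment,
         n_patients = n,
         seed = as.integer(seed)),
    class = "fold_plan"
  )
}

#' Fingerprint of a fold plan
#'
#' @param plan A [make_fold_plan()] object.
#' @return Hex string identifying the plan's assignments.
#' @export
plan_fingerprint <- function(plan) {
  stopifnot(inherits(plan, "fold_plan"))
  fingerprint(plan$assignment)
}

#' Random forest learner specification
#'
#' Hyperparameters of the random forest classifier used in every fold.
#' Defaults: 1000 trees, `sqrt(p)` candidate variables per split, minimum
#' leaf size 1, and balanced bootstrap sampling (each tree draws equally
#' many patients from both outcome classes, with replacement) to counter
#' class imbalance.
#'
#' @param n_trees Number of trees (>= 1).
#' @param max_features `"sqrt"` or an explicit integer count of candidate
#'   variables per split.
#' @param min_leaf Minimum terminal node size.
#' @param class_balance One of `"balanced_bootstrap"`, `"balanced_weights"`,
#'   `"none"`.
#' @param seed Base seed for per-iteration learner seeds; defaults to the
#'   fold-plan seed at fit time when `NULL`.
#' @return A `learner_spec` list.
#' @export
learner_spec <- function(n_trees = 1000, max_features = "sqrt", min_leaf = 1,
                         class_balance = c("balanced_bootstrap",
                                           "balanced_weights", "none"),
                         seed = NULL) {
  class_balance <- match.arg(class_balance)
  if (n_trees < 1) stop("n_trees must be >= 1")
  structure(
    list(n_trees = as.integer(n_trees), max_features = max_features,
         min_leaf = as.integer(min_leaf), class_balance = class_balance,
         seed = seed),
    class = "learner_spec"
  )
}

fit_learner <- function(spec, x, y, seed) {
  y <- factor(y, levels = c(0, 1))
  mtry <- if (identical(spec$max_features, "sqrt")) {
    max(1L, floor(sqrt(ncol(x))))
  } else {
    min(ncol(x), as.integer(spec$max_features))
  }
  args <- list(x = x, y = y, num.trees = spec$n_trees, mtry = mtry,
               min.node.size = spec$min_leaf, probability = TRUE,
               num.threads = 1L, seed = seed, verbose = FALSE)
  if (spec$class_balance == "balanced_bootstrap") {
    tab <- table(y)
    args$replace <- TRUE
    args$sample.fraction <- rep(min(tab) / length(y), 2)
  } else if (spec$class_balance == "balanced_weights") {
    tab <- table(y)
    w <- as.numeric(length(y) / (2 * tab))
    args$class.weights <- w
  }
  do.call(ranger::ranger, args)
}

predict_prob <- function(model, x) {
  pr <- stats::predict(model, data = x,
                       num.threads = 1L, verbose = FALSE)$predictions
  pr[, "1"]
}

as_domain_sets <- function(x, domain_sets) {
  if (is.matrix(x)) {
    if (is.null(domain_sets)) domain_sets <- list(all = colnames(x))
    return(domain_sets)
  }
  if (is.null(domain_sets)) {
    present <- intersect(PREDICTOR_DOMAINS, unique(x$meta$domain))
    domain_sets <- c(stats::setNames(as.list(present), present),
                     list(all = present))
  }
  domain_sets
}

#' Run matched-fold repeated cross-validation per predictor-domain set
#'
#' For every repetition and fold of the plan, fits the random forest on the
#' training rows and stores predicted class-1 probabilities for the test
#' rows, separately for every domain set. All preprocessing that learns
#' from data (median/mode imputation) is refit inside every training fold
#' and only then applied to the fold's test rows, so no test information
#' leaks into training. Encoding is shared across domain sets within a
#' fold, and the identical fold plan is used for all of them.
#'
#' @param x A prepared [cohort_table()] (recoded, filtered, not yet
#'   imputed), or a plain numeric matrix (no imputation performed).
#' @param train_labels 0/1 labels used for training.
#' @param plan A [make_fold_plan()] (built from the training labels).
#' @param learner A [learner_spec()].
#' @param domain_sets Named list of domain subsets to run (for a cohort
#'   table: character vectors of domains; for a matrix: column names).
#'   Default: each available domain singly plus `"all"`.
#' @param eval_labels 0/1 labels stored for evaluation; equal to
#'   `train_labels` except in transfer mode.
#' @return A `cv_result` data.frame with columns `repetition`, `fold`,
#'   `domain_set`, `patient_id`, `prob`, `train_label`, `eval_label`, and
#'   attributes `plan_fingerprint`, `learner`, `patient_ids`.
#' @export
run_cv <- function(x, train_labels, plan, learner = learner_spec(),
                   domain_sets = NULL, eval_labels = train_labels) {
  stopifnot(inherits(plan, "fold_plan"), inherits(learner, "learner_spec"))
  assert_binary_labels(train_labels, "train_labels")
  assert_binary_labels(eval_labels, "eval_labels")
  is_tab <- inherits(x, "cohort_table")
  n <- if (is_tab) n_patients(x) else nrow(x)
  if (length(train_labels) != n || length(eval_labels) != n) {
    stop("labels must align with the patient rows of `x`")
  }
  if (plan$n_patients != n) {
    stop("fold plan was built for a different number of patients")
  }
  patient_ids <- if (is_tab) x$patient_ids else
    (rownames(x) %||% sprintf("P%04d", seq_len(n)))
  domain_sets <- as_domain_sets(x, domain_sets)
  base_seed <- learner$seed %||% plan$seed

  out <- vector("list", plan$n_repetitions * plan$n_folds * length(domain_sets))
  k <- 0L
  for (r in seq_len(plan$n_repetitions)) {
    fold_of <- plan$assignment[, r]
    for (f in seq_len(plan$n_folds)) {
      test <- which(fold_of == f)
      train <- which(fold_of != f)
      if (is_tab) {
        imp <- fit_imputer(x, train)
        full <- apply_imputer(x, imp)
        enc <- encode_for_learner(full)
        mat <- enc$x
        cols_of <- function(ds) enc$map$item_id[enc$map$domain %in% ds]
      } else {
        mat <- x
        cols_of <- function(ds) ds
      }
      for (di in seq_along(domain_sets)) {
        ds_name <- names(domain_sets)[di]
        cols <- cols_of(domain_sets[[di]])
        xm <- mat[, cols, drop = FALSE]
        seed_i <- derive_seed(base_seed, "fit", r, f, di)
        model <- fit_learner(learner, xm[train, , drop = FALSE],
                             train_labels[train], seed_i)
        prob <- predict_prob(model, xm[test, , drop = FALSE])
        k <- k + 1L
        out[[k]] <- data.frame(
          repetition = r, fold = f, domain_set = ds_name,
          patient_id = patient_ids[test], prob = prob,
          train_label = train_labels[test], eval_label = eval_labels[test],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  structure(res,
            plan_fingerprint = plan_fingerprint(plan),
            learner = learner,
            patient_ids = patient_ids,
            domain_sets = names(domain_sets),
            class = c("cv_result", "data.frame"))
}

#' Transfer-label cross-validation
#'
#' Trains on one task's labels but evaluates the held-out predictions
#' against the other task's labels: identical to [run_cv()] with
#' `eval_labels` set to the evaluation task. The fold plan should be
#' stratified on the *training*-task labels, since those drive the fit.
#'
#' @inheritParams run_cv
#' @param labels_train_task 0/1 labels of the task trained on.
#' @param labels_eval_task 0/1 labels of the task evaluated against.
#' @return A `cv_result`, as [run_cv()].
#' @export
run_transfer_cv <- function(x, labels_train_task, labels_eval_task, plan,
                            learner = learner_spec(), domain_sets = NULL) {
  run_cv(x, train_labels = labels_train_task, plan = plan, learner = learner,
         domain_sets = domain_sets, eval_labels = labels_eval_task)
}

#' Evaluate a fitted cross-validation run within a patient subgroup
#'
#' Restricts every test fold to the subgroup members and recomputes the
#' AUC there, using the stored held-out probabilities (the model itself was
#' trained on all patients). Iterations whose restricted test fold lacks
#' one of the classes are skipped and counted.
#'
#' @param result A `cv_result` from [run_cv()].
#' @param subgroup Logical vector over the cohort's patients (aligned with
#'   the patient order used in `run_cv`).
#' @param domain_set Which domain set to evaluate (default `"all"`).
#' @return List with `per_iteration` (repetition, fold, auc), `mean_auc`,
#'   and `n_skipped`.
#' @export
evaluate_subgroup <- function(result, subgroup, domain_set = "all") {
  stopifnot(inherits(result, "cv_result"))
  patient_ids <- attr(result, "patient_ids")
  if (length(subgroup) != length(patient_ids)) {
    stop("subgroup must be defined for every patient")
  }
  if (!any(subgroup)) stop("subgroup is empty")
  members <- patient_ids[as.logical(subgroup)]
  rows <- result[result$domain_set == domain_set &
                   result$patient_id %in% members, , drop = FALSE]
  if (!nrow(rows)) stop("no test predictions for domain set '", domain_set, "'")
  key <- interaction(rows$repetition, rows$fold, drop = TRUE)
  pieces <- split(rows, key)
  aucs <- lapply(pieces, function(d) {
    if (length(unique(d$eval_label)) < 2L) return(NULL)
    data.frame(repetition = d$repetition[1], fold = d$fold[1],
               auc = roc_auc(d$prob, d$eval_label))
  })
  skipped <- sum(vapply(aucs, is.null, logical(1)))
  per_iter <- do.call(rbind, aucs[!vapply(aucs, is.null, logical(1))])
  rownames(per_iter) <- NULL
  list(per_iteration = per_iter,
       mean_auc = mean(per_iter$auc),
       n_skipped = skipped)
}
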