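#' Permutation variable importance with per-variable p-values
#'
#' For each variable, shuffles its test-fold column `n_permutations` times
#' (independently seeded per variable), re-predicts, and measures the AUC
#' drop. The importance is the baseline test AUC minus the mean permuted
#' AUC; the p-value is the add-one fraction of permutations in which
#' destroying the variable does *not* hurt performance,
#' `p = (1 + #\{AUC_perm >= AUC_obs\}) / (1 + n_permutations)`.
#' Impurity-based importances are deliberately not used (they are biased
#' for mixed-type predictors); the columns are permuted without refitting
#' the forest, which keeps the scheme tractable at hundreds of variables.
#'
#' @param model A fitted probability forest (from the internal learner).
#' @param x_test Numeric test-fold matrix (columns named by item).
#' @param eval_labels 0/1 evaluation labels of the test fold (both classes
#'   present).
#' @param n_permutations Permutations per variable (default 1000).
#' @param seed Integer seed.
#' @return data.frame with columns `variable`, `importance`, `p_value`.
#' @export
variable_permutation_pvalues <- function(model, x_test, eval_labels,
                                         n_permutations = 1000, seed = 1L) {
  assert_binary_labels(eval_labels, "eval_labels")
  if (length(unique(eval_labels)) < 2L) {
    stop("test fold must contain both classes")
  }
  n <- nrow(x_test)
  p <- ncol(x_test)
  base_auc <- roc_auc(predict_prob(model, x_test), eval_labels)
  labels_rep <- rep(eval_labels, n_permutations)
  block <- rep(seq_len(n_permutations), each = n)
  out <- data.frame(variable = colnames(x_test),
                    importance = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    perm_idx <- withr::with_seed(derive_seed(seed, "varperm", j), {
      unlist(lapply(seq_len(n_permutations), function(b) sample.int(n)))
    })
    xb <- x_test[rep(seq_len(n), n_permutations), , drop = FALSE]
    xb[, j] <- x_test[perm_idx, j]
    probs <- predict_prob(model, xb)
    perm_auc <- vapply(split(seq_along(probs), block), function(idx) {
      roc_auc(probs[idx], labels_rep[idx])
    }, numeric(1))
    out$importance[j] <- base_auc - mean(perm_auc)
    out$p_value[j] <- (1 + sum(perm_auc >= base_auc)) / (1 + n_permutations)
  }
  attr(out, "base_auc") <- base_auc
  out
}

#' Benjamini-Hochberg step-up rejection
#'
#' Standard FDR step-up procedure: sort p-values ascending, find the
#' largest k with `p_(k) <= k * alpha / m`, reject the k smallest.
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return Logical rejection vector in the original order.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH") <= alpha
}

#' Build a permutation-importance ledger across cross-validation iterations
#'
#' Runs the per-fold importance scheme over (a subset of) the fold plan's
#' iterations, applying BH-FDR across variables *within each iteration*.
#' Preprocessing is refit per training fold exactly as in [run_cv()].
#'
#' @param x A prepared [cohort_table()] or numeric matrix.
#' @param labels 0/1 outcome labels.
#' @param plan A [make_fold_plan()].
#' @param learner A [learner_spec()].
#' @param n_permutations Permutations per variable per iteration.
#' @param alpha FDR level applied within each iteration.
#' @param iterations Optional data.frame with columns `repetition`, `fold`
#'   selecting a subset of iterations (default: all in the plan).
#' @param domains Optional domain restriction (cohort-table input only).
#' @return An `importance_ledger` data.frame: iteration, repetition, fold,
#'   variable, importance, p_value, significant; attribute `n_iterations`.
#' @export
run_cv_importance <- function(x, labels, plan, learner = learner_spec(),
                              n_permutations = 1000, alpha = 0.05,
                              iterations = NULL, domains = NULL) {
  stopifnot(inherits(plan, "fold_plan"))
  assert_binary_labels(labels)
  is_tab <- inherits(x, "cohort_table")
  if (is.null(iterations)) {
    iterations <- expand.grid(fold = seq_len(plan$n_folds),
                              repetition = seq_len(plan$n_repetitions))
    iterations <- iterations[, c("repetition", "fold")]
  }
  base_seed <- learner$seed %||% plan$seed
  rows <- vector("list", nrow(iterations))
  for (i in seq_len(nrow(iterations))) {
    r <- iterations$repetition[i]
    f <- iterations$fold[i]
    fold_of <- plan$assignment[, r]
    train <- which(fold_of != f)
    test <- which(fold_of == f)
    if (is_tab) {
      imp <- fit_imputer(x, train)
      full <- apply_imputer(x, imp)
      enc <- encode_for_learner(full, domains = domains)
      mat <- enc$x
    } else {
      mat <- x
    }
    if (length(unique(labels[test])) < 2L) next  # skipped iteration
    model <- fit_learner(learner, mat[train, , drop = FALSE], labels[train],
                         derive_seed(base_seed, "impfit", r, f))
    vp <- variable_permutation_pvalues(
      model, mat[test, , drop = FALSE], labels[test],
      n_permutations = n_permutations,
      seed = derive_seed(base_seed, "imp", r, f)
    )
    vp$significant <- bh_fdr(vp$p_value, alpha)
    vp$iteration <- i
    vp$repetition <- r
    vp$fold <- f
    rows[[i]] <- vp
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("every requested iteration was skipped")
  ledger <- do.call(rbind, rows)
  ledger <- ledger[, c("iteration", "repetition", "fold", "variable",
                       "importance", "p_value", "significant")]
  rownames(ledger) <- NULL
  structure(ledger, n_iterations = length(rows), alpha = alpha,
            class = c("importance_ledger", "data.frame"))
}

#' Select variables consistently significant across iterations
#'
#' A variable counts as important when it is FDR-significant in at least
#' `min_fraction` (inclusive; default 50\%) of the ledger's iterations.
#' Selected variables are returned ordered by mean importance.
#'
#' @param ledger An `importance_ledger` from [run_cv_importance()].
#' @param min_fraction Consistency threshold in `[0, 1]`.
#' @return data.frame: variable, consistency, mean_importance, mean_rank,
#'   selected — restricted to selected variables; the full per-variable
#'   table is attached as attribute `all_variables`.
#' @export
select_consistent_variables <- function(ledger, min_fraction = 0.5) {
  stopifnot(inherits(ledger, "importance_ledger"))
  n_iter <- attr(ledger, "n_iterations")
  ranks <- stats::ave(-ledger$importance, ledger$iteration,
                      FUN = function(v) rank(v, ties.method = "average"))
  ledger$rank <- ranks
  pieces <- split(ledger, ledger$variable)
  tab <- do.call(rbind, lapply(pieces, function(d) {
    data.frame(variable = d$variable[1],
               consistency = sum(d$significant) / n_iter,
               mean_importance = mean(d$importance),
               mean_rank = mean(d$rank),
               stringsAsFactors = FALSE)
  }))
  tab$selected <- tab$consistency >= min_fraction
  tab <- tab[order(-tab$mean_importance), , drop = FALSE]
  rownames(tab) <- NULL
  out <- tab[tab$selected, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_variables") <- tab
  out
}

#' Compare variable importance rankings between two prediction tasks
#'
#' Ranks every variable's importance within each iteration (1 = most
#' important) for both tasks, then tests each variable's per-iteration rank
#' difference (task A minus task B, on matched iterations) with a sign-flip
#' test, FDR-corrected across variables. A negative mean rank difference
#' means the variable ranks better (lower rank number) for task A.
#'
#' @param ledger_a,ledger_b `importance_ledger`s over the same variables
#'   and matched iterations (same fold plan).
#' @param n_flips Sign patterns per variable (default 10000).
#' @param alpha FDR level across variables.
#' @param seed Integer seed.
#' @return data.frame: variable, mean_rank_a, mean_rank_b, mean_rank_diff,
#'   p_value, p_adjusted, significant.
#' @export
rank_difference_analysis <- function(ledger_a, ledger_b, n_flips = 10000,
                                     alpha = 0.05, seed = 1L) {
  stopifnot(inherits(ledger_a, "importance_ledger"),
            inherits(ledger_b, "importance_ledger"))
  vars <- sort(unique(ledger_a$variable))
  if (!setequal(vars, unique(ledger_b$variable))) {
    stop("ledgers cover different variable sets")
  }
  add_rank <- function(ledger) {
    ledger$rank <- stats::ave(-ledger$importance, ledger$iteration,
                              FUN = function(v) rank(v, ties.method = "average"))
    ledger
  }
  a <- add_rank(as.data.frame(ledger_a))
  b <- add_rank(as.data.frame(ledger_b))
  iters <- intersect(unique(a$iteration), unique(b$iteration))
  if (!length(iters)) stop("ledgers share no iterations")
  a <- a[a$iteration %in% iters, ]
  b <- b[b$iteration %in% iters, ]
  key_a <- paste(a$iteration, a$variable)
  key_b <- paste(b$iteration, b$variable)
  b <- b[match(key_a, key_b), ]
  out <- do.call(rbind, lapply(vars, function(v) {
    sel <- a$variable == v
    d <- a$rank[sel] - b$rank[sel]
    tst <- paired_signflip_test(d, n_flips = n_flips,
                                seed = derive_seed(seed, "rankdiff", v))
    data.frame(variable = v,
               mean_rank_a = mean(a$rank[sel]),
               mean_rank_b = mean(b$rank[sel]),
               mean_rank_diff = mean(d),
               p_value = tst$p_value,
               stringsAsFactors = FALSE)
  }))
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjusted <= alpha
  rownames(out) <- NULL
  out
}
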