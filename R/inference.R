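new_permutation_test_result <- function(observed, null_statistics, p_value,
                                        n_permutations, adjusted_p = NA_real_,
                                        alternative = "greater") {
  structure(
    list(observed = observed, null_statistics = null_statistics,
         p_value = p_value, n_permutations = n_permutations,
         adjusted_p = adjusted_p, alternative = alternative),
    class = "permutation_test_result"
  )
}

#' @export
print.permutation_test_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_test_result> observed = %.4f, p = %.4g (%s, n = %d)%s\n",
    x$observed, x$p_value, x$alternative, x$n_permutations,
    if (is.finite(x$adjusted_p)) sprintf(", adjusted p = %.4g", x$adjusted_p)
    else ""))
  invisible(x)
}

#' Label-permutation significance test of a classification statistic
#'
#' Permutes the outcome labels uniformly at random, reruns the supplied
#' pipeline closure under each permutation, and compares the observed
#' statistic (typically the cross-validated mean AUC) against the null
#' distribution with the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_permutations)` (one-sided:
#' chance performance is the floor for an AUC).
#'
#' Rerunning the full repeated cross-validation for every permutation is
#' the `full_rerun` scheme; the default caller-side economy is to hand in a
#' closure that reruns a single k-fold repetition (`reduced_rerun`).
#'
#' @param stat_fn Function taking a label vector and returning the
#'   statistic (it must rerun the pipeline under those labels).
#' @param labels The observed 0/1 labels.
#' @param n_permutations Number of label permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param m Bonferroni family size for the adjusted p-value (default 1).
#' @return A `permutation_test_result`.
#' @export
label_permutation_test <- function(stat_fn, labels, n_permutations = 1000,
                                   seed = 1L, m = 1L) {
  assert_binary_labels(labels)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  observed <- stat_fn(labels)
  nulls <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations),
           function(i) stat_fn(sample(labels)), numeric(1))
  })
  p <- (1 + sum(nulls >= observed)) / (1 + n_permutations)
  new_permutation_test_result(observed, nulls, p, n_permutations,
                              adjusted_p = min(1, m * p),
                              alternative = "greater")
}

#' Paired sign-flip test on matched per-iteration differences
#'
#' Tests whether paired per-iteration differences (e.g. AUC of domain A
#' minus AUC of domain B on identical test folds) are centred at zero.
#' Differences are first normalized by their across-iteration standard
#' deviation (yielding a scale-free, t-like mean statistic); the null is
#' generated by independently negating each difference, and the two-sided
#' add-one p-value is reported.
#'
#' @param differences Numeric vector of matched per-iteration differences.
#' @param n_flips Number of random sign patterns (default 10000).
#' @param seed Integer seed.
#' @param normalize `"sd"` (default) or `"identity"`.
#' @param m Bonferroni family size for the adjusted p-value.
#' @return A `permutation_test_result` (statistic = mean normalized
#'   difference). An all-zero difference vector returns p = 1.
#' @export
paired_signflip_test <- function(differences, n_flips = 10000, seed = 1L,
                                 normalize = c("sd", "identity"), m = 1L) {
  normalize <- match.arg(normalize)
  differences <- differences[is.finite(differences)]
  if (length(differences) < 2L) {
    stop("need at least two finite paired differences")
  }
  if (all(differences == 0)) {
    return(new_permutation_test_result(0, numeric(0), 1, n_flips,
                                       adjusted_p = 1,
                                       alternative = "two.sided"))
  }
  d <- differences
  if (normalize == "sd") {
    s <- stats::sd(d)
    if (s > 0) d <- d / s   # constant nonzero differences: fall back to raw
  }
  observed <- mean(d)
  k <- length(d)
  nulls <- withr::with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_flips * k, replace = TRUE), n_flips, k)
    as.numeric(signs %*% d) / k
  })
  p <- (1 + sum(abs(nulls) >= abs(observed))) / (1 + n_flips)
  new_permutation_test_result(observed, nulls, p, n_flips,
                              adjusted_p = min(1, m * p),
                              alternative = "two.sided")
}

#' Bonferroni adjustment with an explicit family size
#'
#' Multiplies each p-value by the family size `m` and caps at 1. `m` may
#' exceed the number of p-values supplied (e.g. adjusting the 15 pairwise
#' domain comparisons of one task within a pooled 30-test family).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param m Family size; defaults to `length(p_values)`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (m < length(p_values)) stop("family size m must be >= length(p_values)")
  stats::p.adjust(p_values, method = "bonferroni", n = m)
}

#' Pairwise domain comparison on matched folds
#'
#' For every task and every unordered pair of domain sets, computes the
#' matched per-iteration AUC differences, runs the paired sign-flip test on
#' the normalized differences, and Bonferroni-adjusts jointly over all
#' `n_pairs * n_tasks` tests (30 for six domain sets and two tasks). The
#' matched-fold contract is enforced: every `cv_result` must carry an
#' identical fold-plan fingerprint per task.
#'
#' @param results Named list of `cv_result` objects, one per task, each
#'   covering the same domain sets.
#' @param n_flips Sign patterns per test (default 10000).
#' @param alpha Significance level applied to the adjusted p-values.
#' @param seed Integer seed.
#' @param normalize Passed to [paired_signflip_test()].
#' @return A `domain_comparison` data.frame: task, domain_a, domain_b,
#'   mean_auc_a, mean_auc_b, mean_diff, statistic, p_value, p_adjusted,
#'   significant, direction.
#' @export
compare_domains <- function(results, n_flips = 10000, alpha = 0.05,
                            seed = 1L, normalize = "sd") {
  if (inherits(results, "cv_result")) results <- list(task = results)
  stopifnot(length(results) >= 1L, !is.null(names(results)))
  rows <- list()
  for (task in names(results)) {
    res <- results[[task]]
    stopifnot(inherits(res, "cv_result"))
    aucs <- per_iteration_auc(res)
    sets <- names(aucs)
    if (length(sets) < 2L) stop("need at least two domain sets to compare")
    lens <- lengths(aucs)
    if (length(unique(lens)) != 1L) {
      stop("domain sets cover different numbers of iterations; ",
           "fold plans are not matched")
    }
    pairs <- utils::combn(sets, 2L)
    for (i in seq_len(ncol(pairs))) {
      a <- pairs[1, i]; b <- pairs[2, i]
      d <- aucs[[a]] - aucs[[b]]
      tst <- paired_signflip_test(
        d, n_flips = n_flips,
        seed = derive_seed(seed, "signflip", task, a, b),
        normalize = normalize
      )
      rows[[length(rows) + 1L]] <- data.frame(
        task = task, domain_a = a, domain_b = b,
        mean_auc_a = mean(aucs[[a]], na.rm = TRUE),
        mean_auc_b = mean(aucs[[b]], na.rm = TRUE),
        mean_diff = mean(d, na.rm = TRUE),
        statistic = tst$observed, p_value = tst$p_value,
        stringsAsFactors = FALSE
      )
    }
  }
  report <- do.call(rbind, rows)
  m <- nrow(report)
  report$p_adjusted <- bonferroni_adjust(report$p_value, m)
  report$significant <- report$p_adjusted < alpha
  report$direction <- ifelse(report$mean_diff > 0, report$domain_a,
                             ifelse(report$mean_diff < 0, report$domain_b, ""))
  rownames(report) <- NULL
  structure(report, class = c("domain_comparison", "data.frame"),
            m_comparisons = m, alpha = alpha)
}

#' Induced domain ordering from a pairwise comparison report
#'
#' Orders domain sets by their number of significant pairwise wins (ties
#' broken by mean AUC) within one task.
#'
#' @param comparison A `domain_comparison` from [compare_domains()].
#' @param task Which task to order.
#' @return Character vector of domain sets, best first.
#' @export
domain_ordering <- function(comparison, task) {
  d <- comparison[comparison$task == task, , drop = FALSE]
  sets <- unique(c(d$domain_a, d$domain_b))
  wins <- stats::setNames(numeric(length(sets)), sets)
  mean_auc <- stats::setNames(numeric(length(sets)), sets)
  for (s in sets) {
    mean_auc[s] <- mean(c(d$mean_auc_a[d$domain_a == s],
                          d$mean_auc_b[d$domain_b == s]))
    wins[s] <- sum(d$significant & d$direction == s)
  }
  sets[order(-wins, -mean_auc)]
}
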