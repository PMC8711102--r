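#' Area under the ROC curve via midranks
#'
#' Computes the AUC as the Mann-Whitney probability that a random positive
#' scores above a random negative, with ties counting one half, using
#' midranks: `(sum of positive ranks - n1(n1+1)/2) / (n1 * n0)`.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
roc_auc <- function(scores, labels) {
  assert_binary_labels(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length")
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute an AUC")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold-based confusion metrics
#'
#' Dichotomizes scores at the threshold (predicted positive when
#' `score >= threshold`) and reports sensitivity, specificity, balanced
#' accuracy (their arithmetic mean), PPV and NPV. Ratios with a zero
#' denominator are reported as `NA`, not zero.
#'
#' @inheritParams roc_auc
#' @param threshold Classification threshold in (0, 1); default 0.5.
#' @return Named list with `sensitivity`, `specificity`,
#'   `balanced_accuracy`, `ppv`, `npv`.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  assert_binary_labels(labels)
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)")
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  list(sensitivity = sens,
       specificity = spec,
       balanced_accuracy = (sens + spec) / 2,
       ppv = safe_div(tp, tp + fp),
       npv = safe_div(tn, tn + fn))
}

#' Summarize a cross-validation run into per-domain score tables
#'
#' Computes AUC and the confusion metrics on every (repetition, fold) test
#' set against the stored evaluation labels, then reports mean and sample
#' (n-1) standard deviation across the iteration-level values per domain
#' set. Iterations where a metric is undefined (single-class restricted
#' fold, zero denominator) are excluded from that metric's summary and
#' counted.
#'
#' @param result A `cv_result` from [run_cv()].
#' @param threshold Classification threshold for the confusion metrics.
#' @return List with `per_iteration` (long data.frame: repetition, fold,
#'   domain_set, metric, value) and `summary` (domain_set, metric, mean,
#'   sd, n_used, n_skipped).
#' @export
summarize_cv <- function(result, threshold = 0.5) {
  stopifnot(inherits(result, "cv_result"))
  key <- interaction(result$repetition, result$fold, result$domain_set,
                     drop = TRUE)
  pieces <- split(result, key)
  per_iter <- do.call(rbind, lapply(pieces, function(d) {
    metrics <- c(
      auc = if (length(unique(d$eval_label)) >= 2L) {
        roc_auc(d$prob, d$eval_label)
      } else NA_real_,
      unlist(if (length(unique(d$eval_label)) >= 2L) {
        confusion_metrics(d$prob, d$eval_label, threshold)
      } else {
        list(sensitivity = NA_real_, specificity = NA_real_,
             balanced_accuracy = NA_real_, ppv = NA_real_, npv = NA_real_)
      })
    )
    data.frame(repetition = d$repetition[1], fold = d$fold[1],
               domain_set = d$domain_set[1],
               metric = names(metrics), value = as.numeric(metrics),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(per_iter) <- NULL
  agg <- split(per_iter, list(per_iter$domain_set, per_iter$metric),
               drop = TRUE)
  summary <- do.call(rbind, lapply(agg, function(d) {
    ok <- is.finite(d$value)
    data.frame(domain_set = d$domain_set[1], metric = d$metric[1],
               mean = mean(d$value[ok]),
               sd = stats::sd(d$value[ok]),
               n_used = sum(ok), n_skipped = sum(!ok),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(per_iteration = per_iter, summary = summary)
}

#' Per-iteration AUC vectors for one or more domain sets
#'
#' Helper extracting, for each domain set, the AUC of every (repetition,
#' fold) test set in plan order — the paired vectors that the sign-flip
#' domain comparison operates on.
#'
#' @param result A `cv_result`.
#' @return Named list of numeric vectors (one per domain set), each ordered
#'   by repetition then fold.
#' @export
per_iteration_auc <- function(result) {
  stopifnot(inherits(result, "cv_result"))
  sets <- unique(result$domain_set)
  stats::setNames(lapply(sets, function(ds) {
    d <- result[result$domain_set == ds, , drop = FALSE]
    d <- d[order(d$repetition, d$fold), , drop = FALSE]
    key <- paste(d$repetition, d$fold)
    vapply(unique(key), function(k) {
      dd <- d[key == k, ]
      if (length(unique(dd$eval_label)) < 2L) return(NA_real_)
      roc_auc(dd$prob, dd$eval_label)
    }, numeric(1), USE.NAMES = FALSE)
  }), sets)
}

#' Pooled two-sample t statistic from summary statistics
#'
#' Classic equal-variance two-sample t statistic computed from group means,
#' standard deviations and sizes — the form used to compare excluded versus
#' included patients on baseline characteristics when only summary
#' statistics are available.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return List with `t` (statistic, sign of `mean2 - mean1`), `df`, and
#'   two-sided `p_value`.
#' @export
#' @examples
#' pooled_t_stat(38.25, 12.05, 319, 41.92, 12.20, 887)
pooled_t_stat <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean2 - mean1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}
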