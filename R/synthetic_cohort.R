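#' Configuration for the synthetic cohort generator
#'
#' Describes a synthetic psychiatric cohort with the statistical structure
#' the downstream analysis assumes: five predictor domains of mixed-type
#' items, skip-pattern applicability, item-level missingness (including a
#' subset of patients with heavy missingness, destined to be excluded), and
#' two correlated binary recovery outcomes whose predictive signal is
#' concentrated in configurable domains.
#'
#' The defaults emulate a two-wave naturalistic cohort design of the size
#' this package targets: 994 generated patients
#' of whom roughly 10.8\% carry >20\% missingness (so that about 887 survive
#' the patient filter), 569 items split 300/118/65/74/12 across the
#' clinical/psychological/sociodemographic/biological/lifestyle domains,
#' outcome prevalences 54.6\% (recovery from anxiety disorders) and 40.8\%
#' (recovery from all common mental disorders), and effect scales decreasing
#' from the clinical to the lifestyle domain.
#'
#' @param n_patients Number of patients to generate.
#' @param items_per_domain Named integer vector of item counts per domain.
#' @param type_mix Named list: per domain, proportions of
#'   continuous/ordinal/nominal items (each summing to 1).
#' @param effect_scale Named list with one numeric vector per task
#'   (`anxiety`, `cmd`) giving the standard deviation of that domain's
#'   contribution to the task's linear predictor. 0 = pure-noise domain.
#' @param shared_factor_weight Weight of the latent (unobserved) factor
#'   common to both outcomes; it correlates the labels but, being invisible
#'   to the items, carries no transferable signal.
#' @param signal_overlap Correlation in `[0, 1]` between the two tasks'
#'   planted item weights within each domain. This is the coupling that
#'   makes transfer-label training meaningful: at 1 the tasks share one
#'   item signal, at 0 their item signals are independent.
#' @param target_prevalence Named fractions in (0,1) per task.
#' @param informative_fraction Fraction of each domain's items that carry
#'   signal (minimum one item when the domain's effect scale is positive).
#' @param item_missing_rate_range Interval in `[0,1)` from which each item's
#'   missingness rate is drawn uniformly.
#' @param patient_high_missing_fraction Fraction of patients whose rows get
#'   heavy (>20\%) missingness, emulating patients later excluded.
#' @param skip_pattern_count Number of parent -> child applicability rules.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_patients = 994,
                             items_per_domain = c(clinical = 300,
                                                  psychological = 118,
                                                  sociodemographic = 65,
                                                  biological = 74,
                                                  lifestyle = 12),
                             type_mix = NULL,
                             effect_scale = NULL,
                             shared_factor_weight = 1.0,
                             signal_overlap = 0.75,
                             target_prevalence = c(anxiety = 0.546,
                                                   cmd = 0.408),
                             informative_fraction = 0.2,
                             item_missing_rate_range = c(0, 0.23),
                             patient_high_missing_fraction = 0.108,
                             skip_pattern_count = 8,
                             seed = 1L) {
  if (is.null(type_mix)) {
    # questionnaire-heavy domains are mostly ordinal items, the biological
    # domain mostly continuous assay values, sociodemographics mostly nominal
    type_mix <- list(
      clinical         = c(continuous = 0.10, ordinal = 0.70, nominal = 0.20),
      psychological    = c(continuous = 0.10, ordinal = 0.80, nominal = 0.10),
      sociodemographic = c(continuous = 0.20, ordinal = 0.30, nominal = 0.50),
      biological       = c(continuous = 0.90, ordinal = 0.00, nominal = 0.10),
      lifestyle        = c(continuous = 0.30, ordinal = 0.40, nominal = 0.30)
    )
  }
  if (is.null(effect_scale)) {
    # calibrated once so the clinical domain reaches a cross-validated AUC
    # near 0.7 with the combination of all domains slightly above it,
    # decreasing towards a pure-noise lifestyle domain
    scales <- c(clinical = 2.0, psychological = 1.2, sociodemographic = 0.7,
                biological = 0.3, lifestyle = 0.0)
    effect_scale <- list(anxiety = scales, cmd = scales)
  }
  cfg <- structure(
    list(n_patients = as.integer(n_patients),
         items_per_domain = items_per_domain,
         type_mix = type_mix,
         effect_scale = effect_scale,
         shared_factor_weight = shared_factor_weight,
         signal_overlap = signal_overlap,
         target_prevalence = target_prevalence,
         informative_fraction = informative_fraction,
         item_missing_rate_range = item_missing_rate_range,
         patient_high_missing_fraction = patient_high_missing_fraction,
         skip_pattern_count = as.integer(skip_pattern_count),
         seed = as.integer(seed)),
    class = "generator_config"
  )
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    if (n_patients < 1L) stop("n_patients must be positive")
    if (any(items_per_domain < 0) || sum(items_per_domain) < 1) {
      stop("items_per_domain must be nonnegative with at least one item")
    }
    if (!all(names(items_per_domain) %in% PREDICTOR_DOMAINS)) {
      stop("items_per_domain names must be predictor domains")
    }
    for (d in names(items_per_domain)) {
      mix <- type_mix[[d]]
      if (is.null(mix) || abs(sum(mix) - 1) > 1e-8 || any(mix < 0)) {
        stop("type_mix proportions for domain '", d, "' must be >= 0 and sum to 1")
      }
    }
    for (task in names(target_prevalence)) {
      pv <- target_prevalence[[task]]
      if (!is.finite(pv) || pv <= 0 || pv >= 1) {
        stop("target_prevalence must lie strictly inside (0,1)")
      }
      es <- effect_scale[[task]]
      if (is.null(es) || any(es < 0)) {
        stop("effect_scale must be nonnegative and defined for task '", task, "'")
      }
    }
    r <- item_missing_rate_range
    if (length(r) != 2 || r[1] > r[2] || r[1] < 0 || r[2] >= 1) {
      stop("item_missing_rate_range must be an interval within [0, 1)")
    }
    if (patient_high_missing_fraction < 0 || patient_high_missing_fraction >= 1) {
      stop("patient_high_missing_fraction must lie in [0, 1)")
    }
    if (signal_overlap < 0 || signal_overlap > 1) {
      stop("signal_overlap must lie in [0, 1]")
    }
  })
  invisible(cfg)
}

#' A small generator configuration for fast experimentation
#'
#' Same structure as [generator_config()] but with roughly 10\% of the
#' full item counts, suitable for quick end-to-end runs.
#'
#' @param ... Overrides passed on to [generator_config()].
#' @export
small_generator_config <- function(...) {
  args <- list(...)
  defaults <- list(
    n_patients = 300L,
    items_per_domain = c(clinical = 30, psychological = 12,
                         sociodemographic = 7, biological = 8, lifestyle = 3),
    skip_pattern_count = 3
  )
  do.call(generator_config, utils::modifyList(defaults, args))
}

#' Calibrate a logistic intercept to a target prevalence
#'
#' Finds the intercept `c` such that `mean(plogis(c + lp))` equals the
#' target prevalence, by bisection (the mean is strictly increasing in `c`,
#' so a bracket always exists).
#'
#' @param linear_predictors Finite numeric vector of per-patient linear
#'   predictors (without intercept).
#' @param target_prevalence Fraction strictly inside (0,1).
#' @param tol Convergence tolerance on the achieved prevalence.
#' @return The calibrated intercept (numeric scalar).
#' @export
#' @examples
#' calibrate_intercept(rep(0, 10), 0.5)           # exactly 0
#' calibrate_intercept(rnorm(500), 0.546)
calibrate_intercept <- function(linear_predictors, target_prevalence,
                                tol = 1e-9) {
  if (length(linear_predictors) == 0L || !all(is.finite(linear_predictors))) {
    stop("linear_predictors must be a nonempty finite numeric vector")
  }
  if (!is.finite(target_prevalence) ||
      target_prevalence <= 0 || target_prevalence >= 1) {
    stop("target_prevalence must lie strictly inside (0, 1)")
  }
  f <- function(c0) mean(stats::plogis(c0 + linear_predictors)) - target_prevalence
  lo <- stats::qlogis(target_prevalence) - max(linear_predictors)
  hi <- stats::qlogis(target_prevalence) - min(linear_predictors)
  # f(lo) <= 0 <= f(hi) by monotonicity of the logistic
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tol) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# deterministic integer split of k items into kinds following proportions
split_kinds <- function(k, mix) {
  kinds <- c("continuous", "ordinal", "nominal")
  mix <- mix[kinds]
  counts <- floor(mix * k)
  rem <- k - sum(counts)
  if (rem > 0) {
    extra <- order(mix * k - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  rep(kinds, counts)
}

#' Generate a synthetic cohort
#'
#' Draws a full synthetic cohort according to a [generator_config()]:
#'
#' * one latent standard-normal draw per (patient, item); continuous items
#'   are the latent value shifted by +5 scale units (so observed values are
#'   strictly positive and 0 is an out-of-support sentinel), ordinal items
#'   discretize the latent into 3-5 ordered levels, nominal items into 2-6
#'   categories with randomly permuted labels;
#' * two binary outcomes drawn from logistic models whose linear predictors
#'   combine domain-specific weighted sums of informative items' latent
#'   values (scaled per `effect_scale`) and one shared latent factor; the
#'   intercepts are calibrated by bisection to the target prevalences;
#' * a baseline-comorbidity flag loaded on the shared factor;
#' * skip-pattern rules marking child items inapplicable wherever the
#'   parent sits at its designated "off" level;
#' * completely-at-random missingness with per-item rates drawn from the
#'   configured interval, plus heavy missingness (rate 0.25-0.45) for the
#'   configured fraction of patients.
#'
#' @param config A [generator_config()].
#' @return An object of class `synthetic_cohort`: list with elements
#'   `table` ([cohort_table()]), `labels_anxiety`, `labels_cmd`,
#'   `comorbidity_flag` (0/1 vectors), and `truth` (planted informative
#'   items with their weights, intercepts, and skip rules).
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  domains <- names(cfg$items_per_domain)[cfg$items_per_domain > 0]
  abbrev <- c(clinical = "clin", psychological = "psy",
              sociodemographic = "soc", biological = "bio",
              lifestyle = "life")

  meta_list <- list()
  for (d in domains) {
    k <- cfg$items_per_domain[[d]]
    kinds <- split_kinds(k, cfg$type_mix[[d]])
    meta_list[[d]] <- data.frame(
      item_id = sprintf("%s_%03d", abbrev[[d]], seq_len(k)),
      domain = d, kind = kinds, stringsAsFactors = FALSE
    )
  }
  meta <- do.call(rbind, meta_list)
  rownames(meta) <- NULL
  p <- nrow(meta)

  latent <- matrix(stats::rnorm(n * p), n, p)
  colnames(latent) <- meta$item_id

  values <- vector("list", p)
  levels_list <- vector("list", p)
  for (j in seq_len(p)) {
    z <- latent[, j]
    if (meta$kind[j] == "continuous") {
      # shift by +5 scale units; clip far tail so positivity always holds
      values[[j]] <- pmax(z + 5, 1e-3)
      levels_list[[j]] <- character()
    } else if (meta$kind[j] == "ordinal") {
      k_lev <- sample(3:5, 1L)
      cuts <- stats::qnorm(seq_len(k_lev - 1L) / k_lev)
      lev <- sprintf("L%d", seq_len(k_lev))
      values[[j]] <- lev[findInterval(z, cuts) + 1L]
      levels_list[[j]] <- lev
    } else {
      k_lev <- sample(2:6, 1L)
      probs <- as.numeric(stats::rgamma(k_lev, 2))
      probs <- probs / sum(probs)
      cuts <- stats::qnorm(cumsum(probs)[-k_lev])
      lev <- sprintf("C%d", seq_len(k_lev))
      # permute the label assignment so integer codes are not monotone in z
      lab <- sample(lev)
      values[[j]] <- lab[findInterval(z, cuts) + 1L]
      levels_list[[j]] <- lev
    }
  }
  names(values) <- meta$item_id
  values <- as.data.frame(values, stringsAsFactors = FALSE,
                          check.names = FALSE)
  meta$levels <- levels_list
  meta$parent <- NA_character_
  meta$parent_off_level <- NA_character_

  # ---- planted signal -------------------------------------------------
  tasks <- names(cfg$target_prevalence)
  shared <- stats::rnorm(n)
  lp <- stats::setNames(rep(list(rep(0, n)), length(tasks)), tasks)
  truth_rows <- list()
  draw_weights <- function(k) {
    # random signs with bounded magnitude ratio: every planted item
    # carries non-negligible signal, which a pure normal draw would not
    # guarantee; unit norm so a domain contribution has variance sc^2
    w <- sample(c(-1, 1), k, replace = TRUE) * stats::runif(k, 0.5, 1.5)
    w / sqrt(sum(w^2))
  }
  rho <- cfg$signal_overlap
  for (d in domains) {
    ids <- meta$item_id[meta$domain == d]
    n_inf <- max(1L, ceiling(cfg$informative_fraction * length(ids)))
    inf_ids <- sample(ids, n_inf)
    v <- draw_weights(n_inf)   # item weights shared between the tasks
    for (task in tasks) {
      es <- cfg$effect_scale[[task]]
      sc <- if (d %in% names(es)) es[[d]] else 0
      if (sc == 0) next
      w <- sqrt(1 - rho^2) * draw_weights(n_inf) + rho * v
      w <- w / sqrt(sum(w^2))
      lp[[task]] <- lp[[task]] +
        sc * as.numeric(latent[, inf_ids, drop = FALSE] %*% w)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        task = task, domain = d, item_id = inf_ids, weight = sc * w,
        stringsAsFactors = FALSE
      )
    }
  }
  informative <- if (length(truth_rows)) {
    do.call(rbind, truth_rows)
  } else {
    data.frame(task = character(), domain = character(),
               item_id = character(), weight = numeric())
  }

  labels <- list()
  intercepts <- numeric(0)
  for (task in tasks) {
    eta <- lp[[task]] + cfg$shared_factor_weight * shared
    c0 <- calibrate_intercept(eta, cfg$target_prevalence[[task]])
    labels[[task]] <- stats::rbinom(n, 1L, stats::plogis(c0 + eta))
    intercepts[task] <- c0
  }
  # baseline comorbidity loads on the shared factor: comorbid patients are
  # systematically less likely to be free of all disorders at follow-up
  com_eta <- -0.8 * shared
  com_c0 <- calibrate_intercept(com_eta, 0.56)
  comorbidity <- stats::rbinom(n, 1L, stats::plogis(com_c0 + com_eta))

  # ---- skip patterns ---------------------------------------------------
  applicable <- matrix(TRUE, n, p, dimnames = list(NULL, meta$item_id))
  noninf <- meta$item_id[!(meta$item_id %in% informative$item_id)]
  parent_pool <- sample(intersect(noninf,
                                  meta$item_id[meta$kind != "continuous"]))
  skip_rules <- data.frame(parent = character(), off_level = character(),
                           child = character(), stringsAsFactors = FALSE)
  n_rules <- min(cfg$skip_pattern_count, length(parent_pool))
  parents <- if (n_rules > 0) parent_pool[seq_len(n_rules)] else character(0)
  child_pool <- sample(setdiff(noninf, parents))
  used <- 0L
  for (parent in parents) {
    n_child <- min(sample(1:3, 1L), length(child_pool) - used)
    if (n_child < 1L) break
    children <- child_pool[used + seq_len(n_child)]
    used <- used + n_child
    off <- meta$levels[[match(parent, meta$item_id)]][1L]
    off_rows <- values[[parent]] == off
    for (ch in children) {
      applicable[off_rows, ch] <- FALSE
      values[[ch]][off_rows] <- NA
      skip_rules <- rbind(skip_rules, data.frame(
        parent = parent, off_level = off, child = ch,
        stringsAsFactors = FALSE
      ))
    }
  }
  for (ch in skip_rules$child) {
    j <- match(ch, meta$item_id)
    meta$parent[j] <- skip_rules$parent[match(ch, skip_rules$child)]
    meta$parent_off_level[j] <- skip_rules$off_level[match(ch, skip_rules$child)]
  }

  # ---- missingness (MCAR) ---------------------------------------------
  r <- cfg$item_missing_rate_range
  item_rates <- stats::runif(p, r[1], r[2])
  n_high <- round(cfg$patient_high_missing_fraction * n)
  high_rows <- if (n_high > 0) sample.int(n, n_high) else integer(0)
  rate_mat <- matrix(item_rates, n, p, byrow = TRUE)
  miss <- matrix(stats::runif(n * p), n, p) < rate_mat
  miss[!applicable] <- FALSE   # inapplicable cells stay inapplicable
  # heavy-missingness patients get an exact count of missing cells so their
  # missing fraction is guaranteed to exceed the 20% patient filter
  for (i in high_rows) {
    rate <- stats::runif(1, 0.25, 0.45)
    app_j <- which(applicable[i, ])
    k <- min(ceiling(rate * p), length(app_j))
    miss[i, ] <- FALSE
    miss[i, sample(app_j, k)] <- TRUE
  }
  for (j in seq_len(p)) {
    if (any(miss[, j])) values[[j]][miss[, j]] <- NA
  }

  table <- cohort_table(values, meta, applicable)
  structure(
    list(table = table,
         labels_anxiety = labels[["anxiety"]] %||% labels[[1L]],
         labels_cmd = labels[["cmd"]] %||% labels[[length(labels)]],
         comorbidity_flag = comorbidity,
         truth = list(informative = informative,
                      intercepts = intercepts,
                      shared_factor_weight = cfg$shared_factor_weight,
                      skip_rules = skip_rules,
                      item_missing_rates = stats::setNames(item_rates,
                                                           meta$item_id),
                      high_missing_patients = table$patient_ids[high_rows]),
         config = cfg),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  print(x$table)
  cat(sprintf("  prevalence: anxiety %.3f, cmd %.3f; comorbidity %.3f\n",
              mean(x$labels_anxiety), mean(x$labels_cmd),
              mean(x$comorbidity_flag)))
  invisible(x)
}
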