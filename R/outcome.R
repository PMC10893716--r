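#' Cross-validation configuration for robustness assessment
#'
#' @param k_folds Number of folds per iteration (default 10).
#' @param n_iterations Number of repeated cross-validation iterations
#'   (default 100).
#' @param alpha Significance threshold for a Fisher-combined iteration
#'   p-value (default 0.05).
#' @param seed Root seed; per-(probe, outcome) streams are derived from it
#'   deterministically so evaluation order never matters.
#' @param fold_p_mode `"per_fold_refit"` (default): the full multivariable
#'   model is refit inside each fold and the methylation coefficient's
#'   p-value recorded, giving k independent p-values on disjoint
#'   subsamples. `"train_test_predict"`: the model is trained on the other
#'   k-1 folds and the held-out fold contributes the p-value of the
#'   correlation between predicted and observed outcome.
#' @return A `cv_config` list.
#' @export
cv_config <- function(k_folds = 10, n_iterations = 100, alpha = 0.05,
                      seed = 1L,
                      fold_p_mode = c("per_fold_refit", "train_test_predict")) {
  stopifnot(k_folds >= 2, n_iterations >= 1, alpha > 0, alpha < 1)
  structure(list(k_folds = as.integer(k_folds),
                 n_iterations = as.integer(n_iterations),
                 alpha = alpha, seed = as.integer(seed),
                 fold_p_mode = match.arg(fold_p_mode)),
            class = "cv_config")
}

# Model frame for one (outcome, probe): complete cases among patients.
outcome_model_frame <- function(outcome, probe_m_values, sample_table,
                                covariates) {
  stopifnot(outcome %in% names(sample_table))
  st <- sample_table[sample_table$group == "patient", , drop = FALSE]
  m <- probe_m_values[match(st$sample_id, names(probe_m_values))]
  df <- data.frame(.outcome = st[[outcome]], .meth = m,
                   st[intersect(covariates, names(st))],
                   check.names = FALSE)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  for (v in names(df)) if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  # drop covariates that became constant (e.g. single-level factors)
  keep <- vapply(df, function(col) {
    if (is.factor(col)) nlevels(droplevels(col)) > 1 else stats::var(col) > 0
  }, logical(1))
  keep[c(".outcome", ".meth")] <- TRUE
  df[, keep, drop = FALSE]
}

lm_meth_p <- function(df) {
  if (stats::var(df$.outcome) == 0) stop("Outcome is constant.", call. = FALSE)
  fit <- stats::lm(.outcome ~ ., data = df)
  if (nrow(df) <= length(stats::coef(fit))) {
    stop("Too few observations (", nrow(df), ") for ",
         length(stats::coef(fit)), " model parameters; reduce covariates.",
         call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  c(coefficient = sm[".meth", "Estimate"], p = sm[".meth", "Pr(>|t|)"])
}

#' Multivariable methylation-outcome model
#'
#' Fits, within patients only, `outcome ~ methylation + covariates` by
#' ordinary least squares on the non-missing subset and returns the
#' methylation coefficient with its two-sided p-value.
#'
#' @param outcome Outcome column name in the sample sheet.
#' @param probe_m_values Named vector of M values for one probe (names are
#'   sample ids).
#' @param sample_table Sample sheet (patients are selected internally).
#' @param covariates Adjustment covariate names (baseline risk factors,
#'   linguistic origin, technical PCs).
#' @return One-row tibble: `coefficient`, `p`, `n`.
#' @export
fit_outcome_model <- function(outcome, probe_m_values, sample_table,
                              covariates = character()) {
  df <- outcome_model_frame(outcome, probe_m_values, sample_table, covariates)
  est <- lm_meth_p(df)
  tibble::tibble(coefficient = unname(est["coefficient"]),
                 p = unname(est["p"]), n = nrow(df))
}

#' Combine independent p-values with Fisher's method
#'
#' `statistic = -2 * sum(log(p))` is referred to a chi-square distribution
#' with `2k` degrees of freedom. Zero p-values are clipped to the smallest
#' positive representable double, with a message.
#'
#' @param pvals Vector of independent p-values in (0, 1\].
#' @return One-row tibble: `statistic`, `df`, `p_combined`.
#' @examples
#' fisher_combine(rep(0.5, 10))  # statistic 20*log(2) = 13.863
#' @export
fisher_combine <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1].", call. = FALSE)
  }
  if (any(pvals == 0)) {
    message(sum(pvals == 0), " zero p-value(s) clipped to .Machine$double.xmin.")
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  stat <- -2 * sum(log(pvals))
  df <- 2 * length(pvals)
  tibble::tibble(statistic = stat, df = df,
                 p_combined = stats::pchisq(stat, df, lower.tail = FALSE))
}

# 32-bit-safe derived seed for a (probe, outcome) stream.
derive_seed <- function(root, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(root) * 7919 + h) %% 2147483587)
}

#' Repeated cross-validated robustness of one methylation-outcome pair
#'
#' For each of `n_iterations` iterations the patient set is split into
#' `k_folds` random disjoint folds; each fold yields a p-value for the
#' methylation term (by within-fold refit, or by held-out prediction,
#' per `fold_p_mode`); the k p-values are combined with Fisher's method;
#' the iteration is significant when the combined p is at or below
#' `alpha`. The reported percentage is over iterations. The mean
#' coefficient is averaged over every fold fit and the full-data p-value
#' comes from [fit_outcome_model()] on all patients.
#'
#' @inheritParams fit_outcome_model
#' @param probe_id Probe identifier (also keys the derived random stream).
#' @param config A [cv_config()].
#' @return One-row tibble of class rows: `probe_id`, `outcome`,
#'   `mean_coefficient`, `full_data_p`, `pct_iterations_significant`,
#'   `robust` (pct == 100), `n`.
#' @export
cv_robustness <- function(outcome, probe_id, probe_m_values, sample_table,
                          covariates = character(), config = cv_config()) {
  df <- outcome_model_frame(outcome, probe_m_values, sample_table, covariates)
  full <- lm_meth_p(df)
  n <- nrow(df)
  k <- config$k_folds
  n_par <- ncol(stats::model.matrix(.outcome ~ ., df))
  if (config$fold_p_mode == "per_fold_refit" && floor(n / k) <= n_par) {
    stop("Fold size ", floor(n / k), " too small for ", n_par,
         " model parameters; reduce covariates or folds.", call. = FALSE)
  }
  seed <- derive_seed(config$seed, paste(probe_id, outcome))
  res <- withr::with_seed(seed, {
    sig <- logical(config$n_iterations)
    coefs <- numeric(0)
    for (it in seq_len(config$n_iterations)) {
      fold <- sample(rep_len(seq_len(k), n))
      pvals <- numeric(k)
      for (f in seq_len(k)) {
        test <- fold == f
        if (config$fold_p_mode == "per_fold_refit") {
          est <- lm_meth_p(df[test, , drop = FALSE])
          pvals[f] <- est["p"]
          coefs <- c(coefs, est["coefficient"])
        } else {
          train_fit <- stats::lm(.outcome ~ ., data = df[!test, , drop = FALSE])
          pred <- stats::predict(train_fit, newdata = df[test, , drop = FALSE])
          ct <- stats::cor.test(pred, df$.outcome[test])
          pvals[f] <- ct$p.value
          coefs <- c(coefs, stats::coef(train_fit)[".meth"])
        }
      }
      sig[it] <- fisher_combine(pvals)$p_combined <= config$alpha
    }
    list(pct = 100 * mean(sig), mean_coef = mean(coefs))
  })
  tibble::tibble(probe_id = probe_id, outcome = outcome,
                 mean_coefficient = res$mean_coef,
                 full_data_p = unname(full["p"]),
                 pct_iterations_significant = res$pct,
                 robust = res$pct == 100,
                 n = n)
}

#' Benefit/harm label for a methylation-outcome association
#'
#' Interprets a significant association in the direction of the patients'
#' abnormality: hypomethylation in patients means the abnormal direction is
#' a methylation *decrease*, so the predicted outcome shift is
#' `-mean_coefficient` (and `+mean_coefficient` for hypermethylation). The
#' label is `B` (benefit) when that shift improves the outcome under its
#' polarity, `H` (harm) otherwise, and `none` when the full-data p exceeds
#' `alpha`.
#'
#' @param mean_coefficient Methylation coefficient from the outcome model.
#' @param full_data_p Full-data p-value of the association.
#' @param patient_abnormality `"Hypo"` or `"Hyper"` status of the CpG in
#'   patients versus controls.
#' @param higher_is_better Logical outcome polarity.
#' @param alpha Significance threshold (default 0.05).
#' @return `"B"`, `"H"` or `"none"` (vectorised).
#' @export
label_direction <- function(mean_coefficient, full_data_p,
                            patient_abnormality, higher_is_better,
                            alpha = 0.05) {
  stopifnot(all(patient_abnormality %in% c("Hypo", "Hyper")))
  shift <- ifelse(patient_abnormality == "Hypo",
                  -mean_coefficient, mean_coefficient)
  zero_sig <- full_data_p <= alpha & mean_coefficient == 0
  if (any(zero_sig)) {
    warning("Zero coefficient with significant p; labelled `none`.",
            call. = FALSE)
  }
  ifelse(full_data_p > alpha | zero_sig, "none",
         ifelse((shift > 0) == higher_is_better, "B", "H"))
}

#' Robustness matrix over probes and outcomes
#'
#' Assembles per-(probe, outcome) robustness results into the heatmap
#' matrix of percentages with benefit/harm labels, plus the headline
#' counts: significant pairs (full-data p at or below `alpha`) and robust
#' pairs (significant in 100% of iterations).
#'
#' @param results Row-bound [cv_robustness()] results, one row per
#'   (probe, outcome) pair; duplicates are an error.
#' @param status Named vector (by probe_id) of `"Hypo"`/`"Hyper"` patient
#'   abnormality, for labelling; optional.
#' @param outcome_polarity Named logical vector (by outcome) of
#'   higher-is-better flags; optional (defaults to `TRUE`).
#' @param alpha Significance threshold (default 0.05).
#' @return An object of class `robustness_matrix`: list with `results`
#'   (the labelled tibble, canonically sorted), `matrix` (probes x
#'   outcomes percentage matrix), `n_significant`, `n_robust`,
#'   `pct_robust_of_significant`.
#' @export
robustness_matrix <- function(results, status = NULL,
                              outcome_polarity = NULL, alpha = 0.05) {
  if (anyDuplicated(results[c("probe_id", "outcome")])) {
    stop("Duplicate (probe, outcome) pair in results.", call. = FALSE)
  }
  results <- dplyr::arrange(results, .data$probe_id, .data$outcome)
  if (!is.null(status)) {
    pol <- if (is.null(outcome_polarity)) {
      stats::setNames(rep(TRUE, dplyr::n_distinct(results$outcome)),
                      unique(results$outcome))
    } else outcome_polarity
    results$label <- label_direction(results$mean_coefficient,
                                     results$full_data_p,
                                     unname(status[results$probe_id]),
                                     unname(pol[results$outcome]),
                                     alpha = alpha)
  }
  wide <- tidyr::pivot_wider(results[c("probe_id", "outcome",
                                       "pct_iterations_significant")],
                             names_from = "outcome",
                             values_from = "pct_iterations_significant")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$probe_id
  n_sig <- sum(results$full_data_p <= alpha)
  n_rob <- sum(results$full_data_p <= alpha &
                 results$pct_iterations_significant == 100)
  structure(list(results = results, matrix = mat,
                 n_significant = n_sig, n_robust = n_rob,
                 pct_robust_of_significant =
                   if (n_sig > 0) round(100 * n_rob / n_sig, 1) else NA_real_),
            class = "robustness_matrix")
}

#' @export
print.robustness_matrix <- function(x, ...) {
  cat("<robustness_matrix> ", nrow(x$matrix), " probes x ", ncol(x$matrix),
      " outcomes; ", x$n_significant, " significant pairs, ", x$n_robust,
      " robust (", x$pct_robust_of_significant, "% of significant)\n",
      sep = "")
  invisible(x)
}

#' @rdname robustness_matrix
#' @param x A `robustness_matrix`.
#' @param ... Unused.
#' @return `glance()`: one-row tibble with the counts.
#' @export
glance.robustness_matrix <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$results),
                 n_significant = x$n_significant,
                 n_robust = x$n_robust,
                 pct_robust_of_significant = x$pct_robust_of_significant)
}

#' Heatmap of cross-validated association robustness
#'
#' Tile plot of the percentage of iterations significant per
#' (CpG, outcome) pair, with benefit/harm labels when available.
#'
#' @param object A [robustness_matrix()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.robustness_matrix <- function(object, ...) {
  dat <- object$results
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$outcome, y = .data$probe_id,
                                         fill = .data$pct_iterations_significant)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "% iterations\nsignificant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("label" %in% names(dat)) {
    p <- p + ggplot2::geom_text(
      data = dat[dat$label != "none", ],
      ggplot2::aes(label = .data$label), size = 3)
  }
  p
}
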