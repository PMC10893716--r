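#' Specify a per-CpG model design
#'
#' Describes the multivariable linear model fitted at every CpG on the
#' M-value scale: a contrast variable (e.g. `group`), adjustment covariates,
#' and optionally an interaction between the contrast and one covariate.
#' Categorical covariates are one-hot encoded with the first level as
#' reference; the contrast variable must be two-level (or logical).
#'
#' @param contrast Name of the contrast variable in the sample sheet.
#' @param covariates Character vector of adjustment covariate names.
#' @param interaction Optional name of a covariate whose interaction with the
#'   contrast is to be tested (e.g. `"sex"` or `"age_exposure"`).
#' @return A `design_spec` object.
#' @export
design_spec <- function(contrast, covariates = character(), interaction = NULL) {
  stopifnot(is.character(contrast), length(contrast) == 1)
  if (!is.null(interaction) && !interaction %in% covariates) {
    stop("Interaction term `", interaction,
         "` must also appear among the covariates (both main effects needed).",
         call. = FALSE)
  }
  structure(list(contrast = contrast,
                 covariates = setdiff(covariates, contrast),
                 interaction = interaction),
            class = "design_spec")
}

# Build the model matrix; returns list(X, contrast_cols, interaction_cols).
build_design <- function(sample_table, spec) {
  vars <- unique(c(spec$contrast, spec$covariates))
  missing_vars <- setdiff(vars, names(sample_table))
  if (length(missing_vars) > 0) {
    stop("Sample sheet lacks model variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(sample_table[vars])
  for (v in vars) {
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  }
  if (anyNA(df)) {
    stop("Model variables contain missing values; subset to complete cases first.",
         call. = FALSE)
  }
  cv <- df[[spec$contrast]]
  if (is.factor(cv) && nlevels(droplevels(cv)) != 2 && !is.logical(cv)) {
    stop("Contrast variable `", spec$contrast, "` must have exactly two levels.",
         call. = FALSE)
  }
  rhs <- c(spec$contrast, spec$covariates)
  if (!is.null(spec$interaction)) {
    if (is.factor(df[[spec$interaction]])) {
      by_level <- table(df[[spec$contrast]], droplevels(df[[spec$interaction]]))
      if (any(rowSums(by_level > 0) < 2)) {
        stop("Interaction covariate `", spec$interaction,
             "` is constant within a contrast level.", call. = FALSE)
      }
    } else if (any(tapply(df[[spec$interaction]], df[[spec$contrast]],
                          function(z) stats::var(z) == 0))) {
      stop("Interaction covariate `", spec$interaction,
           "` is constant within a contrast level.", call. = FALSE)
    }
    rhs <- c(rhs, paste0(spec$contrast, ":", spec$interaction))
  }
  form <- stats::as.formula(paste("~", paste(rhs, collapse = " + ")))
  X <- stats::model.matrix(form, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("Design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  if (nrow(X) <= ncol(X)) {
    stop("Fewer samples (", nrow(X), ") than model parameters + 1 (",
         ncol(X) + 1, ").", call. = FALSE)
  }
  assign <- attr(X, "assign")
  terms_lab <- attr(stats::terms(form), "term.labels")
  contrast_cols <- which(assign == match(spec$contrast, terms_lab))
  interaction_cols <- if (!is.null(spec$interaction)) {
    which(assign == match(paste0(spec$contrast, ":", spec$interaction), terms_lab))
  } else integer()
  list(X = X, contrast_cols = contrast_cols, interaction_cols = interaction_cols)
}

as_m_matrix <- function(x) {
  if (inherits(x, "meth_set")) beta_to_m(x$beta) else x
}

#' Fit per-CpG multivariable linear models
#'
#' Ordinary least squares at every probe with a shared design matrix on the
#' M-value scale. The coefficient of the contrast variable is the log fold
#' change in M values; standard errors come from the per-probe residual
#' variance (pre-moderation). Follow with [empirical_bayes_moderate()] for
#' the moderated statistics.
#'
#' @param m_matrix Probes x samples matrix of M values (a [meth_set()] is
#'   accepted and converted with [beta_to_m()]).
#' @param sample_table Sample sheet; rows are matched to matrix columns by
#'   `sample_id`.
#' @param design A [design_spec()].
#' @param coef Which coefficient to report: `"contrast"` (default) or
#'   `"interaction"`.
#' @return An object of class `probe_fit` carrying per-probe estimates,
#'   unscaled standard deviations, residual variances and degrees of
#'   freedom, plus ordinary t, p and 95% CI. Use [tidy()] for a tibble.
#' @export
fit_probewise_models <- function(m_matrix, sample_table, design,
                                 coef = c("contrast", "interaction")) {
  coef <- match.arg(coef)
  M <- as_m_matrix(m_matrix)
  idx <- match(colnames(M), sample_table$sample_id)
  if (anyNA(idx)) {
    stop("Sample sheet is missing matrix sample(s): ",
         paste(utils::head(colnames(M)[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  st <- sample_table[idx, ]
  d <- build_design(st, design)
  X <- d$X
  target <- if (coef == "interaction") d$interaction_cols else d$contrast_cols
  if (length(target) != 1) {
    stop("Expected a single ", coef, " coefficient; found ", length(target), ".",
         call. = FALSE)
  }
  fit <- stats::lm.fit(X, t(M))
  cf <- if (is.matrix(fit$coefficients)) fit$coefficients else
    matrix(fit$coefficients, ncol = 1)
  res <- if (is.matrix(fit$residuals)) fit$residuals else
    matrix(fit$residuals, ncol = 1)
  df_resid <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df_resid
  xtx_inv <- chol2inv(qr.R(qr(X)))
  stdev_unscaled <- sqrt(xtx_inv[target, target])
  coefs <- cf[target, ]
  se <- sqrt(sigma2) * stdev_unscaled
  t_ord <- coefs / se
  crit <- stats::qt(0.975, df_resid)
  structure(list(
    probe_id = rownames(M),
    coef = unname(coefs),
    stdev_unscaled = stdev_unscaled,
    sigma2 = unname(sigma2),
    df_resid = df_resid,
    t = unname(t_ord),
    p = unname(2 * stats::pt(-abs(t_ord), df_resid)),
    ci_low = unname(coefs - crit * se),
    ci_high = unname(coefs + crit * se),
    coef_name = colnames(X)[target],
    n_samples = nrow(X),
    moderated = FALSE
  ), class = "probe_fit")
}

# Newton solve of trigamma(y) = x, vectorised (cf. inverse digamma methods).
trigamma_inverse <- function(x) {
  out <- rep(NA_real_, length(x))
  out[x > 1e7] <- 1 / sqrt(x[x > 1e7])
  out[x < 1e-6] <- 1 / x[x < 1e-6]
  todo <- is.na(out)
  if (any(todo)) {
    y <- 0.5 + 1 / x[todo]
    for (i in 1:60) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / x[todo]) / psigamma(y, deriv = 2)
      y <- y + dif
      if (max(abs(dif / y)) < 1e-10) break
    }
    out[todo] <- y
  }
  out
}

#' Empirical-Bayes moderation of per-CpG variances
#'
#' Shrinks per-probe residual variances toward a common prior by fitting a
#' scaled inverse-chi-square prior to the ensemble of observed variances.
#' The prior parameters (d0, s0^2) are estimated by matching the first two
#' moments of log s^2 (digamma/trigamma equations); each posterior variance
#' is then `(d0*s0^2 + d*s^2) / (d0 + d)`, and moderated t statistics are
#' referred to a t distribution with `d0 + d` degrees of freedom. When the
#' moment equations imply an infinite prior df every posterior variance
#' equals s0^2.
#'
#' @param fit A [fit_probewise_models()] result with at least two probes.
#' @param prior_df Override the estimated prior df (0 forces no shrinkage;
#'   `Inf` forces full shrinkage). Default `NULL`: estimate from the data.
#' @return A `moderated_fit` (inherits `probe_fit`) with elements `s2_post`,
#'   `d0`, `s02`, `df_total`, and moderated `t`, `p`, `ci_low`, `ci_high`.
#' @export
empirical_bayes_moderate <- function(fit, prior_df = NULL) {
  stopifnot(inherits(fit, "probe_fit"))
  s2 <- fit$sigma2
  d <- fit$df_resid
  if (length(s2) < 2) stop("Moderation needs at least two probes.", call. = FALSE)
  ok <- s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.null(prior_df)) {
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      message("Residual-variance spread no wider than sampling noise; prior df set to Inf.")
      d0 <- Inf
      s02 <- exp(emean)
    }
  } else {
    d0 <- prior_df
    s02 <- if (is.finite(d0) && d0 > 0) {
      exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else exp(emean)
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  df_total <- min(d0 + d, 1e9)
  se <- sqrt(s2_post) * fit$stdev_unscaled
  t_mod <- fit$coef / se
  crit <- stats::qt(0.975, df_total)
  out <- fit
  out$s2_post <- s2_post
  out$d0 <- d0
  out$s02 <- s02
  out$df_total <- df_total
  out$t <- unname(t_mod)
  out$p <- unname(2 * stats::pt(-abs(t_mod), df_total))
  out$ci_low <- unname(fit$coef - crit * se)
  out$ci_high <- unname(fit$coef + crit * se)
  out$moderated <- TRUE
  class(out) <- c("moderated_fit", "probe_fit")
  out
}

#' @export
print.probe_fit <- function(x, ...) {
  cat("<", if (x$moderated) "moderated_fit" else "probe_fit", "> ",
      length(x$probe_id), " probes, coefficient `", x$coef_name,
      "`, residual df ", x$df_resid, "\n", sep = "")
  if (x$moderated) {
    cat("  prior df d0 = ", format(signif(x$d0, 4)),
        ", prior variance s0^2 = ", format(signif(x$s02, 4)), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy per-CpG model fits
#'
#' @param x A `probe_fit` or `moderated_fit`.
#' @param ... Unused.
#' @return One row per probe: `probe_id`, `logfc_m`, `se`, `t`, `p`,
#'   `ci_low`, `ci_high` (and `s2_post` when moderated).
#' @export
tidy.probe_fit <- function(x, ...) {
  s2 <- if (x$moderated) x$s2_post else x$sigma2
  tibble::tibble(probe_id = x$probe_id,
                 logfc_m = x$coef,
                 se = sqrt(s2) * x$stdev_unscaled,
                 t = x$t, p = x$p,
                 ci_low = x$ci_low, ci_high = x$ci_high)
}

#' @rdname tidy.probe_fit
#' @return `glance()`: one-row tibble with probe count, sample count,
#'   residual df and (when moderated) prior df and prior variance.
#' @export
glance.probe_fit <- function(x, ...) {
  tibble::tibble(n_probes = length(x$probe_id),
                 n_samples = x$n_samples,
                 df_resid = x$df_resid,
                 prior_df = if (x$moderated) x$d0 else NA_real_,
                 prior_var = if (x$moderated) x$s02 else NA_real_)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values (via [stats::p.adjust()]): monotone in the
#' sorted order, capped at 1, returned in the original order.
#'
#' @param pvals Numeric vector of p-values in \[0,1\].
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1] with no NA.", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Interaction scan over a probe set
#'
#' Refits the per-CpG model with a contrast-by-covariate interaction term and
#' reports the moderated p-value of that interaction coefficient. Normally
#' run on the already-identified DMP set only.
#'
#' @inheritParams fit_probewise_models
#' @param term Covariate whose interaction with the contrast is tested
#'   (e.g. `"sex"` or `"age_exposure"`); must be in the design's covariates.
#' @param prior_df Passed to [empirical_bayes_moderate()]; with few probes
#'   the default data-driven prior can be unstable, so a forced value is
#'   accepted.
#' @return A tibble: `probe_id`, `coef_interaction`, `p_interaction`.
#' @export
interaction_scan <- function(m_matrix, sample_table, design, term,
                             prior_df = NULL) {
  spec <- design_spec(design$contrast, design$covariates, interaction = term)
  fit <- fit_probewise_models(m_matrix, sample_table, spec, coef = "interaction")
  fit <- if (length(fit$probe_id) >= 2) {
    empirical_bayes_moderate(fit, prior_df = prior_df)
  } else fit
  tibble::tibble(probe_id = fit$probe_id,
                 coef_interaction = fit$coef,
                 p_interaction = fit$p)
}

#' Glucocorticoid-treatment contrast within patients
#'
#' Compares methylation between glucocorticoid-treated and untreated former
#' patients only, with the extended covariate list (severity, length of
#' stay, diagnosis, randomisation, malnutrition risk on top of the baseline
#' risk factors and technical PCs). Evaluated on a supplied probe set,
#' normally the previously identified DMPs.
#'
#' @inheritParams fit_probewise_models
#' @param covariates Adjustment covariates for the within-patient model.
#' @param prior_df Passed to [empirical_bayes_moderate()].
#' @return A tibble: `probe_id`, `coef_gc`, `p_gc`.
#' @export
gc_subgroup_contrast <- function(m_matrix, sample_table, covariates,
                                 prior_df = NULL) {
  M <- as_m_matrix(m_matrix)
  st <- sample_table[sample_table$group == "patient", ]
  if (!"gc_treated" %in% names(st) || anyNA(st$gc_treated)) {
    stop("gc_treated must be defined for every patient.", call. = FALSE)
  }
  if (length(unique(st$gc_treated)) < 2) {
    stop("Patients are all-GC or no-GC; contrast is undefined.", call. = FALSE)
  }
  M <- M[, colnames(M) %in% st$sample_id, drop = FALSE]
  spec <- design_spec("gc_treated", covariates)
  fit <- fit_probewise_models(M, st, spec)
  fit <- if (length(fit$probe_id) >= 2) {
    empirical_bayes_moderate(fit, prior_df = prior_df)
  } else fit
  tibble::tibble(probe_id = fit$probe_id,
                 coef_gc = fit$coef,
                 p_gc = fit$p)
}

#' Unadjusted absolute group difference in mean beta values
#'
#' @param x A [meth_set()] or beta matrix (probes x samples).
#' @param groups Vector of group labels (`patient`/`control`) aligned with
#'   the matrix columns, or a sample sheet from which `group` is taken by
#'   `sample_id` match.
#' @return Named numeric vector, one value per probe:
#'   `|mean(beta | patient) - mean(beta | control)|`.
#' @export
abs_mean_beta_diff <- function(x, groups) {
  beta <- if (inherits(x, "meth_set")) x$beta else x
  if (is.data.frame(groups)) {
    groups <- groups$group[match(colnames(beta), groups$sample_id)]
  }
  stopifnot(length(groups) == ncol(beta))
  pt <- groups == "patient"
  ct <- groups == "control"
  if (!any(pt) || !any(ct)) stop("Both groups must be nonempty.", call. = FALSE)
  abs(rowMeans(beta[, pt, drop = FALSE], na.rm = TRUE) -
        rowMeans(beta[, ct, drop = FALSE], na.rm = TRUE))
}

#' Gene panel sizes for the HPA-axis CpG selection
#'
#' Number of selected CpG sites per gene for the genes in which
#' differentially methylated positions were found; used as denominators for
#' per-gene percentages in [summarize_dmps()]. The full 18-gene panel
#' includes further genes whose CpG counts are not packaged.
#'
#' @return Named integer vector.
#' @export
hpa_gene_totals <- function() {
  c(CRHR1 = 41L, POMC = 27L, MC2R = 20L, NR3C1 = 89L, FKBP5 = 51L,
    HSD11B1 = 25L, SRD5A1 = 31L, AKR1D1 = 15L, DUSP1 = 33L,
    TSC22D3 = 50L, TNF = 27L)
}

#' Summarise a DMP result table
#'
#' Headline statistics of a differentially-methylated-position table:
#' count; mean, sample SD and maximum of the absolute beta difference (in
#' percent, one decimal); percentage hypomethylated; number of distinct
#' genes; per-gene counts with percentages against supplied panel totals;
#' and counts of rows with age-interaction, sex-interaction and
#' glucocorticoid p-values at or below `alpha`.
#'
#' @param table DMP tibble with columns `gene`, `status`, `abs_mean_diff`
#'   and optionally `p_int_age`, `p_int_sex`, `p_gc`.
#' @param gene_totals Named vector of per-gene selected-CpG totals
#'   (default [hpa_gene_totals()]); genes without a total get `NA`
#'   percentages.
#' @param alpha Significance threshold for the interaction/GC counts
#'   (default 0.05).
#' @return A list of class `dmp_summary`: `stats` (one-row tibble) and
#'   `per_gene` (tibble).
#' @export
summarize_dmps <- function(table, gene_totals = hpa_gene_totals(),
                           alpha = 0.05) {
  if (nrow(table) == 0) stop("Empty DMP table.", call. = FALSE)
  d <- table$abs_mean_diff
  n <- nrow(table)
  count_le <- function(col) {
    if (col %in% names(table)) sum(table[[col]] <= alpha, na.rm = TRUE)
    else NA_integer_
  }
  stats_row <- tibble::tibble(
    n_dmps = n,
    mean_abs_diff_pct = round(mean(d) * 100, 1),
    sd_abs_diff_pct = if (n > 1) round(stats::sd(d) * 100, 1) else NA_real_,
    max_abs_diff_pct = round(max(d) * 100, 1),
    pct_hypo = round(mean(table$status == "Hypo") * 100, 1),
    n_genes = dplyr::n_distinct(table$gene),
    n_age_interaction = count_le("p_int_age"),
    n_sex_interaction = count_le("p_int_sex"),
    n_gc = count_le("p_gc")
  )
  per_gene <- table |>
    dplyr::count(.data$gene, name = "n_dmps") |>
    dplyr::mutate(
      total = unname(gene_totals[.data$gene]),
      pct_of_selected = round(.data$n_dmps / .data$total * 100, 1)
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_dmps))
  structure(list(stats = stats_row, per_gene = per_gene),
            class = "dmp_summary")
}

#' @export
print.dmp_summary <- function(x, ...) {
  s <- x$stats
  cat("DMP summary: ", s$n_dmps, " positions in ", s$n_genes, " genes; ",
      "absolute beta difference mean ", s$mean_abs_diff_pct, "% (SD ",
      s$sd_abs_diff_pct, "%), up to ", s$max_abs_diff_pct, "%; ",
      s$pct_hypo, "% hypomethylated.\n", sep = "")
  if (!is.na(s$n_age_interaction)) {
    cat("Rows at alpha: age interaction ", s$n_age_interaction,
        ", sex interaction ", s$n_sex_interaction,
        ", glucocorticoid contrast ", s$n_gc, ".\n", sep = "")
  }
  print(x$per_gene)
  invisible(x)
}

#' Table of differentially methylated positions
#'
#' Runs the full DMP workflow: moderated group-contrast models at every
#' probe, FDR control, selection at `fdr`, unadjusted absolute beta
#' differences, hypo/hyper status from the sign of the adjusted log fold
#' change, then (on the DMP set only) sex and age interaction scans and the
#' within-patient glucocorticoid contrast. Interaction and GC p-values are
#' reported unadjusted.
#'
#' @param ms A [meth_set()] of beta values (biological probes only).
#' @param sample_table Sample sheet with technical PCs already attached.
#' @param annotation Probe annotation (for gene and gene-section columns).
#' @param covariates Baseline adjustment covariates (technical PC columns
#'   are added automatically when present).
#' @param gc_covariates Extra covariates for the glucocorticoid contrast.
#' @param fdr FDR threshold for calling DMPs (default 0.05).
#' @param n_pcs_use Number of attached PC columns to include (default: all
#'   present).
#' @param interactions Run the sex/age interaction scans (default `TRUE`
#'   when the needed columns exist).
#' @param gc Run the glucocorticoid subgroup contrast (default `TRUE` when
#'   `gc_treated` exists).
#' @return A tibble, one row per DMP: `probe_id`, `gene`, `gene_section`,
#'   `status`, `logfc_m`, `ci_low`, `ci_high`, `abs_mean_diff`, `q_group`,
#'   and when computed `p_int_sex`, `p_int_age`, `p_gc`. The full per-probe
#'   fit is attached as attribute `"fit"`.
#' @export
dmp_table <- function(ms, sample_table, annotation,
                      covariates = c("age_exposure", "sex"),
                      gc_covariates = c("los_picu", "pim3"),
                      fdr = 0.05, n_pcs_use = NULL,
                      interactions = TRUE, gc = TRUE) {
  pc_cols <- grep("^pc[0-9]+$", names(sample_table), value = TRUE)
  if (!is.null(n_pcs_use)) pc_cols <- utils::head(pc_cols, n_pcs_use)
  covs <- c(covariates, pc_cols)
  spec <- design_spec("group", covs)
  M <- beta_to_m(ms$beta)
  fit <- empirical_bayes_moderate(fit_probewise_models(M, sample_table, spec))
  res <- tidy(fit)
  res$q_group <- bh_adjust(res$p)
  res$abs_mean_diff <- unname(abs_mean_beta_diff(ms, sample_table)[res$probe_id])
  dmps <- res[res$q_group <= fdr, ]
  ann_idx <- match(dmps$probe_id, annotation$probe_id)
  out <- tibble::tibble(
    probe_id = dmps$probe_id,
    gene = if ("gene" %in% names(annotation)) annotation$gene[ann_idx] else NA,
    gene_section = if ("gene_section" %in% names(annotation))
      annotation$gene_section[ann_idx] else NA,
    status = factor(ifelse(dmps$logfc_m < 0, "Hypo", "Hyper"),
                    levels = c("Hypo", "Hyper")),
    logfc_m = dmps$logfc_m,
    ci_low = dmps$ci_low,
    ci_high = dmps$ci_high,
    abs_mean_diff = dmps$abs_mean_diff,
    q_group = dmps$q_group
  )
  if (nrow(out) > 0) {
    M_dmp <- M[out$probe_id, , drop = FALSE]
    if (interactions && all(c("sex", "age_exposure") %in% names(sample_table))) {
      sx <- interaction_scan(M_dmp, sample_table, spec, "sex")
      ag <- interaction_scan(M_dmp, sample_table, spec, "age_exposure")
      out$p_int_sex <- sx$p_interaction[match(out$probe_id, sx$probe_id)]
      out$p_int_age <- ag$p_interaction[match(out$probe_id, ag$probe_id)]
    }
    if (gc && "gc_treated" %in% names(sample_table) &&
        !all(is.na(sample_table$gc_treated))) {
      gcr <- gc_subgroup_contrast(M_dmp, sample_table,
                                  c(covariates, gc_covariates, pc_cols))
      out$p_gc <- gcr$p_gc[match(out$probe_id, gcr$probe_id)]
    }
  }
  attr(out, "fit") <- fit
  out
}

#' Effect-and-CI plot for a DMP table
#'
#' Forest-style display of per-CpG log fold changes (M-value scale) with
#' their 95% confidence intervals, coloured by hypo/hyper status.
#'
#' @param object A DMP tibble from [dmp_table()] or [hpa_dmp_reference()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot_dmp <- function(object, ...) {
  dat <- dplyr::mutate(object,
                       probe_id = stats::reorder(.data$probe_id, .data$logfc_m))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$logfc_m, y = .data$probe_id,
                                    colour = .data$status)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(x = "log fold change (M values)", y = NULL,
                  colour = "status") +
    ggplot2::theme_minimal()
}
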