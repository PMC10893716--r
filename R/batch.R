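#' Principal components of technical control probes
#'
#' Technical (non-negative) control probes measure array performance, not
#' biology, so their principal components proxy batch and other technical
#' variation; the leading PCs enter every downstream model as covariates.
#' PCA is run on the probe-wise centred beta submatrix of probes with
#' `control_type == "other_control"` (negative controls are excluded).
#' Scores are returned in decreasing explained-variance order with a
#' deterministic sign convention: each PC's loading vector sums to a
#' non-negative value.
#'
#' @param x A [meth_set()] containing the control probes.
#' @param annotation Probe annotation with `control_type`.
#' @param n_pcs Number of components requested (default 30); silently
#'   reduced, with a warning, to the rank bound
#'   `min(n_control_probes, n_samples - 1)`.
#' @param scale_probes Scale each control probe to unit variance before the
#'   decomposition (default `FALSE`: centring only).
#' @return An object of class `control_pcs`: list with `scores` (samples x
#'   n_pcs matrix, columns `pc1..pcK`), `loadings`, `explained_variance`
#'   (proportions), `sdev` and `n_pcs`.
#' @export
control_probe_pcs <- function(x, annotation, n_pcs = 30, scale_probes = FALSE) {
  ann <- annotation[match(rownames(x$beta), annotation$probe_id), ]
  keep <- which(ann$control_type == "other_control")
  if (length(keep) == 0) {
    stop("No eligible control probes (control_type == \"other_control\"); ",
         "negative controls are excluded.", call. = FALSE)
  }
  ctrl <- t(x$beta[keep, , drop = FALSE])   # samples x probes
  if (anyNA(ctrl)) stop("Control probes contain missing values.", call. = FALSE)
  vars <- apply(ctrl, 2, stats::var)
  zero_var <- vars < .Machine$double.eps
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance control probe(s) dropped.",
            call. = FALSE)
    ctrl <- ctrl[, !zero_var, drop = FALSE]
  }
  if (ncol(ctrl) == 0) stop("All control probes have zero variance.", call. = FALSE)
  rank_bound <- min(ncol(ctrl), nrow(ctrl) - 1L)
  if (n_pcs > rank_bound) {
    warning("Requested ", n_pcs, " PCs but rank bound is ", rank_bound,
            "; returning ", rank_bound, ".", call. = FALSE)
    n_pcs <- rank_bound
  }
  xc <- scale(ctrl, center = TRUE, scale = scale_probes)
  sv <- svd(xc)
  flip <- ifelse(colSums(sv$v) < 0, -1, 1)
  scores <- sweep(sv$u %*% diag(sv$d, nrow = length(sv$d)), 2, flip, `*`)
  loadings <- sweep(sv$v, 2, flip, `*`)
  sdev <- sv$d / sqrt(nrow(ctrl) - 1)
  k <- seq_len(n_pcs)
  scores <- scores[, k, drop = FALSE]
  rownames(scores) <- colnames(x$beta)
  colnames(scores) <- paste0("pc", k)
  structure(list(scores = scores,
                 loadings = loadings[, k, drop = FALSE],
                 explained_variance = (sdev^2 / sum(sdev^2))[k],
                 sdev = sdev[k],
                 n_pcs = n_pcs),
            class = "control_pcs")
}

#' @export
print.control_pcs <- function(x, ...) {
  cat("<control_pcs> ", nrow(x$scores), " samples x ", x$n_pcs, " PCs\n",
      sep = "")
  cat("  variance explained (first ", min(5, x$n_pcs), "): ",
      paste(signif(utils::head(x$explained_variance, 5), 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Tidy control-probe PC scores
#' @param x A `control_pcs` object.
#' @param ... Unused.
#' @return A tibble: `sample_id` plus one column per PC.
#' @export
tidy.control_pcs <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$scores), rownames = "sample_id")
}

#' @rdname tidy.control_pcs
#' @return `glance()`: one-row tibble with `n_pcs` and the cumulative
#'   variance explained.
#' @export
glance.control_pcs <- function(x, ...) {
  tibble::tibble(n_pcs = x$n_pcs,
                 cum_var_explained = sum(x$explained_variance))
}

#' Attach technical PCs to a sample sheet
#'
#' Appends control-probe PC scores as covariates `pc1..pcK` so that every
#' downstream model can adjust for technical variation. Zero-variance PCs
#' are never attached; attaching twice is an error.
#'
#' @param sample_table Sample sheet; `sample_id` must match the score rows.
#' @param control_pcs A [control_probe_pcs()] result.
#' @return The sample sheet with PC columns appended.
#' @export
attach_technical_covariates <- function(sample_table, control_pcs) {
  scores <- control_pcs$scores
  if (!setequal(sample_table$sample_id, rownames(scores)) ||
      nrow(sample_table) != nrow(scores)) {
    stop("Sample ids of sheet and PC scores do not match.", call. = FALSE)
  }
  keep <- apply(scores, 2, stats::var) > .Machine$double.eps
  scores <- scores[, keep, drop = FALSE]
  dup <- intersect(colnames(scores), names(sample_table))
  if (length(dup) > 0) {
    stop("Covariate name(s) already present (attached twice?): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  idx <- match(sample_table$sample_id, rownames(scores))
  dplyr::bind_cols(sample_table,
                   tibble::as_tibble(as.data.frame(scores[idx, , drop = FALSE])))
}
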