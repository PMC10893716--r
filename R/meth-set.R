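#' Methylation beta-value set
#'
#' Container for a probes x samples matrix of methylation beta values, with an
#' optional matching matrix of detection p-values. Beta values are proportions
#' methylated and must lie in \[0, 1\]; missing measurements are `NA`, never
#' sentinel zeros.
#'
#' @param beta Numeric matrix of beta values, probes in rows, samples in
#'   columns. Row names are probe identifiers, column names sample
#'   identifiers; both must be unique.
#' @param detection_p Optional numeric matrix of per-probe, per-sample
#'   detection p-values with the same dimensions and dimnames as `beta`.
#'
#' @return An object of class `meth_set`: a list with elements `beta` and
#'   `detection_p`.
#' @examples
#' b <- matrix(c(0.1, 0.9, 0.5, 0.2, 0.8, 0.4), nrow = 3,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' ms <- meth_set(b)
#' dim(ms)
#' @export
meth_set <- function(beta, detection_p = NULL) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop("`beta` must be a numeric matrix (probes x samples).", call. = FALSE)
  }
  if ((nrow(beta) > 0 && is.null(rownames(beta))) ||
      (ncol(beta) > 0 && is.null(colnames(beta)))) {
    stop("`beta` must carry probe row names and sample column names.", call. = FALSE)
  }
  if (anyDuplicated(rownames(beta))) {
    stop("Duplicate probe identifiers: ",
         paste(unique(rownames(beta)[duplicated(rownames(beta))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(beta))) {
    stop("Duplicate sample identifiers: ",
         paste(unique(colnames(beta)[duplicated(colnames(beta))]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.na(beta) & (!is.finite(beta) | beta < 0 | beta > 1),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("Beta value out of [0, 1] at probe ", rownames(beta)[bad[1, 1]],
         ", sample ", colnames(beta)[bad[1, 2]],
         " (value ", format(beta[bad[1, , drop = FALSE]]), ").", call. = FALSE)
  }
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !identical(dim(detection_p), dim(beta))) {
      stop("`detection_p` must be a matrix with the same shape as `beta`.",
           call. = FALSE)
    }
    dimnames(detection_p) <- dimnames(beta)
    if (any(!is.na(detection_p) & (detection_p < 0 | detection_p > 1))) {
      stop("Detection p-values must lie in [0, 1].", call. = FALSE)
    }
  }
  structure(list(beta = beta, detection_p = detection_p), class = "meth_set")
}

#' @export
dim.meth_set <- function(x) dim(x$beta)

#' @export
dimnames.meth_set <- function(x) dimnames(x$beta)

#' Probe and sample identifiers of a meth_set
#' @param x A `meth_set`.
#' @return Character vector of identifiers.
#' @export
probe_ids <- function(x) rownames(x$beta)

#' @rdname probe_ids
#' @export
sample_ids <- function(x) colnames(x$beta)

#' Subset a meth_set by probes and/or samples
#'
#' @param x A `meth_set`.
#' @param i Probe index (integer, logical or character).
#' @param j Sample index (integer, logical or character).
#' @param ... Unused.
#' @return A `meth_set` restricted to the selected probes and samples.
#' @export
`[.meth_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$beta))
  if (missing(j)) j <- seq_len(ncol(x$beta))
  meth_set(x$beta[i, j, drop = FALSE],
           if (!is.null(x$detection_p)) x$detection_p[i, j, drop = FALSE])
}

#' @export
print.meth_set <- function(x, ...) {
  cat("<meth_set> ", nrow(x$beta), " probes x ", ncol(x$beta), " samples",
      if (!is.null(x$detection_p)) ", with detection p-values" else "",
      "\n", sep = "")
  cat("  beta range: ",
      paste(signif(range(x$beta, na.rm = TRUE), 3), collapse = " - "),
      "; missing cells: ", sum(is.na(x$beta)), "\n", sep = "")
  invisible(x)
}

#' Tidy a meth_set into long format
#'
#' One row per (probe, sample) measurement; useful for plotting with ggplot2.
#'
#' @param x A `meth_set`.
#' @param ... Unused.
#' @return A tibble with columns `probe_id`, `sample_id`, `beta` and, when
#'   present, `detection_p`.
#' @export
tidy.meth_set <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame.table(x$beta, stringsAsFactors = FALSE))
  names(out) <- c("probe_id", "sample_id", "beta")
  if (!is.null(x$detection_p)) {
    out$detection_p <- as.vector(x$detection_p)
  }
  out
}

#' Density plot of per-sample beta distributions
#'
#' A clean buccal-swab sample shows the characteristic bi-peak beta
#' distribution (modes near 0 and 1); flat mid-heavy curves indicate failed
#' samples. Each curve is one sample.
#'
#' @param object A `meth_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meth_set <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$beta, group = .data$sample_id)) +
    ggplot2::geom_density(alpha = 0.25, colour = "grey30", linewidth = 0.3) +
    ggplot2::labs(x = "beta value", y = "density") +
    ggplot2::theme_minimal()
}
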