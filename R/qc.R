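#' Convert between beta and M values
#'
#' Methylation beta values (proportion methylated, in \[0,1\]) are modelled on
#' the M-value scale, `M = log2(beta / (1 - beta))`. Betas are clipped to
#' `[eps, 1 - eps]` before the logit so boundary values stay finite
#' (|M| <= ~19.9 at the default `eps`).
#'
#' @param beta Numeric vector or matrix of beta values in \[0,1\].
#' @param m Numeric vector or matrix of M values.
#' @param eps Clipping margin, default `1e-6`.
#' @return Transformed values with the same shape as the input.
#' @examples
#' beta_to_m(0.8)   # log2(4) = 2
#' m_to_beta(0)     # 0.5
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}

#' Sample quality control by the bi-peak criterion
#'
#' A clean methylation sample shows a bimodal beta distribution with modes
#' near 0 and 1. The check is a mid-band-fraction rule: a sample fails when
#' the fraction of its (non-missing) beta values falling strictly inside
#' (0.3, 0.7) exceeds `midband_threshold`. Externally known
#' insufficient-DNA-yield samples can be supplied and are failed with that
#' reason regardless of their distribution. A sample with no usable values
#' fails as non-bimodal.
#'
#' @param x A [meth_set()].
#' @param midband_threshold Maximum tolerated mid-band fraction (default 0.4).
#' @param insufficient_yield Character vector of sample ids to fail for
#'   insufficient DNA yield; defaults to the `insufficient_yield` attribute
#'   of `x` if present.
#' @return A tibble with one row per sample: `sample_id`, `midband_frac`,
#'   `pass`, `reason` (`NA`, `"insufficient_yield"` or `"non_bimodal"`).
#' @export
sample_qc <- function(x, midband_threshold = 0.4,
                      insufficient_yield = attr(x, "insufficient_yield")) {
  if (!inherits(x, "meth_set")) stop("`x` must be a meth_set.", call. = FALSE)
  if (ncol(x$beta) == 0 || nrow(x$beta) == 0) {
    stop("Cannot run sample QC on an empty matrix.", call. = FALSE)
  }
  frac <- apply(x$beta, 2, function(b) {
    b <- b[!is.na(b)]
    if (length(b) == 0) return(NA_real_)
    mean(b > 0.3 & b < 0.7)
  })
  all_missing <- is.na(frac)
  if (any(all_missing)) {
    message("Sample(s) with all values missing fail QC: ",
            paste(colnames(x$beta)[all_missing], collapse = ", "))
  }
  non_bimodal <- all_missing | (!is.na(frac) & frac > midband_threshold)
  yield_fail <- colnames(x$beta) %in% insufficient_yield
  pass <- !non_bimodal & !yield_fail
  reason <- dplyr::case_when(
    yield_fail ~ "insufficient_yield",
    non_bimodal ~ "non_bimodal",
    TRUE ~ NA_character_
  )
  tibble::tibble(sample_id = colnames(x$beta),
                 midband_frac = unname(frac),
                 pass = unname(pass),
                 reason = reason)
}

#' Probe filtering by detection p-value and SNP overlap
#'
#' A probe is removed when its detection p-value exceeds `p_thresh` in at
#' least `frac` of the samples (inclusive `>=`, the conservative reading of
#' a "50% of samples" rule), or when the annotation flags it as spanning a
#' single-nucleotide polymorphism. Control probes are exempt from the SNP
#' rule by construction (their flags are cleared on annotation read).
#'
#' @param x A [meth_set()]; `x$detection_p` must be present unless
#'   `use_detection = FALSE`.
#' @param annotation Probe annotation covering every probe of `x`.
#' @param p_thresh Detection p-value threshold (default 0.01).
#' @param frac Fraction of samples that must exceed `p_thresh` for removal
#'   (default 0.5, applied inclusively).
#' @param use_detection Set `FALSE` to skip the detection rule when no
#'   detection p-values exist.
#' @return A list with `matrix` (the filtered [meth_set()]) and `report`
#'   (tibble: `probe_id`, `pass`, `reason` in
#'   `NA`/`"detection_p"`/`"snp"`).
#' @export
probe_filter <- function(x, annotation, p_thresh = 0.01, frac = 0.5,
                         use_detection = !is.null(x$detection_p)) {
  if (!all(rownames(x$beta) %in% annotation$probe_id)) {
    missing <- setdiff(rownames(x$beta), annotation$probe_id)
    stop("Annotation missing probe(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  ann <- annotation[match(rownames(x$beta), annotation$probe_id), ]
  if (use_detection) {
    if (is.null(x$detection_p)) {
      stop("Detection rule requested but `x` has no detection p-values.",
           call. = FALSE)
    }
    det_fail <- rowMeans(x$detection_p > p_thresh, na.rm = TRUE) >= frac
  } else {
    det_fail <- rep(FALSE, nrow(x$beta))
  }
  snp_fail <- ann$snp_flag %in% TRUE
  pass <- !det_fail & !snp_fail
  report <- tibble::tibble(
    probe_id = rownames(x$beta),
    pass = unname(pass),
    reason = dplyr::case_when(det_fail ~ "detection_p",
                              snp_fail ~ "snp",
                              TRUE ~ NA_character_)
  )
  list(matrix = x[pass, ], report = report)
}

#' Quantile normalization of beta values across samples
#'
#' Forces every sample's beta distribution onto the across-sample mean
#' quantile curve while preserving within-sample ranks; tied values share
#' the mean of their quantile span. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param x A [meth_set()] without missing values.
#' @return A [meth_set()] of the same shape.
#' @export
quantile_normalize <- function(x) {
  if (!inherits(x, "meth_set")) stop("`x` must be a meth_set.", call. = FALSE)
  if (anyNA(x$beta)) {
    stop("Quantile normalization requires a complete matrix; impute or drop missing cells first.",
         call. = FALSE)
  }
  if (ncol(x$beta) == 1) {
    warning("Single-sample matrix: quantile normalization is the identity.",
            call. = FALSE)
    return(x)
  }
  norm <- limma::normalizeQuantiles(x$beta, ties = TRUE)
  dimnames(norm) <- dimnames(x$beta)
  meth_set(norm, x$detection_p)
}

#' Impute age at exposure for healthy controls
#'
#' Patients carry their recorded age at PICU admission as age at exposure.
#' Controls, who were never admitted, get `age_exposure = age_followup - 2`
#' (the follow-up visit happens two years after the patients' exposure).
#' A negative imputed age is an error naming the sample.
#'
#' @param sample_table Sample sheet with `group`, `age_followup` and (for
#'   patients) `age_exposure`.
#' @return The sample sheet with `age_exposure` filled in for controls.
#' @examples
#' st <- tibble::tibble(sample_id = c("p1", "c1"),
#'                      group = c("patient", "control"),
#'                      age_followup = c(4.1, 3.8),
#'                      age_exposure = c(2.1, NA))
#' impute_age_at_exposure(st)
#' @export
impute_age_at_exposure <- function(sample_table) {
  if (!all(c("group", "age_followup") %in% names(sample_table))) {
    stop("Sample sheet needs `group` and `age_followup` columns.", call. = FALSE)
  }
  if (!"age_exposure" %in% names(sample_table)) {
    sample_table$age_exposure <- NA_real_
  }
  is_ctrl <- sample_table$group == "control"
  imputed <- sample_table$age_followup[is_ctrl] - 2
  neg <- imputed < 0
  if (any(neg, na.rm = TRUE)) {
    stop("Imputed age at exposure negative for sample(s): ",
         paste(sample_table$sample_id[is_ctrl][which(neg)], collapse = ", "),
         call. = FALSE)
  }
  sample_table$age_exposure[is_ctrl] <- imputed
  sample_table
}
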