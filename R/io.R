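#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# Detect comma vs tab from the header line; `dialect` overrides.
detect_delim <- function(path, dialect = c("auto", "tab", "comma")) {
  dialect <- match.arg(dialect)
  if (dialect == "tab") return("\t")
  if (dialect == "comma") return(",")
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("Empty file: ", path, call. = FALSE)
  if (lengths(regmatches(header, gregexpr("\t", header))) >=
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

#' Read and write beta-value matrices
#'
#' Delimited text with probe identifiers in the first column and sample
#' identifiers in the header row. The delimiter is auto-detected between tab
#' and comma unless `dialect` says otherwise; writers emit headered TSV.
#' Empty cells become `NA` (missing), never zero.
#'
#' @param path File path.
#' @param dialect One of `"auto"`, `"tab"`, `"comma"`.
#' @param detection_p_path Optional path to a detection p-value matrix of the
#'   same layout.
#' @return `read_beta_matrix()` returns a validated [meth_set()];
#'   `write_beta_matrix()` returns `path` invisibly.
#' @export
read_beta_matrix <- function(path, dialect = c("auto", "tab", "comma"),
                             detection_p_path = NULL) {
  delim <- detect_delim(path, match.arg(dialect))
  read_mat <- function(p) {
    tab <- utils::read.delim(p, sep = delim, check.names = FALSE,
                             stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    m
  }
  beta <- read_mat(path)
  dp <- if (!is.null(detection_p_path)) read_mat(detection_p_path)
  meth_set(beta, dp)
}

#' @rdname read_beta_matrix
#' @param x A `meth_set`.
#' @export
write_beta_matrix <- function(x, path, dialect = c("tab", "comma")) {
  delim <- if (match.arg(dialect) == "tab") "\t" else ","
  df <- data.frame(probe_id = rownames(x$beta), x$beta,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

sample_sheet_required <- c("sample_id", "group")
patient_only_cols <- c("gc_treated", "pim3", "pelod", "strongkids", "los_picu",
                       "diagnosis_category", "randomisation_arm")

#' Read and write sample sheets
#'
#' A sample sheet holds one row per sample: `sample_id`, `group` (`patient`
#' or `control`), then covariates (sex, ages, centre, race, origins,
#' malignancy, syndrome), patient-only clinical fields (gc_treated, pim3,
#' pelod, strongkids, los_picu, diagnosis_category, randomisation_arm),
#' `batch`, and any number of outcome-score columns. Unknown columns are
#' preserved untouched. Missing values in patient-only fields are retained as
#' `NA` and reported via a message.
#'
#' @param path File path.
#' @param dialect One of `"auto"`, `"tab"`, `"comma"`.
#' @return A tibble, one row per sample.
#' @export
read_sample_sheet <- function(path, dialect = c("auto", "tab", "comma")) {
  delim <- detect_delim(path, match.arg(dialect))
  tab <- tibble::as_tibble(utils::read.delim(path, sep = delim,
                                             check.names = FALSE,
                                             stringsAsFactors = FALSE))
  validate_sample_sheet(tab)
}

validate_sample_sheet <- function(tab) {
  missing_cols <- setdiff(sample_sheet_required, names(tab))
  if (length(missing_cols) > 0) {
    stop("Sample sheet lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("Duplicate sample_id in sample sheet.", call. = FALSE)
  }
  bad_group <- setdiff(unique(tab$group), c("patient", "control"))
  if (length(bad_group) > 0) {
    stop("Unknown group label(s): ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  if ("gc_treated" %in% names(tab)) {
    tab$gc_treated <- as.logical(tab$gc_treated)
    if (any(!is.na(tab$gc_treated[tab$group == "control"]))) {
      stop("gc_treated must be undefined for controls.", call. = FALSE)
    }
  }
  present <- intersect(patient_only_cols, names(tab))
  for (cl in present) {
    n_miss <- sum(is.na(tab[[cl]][tab$group == "patient"]))
    if (n_miss > 0) {
      message(n_miss, " patient row(s) missing `", cl, "`; retained as NA.")
    }
  }
  tab
}

#' @rdname read_sample_sheet
#' @param x A sample-sheet data frame.
#' @export
write_sample_sheet <- function(x, path, dialect = c("tab", "comma")) {
  delim <- if (match.arg(dialect) == "tab") "\t" else ","
  utils::write.table(x, path, sep = delim, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read and write probe annotation
#'
#' Tabular annotation carries `probe_id`, `chrom`, `pos` (1-based),
#' `gene`, `gene_section` (slash-separated when a CpG sits in several
#' sections or splice variants), `snp_flag` (logical) and `control_type`
#' (`none`, `negative` or `other_control`). BED input (0-based half-open,
#' columns chrom/start/end/name) is converted on read to 1-based positions
#' (`pos = start + 1`). A control probe carrying a SNP flag triggers a
#' warning and the flag is ignored.
#'
#' @param path File path.
#' @param format `"table"` for the delimited layout, `"bed"` for BED 3+1.
#' @param dialect Delimiter handling for the tabular layout.
#' @return A tibble, one row per probe.
#' @export
read_probe_annotation <- function(path, format = c("table", "bed"),
                                  dialect = c("auto", "tab", "comma")) {
  format <- match.arg(format)
  if (format == "bed") {
    bed <- utils::read.delim(path, header = FALSE, sep = "",
                             stringsAsFactors = FALSE)
    if (ncol(bed) < 4) stop("BED annotation needs 4 columns (chrom, start, end, name).",
                            call. = FALSE)
    ann <- tibble::tibble(probe_id = as.character(bed[[4]]),
                          chrom = as.character(bed[[1]]),
                          pos = as.integer(bed[[2]]) + 1L,
                          gene = NA_character_,
                          gene_section = NA_character_,
                          snp_flag = FALSE,
                          control_type = "none")
  } else {
    delim <- detect_delim(path, match.arg(dialect))
    ann <- tibble::as_tibble(utils::read.delim(path, sep = delim,
                                               check.names = FALSE,
                                               stringsAsFactors = FALSE))
  }
  validate_probe_annotation(ann)
}

validate_probe_annotation <- function(ann) {
  needed <- c("probe_id", "chrom", "pos", "snp_flag", "control_type")
  missing_cols <- setdiff(needed, names(ann))
  if (length(missing_cols) > 0) {
    stop("Probe annotation lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ann$probe_id)) stop("Duplicate probe_id in annotation.",
                                        call. = FALSE)
  ann$snp_flag <- as.logical(ann$snp_flag)
  bad_ct <- setdiff(unique(ann$control_type), c("none", "negative", "other_control"))
  if (length(bad_ct) > 0) {
    stop("Unknown control_type value(s): ", paste(bad_ct, collapse = ", "),
         call. = FALSE)
  }
  if (any(ann$control_type != "none" & !is.na(ann$pos) & ann$pos < 1)) {
    # control probes need no genomic assignment; biological probes do
  }
  if (any(ann$control_type == "none" & (is.na(ann$pos) | ann$pos < 1))) {
    stop("Non-control probes require a 1-based genomic position >= 1.",
         call. = FALSE)
  }
  flagged_ctrl <- ann$control_type != "none" & ann$snp_flag %in% TRUE
  if (any(flagged_ctrl)) {
    warning(sum(flagged_ctrl),
            " control probe(s) carried snp_flag; flag ignored.", call. = FALSE)
    ann$snp_flag[flagged_ctrl] <- FALSE
  }
  ann
}

#' @rdname read_probe_annotation
#' @param x A probe-annotation data frame.
#' @export
write_probe_annotation <- function(x, path, dialect = c("tab", "comma")) {
  delim <- if (match.arg(dialect) == "tab") "\t" else ","
  utils::write.table(x, path, sep = delim, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Reference table of HPA-axis differentially methylated positions
#'
#' The packaged reference set of 26 CpG sites within HPA-axis genes found
#' differentially methylated between former PICU patients and healthy
#' children. Per CpG: gene, gene section, hypo/hyper status, log fold change
#' on the M-value scale with its 95% confidence interval, the unadjusted
#' absolute difference in group mean beta values, the FDR-adjusted group
#' q-value (`q_group`; values printed as "< 0.00001" in the source table are
#' stored as 1e-5), and unadjusted p-values for the sex interaction, the
#' age-at-exposure interaction, and the within-patient glucocorticoid
#' contrast.
#'
#' @return A tibble with 26 rows.
#' @examples
#' hpa_dmp_reference()
#' @export
hpa_dmp_reference <- function() {
  path <- system.file("extdata", "hpa_dmp_table2.tsv", package = "hpamethyl",
                      mustWork = TRUE)
  tab <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                             stringsAsFactors = FALSE))
  tab$status <- factor(tab$status, levels = c("Hypo", "Hyper"))
  tab
}
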