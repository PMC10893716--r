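#' Table-1-style cohort comparison
#'
#' Summarises and compares two groups variable by variable: categorical
#' variables as counts (%) per group with a chi-square test (no continuity
#' correction); continuous variables as median (IQR) per group with a
#' rank-based test. The unpaired Wilcoxon rank-sum test is the default for
#' continuous variables; `paired = TRUE` forces the signed-rank test on
#' equal-size pairings.
#'
#' @param sample_table Sample sheet with a two-level `group` column.
#' @param vars Variables to compare; default: every column except
#'   identifiers and group.
#' @param paired Use the paired signed-rank test for continuous variables
#'   (groups must then have equal sizes).
#' @return A tibble: `variable`, `level` (categoricals only), one summary
#'   column per group, `p_value` (shared across a categorical variable's
#'   rows).
#' @export
cohort_compare <- function(sample_table, vars = NULL, paired = FALSE) {
  groups <- unique(sample_table$group)
  if (length(groups) != 2 || any(table(sample_table$group) == 0)) {
    stop("Exactly two nonempty comparison groups required.", call. = FALSE)
  }
  groups <- sort(groups)
  if (is.null(vars)) {
    vars <- setdiff(names(sample_table), c("sample_id", "group"))
  }
  rows <- purrr::map(vars, function(v) {
    x <- sample_table[[v]]
    g <- sample_table$group
    ok <- !is.na(x)
    x <- x[ok]; g <- g[ok]
    if (length(unique(g)) < 2) return(NULL)
    if (is.numeric(x) && dplyr::n_distinct(x) > 5) {
      p <- if (paired) {
        stats::wilcox.test(x[g == groups[1]], x[g == groups[2]],
                           paired = TRUE, exact = FALSE)$p.value
      } else {
        stats::wilcox.test(x ~ g, exact = FALSE)$p.value
      }
      smry <- vapply(groups, function(gg) {
        q <- stats::quantile(x[g == gg], c(0.25, 0.5, 0.75))
        sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
      }, character(1))
      tibble::tibble(variable = v, level = NA_character_,
                     !!groups[1] := smry[1], !!groups[2] := smry[2],
                     p_value = p)
    } else {
      tab <- table(factor(g, levels = groups), x)
      p <- tryCatch(stats::chisq.test(tab, correct = FALSE)$p.value,
                    error = function(e) NA_real_)
      purrr::map_dfr(colnames(tab), function(lv) {
        cnt <- tab[, lv]
        pct <- 100 * cnt / rowSums(tab)
        tibble::tibble(variable = v, level = lv,
                       !!groups[1] := sprintf("%d (%.1f)", cnt[1], pct[1]),
                       !!groups[2] := sprintf("%d (%.1f)", cnt[2], pct[2]),
                       p_value = p)
      })
    }
  })
  dplyr::bind_rows(rows)
}

#' Pipeline configuration
#'
#' Bundles every stage's parameters into one serialisable object. Unknown
#' section or field names are rejected so that configuration typos fail
#' loudly. `write_pipeline_config()` and `read_pipeline_config()`
#' round-trip the object through YAML.
#'
#' @param out_dir Output directory for stage TSVs and the run log.
#' @param seed Root seed for the whole run.
#' @param simulation Named list of [sim_config()] arguments.
#' @param qc List: `midband_threshold`, `detection_p`, `detection_frac`,
#'   `normalize`.
#' @param batch List: `n_pcs`.
#' @param dmp List: `fdr`, `covariates`, `gc_covariates`, `n_pcs_use`.
#' @param dmr List: `lambda`, `C`, `fdr`, `min_cpgs`.
#' @param cv List: `k_folds`, `n_iterations`, `alpha`, `covariates`,
#'   `n_pcs_use`, `max_probes`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("hpamethyl_run_"),
                            seed = 1L,
                            simulation = list(),
                            qc = list(), batch = list(), dmp = list(),
                            dmr = list(), cv = list()) {
  defaults <- list(
    qc = list(midband_threshold = 0.4, detection_p = 0.01,
              detection_frac = 0.5, normalize = TRUE),
    batch = list(n_pcs = 30L),
    dmp = list(fdr = 0.05, covariates = c("age_exposure", "sex"),
               gc_covariates = c("los_picu", "pim3"), n_pcs_use = 10L),
    dmr = list(lambda = 1000, C = 2, fdr = 0.05, min_cpgs = 2L),
    cv = list(k_folds = 10L, n_iterations = 20L, alpha = 0.05,
              covariates = "age_exposure", n_pcs_use = 2L, max_probes = 5L)
  )
  merge_section <- function(name, user) {
    extra <- setdiff(names(user), names(defaults[[name]]))
    if (length(extra) > 0) {
      stop("Unknown `", name, "` option(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
    utils::modifyList(defaults[[name]], user)
  }
  sim_ok <- names(formals(sim_config))
  extra <- setdiff(names(simulation), sim_ok)
  if (length(extra) > 0) {
    stop("Unknown `simulation` option(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulation = simulation,
                 qc = merge_section("qc", qc),
                 batch = merge_section("batch", batch),
                 dmp = merge_section("dmp", dmp),
                 dmr = merge_section("dmr", dmr),
                 cv = merge_section("cv", cv)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("out_dir", "seed", "simulation", "qc", "batch", "dmp", "dmr", "cv")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    stop("Unknown configuration section(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

write_stage_tsv <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) signif(col, 10))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

#' Run the whole analysis pipeline on a simulated cohort
#'
#' Composes every stage in order: cohort simulation, sample QC, probe
#' filtering, optional quantile normalization, control-probe PCA and
#' covariate attachment, moderated DMP models with interaction and
#' glucocorticoid contrasts, kernel-smoothed DMR detection, and repeated
#' cross-validated methylation-outcome robustness. Each stage's table is
#' written to `config$out_dir` as headered TSV together with a run log
#' recording the package version, seed and configuration hash. A stage
#' failure aborts with the stage named; tables written before the failure
#' are retained.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `qc_samples`,
#'   `qc_probes`, `control_pcs`, `dmps`, `dmp_summary`, `dmrs`,
#'   `robustness`, `cohort_table`, `paths`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("Pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  sim <- stage("simulate", {
    sim_args <- utils::modifyList(config$simulation, list(seed = config$seed))
    simulate_cohort(do.call(sim_config, sim_args))
  })

  qc_samples <- stage("sample_qc", {
    sample_qc(sim$ms, midband_threshold = config$qc$midband_threshold)
  })
  ms <- sim$ms[, qc_samples$pass]
  st <- sim$samples[sim$samples$sample_id %in% sample_ids(ms), ]
  paths["qc_samples"] <- write_stage_tsv(qc_samples, config$out_dir, "qc_samples")

  pcs <- stage("control_pcs", {
    control_probe_pcs(ms, sim$annotation, n_pcs = config$batch$n_pcs)
  })
  st <- stage("attach_pcs", attach_technical_covariates(st, pcs))
  paths["control_pcs"] <- write_stage_tsv(tidy(pcs), config$out_dir, "control_pcs")

  bio <- ms[!grepl("^ctrl", probe_ids(ms)), ]
  filt <- stage("probe_filter", {
    probe_filter(bio, sim$annotation, p_thresh = config$qc$detection_p,
                 frac = config$qc$detection_frac)
  })
  paths["qc_probes"] <- write_stage_tsv(filt$report, config$out_dir, "qc_probes")
  bio <- filt$matrix
  if (isTRUE(config$qc$normalize)) {
    bio <- stage("normalize", quantile_normalize(bio))
  }

  dmps <- stage("dmp", {
    dmp_table(bio, st, sim$annotation,
              covariates = config$dmp$covariates,
              gc_covariates = config$dmp$gc_covariates,
              fdr = config$dmp$fdr, n_pcs_use = config$dmp$n_pcs_use)
  })
  paths["dmp_table"] <- write_stage_tsv(dmps, config$out_dir, "dmp_table")
  dmp_summary <- if (nrow(dmps) > 0) {
    counts <- table(sim$annotation$gene[!is.na(sim$annotation$gene)])
    summarize_dmps(dmps, gene_totals = stats::setNames(as.integer(counts),
                                                       names(counts)))
  }

  dmrs <- stage("dmr", {
    dmr_table(attr(dmps, "fit"), sim$annotation,
              lambda = config$dmr$lambda, C = config$dmr$C,
              fdr = config$dmr$fdr, min_cpgs = config$dmr$min_cpgs)
  })
  paths["dmr_table"] <- write_stage_tsv(dmrs, config$out_dir, "dmr_table")

  robustness <- stage("outcome_association", {
    outcomes <- intersect(unique(sim$config$outcome_links$outcome), names(st))
    probes <- utils::head(dmps$probe_id, config$cv$max_probes)
    if (length(probes) == 0 || length(outcomes) == 0) {
      NULL
    } else {
      pc_cols <- utils::head(grep("^pc[0-9]+$", names(st), value = TRUE),
                             config$cv$n_pcs_use)
      covs <- c(config$cv$covariates, pc_cols)
      M <- beta_to_m(bio$beta)
      cfg <- cv_config(k_folds = config$cv$k_folds,
                       n_iterations = config$cv$n_iterations,
                       alpha = config$cv$alpha, seed = config$seed)
      res <- purrr::map_dfr(probes, function(pr) {
        purrr::map_dfr(outcomes, function(oc) {
          cv_robustness(oc, pr, M[pr, ], st, covariates = covs, config = cfg)
        })
      })
      status <- stats::setNames(as.character(dmps$status), dmps$probe_id)
      robustness_matrix(res, status = status,
                        outcome_polarity = attr(sim$samples, "outcome_polarity"),
                        alpha = config$cv$alpha)
    }
  })
  if (!is.null(robustness)) {
    paths["robustness"] <- write_stage_tsv(robustness$results, config$out_dir,
                                           "robustness")
  }

  cohort_table <- stage("cohort_compare", {
    cohort_compare(st, vars = intersect(c("sex", "age_followup", "race",
                                          "malignancy", "syndrome"),
                                        names(st)))
  })
  paths["cohort_table"] <- write_stage_tsv(cohort_table, config$out_dir,
                                           "cohort_table")

  cfg_yaml <- yaml::as.yaml(unclass(config))
  log_lines <- c(
    paste0("hpamethyl ", as.character(utils::packageVersion("hpamethyl"))),
    paste0("run at: <deterministic; see seed>"),
    paste0("seed: ", config$seed),
    paste0("config_hash: ", sum(utf8ToInt(cfg_yaml) * seq_along(utf8ToInt(cfg_yaml))) %% 2147483647),
    paste0("artifacts: ", paste(basename(paths), collapse = ", "))
  )
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  paths["log"] <- file.path(config$out_dir, "run_log.txt")

  structure(list(qc_samples = qc_samples, qc_probes = filt$report,
                 control_pcs = pcs, dmps = dmps, dmp_summary = dmp_summary,
                 dmrs = dmrs, robustness = robustness,
                 cohort_table = cohort_table, paths = paths,
                 config = config, truth = sim$truth),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  samples passing QC: ", sum(x$qc_samples$pass), "/",
      nrow(x$qc_samples), "\n", sep = "")
  cat("  probes passing filters: ", sum(x$qc_probes$pass), "/",
      nrow(x$qc_probes), "\n", sep = "")
  cat("  DMPs: ", nrow(x$dmps), "; DMRs: ", nrow(x$dmrs), "\n", sep = "")
  if (!is.null(x$robustness)) {
    cat("  robustness pairs: ", nrow(x$robustness$results),
        " (", x$robustness$n_robust, " robust)\n", sep = "")
  }
  cat("  artifacts in ", x$config$out_dir, "\n", sep = "")
  invisible(x)
}
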