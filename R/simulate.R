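#' Configuration for the synthetic cohort simulator
#'
#' Describes a two-group EPIC-like methylation cohort: former PICU patients
#' (with a glucocorticoid-treated subgroup) versus healthy children, with
#' plate/chip batch effects expressed through technical control probes,
#' covariates drawn to resemble the study population, spiked group effects
#' at designated CpGs, clustered effects forming regions, and outcome
#' scores causally linked to methylation.
#'
#' The default is a desk-scale cohort: 120 patients (a quarter
#' glucocorticoid-treated) and 60 controls, 3,000 biological probes plus
#' 300 technical control probes on 4 batches. `full_scale = TRUE` mirrors
#' the real cohort sizes (818 patients, 210 treated, 392 controls).
#'
#' @param n_patients,n_controls Group sizes.
#' @param gc_fraction Fraction of patients treated with glucocorticoids.
#' @param n_probes,n_control_probes Biological and technical probe counts.
#' @param n_batches Number of plate/chip batches.
#' @param batch_sd Batch-effect magnitude on the M scale.
#' @param batch_rank Number of latent batch factors shared between
#'   biological and control probes (default 2).
#' @param batch_confounding In \[0, 1\]: 0 (default) assigns batches
#'   independently of group; larger values skew patients toward the first
#'   half of the batches and controls toward the second half, confounding
#'   batch with the group contrast.
#' @param sigma2_prior,sigma2_prior_df Scaled inverse-chi-square prior from
#'   which per-probe residual variances (M scale) are drawn; the defaults
#'   give residual SDs near 0.5, producing confidence-interval widths like
#'   those seen in cohorts of this size.
#' @param spike_table Tibble with columns `probe` (index into the
#'   biological probes), `delta_beta` (signed target difference in group
#'   mean beta) and optionally `gene`. `NULL` gives the default panel of 26
#'   spikes whose magnitudes and signs follow the packaged DMP reference
#'   table.
#' @param region_spikes Tibble with columns `chrom`, `n_cpgs`, `span_bp`,
#'   `delta_beta`, `gene`: clusters of adjacent spiked CpGs forming true
#'   regions. `NULL` gives three regions of 4/8/12 CpGs spanning
#'   665/438/146 bp (genes AVP, TSC22D3, TNF).
#' @param outcome_links Tibble with columns `probe`, `outcome`,
#'   `coefficient`, `noise_sd`, `higher_is_better`: causal links from
#'   methylation (M value) to outcome scores. `NULL` gives a default set of
#'   developmental outcomes with a few strong links.
#' @param probe_spacing_bp Spacing in bp between consecutive non-region
#'   probes (default 600, the dense within-gene spacing typical of a
#'   targeted panel).
#' @param n_detection_fail Number of probes given failing detection
#'   p-values in most samples.
#' @param n_snp_probes Number of probes flagged as SNP-overlapping.
#' @param full_scale Use the real-cohort sample sizes.
#' @param seed Integer seed; fully determines the simulated cohort.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 120, n_controls = 60, gc_fraction = 0.25,
                       n_probes = 3000, n_control_probes = 300,
                       n_batches = 4, batch_sd = 0.3, batch_rank = 2,
                       batch_confounding = 0,
                       sigma2_prior = 0.25, sigma2_prior_df = 20,
                       spike_table = NULL, region_spikes = NULL,
                       outcome_links = NULL, probe_spacing_bp = 600,
                       n_detection_fail = 10, n_snp_probes = 10,
                       full_scale = FALSE, seed = 1L) {
  if (full_scale) {
    n_patients <- 818; n_controls <- 392; gc_fraction <- 210 / 818
  }
  if (is.null(spike_table)) spike_table <- default_spike_table(n_probes)
  if (is.null(region_spikes)) region_spikes <- default_region_spikes()
  if (is.null(outcome_links)) outcome_links <- default_outcome_links(spike_table)
  stopifnot(n_patients > 0, n_controls > 0, gc_fraction >= 0, gc_fraction <= 1,
            n_probes > 0, n_control_probes > 0, n_batches >= 1,
            batch_sd >= 0, sigma2_prior > 0,
            batch_confounding >= 0, batch_confounding <= 1,
            probe_spacing_bp > 0)
  if (nrow(spike_table) > 0) {
    if (any(abs(spike_table$delta_beta) <= 0 | abs(spike_table$delta_beta) >= 0.5)) {
      stop("Spike |delta_beta| must lie in (0, 0.5).", call. = FALSE)
    }
    if (max(spike_table$probe) > n_probes) {
      stop("spike_table refers to probe indices beyond n_probes.", call. = FALSE)
    }
  }
  n_region_cpgs <- sum(region_spikes$n_cpgs)
  if (nrow(spike_table) + n_region_cpgs > n_probes) {
    stop("More spiked probes requested than n_probes.", call. = FALSE)
  }
  structure(list(n_patients = n_patients, n_controls = n_controls,
                 gc_fraction = gc_fraction, n_probes = n_probes,
                 n_control_probes = n_control_probes, n_batches = n_batches,
                 batch_sd = batch_sd, batch_rank = batch_rank,
                 batch_confounding = batch_confounding,
                 sigma2_prior = sigma2_prior,
                 sigma2_prior_df = sigma2_prior_df,
                 spike_table = spike_table, region_spikes = region_spikes,
                 outcome_links = outcome_links,
                 probe_spacing_bp = probe_spacing_bp,
                 n_detection_fail = n_detection_fail,
                 n_snp_probes = n_snp_probes,
                 seed = as.integer(seed)),
            class = "sim_config")
}

default_spike_table <- function(n_probes) {
  ref <- hpa_dmp_reference()
  delta <- ref$abs_mean_diff * ifelse(ref$status == "Hypo", -1, 1)
  delta[abs(delta) < 0.002] <- 0.002 * sign(delta[abs(delta) < 0.002] + 1e-9)
  n <- length(delta)
  tibble::tibble(probe = floor(seq(10, max(n_probes - 60, n), length.out = n)),
                 delta_beta = delta,
                 gene = ref$gene)
}

default_region_spikes <- function() {
  tibble::tibble(chrom = c("chr20", "chrX", "chr6"),
                 n_cpgs = c(4L, 8L, 12L),
                 span_bp = c(665L, 438L, 146L),
                 delta_beta = c(-0.03, 0.03, -0.03),
                 gene = c("AVP", "TSC22D3", "TNF"))
}

default_outcome_links <- function(spike_table) {
  if (nrow(spike_table) == 0) {
    return(tibble::tibble(probe = integer(), outcome = character(),
                          coefficient = numeric(), noise_sd = numeric(),
                          higher_is_better = logical()))
  }
  pick <- spike_table$probe[order(-abs(spike_table$delta_beta))]
  pick <- utils::head(rep(pick, length.out = 6), 6)
  tibble::tibble(
    probe = pick,
    outcome = c("iq", "vmi", "weight_z", "memory", "alertness", "behaviour_problems"),
    coefficient = c(2, 2, 1.5, 1.8, 1.6, -1.8),
    noise_sd = 1,
    higher_is_better = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_patients, " patients (",
      round(x$n_patients * x$gc_fraction), " GC-treated) + ", x$n_controls,
      " controls; ", x$n_probes, " probes + ", x$n_control_probes,
      " control probes; ", x$n_batches, " batches; seed ", x$seed, "\n",
      sep = "")
  cat("  spikes: ", nrow(x$spike_table), " positions, ",
      nrow(x$region_spikes), " regions; outcome links: ",
      nrow(x$outcome_links), "\n", sep = "")
  invisible(x)
}

# Expected beta under M-scale Gaussian noise, by Gauss-Legendre-style grid.
expected_beta <- function(m0, shift, sigma) {
  z <- seq(-4.5, 4.5, length.out = 91)
  w <- stats::dnorm(z)
  w <- w / sum(w)
  sum(w * m_to_beta(m0 + shift + sigma * z))
}

# Solve for the M-scale shift whose expected beta difference equals delta.
calibrate_m_shift <- function(m0, delta, sigma) {
  base <- expected_beta(m0, 0, sigma)
  target <- base + delta
  if (target <= 1e-4 || target >= 1 - 1e-4) {
    stop("Spike delta_beta pushes expected beta outside (0, 1).", call. = FALSE)
  }
  stats::uniroot(function(e) expected_beta(m0, e, sigma) - target,
                 lower = -15, upper = 15, tol = 1e-9)$root
}

#' Simulate a two-group methylation cohort
#'
#' Draws a complete synthetic cohort under `config`: per-probe baseline M
#' values from a three-component mixture giving the characteristic bimodal
#' beta distribution (modes near 0.1 and 0.9); per-sample values are the
#' inverse-M transform of baseline + group effect (patients only) +
#' rank-`batch_rank` latent batch effect + Gaussian residual noise with
#' probe-specific variance drawn from a scaled inverse-chi-square. Spiked
#' group effects are calibrated on the M scale so the *expected* group
#' difference in mean beta equals the requested `delta_beta` (the
#' nonlinearity of the inverse-logit would otherwise shrink it). Control
#' probes carry batch effects and noise but never group effects. Detection
#' p-values are small except at designated failing probes.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort`: `ms` ([meth_set()]), `samples`
#'   (sample sheet with batch and, from [simulate_outcomes()], outcome
#'   scores), `annotation` (probe annotation), `truth` (per-probe truth
#'   tibble: `probe_id`, `effect_m`, `effect_beta`, `region_id`,
#'   `is_control`).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 20, n_controls = 10,
#'                                      n_probes = 50, n_control_probes = 10,
#'                                      spike_table = tibble::tibble(
#'                                        probe = 5, delta_beta = 0.05,
#'                                        gene = "FKBP5"),
#'                                      region_spikes = tibble::tibble(
#'                                        chrom = character(), n_cpgs = integer(),
#'                                        span_bp = integer(), delta_beta = numeric(),
#'                                        gene = character()),
#'                                      seed = 7))
#' cohort$ms
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n_pt <- cfg$n_patients; n_ct <- cfg$n_controls
  n_all <- n_pt + n_ct
  samples <- tibble::tibble(
    sample_id = c(sprintf("pt%04d", seq_len(n_pt)),
                  sprintf("ct%04d", seq_len(n_ct))),
    group = rep(c("patient", "control"), c(n_pt, n_ct))
  )
  n_gc <- round(n_pt * cfg$gc_fraction)
  gc <- rep(FALSE, n_pt); gc[sample.int(n_pt, n_gc)] <- TRUE
  samples$gc_treated <- c(gc, rep(NA, n_ct))
  samples$sex <- ifelse(stats::runif(n_all) <
                          rep(c(0.581, 0.541), c(n_pt, n_ct)), "male", "female")
  samples$age_followup <- pmin(pmax(exp(stats::rnorm(n_all, log(4.2), 0.55)),
                                    2.05), 17.9)
  samples$age_exposure <- c(samples$age_followup[seq_len(n_pt)] - 2, rep(NA, n_ct))
  samples <- impute_age_at_exposure(samples)
  samples$centre <- sample(c("Leuven", "Rotterdam"), n_all, TRUE, c(0.7, 0.3))
  samples$race <- sample(c("caucasian", "other"), n_all, TRUE, c(0.92, 0.08))
  samples$geographic_origin <- sample(c("european", "other"), n_all, TRUE,
                                      c(0.84, 0.16))
  samples$linguistic_origin <- sample(c("dutch_english", "other"), n_all, TRUE,
                                      c(0.78, 0.22))
  samples$malignancy <- c(stats::runif(n_pt) < 0.048, rep(FALSE, n_ct))
  samples$syndrome <- stats::runif(n_all) < rep(c(0.205, 0.01), c(n_pt, n_ct))
  samples$pim3 <- c(stats::rnorm(n_pt, -3.8, 1.1), rep(NA, n_ct))
  samples$pelod <- c(pmax(round(stats::rnorm(n_pt, 22, 11)), 0), rep(NA, n_ct))
  samples$strongkids <- c(sample(c("medium", "high"), n_pt, TRUE, c(0.9, 0.1)),
                          rep(NA, n_ct))
  samples$los_picu <- c(round(exp(stats::rnorm(n_pt, log(5), 0.8)), 1),
                        rep(NA, n_ct))
  samples$diagnosis_category <- c(sample(c("cardiac_surgery", "elective_surgery",
                                           "urgent_surgery", "medical"),
                                         n_pt, TRUE,
                                         c(0.445, 0.142, 0.174, 0.239)),
                                  rep(NA, n_ct))
  samples$randomisation_arm <- c(sample(c("early_pn", "late_pn"), n_pt, TRUE),
                                 rep(NA, n_ct))
  first_half <- seq_len(cfg$n_batches) <= cfg$n_batches / 2
  w_pt <- ifelse(first_half, 1 + cfg$batch_confounding,
                 1 - cfg$batch_confounding)
  w_ct <- ifelse(first_half, 1 - cfg$batch_confounding,
                 1 + cfg$batch_confounding)
  samples$batch <- c(
    sample(sprintf("batch%02d", seq_len(cfg$n_batches)), n_pt, TRUE, w_pt),
    sample(sprintf("batch%02d", seq_len(cfg$n_batches)), n_ct, TRUE, w_ct))

  # --- probes and annotation ---------------------------------------------
  n_bio <- cfg$n_probes
  n_region <- sum(cfg$region_spikes$n_cpgs)
  probe_id <- sprintf("cg%07d", seq_len(n_bio))
  ctrl_id <- sprintf("ctrl%05d", seq_len(cfg$n_control_probes))
  # region CpGs take the last n_region biological probe slots
  region_rows <- if (n_region > 0) (n_bio - n_region + 1):n_bio else integer()
  if (length(intersect(cfg$spike_table$probe, region_rows)) > 0) {
    stop("spike_table overlaps the probe slots reserved for region spikes.",
         call. = FALSE)
  }
  chrom <- rep("chr1", n_bio)
  pos <- 100000L + as.integer(cfg$probe_spacing_bp) * seq_len(n_bio)
  gene <- rep(NA_character_, n_bio)
  region_id <- rep(NA_character_, n_bio)
  at <- 1
  for (r in seq_len(nrow(cfg$region_spikes))) {
    rs <- cfg$region_spikes[r, ]
    rows <- region_rows[at:(at + rs$n_cpgs - 1)]
    at <- at + rs$n_cpgs
    chrom[rows] <- rs$chrom
    pos[rows] <- 500000L +
      as.integer(round(seq(0, rs$span_bp - 1, length.out = rs$n_cpgs)))
    gene[rows] <- rs$gene
    region_id[rows] <- paste0("region_", r)
  }
  if ("gene" %in% names(cfg$spike_table)) {
    gene[cfg$spike_table$probe] <- cfg$spike_table$gene
  }
  snp_rows <- setdiff(seq_len(n_bio),
                      c(cfg$spike_table$probe, region_rows))
  snp_rows <- utils::head(snp_rows, cfg$n_snp_probes)
  section <- ifelse(is.na(gene), NA_character_, "Body")
  annotation <- tibble::tibble(
    probe_id = c(probe_id, ctrl_id),
    chrom = c(chrom, rep(NA_character_, cfg$n_control_probes)),
    pos = c(pos, rep(NA_integer_, cfg$n_control_probes)),
    gene = c(gene, rep(NA_character_, cfg$n_control_probes)),
    gene_section = c(section, rep(NA_character_, cfg$n_control_probes)),
    snp_flag = c(seq_len(n_bio) %in% snp_rows,
                 rep(FALSE, cfg$n_control_probes)),
    control_type = c(rep("none", n_bio),
                     rep(c("negative", "other_control"),
                         c(max(1L, round(cfg$n_control_probes * 0.2)),
                           cfg$n_control_probes -
                             max(1L, round(cfg$n_control_probes * 0.2)))))
  )

  # --- baseline means and residual SDs ------------------------------------
  comp <- sample.int(3, n_bio, TRUE, prob = c(0.45, 0.45, 0.10))
  m0 <- c(stats::rnorm(n_bio, -3.17, 0.6),
          stats::rnorm(n_bio, 3.17, 0.6),
          stats::rnorm(n_bio, 0, 1))[seq_len(n_bio) + (comp - 1) * n_bio]
  sigma <- sqrt(cfg$sigma2_prior * cfg$sigma2_prior_df /
                  stats::rchisq(n_bio, cfg$sigma2_prior_df))

  # spiked probes get moderate baselines so the beta shift is realisable
  effect_beta <- rep(0, n_bio)
  if (nrow(cfg$spike_table) > 0) {
    sp <- cfg$spike_table
    m0[sp$probe] <- -sign(sp$delta_beta) *
      abs(stats::rnorm(nrow(sp), 1.8, 0.3))
    effect_beta[sp$probe] <- sp$delta_beta
  }
  at <- 1
  for (r in seq_len(nrow(cfg$region_spikes))) {
    rs <- cfg$region_spikes[r, ]
    rows <- region_rows[at:(at + rs$n_cpgs - 1)]
    at <- at + rs$n_cpgs
    m0[rows] <- -sign(rs$delta_beta) * abs(stats::rnorm(rs$n_cpgs, 1.8, 0.3))
    effect_beta[rows] <- rs$delta_beta
  }
  spiked <- which(effect_beta != 0)
  effect_m <- rep(0, n_bio)
  for (j in spiked) {
    effect_m[j] <- calibrate_m_shift(m0[j], effect_beta[j], sigma[j])
  }

  # --- batch structure -----------------------------------------------------
  u <- matrix(stats::rnorm(cfg$n_batches * cfg$batch_rank),
              cfg$n_batches, cfg$batch_rank)
  batch_idx <- match(samples$batch, sprintf("batch%02d", seq_len(cfg$n_batches)))
  load_bio <- matrix(stats::rnorm(n_bio * cfg$batch_rank,
                                  sd = cfg$batch_sd / sqrt(cfg$batch_rank)),
                     n_bio, cfg$batch_rank)
  load_ctrl <- matrix(stats::rnorm(cfg$n_control_probes * cfg$batch_rank,
                                   sd = 2 * cfg$batch_sd / sqrt(cfg$batch_rank)),
                      cfg$n_control_probes, cfg$batch_rank)

  is_pt <- samples$group == "patient"
  M <- m0 + outer(effect_m, as.numeric(is_pt)) +
    load_bio %*% t(u[batch_idx, , drop = FALSE]) +
    matrix(stats::rnorm(n_bio * n_all), n_bio, n_all) * sigma
  m0_ctrl <- stats::rnorm(cfg$n_control_probes, 0, 1)
  M_ctrl <- m0_ctrl + load_ctrl %*% t(u[batch_idx, , drop = FALSE]) +
    matrix(stats::rnorm(cfg$n_control_probes * n_all, sd = 0.2),
           cfg$n_control_probes, n_all)
  beta <- m_to_beta(rbind(M, M_ctrl))
  rownames(beta) <- c(probe_id, ctrl_id)
  colnames(beta) <- samples$sample_id

  det <- matrix(stats::runif(length(beta), 0, 0.008),
                nrow(beta), ncol(beta), dimnames = dimnames(beta))
  fail_rows <- setdiff(seq_len(n_bio), c(spiked, snp_rows))
  fail_rows <- utils::tail(utils::head(fail_rows, 200), cfg$n_detection_fail)
  for (j in fail_rows) {
    bad <- stats::runif(n_all) < 0.7
    det[j, bad] <- stats::runif(sum(bad), 0.02, 0.5)
  }
  ms <- meth_set(beta, det)

  truth <- tibble::tibble(
    probe_id = c(probe_id, ctrl_id),
    effect_m = c(effect_m, rep(0, cfg$n_control_probes)),
    effect_beta = c(effect_beta, rep(0, cfg$n_control_probes)),
    region_id = c(region_id, rep(NA_character_, cfg$n_control_probes)),
    is_control = c(rep(FALSE, n_bio), rep(TRUE, cfg$n_control_probes))
  )
  out <- list(ms = ms, samples = samples, annotation = annotation,
              truth = truth, config = cfg)
  class(out) <- "sim_cohort"
  out$samples <- simulate_outcomes(out$samples, ms, cfg$outcome_links,
                                   seed = cfg$seed + 101L)
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", sum(x$samples$group == "patient"), " patients + ",
      sum(x$samples$group == "control"), " controls; ",
      nrow(x$ms$beta), " probes (", sum(x$truth$is_control),
      " control probes); ", sum(x$truth$effect_beta != 0),
      " spiked CpGs\n", sep = "")
  invisible(x)
}

#' Attach simulated outcome scores to a sample sheet
#'
#' Each linked outcome is `sum(coefficient * M[probe, ]) + 0.2 *
#' age_exposure + N(0, noise_sd)`; outcomes named in the links but with all
#' coefficients zero are pure covariate + noise. The per-outcome
#' higher-is-better polarity is attached as the `outcome_polarity`
#' attribute (metadata only; values are unaffected).
#'
#' @param sample_table Sample sheet.
#' @param ms [meth_set()] holding the linked probes.
#' @param outcome_links Tibble as in [sim_config()].
#' @param seed Integer seed for the noise draws.
#' @return The sample sheet with one numeric column per outcome and the
#'   polarity attribute.
#' @export
simulate_outcomes <- function(sample_table, ms, outcome_links, seed = 1L) {
  if (nrow(outcome_links) == 0) return(sample_table)
  bio_ids <- rownames(ms$beta)[!grepl("^ctrl", rownames(ms$beta))]
  withr::with_seed(seed, {
    M <- beta_to_m(ms$beta)
    polarity <- logical()
    for (oc in unique(outcome_links$outcome)) {
      links <- outcome_links[outcome_links$outcome == oc, ]
      if (any(links$probe > length(bio_ids))) {
        stop("Outcome link refers to unknown probe index.", call. = FALSE)
      }
      pid <- bio_ids[links$probe]
      sig <- drop(crossprod(M[pid, sample_table$sample_id, drop = FALSE],
                            links$coefficient))
      age_term <- if ("age_exposure" %in% names(sample_table)) {
        0.2 * sample_table$age_exposure
      } else 0
      sample_table[[oc]] <- as.numeric(sig + age_term +
        stats::rnorm(nrow(sample_table), sd = links$noise_sd[1]))
      polarity[oc] <- links$higher_is_better[1]
    }
    attr(sample_table, "outcome_polarity") <- polarity
    sample_table
  })
}

#' Patient-swab QC fixture
#'
#' A deterministic 821-sample fixture emulating the patient swab set at the
#' QC stage: every sample draws its beta values from the typical bimodal
#' distribution except two designated samples with mid-heavy (uniform on
#' \[0.3, 0.7\]) distributions, and one further sample flagged as having had
#' insufficient DNA yield. Running [sample_qc()] on it therefore passes
#' exactly 818 samples.
#'
#' @param n_samples Number of patient samples (default 821).
#' @param n_probes Number of probes (default 400; the QC rule is
#'   per-sample, so probe count only affects Monte-Carlo noise).
#' @param seed Integer seed.
#' @return A [meth_set()] with attributes `insufficient_yield` (one sample
#'   id) and `non_bimodal` (two sample ids).
#' @export
make_qc_fixture <- function(n_samples = 821, n_probes = 400, seed = 2024L) {
  withr::with_seed(seed, {
    ids <- sprintf("swab%04d", seq_len(n_samples))
    flagged <- sample(ids, 3)
    beta <- matrix(0, n_probes, n_samples, dimnames = list(
      sprintf("cg%07d", seq_len(n_probes)), ids))
    for (s in seq_len(n_samples)) {
      if (ids[s] %in% flagged[2:3]) {
        beta[, s] <- stats::runif(n_probes, 0.3, 0.7)
      } else {
        comp <- stats::runif(n_probes)
        b <- ifelse(comp < 0.45, stats::rnorm(n_probes, 0.08, 0.04),
                    ifelse(comp < 0.9, stats::rnorm(n_probes, 0.92, 0.04),
                           stats::runif(n_probes)))
        beta[, s] <- pmin(pmax(b, 0.001), 0.999)
      }
    }
    ms <- meth_set(beta)
    attr(ms, "insufficient_yield") <- flagged[1]
    attr(ms, "non_bimodal") <- flagged[2:3]
    ms
  })
}
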