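# Shared builders for small simulated cohorts and spike tables.

no_spikes <- function() {
  tibble::tibble(probe = integer(), delta_beta = numeric(), gene = character())
}

no_regions <- function() {
  tibble::tibble(chrom = character(), n_cpgs = integer(), span_bp = integer(),
                 delta_beta = numeric(), gene = character())
}

no_links <- function() {
  tibble::tibble(probe = integer(), outcome = character(),
                 coefficient = numeric(), noise_sd = numeric(),
                 higher_is_better = logical())
}

# A clean cohort with no spikes and no failing/SNP probes unless overridden.
tiny_config <- function(seed, n_patients = 60, n_controls = 30,
                        n_probes = 100, n_control_probes = 40, ...) {
  sim_config(n_patients = n_patients, n_controls = n_controls,
             n_probes = n_probes, n_control_probes = n_control_probes,
             spike_table = no_spikes(), region_spikes = no_regions(),
             outcome_links = no_links(),
             n_detection_fail = 0, n_snp_probes = 0, seed = seed, ...)
}

# Sample sheet + attached control-probe PCs + biological-probe subset.
prepared_cohort <- function(cfg, n_pcs = 5) {
  sim <- simulate_cohort(cfg)
  pcs <- control_probe_pcs(sim$ms, sim$annotation, n_pcs = n_pcs)
  sim$samples <- attach_technical_covariates(sim$samples, pcs)
  sim$bio <- sim$ms[!grepl("^ctrl", probe_ids(sim$ms)), ]
  sim$pc_cols <- paste0("pc", seq_len(n_pcs))
  sim
}

# Random valid meth_set for round-trip properties.
random_meth_set <- function(seed, n_probes = 8, n_samples = 5,
                            detection = FALSE) {
  withr::with_seed(seed, {
    b <- matrix(round(stats::runif(n_probes * n_samples), 6),
                n_probes, n_samples,
                dimnames = list(sprintf("cg%03d", seq_len(n_probes)),
                                sprintf("s%02d", seq_len(n_samples))))
    d <- if (detection) {
      matrix(round(stats::runif(n_probes * n_samples, 0, 0.02), 6),
             n_probes, n_samples, dimnames = dimnames(b))
    }
    meth_set(b, d)
  })
}
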