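test_that("kernel smoothing degenerates correctly for single CpGs and tiny bandwidths", {
  one <- kernel_smooth_stats(stats = 2.5, chrom = "chr1", pos = 100L)
  expect_equal(one$smoothed, 2.5^2)
  expect_equal(one$eff_df, 1)
  # lambda -> 0+: each CpG keeps its own squared statistic
  t <- c(1, -2, 3)
  sm <- kernel_smooth_stats(t, rep("chr1", 3), c(100L, 200L, 300L),
                            lambda = 1e-3)
  expect_equal(sm$smoothed, t^2, tolerance = 1e-12)
  expect_equal(sm$eff_df, rep(1, 3), tolerance = 1e-12)
})

test_that("Gaussian weights follow the closed form at 500 bp with sigma 500", {
  t <- c(2, 1)
  sm <- kernel_smooth_stats(t, c("chr1", "chr1"), c(1000L, 1500L),
                            lambda = 1000, C = 2)
  w <- exp(-0.5)  # distance 500, sigma 500
  expect_equal(w, 0.60653, tolerance = 1e-4)
  expect_equal(sm$smoothed[1], (4 + w * 1) / (1 + w))
  expect_equal(sm$smoothed[2], (1 + w * 4) / (1 + w))
  expect_equal(sm$eff_df, rep((1 + w)^2 / (1 + w^2), 2))
  # weights never cross chromosomes
  sm2 <- kernel_smooth_stats(t, c("chr1", "chr2"), c(1000L, 1500L))
  expect_equal(sm2$smoothed, t^2)
  expect_error(kernel_smooth_stats(t, c("chr1", "chr1"), c(1000L, 1000L)),
               "Duplicate positions")
})

test_that("scaled chi-square p-values hit their closed-form identities", {
  tab <- tibble::tibble(smoothed = c(0, 4), eff_df = c(2, 1))
  out <- satterthwaite_pvals(tab)
  expect_equal(out$p[1], 1)
  # nu = 1, S = t^2: equals the two-sided normal p of t
  expect_equal(out$p[2], 2 * pnorm(-2))
})

test_that("equal-weight windows of null statistics give uniform p-values", {
  withr::with_seed(5, {
    k <- 4; n <- 20000
    s <- rowMeans(matrix(rchisq(k * n, df = 1), n, k))
    p <- satterthwaite_pvals(tibble::tibble(smoothed = s, eff_df = k))$p
    expect_gt(ks.test(p, "punif")$p.value, 0.01)
  })
})

test_that("region grouping applies the gap rule, singleton drop and direction call", {
  scored <- tibble::tibble(chrom = "chr1",
                           pos = c(100L, 600L, 5000L),
                           q = c(0.01, 0.02, 0.01),
                           effect = c(-0.2, -0.3, 0.4))
  out <- group_regions(scored, lambda = 1000)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 100L)
  expect_equal(out$end, 600L)
  expect_equal(out$width, 501L)
  expect_equal(out$n_cpgs, 2L)
  expect_equal(out$direction, "Hypo")
  expect_equal(out$min_q, 0.01)
  # mixed signs inside one run
  scored2 <- tibble::tibble(chrom = "chr1", pos = c(100L, 400L),
                            q = 0.01, effect = c(-1, 1))
  expect_equal(group_regions(scored2)$direction, "Mixed")
  # nothing significant -> empty table
  scored$q <- 0.5
  expect_equal(nrow(group_regions(scored)), 0L)
})

test_that("regions are disjoint and invariant to input row order", {
  withr::with_seed(19, {
    scored <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), 60, TRUE),
      pos = sample.int(20000, 60),
      q = runif(60, 0, 0.1),
      effect = rnorm(60))
    scored <- scored[!duplicated(scored[c("chrom", "pos")]), ]
    a <- group_regions(scored)
    b <- group_regions(scored[sample(nrow(scored)), ])
    expect_equal(a, b)
    # member CpGs belong to at most one region
    for (ch in unique(a$chrom)) {
      r <- a[a$chrom == ch, ]
      if (nrow(r) > 1) expect_true(all(r$start[-1] > r$end[-nrow(r)]))
    }
  })
})

test_that("a spiked 8-CpG region is recovered with high overlap", {
  region <- tibble::tibble(chrom = "chr2", n_cpgs = 8L, span_bp = 438L,
                           delta_beta = 0.04, gene = "TSC22D3")
  jac <- sapply(1:5, function(s) {
    cfg <- sim_config(n_patients = 120, n_controls = 60, n_probes = 300,
                      n_control_probes = 60, spike_table = no_spikes(),
                      region_spikes = region, outcome_links = no_links(),
                      n_detection_fail = 0, n_snp_probes = 0, seed = 400 + s)
    sim <- simulate_cohort(cfg)
    pcs <- control_probe_pcs(sim$ms, sim$annotation, n_pcs = 5)
    st <- attach_technical_covariates(sim$samples, pcs)
    bio <- sim$ms[!grepl("^ctrl", probe_ids(sim$ms)), ]
    fit <- empirical_bayes_moderate(fit_probewise_models(
      bio, st, design_spec("group", c("age_exposure", "sex", paste0("pc", 1:5)))))
    dmrs <- dmr_table(fit, sim$annotation)
    truth_ids <- sim$truth$probe_id[!is.na(sim$truth$region_id)]
    scored <- attr(dmrs, "scored")
    if (nrow(dmrs) == 0) return(0)
    max(sapply(seq_len(nrow(dmrs)), function(r) {
      member <- scored$probe_id[scored$chrom == dmrs$chrom[r] &
                                  scored$pos >= dmrs$start[r] &
                                  scored$pos <= dmrs$end[r]]
      length(intersect(member, truth_ids)) / length(union(member, truth_ids))
    }))
  })
  expect_true(all(jac >= 0.8))
})

test_that("null cohorts rarely produce any region", {
  n_regions <- sapply(1:8, function(s) {
    cfg <- tiny_config(500 + s, n_patients = 60, n_controls = 30,
                       n_probes = 400, n_control_probes = 40)
    sim <- simulate_cohort(cfg)
    pcs <- control_probe_pcs(sim$ms, sim$annotation, n_pcs = 5)
    st <- attach_technical_covariates(sim$samples, pcs)
    bio <- sim$ms[!grepl("^ctrl", probe_ids(sim$ms)), ]
    fit <- empirical_bayes_moderate(fit_probewise_models(
      bio, st, design_spec("group", c("age_exposure", "sex", paste0("pc", 1:5)))))
    nrow(dmr_table(fit, sim$annotation))
  })
  expect_lte(mean(n_regions), 1)
})
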