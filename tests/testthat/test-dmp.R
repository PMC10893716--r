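make_two_group_sheet <- function(n_pt, n_ct, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n_pt + n_ct)),
    group = rep(c("patient", "control"), c(n_pt, n_ct)),
    sex = sample(c("male", "female"), n_pt + n_ct, TRUE),
    age_exposure = runif(n_pt + n_ct, 0.5, 15)
  ))
}

test_that("equal group means give zero logFC and p of one", {
  st <- make_two_group_sheet(3, 3)
  y <- matrix(rep(c(1, 2, 3), 2), 1, 6,
              dimnames = list("cg1", st$sample_id))
  fit <- fit_probewise_models(y, st, design_spec("group"))
  expect_equal(fit$coef, 0, tolerance = 1e-12)
  expect_equal(fit$p, 1, tolerance = 1e-10)
})

test_that("a single-probe fit solves the normal equations", {
  st <- make_two_group_sheet(3, 3, seed = 2)
  y <- matrix(c(2.1, 1.7, 2.6, 0.4, 0.9, 0.2), 1, 6,
              dimnames = list("cg1", st$sample_id))
  fit <- fit_probewise_models(y, st, design_spec("group", "age_exposure"))
  # oracle: solve X'X beta = X'y directly
  X <- model.matrix(~ group + age_exposure,
                    transform(as.data.frame(st),
                              group = factor(group, c("control", "patient"))))
  beta_hat <- solve(t(X) %*% X, t(X) %*% as.vector(y))
  expect_equal(fit$coef, as.numeric(beta_hat["grouppatient", 1]),
               tolerance = 1e-10)
  # and matches lm() standard errors
  lmfit <- summary(lm(as.vector(y) ~ group + age_exposure,
                      transform(as.data.frame(st),
                                group = factor(group, c("control", "patient")))))
  expect_equal(fit$t, lmfit$coefficients["grouppatient", "t value"],
               tolerance = 1e-10)
})

test_that("rank-deficient designs fail with the aliased column named", {
  st <- make_two_group_sheet(4, 4)
  st$copy <- st$age_exposure  # perfectly collinear
  y <- matrix(rnorm(8), 1, 8, dimnames = list("cg1", st$sample_id))
  expect_error(fit_probewise_models(y, st,
                                    design_spec("group", c("age_exposure", "copy"))),
               "aliased.*copy")
  expect_error(fit_probewise_models(y, st[1:3, ],
                                    design_spec("group", c("age_exposure", "sex"))),
               "Fewer samples|missing matrix sample")
})

test_that("unmoderated confidence intervals cover a spiked M-scale effect", {
  withr::with_seed(55, {
    n <- 30; p <- 500; delta <- 0.4
    st <- make_two_group_sheet(15, 15, seed = 5)
    y <- matrix(rnorm(p * n, sd = 0.5), p, n,
                dimnames = list(sprintf("cg%04d", 1:p), st$sample_id))
    y[, st$group == "patient"] <- y[, st$group == "patient"] + delta
    fit <- fit_probewise_models(y, st, design_spec("group"))
    coverage <- mean(fit$ci_low <= delta & delta <= fit$ci_high)
    expect_gte(coverage, 0.93)
    # bias below 5% of the effect size
    expect_lt(abs(mean(fit$coef) - delta), 0.05 * delta)
  })
})

test_that("moderation limits behave: d0 = 0 is ordinary t, d0 = Inf full shrinkage", {
  st <- make_two_group_sheet(10, 10, seed = 6)
  y <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(sprintf("cg%03d", 1:50), st$sample_id))
  fit <- fit_probewise_models(y, st, design_spec("group"))
  m0 <- empirical_bayes_moderate(fit, prior_df = 0)
  expect_lt(max(abs(m0$t - fit$t)), 1e-10)
  minf <- empirical_bayes_moderate(fit, prior_df = Inf)
  expect_equal(unique(round(minf$s2_post, 12)), round(minf$s02, 12))
})

test_that("the variance prior is recovered from scaled inv-chi-square draws", {
  withr::with_seed(77, {
    n <- 30; p <- 5000
    s2_true <- 1 * 4 / rchisq(p, 4)   # d0 = 4, s0^2 = 1
    y <- matrix(rnorm(p * n), p, n) * sqrt(s2_true)
    dimnames(y) <- list(sprintf("cg%05d", 1:p), sprintf("s%02d", 1:n))
    st <- tibble::tibble(sample_id = colnames(y),
                         group = rep(c("patient", "control"), each = n / 2))
    fit <- empirical_bayes_moderate(fit_probewise_models(y, st, design_spec("group")))
    expect_gt(fit$d0, 3); expect_lt(fit$d0, 5)
    expect_equal(fit$s02, 1, tolerance = 0.15)
  })
})

test_that("moderated statistics agree with the limma reference implementation", {
  withr::with_seed(88, {
    n <- 24; p <- 300
    st <- make_two_group_sheet(12, 12, seed = 8)
    y <- matrix(rnorm(p * n, sd = rep(runif(p, 0.3, 1.2), n)), p, n,
                dimnames = list(sprintf("cg%04d", 1:p), st$sample_id))
    fit <- empirical_bayes_moderate(
      fit_probewise_models(y, st, design_spec("group", c("sex", "age_exposure"))))
    df <- transform(as.data.frame(st),
                    group = factor(group, c("control", "patient")),
                    sex = factor(sex))
    X <- model.matrix(~ group + sex + age_exposure, df)
    ref <- limma::eBayes(limma::lmFit(y, X))
    expect_equal(fit$d0, ref$df.prior, tolerance = 1e-6)
    expect_equal(fit$s02, ref$s2.prior, tolerance = 1e-6)
    expect_lt(max(abs(fit$t - ref$t[, "grouppatient"])), 1e-8)
    expect_lt(max(abs(fit$p - ref$p.value[, "grouppatient"])), 1e-10)
  })
})

test_that("BH adjustment matches the exhaustive step-up oracle", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      q[o[i]] <- min(1, min(m * p[o[i:m]] / (i:m)))
    }
    q
  }
  expect_equal(bh_adjust(rep(0.01, 10)), rep(0.01, 10))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  grid <- c(0.001, 0.01, 0.049, 0.05, 0.2, 0.5, 0.9, 1)
  withr::with_seed(12, {
    for (len in 1:6) {
      for (rep in 1:40) {
        p <- sample(grid, len, replace = TRUE)
        expect_equal(bh_adjust(p), bh_oracle(p))
      }
    }
  })
  # q never below p, order restored
  withr::with_seed(13, {
    p <- runif(50)
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-15))
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("interaction scan is calibrated under the null and powered under slope shifts", {
  withr::with_seed(101, {
    n_pt <- 100; n_ct <- 50; n <- n_pt + n_ct
    st <- make_two_group_sheet(n_pt, n_ct, seed = 9)
    # null: group effect but no interaction
    p_probes <- 1000
    y <- matrix(rnorm(p_probes * n, sd = 0.5), p_probes, n,
                dimnames = list(sprintf("cg%05d", 1:p_probes), st$sample_id))
    y[, st$group == "patient"] <- y[, st$group == "patient"] + 0.3
    spec <- design_spec("group", c("sex", "age_exposure"))
    null_p <- interaction_scan(y, st, spec, "age_exposure")$p_interaction
    rate <- mean(null_p < 0.05)
    expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / p_probes))
    expect_gt(ks.test(null_p, "punif")$p.value, 0.01)
    # power: slope difference 0.15 per year of age at exposure, sigma 0.5
    delta <- 0.15
    y2 <- y
    is_pt <- st$group == "patient"
    y2[, is_pt] <- sweep(y2[, is_pt], 2, delta * st$age_exposure[is_pt], `+`)
    pow_p <- interaction_scan(y2, st, spec, "age_exposure")$p_interaction
    expect_gt(mean(pow_p < 0.05), 0.8)
  })
})

test_that("interaction with a within-group-constant covariate is an error", {
  st <- make_two_group_sheet(6, 6)
  st$sex[st$group == "patient"] <- "male"
  y <- matrix(rnorm(12), 1, 12, dimnames = list("cg1", st$sample_id))
  expect_error(interaction_scan(y, st, design_spec("group", c("sex", "age_exposure")),
                                "sex"),
               "constant within")
})

test_that("the glucocorticoid contrast recovers direction and top ranking", {
  hits <- sapply(300 + 1:20, function(seed) {
    withr::with_seed(seed, {
      n_pt <- 80
      st <- tibble::tibble(sample_id = sprintf("p%03d", 1:n_pt),
                           group = "patient",
                           gc_treated = rep(c(TRUE, FALSE), c(30, 50)),
                           age_exposure = runif(n_pt, 0.5, 12),
                           los_picu = rexp(n_pt, 0.2))
      p <- 40
      y <- matrix(rnorm(p * n_pt, sd = 0.5), p, n_pt,
                  dimnames = list(sprintf("cg%03d", 1:p), st$sample_id))
      aggravated <- 1:5
      y[aggravated, st$gc_treated] <- y[aggravated, st$gc_treated] - 0.6
      res <- gc_subgroup_contrast(y, st, c("age_exposure", "los_picu"))
      top5 <- res$probe_id[order(res$p_gc)][1:5]
      sign_ok <- all(res$coef_gc[aggravated] < 0)
      setequal(top5, sprintf("cg%03d", aggravated)) && sign_ok
    })
  })
  expect_gte(mean(hits), 0.9)
})

test_that("permuted glucocorticoid labels give nominal rejection rates", {
  withr::with_seed(202, {
    n_pt <- 60; p <- 800
    st <- tibble::tibble(sample_id = sprintf("p%03d", 1:n_pt),
                         group = "patient",
                         gc_treated = sample(rep(c(TRUE, FALSE), c(20, 40))),
                         age_exposure = runif(n_pt, 0.5, 12))
    y <- matrix(rnorm(p * n_pt, sd = 0.5), p, n_pt,
                dimnames = list(sprintf("cg%04d", 1:p), st$sample_id))
    res <- gc_subgroup_contrast(y, st, "age_exposure")
    rate <- mean(res$p_gc < 0.05)
    expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / p))
  })
  st_all <- tibble::tibble(sample_id = c("a", "b"), group = "patient",
                           gc_treated = c(TRUE, TRUE))
  y <- matrix(c(0.5, 0.6), 1, 2, dimnames = list("cg1", c("a", "b")))
  expect_error(gc_subgroup_contrast(y, st_all, character()), "all-GC or no-GC")
})

test_that("absolute mean beta differences are plain arithmetic and symmetric", {
  b <- rbind(cg1 = c(0.50, 0.50, 0.52, 0.52),
             cg2 = c(0.30, 0.40, 0.30, 0.40))
  colnames(b) <- c("p1", "p2", "c1", "c2")
  g <- c("patient", "patient", "control", "control")
  d <- abs_mean_beta_diff(b, g)
  expect_equal(unname(d), c(0.02, 0))
  # invariant under sample reordering
  o <- c(3, 1, 4, 2)
  expect_equal(abs_mean_beta_diff(b[, o], g[o]), d)
  expect_error(abs_mean_beta_diff(b, rep("patient", 4)), "nonempty")
})

test_that("the reference DMP table summarises to the published headline numbers", {
  s <- summarize_dmps(hpa_dmp_reference())
  expect_equal(s$stats$n_dmps, 26L)
  expect_equal(s$stats$mean_abs_diff_pct, 2.2)
  expect_equal(s$stats$sd_abs_diff_pct, 1.5)
  expect_equal(s$stats$max_abs_diff_pct, 5.5)
  expect_equal(s$stats$pct_hypo, 76.9)
  expect_equal(s$stats$n_genes, 11L)
  fk <- s$per_gene[s$per_gene$gene == "FKBP5", ]
  expect_equal(fk$n_dmps, 7L)
  expect_equal(fk$pct_of_selected, 13.7)
  expect_equal(s$stats$n_age_interaction, 4L)
  expect_equal(s$stats$n_sex_interaction, 0L)
  expect_equal(s$stats$n_gc, 5L)
})

test_that("a one-row effect table reports an undefined SD", {
  one <- tibble::tibble(gene = "FKBP5", status = factor("Hypo", c("Hypo", "Hyper")),
                        abs_mean_diff = 0)
  s <- summarize_dmps(one)
  expect_equal(s$stats$mean_abs_diff_pct, 0)
  expect_true(is.na(s$stats$sd_abs_diff_pct))
  expect_error(summarize_dmps(one[0, ]), "Empty")
})
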