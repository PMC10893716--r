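patient_sheet <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    sample_id = sprintf("p%03d", seq_len(n)),
    group = "patient",
    age_exposure = runif(n, 0.5, 12),
    sex = sample(c("male", "female"), n, TRUE)
  ))
}

test_that("a noiseless linear outcome is recovered exactly", {
  st <- patient_sheet(40)
  m <- setNames(rnorm(40, 0, 0.8), st$sample_id)
  st$score <- 2 * m + 0.5 * st$age_exposure
  suppressWarnings({
    fit <- fit_outcome_model("score", m, st, covariates = "age_exposure")
  })
  expect_equal(fit$coefficient, 2, tolerance = 1e-8)
  expect_lt(fit$p, 1e-12)
  expect_equal(fit$n, 40L)
  st$flat <- 1
  expect_error(fit_outcome_model("flat", m, st, "age_exposure"), "constant")
})

test_that("permuting methylation against the outcome gives uniform p-values", {
  withr::with_seed(61, {
    st <- patient_sheet(80, seed = 3)
    st$score <- rnorm(80)
    p <- replicate(1000, {
      m <- setNames(rnorm(80), st$sample_id)
      fit_outcome_model("score", m, st, "age_exposure")$p
    })
    expect_gt(ks.test(p, "punif")$p.value, 0.01)
  })
})

test_that("outcome-model coefficients cover the simulated link", {
  withr::with_seed(62, {
    beta_true <- 1.2
    covered <- replicate(500, {
      st <- tibble::tibble(sample_id = sprintf("p%02d", 1:25),
                          group = "patient")
      m <- setNames(rnorm(25, 0, 0.8), st$sample_id)
      st$score <- beta_true * m + rnorm(25)
      fit <- fit_outcome_model("score", m, st)
      # back out the standard error from the two-sided p (df = n - 2)
      se <- abs(fit$coefficient) / qt(1 - fit$p / 2, fit$n - 2)
      crit <- qt(0.975, fit$n - 2)
      fit$coefficient - crit * se <= beta_true &&
        beta_true <= fit$coefficient + crit * se
    })
    expect_gte(mean(covered), 0.93)
  })
})

test_that("Fisher combination follows its chi-square closed form", {
  one <- fisher_combine(rep(1, 10))
  expect_equal(one$statistic, 0)
  expect_equal(one$p_combined, 1)
  expect_equal(fisher_combine(0.037)$p_combined, 0.037)  # k = 1 identity
  ten <- fisher_combine(rep(0.5, 10))
  expect_equal(ten$statistic, 20 * log(2), tolerance = 1e-12)
  expect_equal(ten$statistic, 13.8629, tolerance = 1e-4)
  expect_equal(ten$df, 20)
  expect_equal(ten$p_combined, pchisq(20 * log(2), 20, lower.tail = FALSE))
  expect_message(z <- fisher_combine(c(0, 0.5)), "clipped")
  expect_gt(z$statistic, 0)
  expect_error(fisher_combine(c(0.5, 1.4)), "\\[0, 1\\]")
})

test_that("Fisher combination matches a Monte-Carlo uniform oracle", {
  withr::with_seed(63, {
    k <- 10; n <- 4000
    u <- matrix(runif(k * n), n, k)
    combined <- apply(u, 1, function(p) fisher_combine(p)$p_combined)
    # under the null the combined p is itself uniform
    for (thr in c(0.05, 0.2, 0.5)) {
      expect_lt(abs(mean(combined <= thr) - thr), 0.02)
    }
  })
})

test_that("cross-validated robustness is deterministic and saturates on pure signal", {
  st <- patient_sheet(60, seed = 5)
  m <- setNames(rnorm(60, 0, 0.8), st$sample_id)
  st$score <- 1.5 * m + 0.3 * st$age_exposure
  cfg <- cv_config(n_iterations = 10, seed = 77)
  suppressWarnings({
    a <- cv_robustness("score", "cgX", m, st, "age_exposure", cfg)
    b <- cv_robustness("score", "cgX", m, st, "age_exposure", cfg)
  })
  expect_identical(a, b)
  expect_equal(a$pct_iterations_significant, 100)
  expect_true(a$robust)
  expect_equal(a$mean_coefficient, 1.5, tolerance = 1e-6)
  # saturation is stable across root seeds for the zero-noise case
  suppressWarnings({
    pcts <- sapply(1:5, function(s) {
      cv_robustness("score", "cgX", m, st, "age_exposure",
                    cv_config(n_iterations = 5, seed = s))$pct_iterations_significant
    })
  })
  expect_true(all(pcts == 100))
})

test_that("both fold p-value modes run and agree on strong signal", {
  withr::with_seed(91, {
    st <- patient_sheet(80, seed = 6)
    m <- setNames(rnorm(80, 0, 0.8), st$sample_id)
    st$score <- 1.5 * m + rnorm(80, sd = 0.5)
    refit <- cv_robustness("score", "cgX", m, st, "age_exposure",
                           cv_config(n_iterations = 5, seed = 2))
    pred <- cv_robustness("score", "cgX", m, st, "age_exposure",
                          cv_config(n_iterations = 5, seed = 2,
                                    fold_p_mode = "train_test_predict"))
    expect_equal(refit$pct_iterations_significant, 100)
    expect_equal(pred$pct_iterations_significant, 100)
  })
})

test_that("fold sizes smaller than the parameter count are refused", {
  st <- patient_sheet(25, seed = 7)
  m <- setNames(rnorm(25), st$sample_id)
  st$score <- rnorm(25)
  expect_error(cv_robustness("score", "cgX", m, st,
                             c("age_exposure", "sex"),
                             cv_config(k_folds = 10, seed = 1)),
               "reduce covariates")
})

test_that("benefit/harm labels follow the abnormality-direction truth table", {
  cases <- expand.grid(abn = c("Hypo", "Hyper"), coef = c(1, -1),
                       better = c(TRUE, FALSE), stringsAsFactors = FALSE)
  # independent enumeration: predicted shift in the patients' abnormal
  # direction is -coef for Hypo, +coef for Hyper; B iff shift helps
  expected <- with(cases, {
    shift <- ifelse(abn == "Hypo", -coef, coef)
    ifelse((shift > 0) == better, "B", "H")
  })
  got <- label_direction(cases$coef, rep(0.01, 8), cases$abn, cases$better)
  expect_equal(got, expected)
  # spec case: Hypo, +1, higher is better -> harm
  expect_equal(label_direction(1, 0.01, "Hypo", TRUE), "H")
  # polarity flip exchanges B and H, never none
  flipped <- label_direction(cases$coef, rep(0.01, 8), cases$abn, !cases$better)
  expect_equal(flipped, ifelse(expected == "B", "H", "B"))
  # non-significant pairs are unlabelled regardless of signs
  expect_equal(label_direction(c(1, -1), c(0.2, 0.9), c("Hypo", "Hyper"),
                               c(TRUE, FALSE)),
               c("none", "none"))
  expect_warning(out <- label_direction(0, 0.01, "Hypo", TRUE), "Zero")
  expect_equal(out, "none")
})

test_that("the robustness matrix is canonically ordered and counts pairs", {
  res <- tibble::tibble(
    probe_id = c("cg2", "cg1", "cg2", "cg1"),
    outcome = c("iq", "iq", "weight", "weight"),
    mean_coefficient = c(1, -1, 0.5, 0.2),
    full_data_p = c(0.01, 0.2, 0.03, 0.04),
    pct_iterations_significant = c(100, 10, 80, 100),
    robust = c(TRUE, FALSE, FALSE, TRUE), n = 50L)
  status <- c(cg1 = "Hypo", cg2 = "Hyper")
  pol <- c(iq = TRUE, weight = TRUE)
  rm1 <- robustness_matrix(res, status, pol)
  rm2 <- robustness_matrix(res[sample(4), ], status, pol)
  expect_equal(rm1$results, rm2$results)
  expect_equal(rm1$n_significant, 3L)
  expect_equal(rm1$n_robust, 2L)
  expect_equal(rm1$pct_robust_of_significant, 66.7)
  expect_equal(dim(rm1$matrix), c(2L, 2L))
  expect_equal(rm1$matrix["cg2", "iq"], 100)
  expect_equal(rm1$results$label[rm1$results$probe_id == "cg2" &
                                   rm1$results$outcome == "iq"], "B")
  expect_error(robustness_matrix(dplyr::bind_rows(res, res[1, ])),
               "Duplicate")
})

test_that("strong designated links are exactly the robust pairs", {
  hits <- sapply(1:5, function(s) {
    withr::with_seed(700 + s, {
      st <- patient_sheet(70, seed = 700 + s)
      M <- matrix(rnorm(4 * 70, 0, 0.8), 4, 70,
                  dimnames = list(paste0("cg", 1:4), st$sample_id))
      st$iq <- 2 * M[1, ] + rnorm(70, sd = 0.8)
      st$weight <- rnorm(70)
      cfg <- cv_config(n_iterations = 10, seed = s)
      res <- purrr::map_dfr(rownames(M), function(pr) {
        purrr::map_dfr(c("iq", "weight"), function(oc) {
          cv_robustness(oc, pr, M[pr, ], st, "age_exposure", cfg)
        })
      })
      rob <- res[res$pct_iterations_significant == 100 & res$full_data_p <= 0.05, ]
      nrow(rob) == 1 && rob$probe_id == "cg1" && rob$outcome == "iq"
    })
  })
  expect_gte(mean(hits), 0.8)
})
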