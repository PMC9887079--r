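# ROC/AUC, Kruskal-Wallis, operating point, normality check and the
# cohort-level discrimination.

test_that("AUC: perfect separation, no information, and pair-count identity", {
  expect_equal(rank_auc(c(2, 3), c(0, 1))$auc, 1)
  expect_equal(rank_auc(c(0, 1, 1, 2), c(0, 1, 1, 2))$auc, 0.5)
  set.seed(31)
  for (i in 1:25) {
    pos <- round(rnorm(15, 1), 1) # rounding forces ties
    neg <- round(rnorm(15, 0), 1)
    expect_equal(rank_auc(pos, neg)$auc, auc_pair_oracle(pos, neg),
                 tolerance = 1e-12)
    # complement identity and invariance under increasing transforms
    expect_equal(rank_auc(pos, neg)$auc + rank_auc(neg, pos)$auc, 1,
                 tolerance = 1e-12)
    expect_equal(rank_auc(exp(pos), exp(neg))$auc, rank_auc(pos, neg)$auc,
                 tolerance = 1e-12)
  }
  expect_error(rank_auc(numeric(0), 1), "non-empty")
  expect_error(rank_auc(c(1, NA), c(0)), "finite")
})

test_that("ROC runs from (0,0) to (1,1) and is monotone in both rates", {
  set.seed(32)
  roc <- rank_auc(rnorm(20, 1), rnorm(25))$roc
  expect_equal(unlist(roc[1, c("tpr", "fpr")]), c(tpr = 0, fpr = 0))
  expect_equal(unlist(roc[nrow(roc), c("tpr", "fpr")]), c(tpr = 1, fpr = 1))
  expect_true(all(diff(roc$tpr) >= 0) && all(diff(roc$fpr) >= 0))
})

test_that("Kruskal-Wallis: degenerate input, tiny exact case, permutation oracle", {
  expect_identical(kruskal_wallis(list(c(2, 2), c(2, 2))),
                   list(statistic = 0, p_value = 1))
  # fully separated 3+3: both routes computed exactly. The chi-squared
  # approximation (the implementation's documented p) and the exhaustive
  # permutation p over all C(6,3) = 20 assignments differ markedly at this
  # size — both are pinned here.
  k <- kruskal_wallis(list(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(k$statistic, 3.857142857, tolerance = 1e-8)
  expect_equal(k$p_value, 0.04953461, tolerance = 1e-6)
  expect_equal(kw_perm_oracle(c(1, 2, 3), c(10, 11, 12)), 0.1)
  # at n = 8 + 8 with a moderate shift the approximation agrees with the
  # exhaustive permutation oracle
  set.seed(4)
  x <- round(rnorm(8, 0, 1), 2); y <- round(rnorm(8, 0.7, 1), 2)
  k2 <- kruskal_wallis(list(x, y))
  expect_equal(k2$p_value, kw_perm_oracle(x, y), tolerance = 0.1)
})

test_that("two-group Kruskal-Wallis matches the Mann-Whitney normal approximation", {
  set.seed(34)
  for (i in 1:100) {
    x <- rnorm(sample(5:30, 1), 0, 1)
    y <- rnorm(sample(5:30, 1), runif(1, 0, 1), 1)
    kw_p <- kruskal_wallis(list(x, y))$p_value
    mw_p <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
    expect_equal(kw_p, mw_p, tolerance = 5e-4)
  }
})

test_that("operating point maximises Youden's J with stated tie-breaks", {
  # perfect separation: sensitivity = specificity = 1
  op <- optimal_operating_point(rank_auc(c(2, 3), c(0, 1))$roc)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  # interleaved scores carry no signal: J at the optimum is O(1/n)
  n <- 50
  pos <- seq(1, 2 * n, by = 2); neg <- seq(2, 2 * n, by = 2)
  op2 <- optimal_operating_point(rank_auc(pos, neg)$roc)
  expect_lte(op2$sensitivity + op2$specificity - 1, 2 / n + 1e-12)
  # 10-score toy case: optimum matches exhaustive threshold enumeration
  set.seed(35)
  pos <- round(rnorm(5, 0.8), 2); neg <- round(rnorm(5), 2)
  rc <- rank_auc(pos, neg)
  op3 <- optimal_operating_point(rc$roc)
  js <- sapply(c(Inf, sort(unique(c(pos, neg)))), function(th)
    mean(pos >= th) + mean(neg < th) - 1)
  expect_equal(op3$sensitivity + op3$specificity - 1, max(js),
               tolerance = 1e-12)
})

test_that("normality check rejects exponential data and is conservative under the null", {
  set.seed(36)
  expect_lt(normality_check(rexp(1000)), 0.01)
  expect_warning(p0 <- normality_check(rep(3, 10)), "degenerate")
  expect_identical(p0, 0)
  expect_error(normality_check(c(1, 2)), "at least 5")
  # with estimated mean/SD the KS p is biased toward 1 under the null, so
  # false rejections at 0.05 are rare
  ps <- replicate(200, normality_check(rnorm(50)))
  expect_lte(mean(ps < 0.05), 0.05)
})

test_that("discrimination on a separated cohort is perfect and significant", {
  set.seed(37)
  cfg <- cohort_config(n_pd = 8, n_rn = 8, beta_pd_mean = 0, beta_rn_mean = 4,
                       beta_pd_sd = 0.2, beta_rn_sd = 0.2, noise_bound = 0)
  ft <- fit_cohort(generate_cohort(cfg, seed = 3))
  res <- run_discrimination(ft)
  expect_equal(res$auc, 1)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$operating_point$sensitivity, 1)
  expect_equal(res$operating_point$specificity, 1)
})

test_that("label permutation centres the AUC on one half", {
  ft <- fit_cohort(generate_cohort(cohort_config(n_pd = 20, n_rn = 15), seed = 4))
  set.seed(38)
  aucs <- replicate(200, {
    ft$label <- sample(ft$label)
    run_discrimination(ft)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("strata filter correctly and empty/single-class strata are named errors", {
  cohort <- generate_cohort(cohort_config(n_pd = 25, n_rn = 20), seed = 5)
  ft <- fit_cohort(cohort)
  res <- run_discrimination(ft, stratum = "SRS", n_comparisons = 3)
  expect_identical(res$n_pd + res$n_rn,
                   sum(ft$subgroup == "SRS" & ft$status == "converged"))
  expect_equal(res$p_adjusted, min(1, res$p_value * 3))
  ft$upfront_wbrt <- FALSE
  expect_error(run_discrimination(ft, stratum = "WBRT"), "WBRT")
  ft2 <- ft[ft$label == "PD", ]
  expect_error(run_discrimination(ft2, stratum = "all"), "single outcome class")
  expect_error(run_discrimination(ft, robust_only = TRUE), "add_robustness")
})

test_that("the default calibrated cohort separates the groups as expected", {
  ft <- fit_cohort(generate_cohort(cohort_config(), seed = 0))
  res <- run_discrimination(ft)
  expect_gt(res$beta_summary_rn["mean"], res$beta_summary_pd["mean"])
  expect_lt(res$p_value, 0.001)
  # both growth-rate comparisons are exposed so the ordering reversal
  # between lambda1 and lambda2 is inspectable
  expect_identical(res$lambda_summary$group, c("PD", "RN"))
  expect_true(all(is.finite(unlist(res$lambda_summary[, -1]))))
})
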