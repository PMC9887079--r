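# Cohort-level statistics: nonparametric group comparison of exponents,
# ROC/AUC classification of RN vs PD, operating-point selection, and the
# stratified (subgroup) analyses.

#' Empirical ROC curve and AUC
#'
#' Builds the empirical receiver operating characteristic over all distinct
#' score thresholds (classification rule: score >= threshold is called
#' positive) and integrates it by the trapezoidal rule. Radiation necrosis
#' is the positive class and the growth exponent the score, so higher
#' scores mean "more RN-like". With trapezoidal integration ties contribute
#' one half, making the AUC identical to the Mann-Whitney concordance
#' probability.
#'
#' @param scores_positive Scores of the positive group (RN); non-empty,
#'   finite.
#' @param scores_negative Scores of the negative group (PD); non-empty,
#'   finite.
#' @return List with `auc` and `roc`, a data.frame of `threshold`,
#'   `tpr`, `fpr` ordered from (0, 0) to (1, 1) (the first row has
#'   threshold `Inf`: call everything negative).
#' @examples
#' rank_auc(c(2, 3), c(0, 1))$auc # perfect separation: 1
#' @export
rank_auc <- function(scores_positive, scores_negative) {
  if (length(scores_positive) == 0L || length(scores_negative) == 0L)
    stop("both score groups must be non-empty", call. = FALSE)
  if (any(!is.finite(c(scores_positive, scores_negative))))
    stop("scores must be finite", call. = FALSE)
  thr <- sort(unique(c(scores_positive, scores_negative)), decreasing = TRUE)
  tpr <- vapply(thr, function(k) mean(scores_positive >= k), numeric(1))
  fpr <- vapply(thr, function(k) mean(scores_negative >= k), numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr))
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  list(auc = auc, roc = roc)
}

#' ROC operating point by Youden's J
#'
#' Selects the threshold maximising Youden's J = sensitivity +
#' specificity - 1 on an empirical ROC, breaking ties toward higher
#' sensitivity and then toward the lower threshold.
#'
#' @param roc ROC data.frame as returned by [rank_auc()] (columns
#'   `threshold`, `tpr`, `fpr`).
#' @return List with `threshold`, `sensitivity`, `specificity`.
#' @export
optimal_operating_point <- function(roc) {
  stopifnot(is.data.frame(roc), all(c("threshold", "tpr", "fpr") %in% names(roc)))
  j <- roc$tpr - roc$fpr
  best <- which(j > max(j) - 1e-12)
  best <- best[order(-roc$tpr[best], roc$threshold[best])][1]
  list(threshold = roc$threshold[best],
       sensitivity = roc$tpr[best],
       specificity = 1 - roc$fpr[best])
}

#' Kruskal-Wallis comparison of groups
#'
#' Rank-based H test (with tie correction, chi-squared approximation for
#' the p-value) that the groups share a distribution; the nonparametric
#' route used because growth exponents are far from normal. For exactly
#' two groups the test is equivalent to the two-sided Mann-Whitney test.
#' When every value in every group is identical the statistic is 0 and
#' p = 1.
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return List with `statistic` and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L ||
      any(lengths(groups) == 0L))
    stop("'groups' must be a list of >= 2 non-empty numeric vectors",
         call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, p_value = 1))
  k <- stats::kruskal.test(values,
                           factor(rep(seq_along(groups), lengths(groups))))
  list(statistic = unname(k$statistic), p_value = k$p.value)
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' KS test of the values against a normal with the sample mean and SD;
#' used to justify the nonparametric analysis path, never to gate it.
#' Because the reference parameters are estimated from the same sample,
#' the p-value is conservative (biased toward 1) under the null.
#'
#' @param values At least 5 numeric values.
#' @return The KS p-value; 0 (with a warning) for zero-variance input.
#' @export
normality_check <- function(values) {
  if (length(values) < 5L)
    stop("normality check needs at least 5 values", call. = FALSE)
  if (stats::sd(values) == 0) {
    warning("degenerate input: zero variance, returning p = 0")
    return(0)
  }
  suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values))$p.value
  )
}

#' Discriminate radiation necrosis from progression in a fitted cohort
#'
#' Runs the cohort-level discrimination on a per-lesion fit table (from
#' [fit_cohort()], optionally augmented by [add_robustness()]): filters to
#' the requested treatment stratum and, optionally, to robust lesions only;
#' compares the growth exponents of the PD and RN groups by Kruskal-Wallis;
#' classifies by the exponent (positive class RN, higher beta more
#' RN-like) with empirical ROC, trapezoidal AUC and a Youden operating
#' point; and summarises both two-point growth rates per group so their
#' (possibly opposite) orderings are inspectable.
#'
#' @param fit_table Per-lesion data.frame from [fit_cohort()]; every row
#'   used must carry label `"PD"` or `"RN"`.
#' @param stratum `"all"`, `"WBRT"` (upfront whole-brain radiotherapy),
#'   `"SRS"` (single-session) or `"FSRT"` (fractionated).
#' @param robust_only If `TRUE`, keep only lesions whose exponent passed
#'   the robustness screen (requires [add_robustness()] columns).
#' @param robust_summary Which robustness verdict to filter on, `"mean"`
#'   or `"median"`.
#' @param n_comparisons Number of strata analysed in the same run;
#'   Bonferroni multiplier for `p_adjusted` (raw p is always reported).
#'
#' @return An object of class `"cohort_result"`: counts, per-group beta
#'   summaries (mean/median/IQR), `kw_statistic`, `p_value`, `p_adjusted`,
#'   `roc`, `auc`, `operating_point`, per-group `lambda_summary` and the
#'   `subgroup_tag`.
#' @export
run_discrimination <- function(fit_table,
                               stratum = c("all", "WBRT", "SRS", "FSRT"),
                               robust_only = FALSE,
                               robust_summary = c("mean", "median"),
                               n_comparisons = 1) {
  stratum <- match.arg(stratum)
  robust_summary <- match.arg(robust_summary)
  stopifnot(is.data.frame(fit_table))
  d <- fit_table[fit_table$eligible & fit_table$status == "converged", ,
                 drop = FALSE]
  d <- switch(stratum,
    all  = d,
    WBRT = d[!is.na(d$upfront_wbrt) & d$upfront_wbrt, , drop = FALSE],
    SRS  = d[!is.na(d$subgroup) & d$subgroup == "SRS", , drop = FALSE],
    FSRT = d[!is.na(d$subgroup) & d$subgroup == "FSRT", , drop = FALSE])
  if (robust_only) {
    col <- paste0("robust_by_", robust_summary)
    if (!col %in% names(d))
      stop("robust_only = TRUE requires add_robustness() columns",
           call. = FALSE)
    d <- d[!is.na(d[[col]]) & d[[col]], , drop = FALSE]
  }
  if (nrow(d) == 0L)
    stop("stratum '", stratum, "' is empty after filtering", call. = FALSE)
  if (any(!d$label %in% c("PD", "RN")))
    stop("every lesion must be labelled PD or RN", call. = FALSE)
  beta_pd <- d$beta[d$label == "PD"]
  beta_rn <- d$beta[d$label == "RN"]
  if (length(beta_pd) == 0L || length(beta_rn) == 0L)
    stop("stratum '", stratum, "' has a single outcome class", call. = FALSE)

  kw <- kruskal_wallis(list(beta_pd, beta_rn))
  rc <- rank_auc(beta_rn, beta_pd)
  summarise <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    c(mean = mean(x), median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1])
  }
  lam <- function(lab, which)
    mean(d[[which]][d$label == lab])
  structure(list(
    n_pd = length(beta_pd), n_rn = length(beta_rn),
    beta_summary_pd = summarise(beta_pd),
    beta_summary_rn = summarise(beta_rn),
    kw_statistic = kw$statistic,
    p_value = kw$p_value,
    p_adjusted = min(1, kw$p_value * n_comparisons),
    roc = rc$roc, auc = rc$auc,
    operating_point = optimal_operating_point(rc$roc),
    lambda_summary = data.frame(
      group = c("PD", "RN"),
      mean_lambda1 = c(lam("PD", "lambda1"), lam("RN", "lambda1")),
      mean_lambda2 = c(lam("PD", "lambda2"), lam("RN", "lambda2"))),
    subgroup_tag = stratum,
    robust_only = robust_only),
    class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("Discrimination of RN vs PD by growth exponent — stratum %s%s\n",
              x$subgroup_tag, if (x$robust_only) " (robust lesions only)" else ""))
  cat(sprintf("  n: %d PD, %d RN\n", x$n_pd, x$n_rn))
  cat(sprintf("  mean beta: PD %.3g, RN %.3g\n",
              x$beta_summary_pd["mean"], x$beta_summary_rn["mean"]))
  cat(sprintf("  Kruskal-Wallis H = %.3g, p = %.3g (adjusted %.3g)\n",
              x$kw_statistic, x$p_value, x$p_adjusted))
  op <- x$operating_point
  cat(sprintf("  AUC = %.3f; at beta >= %.3g: sensitivity %.3f, specificity %.3f\n",
              x$auc, op$threshold, op$sensitivity, op$specificity))
  ls <- x$lambda_summary
  cat(sprintf("  mean lambda1: PD %.3g vs RN %.3g; mean lambda2: PD %.3g vs RN %.3g\n",
              ls$mean_lambda1[1], ls$mean_lambda1[2],
              ls$mean_lambda2[1], ls$mean_lambda2[2]))
  invisible(x)
}
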