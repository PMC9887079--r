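# Per-lesion fitting across a cohort: the table every downstream stage
# (robustness screen, discrimination, pipeline artifacts) operates on.

#' Fit the growth exponent across a cohort
#'
#' Applies [fit_vb_exponent()] and [growth_rates()] to every lesion in a
#' cohort and returns one row per lesion. Lesions failing the inclusion
#' criterion (three increasing volumes) are kept with `eligible = FALSE`
#' and `NA` estimates rather than dropped, mirroring the screening of a
#' scan database down to eligible lesions.
#'
#' @param lesions List of [lesion_series()] (synthetic lesions from
#'   [generate_cohort()] are accepted too; their `$series` is used).
#' @param beta_bracket,tol Passed to [fit_vb_exponent()].
#' @return data.frame with columns `lesion_id`, `patient_id`, `label`,
#'   `subgroup`, `upfront_wbrt`, `eligible`, `status`, `beta`, `alpha`,
#'   `v0`, `lambda1`, `lambda2`.
#' @export
fit_cohort <- function(lesions, beta_bracket = c(-5, 10), tol = 1e-10) {
  lesions <- lapply(lesions, function(x)
    if (inherits(x, "synthetic_lesion")) x$series else x)
  stopifnot(all(vapply(lesions, inherits, logical(1), "lesion_series")))
  rows <- lapply(lesions, function(s) {
    out <- data.frame(lesion_id = s$lesion_id, patient_id = s$patient_id,
                      label = s$label, subgroup = s$subgroup,
                      upfront_wbrt = s$upfront_wbrt,
                      eligible = is_fittable(s), status = "ineligible",
                      beta = NA_real_, alpha = NA_real_, v0 = NA_real_,
                      lambda1 = NA_real_, lambda2 = NA_real_,
                      stringsAsFactors = FALSE)
    if (out$eligible) {
      f <- fit_vb_exponent(s, beta_bracket = beta_bracket, tol = tol)
      out$status <- f$status
      if (f$status == "converged") {
        out$beta <- f$params$beta
        out$alpha <- f$params$alpha
        out$v0 <- f$params$v0
        gr <- growth_rates(s)
        out$lambda1 <- gr$lambda1
        out$lambda2 <- gr$lambda2
      }
    }
    out
  })
  do.call(rbind, rows)
}

#' Robustness screen across a fitted cohort
#'
#' Runs [assess_robustness()] on every eligible, converged lesion and adds
#' the perturbed-exponent summaries and robust/non-robust verdicts as
#' columns of the fit table. Per-lesion seeds are derived deterministically
#' from `seed` and the lesion's position, so results are reproducible and
#' independent of evaluation order.
#'
#' @param fit_table data.frame from [fit_cohort()].
#' @param lesions The same cohort the table was fitted from.
#' @param n_reps,noise_bound,threshold Passed to [assess_robustness()].
#' @param seed Integer master seed.
#' @return `fit_table` with added columns `beta_perturbed_mean`,
#'   `beta_perturbed_median`, `n_successful`, `robust_by_mean`,
#'   `robust_by_median`.
#' @export
add_robustness <- function(fit_table, lesions, n_reps = 200,
                           noise_bound = 0.05, threshold = 0.5, seed = 0) {
  lesions <- lapply(lesions, function(x)
    if (inherits(x, "synthetic_lesion")) x$series else x)
  stopifnot(nrow(fit_table) == length(lesions))
  fit_table$beta_perturbed_mean <- NA_real_
  fit_table$beta_perturbed_median <- NA_real_
  fit_table$n_successful <- NA_integer_
  fit_table$robust_by_mean <- NA
  fit_table$robust_by_median <- NA
  for (i in seq_along(lesions)) {
    if (!fit_table$eligible[i] || fit_table$status[i] != "converged") next
    rb <- assess_robustness(lesions[[i]], n_reps = n_reps,
                            noise_bound = noise_bound, threshold = threshold,
                            seed = substream_seed(seed, i))
    fit_table$beta_perturbed_mean[i] <- rb$beta_perturbed_mean
    fit_table$beta_perturbed_median[i] <- rb$beta_perturbed_median
    fit_table$n_successful[i] <- rb$n_successful
    fit_table$robust_by_mean[i] <- rb$robust_by_mean
    fit_table$robust_by_median[i] <- rb$robust_by_median
  }
  fit_table
}
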