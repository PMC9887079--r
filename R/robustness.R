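# Sensitivity of the fitted growth exponent to bounded segmentation error:
# every volume is perturbed by an independent multiplicative error of at
# most +/- noise_bound, the triplet is refitted, and the perturbed exponent
# summaries are compared to the original fit.

#' Perturb volumes with bounded multiplicative error
#'
#' Multiplies each volume by an independent `1 + u` with
#' `u ~ Uniform(-noise_bound, +noise_bound)`, the error model for
#' segmentation/acquisition uncertainty. The bound is respected exactly.
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param volumes Positive volumes in cm^3.
#' @param noise_bound Maximum relative error, in `[0, 1)`; default 0.05
#'   (+/- 5%).
#' @return Perturbed volumes, same length, all positive.
#' @export
perturb_volumes <- function(volumes, noise_bound = 0.05) {
  if (any(volumes <= 0)) stop("volumes must be positive", call. = FALSE)
  if (!is.numeric(noise_bound) || noise_bound < 0 || noise_bound >= 1)
    stop("'noise_bound' must be in [0, 1)", call. = FALSE)
  volumes * (1 + stats::runif(length(volumes), -noise_bound, noise_bound))
}

#' Robustness of the fitted exponent to volume perturbation
#'
#' Monte-Carlo screen for lesions whose growth exponent is fragile to small
#' volume errors. The three volumes are perturbed `n_reps` times with
#' independent multiplicative Uniform(+/- `noise_bound`) errors; perturbed
#' triplets that are no longer strictly increasing are discarded and
#' redrawn (the fit is undefined for non-increasing data), up to a redraw
#' cap of `100 * n_reps` total draws, after which a partial result is
#' returned with `n_successful < n_requested`. Each retained triplet is
#' refitted and the perturbed exponents are summarised by their mean and
#' median. The lesion is *robust* under a summary when the absolute
#' difference between that summary and the original exponent is strictly
#' below `threshold`.
#'
#' @param series A fittable [lesion_series()].
#' @param n_reps Number of perturbed refits requested (default 200).
#' @param noise_bound Maximum relative volume error (default 0.05).
#' @param threshold Robustness cutoff on |summary(beta*) - beta| (default
#'   0.5, strict inequality).
#' @param seed Optional integer seed; when given, results are reproducible
#'   and the caller's RNG state is left untouched.
#'
#' @return An object of class `"vb_robustness"`: list with `beta_original`,
#'   `beta_perturbed_mean`, `beta_perturbed_median`, `n_requested`,
#'   `n_successful`, `robust_by_mean`, `robust_by_median`, `threshold`,
#'   `noise_bound`, `seed`.
#' @seealso [perturb_volumes()], [fit_vb_exponent()]
#' @export
assess_robustness <- function(series, n_reps = 200, noise_bound = 0.05,
                              threshold = 0.5, seed = NULL) {
  fit0 <- fit_vb_exponent(series)
  if (fit0$status != "converged")
    stop("original series could not be fitted; robustness is undefined",
         call. = FALSE)
  run <- function() {
    vv <- series$volumes[1:3]
    tt <- series$times[1:3]
    betas <- numeric(0)
    draws <- 0L
    cap <- 100L * n_reps
    while (length(betas) < n_reps && draws < cap) {
      draws <- draws + 1L
      vstar <- perturb_volumes(vv, noise_bound)
      if (all(diff(vstar) > 0)) {
        f <- fit_vb_exponent(lesion_series(series$lesion_id, tt, vstar))
        if (f$status == "converged") betas <- c(betas, f$params$beta)
      }
    }
    betas
  }
  betas <- if (is.null(seed)) run() else with_seed(seed, run())
  m <- mean(betas)
  md <- stats::median(betas)
  structure(list(beta_original = fit0$params$beta,
                 beta_perturbed_mean = m,
                 beta_perturbed_median = md,
                 n_requested = as.integer(n_reps),
                 n_successful = length(betas),
                 robust_by_mean = abs(m - fit0$params$beta) < threshold,
                 robust_by_median = abs(md - fit0$params$beta) < threshold,
                 threshold = threshold, noise_bound = noise_bound,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "vb_robustness")
}

#' @export
print.vb_robustness <- function(x, ...) {
  cat(sprintf("Exponent robustness (+/-%g%% volume error, %d/%d refits)\n",
              100 * x$noise_bound, x$n_successful, x$n_requested))
  cat(sprintf("  beta = %.4g; perturbed mean %.4g, median %.4g\n",
              x$beta_original, x$beta_perturbed_mean, x$beta_perturbed_median))
  cat(sprintf("  robust (|diff| < %g): by mean %s, by median %s\n",
              x$threshold, x$robust_by_mean, x$robust_by_median))
  invisible(x)
}
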