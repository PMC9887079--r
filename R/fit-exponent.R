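# Exact identification of (V0, alpha, beta) from three increasing dated
# volumes, and the two-point instantaneous growth rates.
#
# With three data and three parameters the fit is an interpolation: V0 is
# pinned to the first measurement and beta solves the 1-D condition
#   g(beta) = r,   r = (t2 - t1) / (t1 - t0),
#   g(beta) = [V2^(1-beta) - V1^(1-beta)] / [V1^(1-beta) - V0^(1-beta)],
# after which alpha follows by back-substitution. g is computed in the
# overflow-safe form expm1(s*a) / (-expm1(-s*b)) with s = 1-beta,
# a = log(V2/V1), b = log(V1/V0); it is strictly decreasing in beta from
# +Inf to 0, so the root exists and is unique for any increasing triplet.

# g(beta) with its analytic limit a/b at beta = 1; vectorised over beta.
.vb_g <- function(beta, a, b) {
  s <- 1 - beta
  ifelse(abs(s) < .VB_EXP_BAND, a / b, expm1(s * a) / (-expm1(-s * b)))
}

#' Identify the growth exponent from three increasing volumes
#'
#' Exactly identifies the three parameters `(V0, alpha, beta)` of the
#' Von Bertalanffy law from the first three measurements of a lesion series.
#' `V0` is fixed to the first measured volume; `beta` is the unique root of
#' the interpolation condition matching the ratio of the two log-volume
#' increments to the ratio of the two scan intervals, found by bracketed
#' Brent root-finding; `alpha` is back-substituted. The fitted trajectory
#' passes through all three points, and any finite-time blow-up lies beyond
#' the last scan.
#'
#' @param series A [lesion_series()] whose first three volumes are strictly
#'   increasing (see [is_fittable()]).
#' @param beta_bracket Initial search bracket for `beta`; widened outward by
#'   doubling (up to `c(-50, 100)`) if it does not bracket the root.
#' @param tol Absolute tolerance on `beta` for the root solve.
#'
#' @return An object of class `"vb_fit"`: a list with `params`
#'   ([vb_params()]), `ratio_residual` (|g(beta) - r| at the solution),
#'   `bracket`, `iterations` and `status` (`"converged"` or `"failed"`).
#' @examples
#' s <- lesion_series("L1", times = c(0, 1, 2), volumes = c(1, 2, 4))
#' fit_vb_exponent(s)$params$beta # exactly exponential: beta = 1
#' @export
fit_vb_exponent <- function(series, beta_bracket = c(-5, 10), tol = 1e-10) {
  stopifnot(inherits(series, "lesion_series"))
  if (length(series$volumes) < 3L)
    stop("exponent identification needs at least 3 measurements",
         call. = FALSE)
  tt <- series$times[1:3]
  vv <- series$volumes[1:3]
  if (any(diff(vv) <= 0))
    stop("inclusion criterion violated: the first three volumes must ",
         "increase at each time point", call. = FALSE)

  b <- log(vv[2] / vv[1])          # first log-increment
  a <- log(vv[3] / vv[2])          # second log-increment
  r <- (tt[3] - tt[2]) / (tt[2] - tt[1])
  h <- function(beta) .vb_g(beta, a, b) - r

  lo <- beta_bracket[1]; hi <- beta_bracket[2]
  width <- hi - lo
  while (h(lo) * h(hi) > 0 && (lo > -50 || hi < 100)) {
    lo <- max(-50, lo - width)
    hi <- min(100, hi + width)
    width <- 2 * width
  }
  if (h(lo) * h(hi) > 0) {
    return(structure(list(params = NULL, ratio_residual = NA_real_,
                          bracket = c(lo, hi), iterations = 0L,
                          status = "failed"),
                     class = "vb_fit"))
  }
  root <- stats::uniroot(h, lower = lo, upper = hi, tol = tol,
                         maxiter = 1000L)
  beta <- root$root
  if (abs(beta - 1) < .VB_EXP_BAND) beta <- 1   # exponential branch
  s <- 1 - beta
  dt1 <- tt[2] - tt[1]
  alpha <- if (beta == 1) b / dt1
           else exp(s * log(vv[1])) * expm1(s * b) / (s * dt1)
  params <- vb_params(v0 = vv[1], alpha = alpha, beta = beta, t0 = tt[1])

  # converged means the interpolation actually holds: trajectory through
  # all three points and no blow-up before the last scan
  ok <- vb_blowup_time(params) > tt[3]
  if (ok) {
    rel <- abs(vb_trajectory(params, tt) - vv) / vv
    ok <- all(rel <= 1e-6)
  }
  structure(list(params = params,
                 ratio_residual = abs(h(beta)),
                 bracket = c(lo, hi),
                 iterations = root$iter,
                 status = if (ok) "converged" else "failed"),
            class = "vb_fit")
}

#' @export
print.vb_fit <- function(x, ...) {
  cat("Von Bertalanffy exponent fit:", x$status, "\n")
  if (!is.null(x$params)) {
    cat(sprintf("  beta = %.6g, alpha = %.6g, V0 = %.6g cm^3\n",
                x$params$beta, x$params$alpha, x$params$v0))
    cat(sprintf("  ratio residual %.3g after %d iterations in bracket [%g, %g]\n",
                x$ratio_residual, x$iterations, x$bracket[1], x$bracket[2]))
  }
  invisible(x)
}

#' Instantaneous growth rate between two scans
#'
#' Specific growth rate between two volume measurements,
#' \eqn{\lambda = \log(V_b / V_a) / (t_b - t_a)} (natural logarithm), in
#' 1/month. This is the exponent of the best exponential interpolant
#' through the two points.
#'
#' @param v_a,v_b Volumes in cm^3 at the earlier and later scan; positive.
#' @param t_a,t_b Scan times in months, `t_b > t_a`.
#' @return Growth rate in 1/month (negative if the volume decreased).
#' @examples
#' growth_rate(1, 2, 0, 1) # doubling in a month: log(2)
#' @export
growth_rate <- function(v_a, v_b, t_a, t_b) {
  if (any(t_b <= t_a))
    stop("'t_b' must be later than 't_a'", call. = FALSE)
  if (any(v_a <= 0) || any(v_b <= 0))
    stop("volumes must be positive", call. = FALSE)
  log(v_b / v_a) / (t_b - t_a)
}

#' Two-point growth rates of a lesion series
#'
#' Computes the instantaneous growth rate twice: `lambda1` from the first
#' and second measurements and `lambda2` from the second and third. For a
#' series satisfying the inclusion criterion both are positive, and
#' `lambda2 > lambda1` exactly when the fitted growth exponent exceeds 1
#' (accelerating, super-exponential growth).
#'
#' @param series A [lesion_series()] with at least 3 measurements.
#' @return An object of class `"growth_rates"`: list with `lambda1` and
#'   `lambda2` in 1/month.
#' @seealso [growth_rate()], [fit_vb_exponent()]
#' @export
growth_rates <- function(series) {
  stopifnot(inherits(series, "lesion_series"))
  if (length(series$volumes) < 3L)
    stop("growth_rates needs at least 3 measurements", call. = FALSE)
  tt <- series$times; vv <- series$volumes
  structure(list(lambda1 = growth_rate(vv[1], vv[2], tt[1], tt[2]),
                 lambda2 = growth_rate(vv[2], vv[3], tt[2], tt[3])),
            class = "growth_rates")
}

#' @export
print.growth_rates <- function(x, ...) {
  cat(sprintf("lambda1 = %.4g /month, lambda2 = %.4g /month (%s)\n",
              x$lambda1, x$lambda2,
              if (x$lambda2 > x$lambda1) "accelerating" else "decelerating"))
  invisible(x)
}
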