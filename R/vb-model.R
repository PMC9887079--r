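# Von Bertalanffy power-law growth model: dV/dt = alpha * V^beta, V(t0) = V0.
# Closed-form solution, trajectory evaluation and finite-time blow-up handling.

# |beta - 1| below this band uses the analytic exponential limit; the general
# closed form is 0/0 at beta = 1 and suffers catastrophic cancellation nearby.
.VB_EXP_BAND <- 1e-7

#' Von Bertalanffy growth parameters
#'
#' Container for the three parameters of the power-law growth model
#' \deqn{dV/dt = \alpha V^\beta, \quad V(t_0) = V_0,}
#' the model used to describe contrast-enhancing volume growth of brain
#' metastases between consecutive MRI follow-ups. Volumes are in cm^3 and
#' times in months throughout the package.
#'
#' Only growing lesions are modelled (tumour cell loss assumed negligible),
#' so `alpha` must be positive. `beta` may be any finite real: `beta < 1`
#' gives decelerating (sub-exponential) growth, `beta = 1` exponential
#' growth, and `beta > 1` super-exponential growth with a finite-time
#' blow-up (see [vb_blowup_time()]).
#'
#' @param v0 Volume in cm^3 at the reference time `t0`; must be positive.
#' @param alpha Growth coefficient in cm^3^(1-beta) per month; must be
#'   positive.
#' @param beta Dimensionless growth exponent; any finite value.
#' @param t0 Reference time in months (default 0).
#'
#' @return An object of class `"vb_params"`.
#' @seealso [vb_volume()], [vb_blowup_time()], [fit_vb_exponent()]
#' @examples
#' p <- vb_params(v0 = 1, alpha = log(2), beta = 1)
#' vb_volume(p, 3) # doubles every month: 8 cm^3
#' @export
vb_params <- function(v0, alpha, beta, t0 = 0) {
  for (nm in c("v0", "alpha", "beta", "t0")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (v0 <= 0) stop("'v0' must be positive", call. = FALSE)
  if (alpha <= 0)
    stop("'alpha' must be positive: only growing lesions are modelled",
         call. = FALSE)
  structure(list(v0 = as.numeric(v0), alpha = as.numeric(alpha),
                 beta = as.numeric(beta), t0 = as.numeric(t0)),
            class = "vb_params")
}

#' @export
print.vb_params <- function(x, ...) {
  cat("Von Bertalanffy parameters\n")
  cat(sprintf("  V0    = %.6g cm^3 at t0 = %.6g months\n", x$v0, x$t0))
  cat(sprintf("  alpha = %.6g cm^3^(1-beta)/month\n", x$alpha))
  cat(sprintf("  beta  = %.6g\n", x$beta))
  tb <- vb_blowup_time(x)
  if (is.finite(tb))
    cat(sprintf("  finite-time blow-up at t = %.6g months\n", tb))
  invisible(x)
}

#' Finite-time blow-up of the growth law
#'
#' For `beta > 1` the solution of the power-law growth model diverges at
#' \deqn{t_b = t_0 + V_0^{1-\beta} / (\alpha (\beta - 1)),}
#' the finite-time blow-up. For `beta <= 1` the solution exists for all
#' times and `Inf` is returned.
#'
#' @param params A [vb_params()] object.
#' @return Blow-up time in months, or `Inf` when `beta <= 1`.
#' @examples
#' vb_blowup_time(vb_params(1, 1, 2)) # 1 month
#' @export
vb_blowup_time <- function(params) {
  stopifnot(inherits(params, "vb_params"))
  if (params$beta <= 1 + .VB_EXP_BAND) return(Inf)
  s <- 1 - params$beta
  params$t0 + exp(s * log(params$v0)) / (params$alpha * (params$beta - 1))
}

#' Evaluate the Von Bertalanffy growth law
#'
#' Closed-form solution of `dV/dt = alpha * V^beta` with `V(t0) = v0`:
#' \deqn{V(t) = \left[V_0^{1-\beta} + \alpha(1-\beta)(t - t_0)\right]^{1/(1-\beta)}}
#' for `beta != 1`, and the analytic limit
#' \eqn{V(t) = V_0 e^{\alpha (t - t_0)}} at `beta = 1` (used within a narrow
#' band around 1 for numerical stability).
#'
#' @param params A [vb_params()] object.
#' @param t Evaluation time(s) in months; must be finite, `>= t0` and, for
#'   `beta > 1`, strictly before the blow-up time.
#' @return Volume(s) in cm^3, same length as `t`.
#' @seealso [vb_trajectory()], [vb_blowup_time()]
#' @export
vb_volume <- function(params, t) {
  stopifnot(inherits(params, "vb_params"))
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("evaluation times must be finite numbers", call. = FALSE)
  if (any(t < params$t0))
    stop("evaluation times must not precede t0 = ", params$t0, call. = FALSE)
  tb <- vb_blowup_time(params)
  if (any(t >= tb))
    stop(sprintf(
      "volume diverges: evaluation at or after the blow-up time %.6g months (beta = %.4g > 1)",
      tb, params$beta), call. = FALSE)
  s <- 1 - params$beta
  dt <- t - params$t0
  if (abs(s) < .VB_EXP_BAND) {
    params$v0 * exp(params$alpha * dt)
  } else {
    base <- exp(s * log(params$v0)) + params$alpha * s * dt
    exp(log(base) / s)
  }
}

#' Volume trajectory along a sorted time grid
#'
#' Element-wise [vb_volume()] with the additional contract that the time
#' grid is sorted ascending; the returned volumes are then strictly
#' increasing (the model only describes growth).
#'
#' @param params A [vb_params()] object.
#' @param times Numeric vector of months, sorted ascending, all within the
#'   domain of [vb_volume()].
#' @return Numeric vector of volumes in cm^3.
#' @export
vb_trajectory <- function(params, times) {
  if (length(times) == 0L) return(numeric(0))
  if (is.unsorted(times))
    stop("'times' must be sorted ascending", call. = FALSE)
  vb_volume(params, times)
}
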