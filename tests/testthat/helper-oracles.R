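# Independent oracles used across the suite. Each one re-derives the
# quantity by a different route than the package (numerical ODE
# integration, exhaustive grid scan, exhaustive pair counting, exhaustive
# permutation), so agreement is evidence, not tautology.

# High-accuracy Runge-Kutta integration of dV/dt = alpha * V^beta from
# (t0, v0); independent of the package's closed form.
ode_volume <- function(v0, alpha, beta, t0, t) {
  if (t == t0) return(v0)
  out <- deSolve::ode(y = c(V = v0), times = c(t0, t),
                      func = function(tt, y, p) list(alpha * y[1]^beta),
                      parms = NULL, method = "ode45",
                      rtol = 1e-10, atol = 1e-12)
  unname(out[nrow(out), "V"])
}

# Exhaustive grid scan of the interpolation condition
# g(beta) = (V2^s - V1^s) / (V1^s - V0^s), s = 1 - beta, against
# r = (t2-t1)/(t1-t0), refined by bisection. Direct power form, no shared
# code with the package. Returns the refined root(s) and the number of
# sign changes found on the grid.
grid_beta_oracle <- function(times, volumes, lo = -5, hi = 10, step = 1e-4) {
  v0 <- volumes[1]; v1 <- volumes[2]; v2 <- volumes[3]
  r <- (times[3] - times[2]) / (times[2] - times[1])
  h <- function(beta) {
    s <- 1 - beta
    (v2^s - v1^s) / (v1^s - v0^s) - r
  }
  # offset by step/2 so the 0/0 point beta = 1 is never hit exactly
  grid <- seq(lo + step / 2, hi, by = step)
  hv <- h(grid)
  sc <- which(hv[-length(hv)] * hv[-1] < 0)
  roots <- vapply(sc, function(i) {
    a <- grid[i]; b <- grid[i + 1]
    for (k in 1:60) {
      m <- (a + b) / 2
      if (h(a) * h(m) <= 0) b <- m else a <- m
    }
    (a + b) / 2
  }, numeric(1))
  list(roots = roots, n_sign_changes = length(sc))
}

# Mann-Whitney concordance probability by exhaustive pair counting,
# ties counted one half.
auc_pair_oracle <- function(pos, neg) {
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Exact permutation p-value of the (tie-corrected) Kruskal-Wallis H for
# two groups, over all C(n1+n2, n1) label assignments.
kw_perm_oracle <- function(x, y) {
  obs <- suppressWarnings(kruskal.test(list(x, y))$statistic)
  vals <- c(x, y)
  idx <- utils::combn(length(vals), length(x))
  Hs <- apply(idx, 2, function(i)
    suppressWarnings(kruskal.test(list(vals[i], vals[-i]))$statistic))
  mean(Hs >= obs - 1e-12)
}

# A random noiseless fittable series with known truth, drawn under the
# generator's study conditions but with measurement noise off.
random_true_lesion <- function(beta, config = cohort_config(noise_bound = 0)) {
  generate_trajectory(beta, config)
}
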