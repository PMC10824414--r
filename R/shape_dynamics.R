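#' Construct a biexponential shape trajectory
#'
#' An age-dependent beta distribution is defined by letting each shape
#' parameter decay as the sum of two exponentials in age:
#' `alpha(t) = b1 * exp(-a1 * (t - t0)) + b2 * exp(-a2 * (t - t0))`, and the
#' same form for `beta(t)`. The fast component captures the rapid change of
#' the well-proportion distribution in young animals, the slow component its
#' gradual drift thereafter.
#'
#' @param t0 First measured age in weeks; the trajectory is defined for
#'   `t >= t0`.
#' @param alpha,beta Numeric vectors `c(b1, a1, b2, a2)`: amplitudes (b) and
#'   decay rates (a, per week) for each shape parameter. By convention
#'   `a1 >= a2` (fast component first).
#' @param check_positive Ages over which evaluated positivity of alpha(t) and
#'   beta(t) is verified (warning on violation).
#' @return An object of class `shape_trajectory`.
#' @export
shape_trajectory <- function(t0, alpha, beta,
                             check_positive = seq(t0, 72, by = 0.25)) {
  stopifnot(is.numeric(alpha), length(alpha) == 4L,
            is.numeric(beta), length(beta) == 4L,
            is.numeric(t0), length(t0) == 1L, is.finite(t0))
  alpha <- order_components(unname(alpha))
  beta <- order_components(unname(beta))
  traj <- structure(
    list(t0 = t0,
         alpha = c(b1 = alpha[1], a1 = alpha[2], b2 = alpha[3], a2 = alpha[4]),
         beta = c(b1 = beta[1], a1 = beta[2], b2 = beta[3], a2 = beta[4])),
    class = "shape_trajectory")
  if (length(check_positive)) {
    ev <- eval_trajectory(traj, check_positive)
    if (any(ev$alpha <= 0) || any(ev$beta <= 0))
      warning("trajectory evaluates to non-positive shape parameter(s) in [",
              min(check_positive), ", ", max(check_positive), "] weeks",
              call. = FALSE)
  }
  traj
}

## enforce a1 >= a2 by swapping (b1, a1) with (b2, a2)
order_components <- function(p) {
  if (p[2] < p[4]) p <- p[c(3, 4, 1, 2)]
  p
}

#' @export
print.shape_trajectory <- function(x, ...) {
  cat("Biexponential beta-shape trajectory (t0 =", x$t0, "weeks)\n")
  cat(sprintf("  alpha(t) = %.4g exp(-%.4g (t-t0)) + %.4g exp(-%.4g (t-t0))\n",
              x$alpha["b1"], x$alpha["a1"], x$alpha["b2"], x$alpha["a2"]))
  cat(sprintf("  beta(t)  = %.4g exp(-%.4g (t-t0)) + %.4g exp(-%.4g (t-t0))\n",
              x$beta["b1"], x$beta["a1"], x$beta["b2"], x$beta["a2"]))
  invisible(x)
}

#' Evaluate the shape trajectory at given ages
#'
#' @param traj A [shape_trajectory()].
#' @param t Ages in weeks, all `>= traj$t0`.
#' @return A list with numeric vectors `alpha` and `beta`, one value per age.
#' @export
eval_trajectory <- function(traj, t) {
  stopifnot(inherits(traj, "shape_trajectory"))
  if (any(t < traj$t0 - 1e-12))
    stop("domain error: age ", min(t), " is before t0 = ", traj$t0)
  biexp <- function(p, tau) p["b1"] * exp(-p["a1"] * tau) +
    p["b2"] * exp(-p["a2"] * tau)
  tau <- t - traj$t0
  list(alpha = unname(biexp(traj$alpha, tau)),
       beta = unname(biexp(traj$beta, tau)))
}

#' Fit biexponential age trajectories to per-age shape estimates
#'
#' Fits `alpha(t)` and `beta(t)` independently by unweighted nonlinear least
#' squares on the natural scale of the per-age maximum-likelihood estimates
#' (Levenberg-Marquardt, multi-start over a fixed grid of rate pairs and
#' amplitude splits, plus a nested single-exponential start so the
#' biexponential fit can never be worse than the best single exponential).
#'
#' @param estimates Data frame from [fit_all_ages()] with columns `age_weeks`,
#'   `alpha`, `beta`; at least 4 distinct ages.
#' @param t0 Trajectory origin; must equal the smallest fitted age.
#' @return A [shape_trajectory()] with attributes `ssr_alpha` and `ssr_beta`
#'   (residual sums of squares of each curve fit).
#' @export
fit_trajectory <- function(estimates, t0 = min(estimates$age_weeks)) {
  stopifnot(is.data.frame(estimates),
            all(c("age_weeks", "alpha", "beta") %in% names(estimates)))
  ages <- estimates$age_weeks
  if (length(unique(ages)) < 4L)
    stop("need at least 4 distinct ages to fit 4 parameters per curve")
  if (abs(t0 - min(ages)) > 1e-9)
    stop("t0 must equal the smallest estimated age (", min(ages), ")")
  fa <- fit_biexp(ages - t0, estimates$alpha)
  fb <- fit_biexp(ages - t0, estimates$beta)
  traj <- shape_trajectory(t0, alpha = fa$par, beta = fb$par)
  attr(traj, "ssr_alpha") <- fa$ssr
  attr(traj, "ssr_beta") <- fb$ssr
  traj
}

## least-squares biexponential y ~ b1 exp(-a1 tau) + b2 exp(-a2 tau)
## multi-start Levenberg-Marquardt over a fixed, deterministic start grid
fit_biexp <- function(tau, y) {
  resid_fn <- function(p) y - (p[1] * exp(-p[2] * tau) +
                                 p[3] * exp(-p[4] * tau))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                     ptol = 1e-15, gtol = 0)
  run <- function(start) {
    tryCatch(minpack.lm::nls.lm(par = start, fn = resid_fn, control = ctrl),
             error = function(e) NULL)
  }

  # nested single-exponential fit: y ~ b exp(-a tau)
  sres <- function(p) y - p[1] * exp(-p[2] * tau)
  sbest <- NULL
  for (a0 in c(0, 0.01, 0.05, 0.2, 1)) {
    o <- tryCatch(minpack.lm::nls.lm(par = c(y[1], a0), fn = sres,
                                     control = ctrl),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(sbest) || o$deviance < sbest$deviance))
      sbest <- o
  }

  span <- max(tau) - min(tau)
  rates <- exp(seq(log(0.02 / max(span, 1)), log(5), length.out = 5))
  starts <- list()
  for (a1 in rates) for (frac in c(0.3, 0.7)) {
    a2 <- a1 / 20
    starts[[length(starts) + 1L]] <- c(frac * y[1], a1, (1 - frac) * y[1], a2)
  }
  if (!is.null(sbest))  # nesting: start from the single-exponential optimum
    starts[[length(starts) + 1L]] <- c(sbest$par[1], sbest$par[2], 0, 0)

  best <- NULL
  for (s in starts) {
    o <- run(s)
    if (!is.null(o) && (is.null(best) || o$deviance < best$deviance))
      best <- o
  }
  if (is.null(best))
    stop("biexponential least squares failed from all starts")
  list(par = order_components(best$par), ssr = best$deviance)
}
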