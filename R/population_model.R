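#' Parameters of the two-compartment HSC/progenitor model
#'
#' The stem compartment S (CD34-CD150+KSL cells) gains one cell per S-S
#' division and loses one per P-P division; the progenitor compartment P gains
#' one cell per S-P division and two per P-P division and is removed (further
#' differentiation out of KSL) at rate `d`:
#' \deqn{dS/dt = r p(t) S - r (1 - p(t) - q(t)) S}
#' \deqn{dP/dt = r q(t) S + 2 r (1 - p(t) - q(t)) S - d P}
#' with `r` the HSC division rate. HSC death is omitted (apoptotic HSC
#' fractions are negligible). KSL counts are modelled as S + P.
#'
#' @param r HSC division rate, per week (> 0).
#' @param d Progenitor removal rate, per week (> 0); 0.1 by default
#'   (mean progenitor residence 10 weeks).
#' @param S0,P0 Compartment sizes at `t0` (> 0).
#' @param t0 Model origin in weeks.
#' @return An object of class `model_params`.
#' @export
model_params <- function(r, d = 0.1, S0, P0, t0 = 4) {
  vals <- c(r = r, d = d, S0 = S0, P0 = P0)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("r, d, S0 and P0 must all be positive and finite")
  structure(list(r = r, d = d, S0 = S0, P0 = P0, t0 = t0),
            class = "model_params")
}

#' Integrate the stem/progenitor compartment model
#'
#' Solves the two-compartment system driven by age-dependent division
#' fractions. Two routes are provided: `"lsoda"` uses the adaptive solver of
#' \pkg{deSolve} (rtol 1e-8, atol 1e-10); `"grid"` evaluates the exact
#' integrating-factor solution of this linear system on a fine age grid with
#' cumulative trapezoidal quadrature, which is considerably faster and is
#' used inside the fitting loops. The two routes agree to solver tolerance
#' (a tested property).
#'
#' @param params A [model_params()].
#' @param fractions A function of age returning a list with elements `p`, `q`,
#'   `pp` (vectorized over age), e.g. from [make_fraction_fun()].
#' @param ages Ascending age grid starting at `params$t0`.
#' @param method `"grid"` (default) or `"lsoda"`.
#' @param grid_step Fine-grid spacing in weeks for the `"grid"` method.
#' @param rtol,atol Relative/absolute local error tolerances for `"lsoda"`.
#' @return Data frame of class `population_trajectory` with columns
#'   `age_weeks`, `S`, `P`, `KSL` (= S + P).
#' @export
integrate_model <- function(params, fractions, ages,
                            method = c("grid", "lsoda"), grid_step = 0.02,
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "model_params"), is.function(fractions))
  method <- match.arg(method)
  if (length(ages) < 1L || is.unsorted(ages, strictly = TRUE))
    stop("'ages' must be strictly ascending")
  if (abs(ages[1] - params$t0) > 1e-12)
    stop("ages[1] must equal t0 = ", params$t0)

  if (method == "lsoda") {
    rhs <- function(t, y, parms) {
      f <- fractions(t)
      pp <- f$pp
      dS <- parms$r * f$p * y[1] - parms$r * pp * y[1]
      dP <- parms$r * f$q * y[1] + 2 * parms$r * pp * y[1] - parms$d * y[2]
      list(c(dS, dP))
    }
    sol <- deSolve::ode(y = c(S = params$S0, P = params$P0), times = ages,
                        func = rhs, parms = params, method = "lsoda",
                        rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("integration error: solver failed near age ",
           max(sol[, "time"]), " weeks")
    out <- data.frame(age_weeks = ages, S = sol[, "S"], P = sol[, "P"])
  } else {
    grid <- sort(unique(c(seq(params$t0, max(ages), by = grid_step),
                          max(ages), ages)))
    sp <- grid_solution(params, fractions, grid)
    idx <- match(ages, grid)
    out <- data.frame(age_weeks = ages, S = sp$S[idx], P = sp$P[idx])
  }
  out$KSL <- out$S + out$P
  class(out) <- c("population_trajectory", "data.frame")
  out
}

## exact solution of the linear system on a grid:
##   S(t)  = S0 exp(r G(t)),                G = int (p - pp)
##   P(t)  = e^{-d (t-t0)} [P0 + int e^{d (s-t0)} r (q + 2 pp) S ds]
grid_solution <- function(params, fractions, grid) {
  f <- fractions(grid)
  g <- f$p - f$pp
  S <- params$S0 * exp(params$r * cumtrapz(grid, g))
  src <- params$r * (f$q + 2 * f$pp) * S
  w <- exp(params$d * (grid - params$t0))
  P <- (params$P0 + cumtrapz(grid, w * src)) / w
  list(S = S, P = P)
}

## cumulative trapezoidal integral, first element 0
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

#' Instantaneous net HSC growth rate
#'
#' The stem compartment obeys `dS/dt = r (p(t) - pp(t)) S`, so its
#' instantaneous per-week growth rate is `r (p(t) - pp(t))`: positive while
#' symmetric self-renewal outweighs symmetric differentiation, and zero at
#' the age where the two balance (the HSC pool plateau).
#'
#' @inheritParams integrate_model
#' @param t Ages in weeks.
#' @return Net growth rate(s), per week.
#' @export
steady_growth_rate <- function(params, fractions, t) {
  stopifnot(inherits(params, "model_params"))
  f <- fractions(t)
  params$r * (f$p - f$pp)
}
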