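#' Division-mode thresholds on the 0.1 grid
#'
#' Two cutoffs on the per-well proportion of functional HSCs classify the
#' inferred first division of the seeded cell: below `c1` a symmetric
#' differentiation (P-P) division, between `c1` and `c2` an asymmetric (S-P)
#' division, above `c2` a symmetric self-renewal (S-S) division. Both cutoffs
#' are restricted to exact multiples of 0.1 in (0, 1); the model intentionally
#' does not support continuous thresholds, which would permit implausibly
#' small `c1` values.
#'
#' @param c1,c2 Thresholds in `{0.1, ..., 0.9}` with `c1 < c2`.
#' @return An object of class `division_thresholds`.
#' @export
division_thresholds <- function(c1, c2) {
  check_grid_point(c1, "c1", allow_zero = FALSE)
  check_grid_point(c2, "c2", allow_zero = FALSE)
  if (c1 >= c2) stop("c1 must be strictly less than c2")
  structure(list(c1 = round(c1, 1), c2 = round(c2, 1)),
            class = "division_thresholds")
}

#' @export
print.division_thresholds <- function(x, ...) {
  cat("Division thresholds: P-P below", x$c1, "| S-P |  S-S above", x$c2, "\n")
  invisible(x)
}

check_grid_point <- function(x, name, allow_zero = TRUE) {
  lo <- if (allow_zero) 0 else 0.1
  ok <- length(x) == 1L && is.finite(x) &&
    min(abs(x - seq(lo, 0.9, by = 0.1))) < 1e-9
  if (!ok)
    stop("domain error: ", name, " must be one of {",
         paste(format(seq(lo, 0.9, 0.1)), collapse = ", "), "}")
  invisible(TRUE)
}

#' Probability mass of one 0.1-wide bin of the age-dependent beta distribution
#'
#' Returns the mass of `Beta(alpha(t), beta(t))` on the bin
#' `[x_lo, x_lo + 0.1]`, computed as the difference of the regularized
#' incomplete beta function at the two bin edges.
#'
#' @param traj A [shape_trajectory()].
#' @param t Age in weeks (`>= t0`).
#' @param x_lo Lower bin edge, one of `{0.0, 0.1, ..., 0.9}`.
#' @return Bin probability in \[0, 1\].
#' @export
discretized_bin_mass <- function(traj, t, x_lo) {
  check_grid_point(x_lo, "x_lo", allow_zero = TRUE)
  ab <- eval_trajectory(traj, t)
  stats::pbeta(round(x_lo, 1) + 0.1, ab$alpha, ab$beta) -
    stats::pbeta(round(x_lo, 1), ab$alpha, ab$beta)
}

#' Discretized cumulative probability below a grid threshold
#'
#' Accumulates the 0.1-bin masses of [discretized_bin_mass()] from 0 up to
#' `c`, i.e. the discretized CDF of the age-dependent beta distribution. By
#' telescoping this equals the continuous regularized incomplete beta
#' function at `c` exactly; the sum is computed explicitly so that identity
#' is a checkable property rather than an assumption.
#'
#' @inheritParams discretized_bin_mass
#' @param c Threshold, one of `{0.1, ..., 0.9}`.
#' @return Cumulative probability `P_c` in \[0, 1\].
#' @export
cumulative_below <- function(traj, t, c) {
  check_grid_point(c, "c", allow_zero = FALSE)
  edges <- seq(0, round(c, 1) - 0.1, by = 0.1)
  sum(vapply(edges, function(x) discretized_bin_mass(traj, t, x), numeric(1)))
}

#' Division-mode fractions at one age
#'
#' Converts the age-dependent beta distribution of well proportions into
#' fractions of the three division modes: `p = 1 - P_c2` (S-S),
#' `q = P_c2 - P_c1` (S-P) and `pp = P_c1` (P-P), where `P_c` is the
#' discretized cumulative probability of [cumulative_below()]. The three
#' fractions always sum to one.
#'
#' @inheritParams discretized_bin_mass
#' @param thr A [division_thresholds()].
#' @return A list with `age_weeks`, `p`, `q`, `pp`.
#' @export
division_fractions_at <- function(traj, t, thr) {
  stopifnot(inherits(thr, "division_thresholds"))
  p1 <- cumulative_below(traj, t, thr$c1)
  p2 <- cumulative_below(traj, t, thr$c2)
  list(age_weeks = t, p = 1 - p2, q = p2 - p1, pp = p1)
}

#' Division-mode fractions over an age grid
#'
#' @inheritParams division_fractions_at
#' @param ages Numeric vector of ages in weeks, all `>= t0`.
#' @return Data frame with columns `age_weeks`, `p_ss`, `q_sp`, `pp`; one row
#'   per age, each row summing to 1.
#' @export
fraction_timecourse <- function(traj, thr, ages) {
  stopifnot(inherits(thr, "division_thresholds"))
  ab <- eval_trajectory(traj, ages)
  p1 <- stats::pbeta(thr$c1, ab$alpha, ab$beta)
  p2 <- stats::pbeta(thr$c2, ab$alpha, ab$beta)
  data.frame(age_weeks = ages, p_ss = 1 - p2, q_sp = p2 - p1, pp = p1)
}

## vectorized fraction evaluator used in the fitting hot path:
## returns a function(t) -> list(p, q, pp)
make_fraction_fun <- function(traj, thr) {
  stopifnot(inherits(traj, "shape_trajectory"),
            inherits(thr, "division_thresholds"))
  force(traj); force(thr)
  function(t) {
    ab <- eval_trajectory(traj, t)
    p1 <- stats::pbeta(thr$c1, ab$alpha, ab$beta)
    p2 <- stats::pbeta(thr$c2, ab$alpha, ab$beta)
    list(p = 1 - p2, q = p2 - p1, pp = p1)
  }
}
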