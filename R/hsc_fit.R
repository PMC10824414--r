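#' Fit the full division-mode model to an ex vivo / in vivo study
#'
#' Runs the complete analysis: (1) beta-distribution maximum likelihood per
#' ex vivo age ([fit_all_ages()]); (2) biexponential age trajectories of the
#' shape parameters ([fit_trajectory()]); (3) exhaustive grid search over the
#' 36 admissible threshold pairs, each with a nonlinear least-squares fit of
#' (r, S0, P0) to the census ([grid_search_thresholds()]); (4) posterior
#' sampling of (r, S0, P0) at the selected thresholds by adaptive Metropolis
#' MCMC ([run_mcmc()]); and (5) a sensitivity sweep over the fixed progenitor
#' removal rate d ([sensitivity_d()]) when `cfg$d_values` has several values.
#'
#' @param wells Well-proportion data frame (see [read_well_proportions()]).
#' @param census Census data frame (see [read_census()]).
#' @param cfg A [fit_config()].
#' @param mcmc Logical; run the posterior-sampling stage (default TRUE).
#' @return An object of class `hsc_fit` with components `shapes`,
#'   `trajectory`, `thresholds`, `params`, `ssr`, `ssr_grid`, `posterior`
#'   (or NULL), `sensitivity` (or NULL), `cfg`, and the input data.
#' @examples
#' spec <- paper_like_spec(seed = 42)
#' wells <- generate_wells(spec)
#' census <- generate_census(spec)
#' cfg <- fit_config(mcmc = list(n_steps = 2000L, n_burn = 500L,
#'                               n_chains = 2L))
#' fit <- hsc_fit(wells, census, cfg)
#' coef(fit)
#' @export
hsc_fit <- function(wells, census, cfg = fit_config(), mcmc = TRUE) {
  shapes <- fit_all_ages(wells)
  traj <- fit_trajectory(shapes, t0 = cfg$t0)
  gs <- grid_search_thresholds(traj, census, cfg)
  post <- NULL
  if (isTRUE(mcmc))
    post <- run_mcmc(gs$thresholds, traj, census, cfg,
                     point = list(params = gs$params, ssr = gs$ssr))
  sens <- NULL
  if (length(cfg$d_values) > 1L)
    sens <- sensitivity_d(traj, census, cfg, thresholds = gs$thresholds)
  structure(list(shapes = shapes, trajectory = traj,
                 thresholds = gs$thresholds, params = gs$params,
                 ssr = gs$ssr, ssr_grid = gs$ssr_grid,
                 posterior = post, sensitivity = sens,
                 cfg = cfg, wells = wells, census = census),
            class = "hsc_fit")
}

#' @export
print.hsc_fit <- function(x, ...) {
  cat("Age-dependent HSC division-mode model fit\n")
  cat(sprintf("  thresholds: c1 = %.1f, c2 = %.1f (SSR = %.4g, %s scale)\n",
              x$thresholds$c1, x$thresholds$c2, x$ssr, x$cfg$loss_scale))
  cat(sprintf("  r = %.4g /week, S0 = %.4g, P0 = %.4g (d = %.3g fixed, t0 = %g wk)\n",
              x$params$r, x$params$S0, x$params$P0, x$params$d, x$params$t0))
  if (!is.null(x$posterior)) {
    s <- x$posterior$summary
    cat(sprintf("  posterior r: mean %.4g, 95%% CI (%.4g, %.4g)\n",
                s$mean[s$parameter == "r"], s$q2.5[s$parameter == "r"],
                s$q97.5[s$parameter == "r"]))
  }
  invisible(x)
}

#' @export
coef.hsc_fit <- function(object, ...) {
  c(c1 = object$thresholds$c1, c2 = object$thresholds$c2,
    r = object$params$r, d = object$params$d,
    S0 = object$params$S0, P0 = object$params$P0)
}

#' @export
logLik.hsc_fit <- function(object, ...) {
  n <- 2L * nrow(census_subset(object$census, object$cfg))
  s2 <- object$ssr / n
  val <- -n / 2 * (log(2 * pi * s2) + 1)
  structure(val, df = 5L, nobs = n, class = "logLik")
}

#' Predicted cell counts or division fractions from a fitted model
#'
#' @param object An [hsc_fit()] object.
#' @param ages Ages (weeks) at which to predict; default a weekly grid from
#'   t0 to the last census age.
#' @param what `"counts"` for S, P and KSL numbers; `"fractions"` for the
#'   division-mode fractions.
#' @param ... Unused.
#' @return A data frame.
#' @export
predict.hsc_fit <- function(object, ages = NULL,
                            what = c("counts", "fractions"), ...) {
  what <- match.arg(what)
  if (is.null(ages))
    ages <- seq(object$params$t0, max(object$census$age_weeks), by = 1)
  ages <- sort(unique(c(object$params$t0, ages)))
  if (what == "fractions")
    return(fraction_timecourse(object$trajectory, object$thresholds, ages))
  fr <- make_fraction_fun(object$trajectory, object$thresholds)
  out <- integrate_model(object$params, fr, ages, method = "grid")
  as.data.frame(out)
}

#' @export
residuals.hsc_fit <- function(object, ...) {
  obs <- census_subset(object$census, object$cfg)
  fr <- make_fraction_fun(object$trajectory, object$thresholds)
  ages <- sort(unique(c(object$cfg$t0, obs$age_weeks)))
  pred <- integrate_model(object$params, fr, ages, method = "grid")
  i <- match(obs$age_weeks, pred$age_weeks)
  if (object$cfg$loss_scale == "log10") {
    data.frame(age_weeks = obs$age_weeks,
               hsc = log10(obs$hsc_count) - log10(pred$S[i]),
               ksl = log10(obs$ksl_count) - log10(pred$KSL[i]))
  } else {
    data.frame(age_weeks = obs$age_weeks,
               hsc = obs$hsc_count - pred$S[i],
               ksl = obs$ksl_count - pred$KSL[i])
  }
}

#' Simulate replicate studies from a fitted model
#'
#' Draws new synthetic studies treating the fitted trajectory, thresholds and
#' kinetic parameters as truth, using the same design (ages, mice, wells) as
#' the data the model was fitted to.
#'
#' @param object An [hsc_fit()] object.
#' @param nsim Number of replicate studies.
#' @param seed Integer seed for the first replicate; replicate k uses
#'   `seed + k - 1`.
#' @param census_sigma Observation noise for the simulated censuses.
#' @param ... Unused.
#' @return A list of length `nsim`; each element has `wells` and `census`.
#' @export
simulate.hsc_fit <- function(object, nsim = 1, seed = 1L,
                             census_sigma = 0.05, ...) {
  wells <- object$wells
  ages_ex <- sort(unique(wells$age_weeks))
  mice <- vapply(ages_ex, function(a)
    length(unique(wells$mouse_id[wells$age_weeks == a])), integer(1))
  wpm <- max(1L, round(nrow(wells) / sum(mice)))
  out <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    spec <- generator_spec(
      trajectory = object$trajectory, thresholds = object$thresholds,
      ode_params = object$params,
      ages_exvivo = ages_ex, mice_per_age = mice, wells_per_mouse = wpm,
      ages_invivo = sort(unique(object$census$age_weeks)),
      mice_per_age_invivo = max(1L, round(nrow(census_subset(
        object$census, object$cfg)) / length(unique(object$census$age_weeks)))),
      census_sigma = census_sigma, seed = as.integer(seed) + k - 1L)
    out[[k]] <- list(wells = generate_wells(spec),
                     census = generate_census(spec))
  }
  if (nsim == 1) out[[1]] else out
}

#' Summary of a fitted division-mode model
#'
#' @param object An [hsc_fit()] object.
#' @param fraction_ages Ages at which division-mode fractions are reported.
#' @param ... Unused.
#' @return An object of class `summary.hsc_fit`: the parameter table (point
#'   estimates with posterior means and 95\% credible intervals where
#'   available), the division fractions at `fraction_ages`, and the
#'   sensitivity table if one was computed.
#' @export
summary.hsc_fit <- function(object, fraction_ages = c(10, 70), ...) {
  par_tab <- data.frame(
    parameter = c("c1", "c2", "r", "d", "S0", "P0"),
    estimate = unname(coef(object)),
    stringsAsFactors = FALSE)
  if (!is.null(object$posterior)) {
    s <- object$posterior$summary
    i <- match(par_tab$parameter, s$parameter)
    par_tab$post_mean <- s$mean[i]
    par_tab$ci_lower <- s$q2.5[i]
    par_tab$ci_upper <- s$q97.5[i]
  }
  fr <- fraction_timecourse(object$trajectory, object$thresholds,
                            fraction_ages)
  structure(list(parameters = par_tab, ssr = object$ssr,
                 loss_scale = object$cfg$loss_scale, fractions = fr,
                 sensitivity = object$sensitivity,
                 rhat = if (!is.null(object$posterior))
                   object$posterior$rhat else NA_real_),
            class = "summary.hsc_fit")
}

#' @export
print.summary.hsc_fit <- function(x, ...) {
  cat("Estimated parameters of the HSC division-mode model\n")
  print(x$parameters, digits = 4, row.names = FALSE)
  cat(sprintf("SSR = %.4g (%s scale)", x$ssr, x$loss_scale))
  if (is.finite(x$rhat)) cat(sprintf(", max split R-hat = %.3f", x$rhat))
  cat("\n\nDivision-mode fractions (S-S, S-P, P-P):\n")
  fr <- x$fractions
  for (k in seq_len(nrow(fr)))
    cat(sprintf("  %5.1f wk: %5.1f%%  %5.1f%%  %5.1f%%\n", fr$age_weeks[k],
                100 * fr$p_ss[k], 100 * fr$q_sp[k], 100 * fr$pp[k]))
  if (!is.null(x$sensitivity)) {
    cat("\nSensitivity to the progenitor removal rate d:\n")
    print(x$sensitivity, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Plot a fitted division-mode model
#'
#' Two panels: census counts (HSC and KSL, log scale) with the fitted model
#' curves, and the age course of the three division-mode fractions.
#'
#' @param x An [hsc_fit()] object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hsc_fit <- function(x, ...) {
  obs <- census_subset(x$census, x$cfg)
  ages <- seq(x$params$t0, max(obs$age_weeks), by = 0.5)
  pred <- predict(x, ages = ages, what = "counts")
  fr <- predict(x, ages = ages, what = "fractions")
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(pred$age_weeks, pred$KSL, type = "l", log = "y",
                 ylim = range(c(obs$hsc_count, obs$ksl_count, pred$S,
                                pred$KSL)),
                 xlab = "age (weeks)", ylab = "cells",
                 main = paste0("census fit (", x$cfg$bone, ")"), ...)
  graphics::lines(pred$age_weeks, pred$S, col = 2)
  graphics::points(obs$age_weeks, obs$ksl_count, pch = 1)
  graphics::points(obs$age_weeks, obs$hsc_count, pch = 16, col = 2)
  graphics::legend("topright", bty = "n", col = c(1, 2), lty = 1,
                   pch = c(1, 16), legend = c("KSL (S+P)", "HSC (S)"))
  graphics::plot(fr$age_weeks, fr$p_ss, type = "l", ylim = c(0, 1), col = 2,
                 xlab = "age (weeks)", ylab = "fraction of divisions",
                 main = "division modes")
  graphics::lines(fr$age_weeks, fr$q_sp, col = 3)
  graphics::lines(fr$age_weeks, fr$pp, col = 4)
  graphics::legend("topright", bty = "n", col = c(2, 3, 4), lty = 1,
                   legend = c("S-S", "S-P", "P-P"))
  invisible(x)
}
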