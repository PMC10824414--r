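#' Configuration of the census-fitting stage
#'
#' @param d_values Progenitor removal rates (per week) to fit under; the
#'   first value is the primary rate, further values are the sensitivity
#'   sweep (0.05 and 0.2 double and halve the mean progenitor residence).
#' @param loss_scale `"log10"` (default) fits residuals on decadic-log counts,
#'   appropriate for positive counts spanning an order of magnitude;
#'   `"linear"` fits raw counts.
#' @param bone Which bone's census rows are fitted.
#' @param t0 Model origin in weeks; compartment sizes S0, P0 are defined here
#'   and the model is integrated from `t0` even when the first census age is
#'   later.
#' @param r_bounds Box for the division rate r (per week).
#' @param s0_bounds,p0_bounds Boxes for the initial compartment sizes.
#' @param mcmc List of sampler settings: `n_chains`, `n_steps`, `n_burn`,
#'   `seed`, `proposal_scale` (initial relative step size).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(d_values = 0.1,
                       loss_scale = c("log10", "linear"),
                       bone = c("femur", "pelvis", "sternum"),
                       t0 = 4,
                       r_bounds = c(1e-3, 2),
                       s0_bounds = NULL,
                       p0_bounds = NULL,
                       mcmc = list()) {
  loss_scale <- match.arg(loss_scale)
  bone <- match.arg(bone)
  stopifnot(all(d_values > 0), all(r_bounds > 0), diff(r_bounds) > 0)
  m <- utils::modifyList(
    list(n_chains = 4L, n_steps = 20000L, n_burn = 5000L, seed = 1L,
         proposal_scale = 0.1),
    mcmc)
  if (m$n_steps <= m$n_burn) stop("mcmc n_steps must exceed n_burn")
  structure(list(d_values = d_values, loss_scale = loss_scale, bone = bone,
                 t0 = t0, r_bounds = r_bounds, s0_bounds = s0_bounds,
                 p0_bounds = p0_bounds, mcmc = m),
            class = "fit_config")
}

## census rows for the configured bone, with basic domain checks
census_subset <- function(census, cfg) {
  validate_census(census)
  obs <- census[census$bone == cfg$bone, , drop = FALSE]
  if (!nrow(obs)) stop("no census rows for bone '", cfg$bone, "'")
  if (any(obs$age_weeks < cfg$t0))
    stop("domain error: census age before t0 = ", cfg$t0)
  obs
}

#' Sum of squared residuals of the compartment model against a census
#'
#' Integrates the model at the census ages and accumulates, over every
#' (age, mouse) replicate, the squared residual of the observed HSC count
#' against S(age) plus that of the observed KSL count against S(age)+P(age),
#' each on the configured loss scale (decadic log by default).
#'
#' @param params A [model_params()].
#' @param thr A [division_thresholds()].
#' @param traj A [shape_trajectory()].
#' @param census Census data frame (see [read_census()]).
#' @param cfg A [fit_config()].
#' @return Nonnegative scalar SSR.
#' @export
ssr_objective <- function(params, thr, traj, census, cfg = fit_config()) {
  obs <- census_subset(census, cfg)
  fr <- make_fraction_fun(traj, thr)
  ages <- sort(unique(c(cfg$t0, obs$age_weeks)))
  pred <- integrate_model(params, fr, ages, method = "grid")
  i <- match(obs$age_weeks, pred$age_weeks)
  ssr_from_pred(obs, pred$S[i], pred$KSL[i], cfg$loss_scale)
}

ssr_from_pred <- function(obs, S, KSL, loss_scale) {
  if (loss_scale == "log10") {
    sum((log10(obs$hsc_count) - log10(S))^2) +
      sum((log10(obs$ksl_count) - log10(KSL))^2)
  } else {
    sum((obs$hsc_count - S)^2) + sum((obs$ksl_count - KSL)^2)
  }
}

## Fast closure over fixed (thr, traj, census, cfg, d): SSR as a function of
## theta = (r, log S0, log P0). Fractions and quadrature grid are precomputed
## once; each evaluation is a few vector operations.
make_ssr_fn <- function(thr, traj, census, cfg, d) {
  obs <- census_subset(census, cfg)
  if (cfg$loss_scale == "log10" &&
      any(obs$hsc_count <= 0 | obs$ksl_count <= 0))
    stop("log10 loss requires strictly positive counts")
  fr <- make_fraction_fun(traj, thr)
  grid <- sort(unique(c(seq(cfg$t0, max(obs$age_weeks), by = 0.02),
                        max(obs$age_weeks), obs$age_weeks)))
  f <- fr(grid)
  G <- cumtrapz(grid, f$p - f$pp)          # S = S0 exp(r G)
  h <- f$q + 2 * f$pp                       # P source coefficient
  w <- exp(d * (grid - cfg$t0))
  i <- match(obs$age_weeks, grid)
  lh <- log10(obs$hsc_count); lk <- log10(obs$ksl_count)
  function(theta) {
    r <- theta[1]; S0 <- exp(theta[2]); P0 <- exp(theta[3])
    S <- S0 * exp(r * G)
    P <- (P0 + cumtrapz(grid, w * r * h * S)) / w
    if (cfg$loss_scale == "log10") {
      sum((lh - log10(S[i]))^2) + sum((lk - log10(S[i] + P[i]))^2)
    } else {
      sum((obs$hsc_count - S[i])^2) + sum((obs$ksl_count - S[i] - P[i])^2)
    }
  }
}

## parameter box in theta = (r, log S0, log P0) space
theta_bounds <- function(census, cfg) {
  obs <- census_subset(census, cfg)
  s0 <- cfg$s0_bounds
  p0 <- cfg$p0_bounds
  if (is.null(s0)) s0 <- c(min(obs$hsc_count) / 100, max(obs$hsc_count) * 100)
  if (is.null(p0)) p0 <- c(min(obs$ksl_count) / 100, max(obs$ksl_count) * 100)
  list(lower = c(cfg$r_bounds[1], log(s0[1]), log(p0[1])),
       upper = c(cfg$r_bounds[2], log(s0[2]), log(p0[2])))
}

#' Point estimation of (r, S0, P0) at fixed thresholds
#'
#' Minimizes [ssr_objective()] over the division rate and the two initial
#' compartment sizes (the latter on the log scale), with the progenitor
#' removal rate `d` fixed. A fixed set of multi-starts (Nelder-Mead followed
#' by bounded quasi-Newton polish) makes the optimum deterministic.
#'
#' @inheritParams ssr_objective
#' @param d Progenitor removal rate to fix (defaults to `cfg$d_values[1]`).
#' @return A list with `params` (a [model_params()]) and `ssr`.
#' @export
fit_point <- function(thr, traj, census, cfg = fit_config(),
                      d = cfg$d_values[1]) {
  obs <- census_subset(census, cfg)
  fn <- make_ssr_fn(thr, traj, census, cfg, d)
  bd <- theta_bounds(census, cfg)
  clip <- function(th) pmin(pmax(th, bd$lower + 1e-10), bd$upper - 1e-10)
  fnb <- function(th) {
    if (any(th < bd$lower) || any(th > bd$upper)) return(1e12)
    fn(th)
  }

  first <- which.min(obs$age_weeks)
  s_guess <- stats::median(obs$hsc_count[obs$age_weeks ==
                                           obs$age_weeks[first]])
  k_guess <- stats::median(obs$ksl_count[obs$age_weeks ==
                                           obs$age_weeks[first]])
  starts <- lapply(c(0.05, 0.17, 0.5), function(r0)
    clip(c(r0, log(s_guess), log(max(k_guess - s_guess, 1)))))
  starts <- c(starts, list(clip(c(0.17, log(s_guess / 5), log(k_guess * 2)))))

  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s, fnb, method = "Nelder-Mead",
                   control = list(maxit = 3000, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(o)) next
    o2 <- tryCatch(
      stats::optim(clip(o$par), fn, method = "L-BFGS-B",
                   lower = bd$lower, upper = bd$upper,
                   control = list(maxit = 500, factr = 10)),
      error = function(e) NULL)
    if (!is.null(o2) && o2$value < o$value) o <- o2
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("optimization error: all point-fit starts failed")
  list(params = model_params(r = best$par[1], d = d,
                             S0 = exp(best$par[2]), P0 = exp(best$par[3]),
                             t0 = cfg$t0),
       ssr = best$value)
}

#' Exhaustive threshold grid search
#'
#' Runs [fit_point()] at every admissible threshold pair (all 36 pairs
#' `c1 < c2` on the 0.1 grid) and selects the pair with the smallest SSR.
#' Ties within 1e-9 are broken deterministically in favour of smaller `c1`,
#' then larger `c2`. The full SSR table is returned for audit.
#'
#' @inheritParams ssr_objective
#' @return A list with `thresholds`, `params`, `ssr` and `ssr_grid` (a
#'   36-row data frame with columns `c1`, `c2`, `ssr`, `r`, `S0`, `P0`).
#' @export
grid_search_thresholds <- function(traj, census, cfg = fit_config()) {
  grid <- expand.grid(c1 = seq(0.1, 0.9, 0.1), c2 = seq(0.1, 0.9, 0.1))
  grid <- grid[grid$c1 < grid$c2 - 1e-9, ]
  # deterministic tie-break order: smaller c1 first, then larger c2
  grid <- grid[order(grid$c1, -grid$c2), ]
  fits <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    thr <- division_thresholds(grid$c1[k], grid$c2[k])
    fits[[k]] <- fit_point(thr, traj, census, cfg)
  }
  tab <- data.frame(
    c1 = grid$c1, c2 = grid$c2,
    ssr = vapply(fits, `[[`, numeric(1), "ssr"),
    r = vapply(fits, function(f) f$params$r, numeric(1)),
    S0 = vapply(fits, function(f) f$params$S0, numeric(1)),
    P0 = vapply(fits, function(f) f$params$P0, numeric(1)))
  rownames(tab) <- NULL
  k_best <- which(tab$ssr <= min(tab$ssr) + 1e-9)[1]
  list(thresholds = division_thresholds(tab$c1[k_best], tab$c2[k_best]),
       params = fits[[k_best]]$params,
       ssr = tab$ssr[k_best],
       ssr_grid = tab)
}

#' Posterior sampling of (r, S0, P0) by adaptive Metropolis MCMC
#'
#' Samples the posterior implied by a Gaussian likelihood on the SSR scale
#' (residual variance estimated from the least-squares fit), a uniform prior
#' on `r` and log-uniform priors on `S0`, `P0` within the configured bounds.
#' Chains start at the point estimate (jittered) and use a Gaussian random
#' walk whose scale and covariance adapt during burn-in, then stay fixed so
#' the post-burn-in chain is Markovian. Convergence is monitored with the
#' split-chain potential scale reduction factor (R-hat).
#'
#' @inheritParams ssr_objective
#' @param point The least-squares optimum from [fit_point()] (chain start).
#' @param d Progenitor removal rate (fixed), default `point$params$d`.
#' @return A list with `samples` (post-burn-in draws of r, S0, P0 pooled over
#'   chains), `summary` (mean and 2.5/97.5 percentiles per parameter),
#'   `acceptance_rate`, `rhat`, and `sigma2` (residual variance used).
#' @export
run_mcmc <- function(thr, traj, census, cfg = fit_config(), point,
                     d = point$params$d) {
  fn <- make_ssr_fn(thr, traj, census, cfg, d)
  bd <- theta_bounds(census, cfg)
  obs <- census_subset(census, cfg)
  n_obs <- 2L * nrow(obs)
  theta0 <- c(point$params$r, log(point$params$S0), log(point$params$P0))
  sigma2 <- max(point$ssr / n_obs, 1e-12)
  logpost <- function(th) {
    if (any(th < bd$lower) || any(th > bd$upper)) return(-Inf)
    -fn(th) / (2 * sigma2)
  }

  m <- cfg$mcmc
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(m$seed)

  scale0 <- m$proposal_scale * pmax(abs(theta0), 0.05)
  chains <- vector("list", m$n_chains)
  acc_all <- numeric(m$n_chains)
  for (ch in seq_len(m$n_chains)) {
    chains[[ch]] <- am_chain(logpost, theta0, scale0, m$n_steps, m$n_burn,
                             bd)
    acc_all[ch] <- chains[[ch]]$acceptance
  }
  draws <- lapply(chains, `[[`, "draws")
  rhat <- max(vapply(1:3, function(j)
    split_rhat(lapply(draws, function(d) d[, j])), numeric(1)))
  if (is.finite(rhat) && rhat >= 1.05)
    warning("MCMC convergence warning: max split R-hat = ",
            round(rhat, 3), " (threshold 1.05)", call. = FALSE)
  th <- do.call(rbind, draws)
  samples <- data.frame(r = th[, 1], S0 = exp(th[, 2]), P0 = exp(th[, 3]))
  summ <- t(vapply(samples, function(x)
    c(mean = mean(x), q2.5 = unname(stats::quantile(x, 0.025)),
      q97.5 = unname(stats::quantile(x, 0.975))), numeric(3)))
  list(samples = samples,
       summary = data.frame(parameter = rownames(summ), summ,
                            row.names = NULL, check.names = FALSE),
       acceptance_rate = mean(acc_all), rhat = rhat, sigma2 = sigma2)
}

## one adaptive-Metropolis chain; adaptation frozen after burn-in
am_chain <- function(logpost, theta0, scale0, n_steps, n_burn, bd) {
  p <- length(theta0)
  # jittered start inside the box
  th <- pmin(pmax(theta0 * (1 + 0.02 * stats::rnorm(p)),
                  bd$lower + 1e-8), bd$upper - 1e-8)
  lp <- logpost(th)
  if (!is.finite(lp)) { th <- theta0; lp <- logpost(th) }
  S <- diag(scale0^2, p)
  lam <- 2.38^2 / p
  hist <- matrix(NA_real_, n_steps, p)
  n_acc <- 0L
  chol_S <- chol(S)
  for (i in seq_len(n_steps)) {
    prop <- th + sqrt(lam) * drop(stats::rnorm(p) %*% chol_S)
    lp_prop <- logpost(prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
      th <- prop; lp <- lp_prop
      if (i > n_burn) n_acc <- n_acc + 1L
      acc <- 1
    } else acc <- 0
    hist[i, ] <- th
    if (i <= n_burn) {
      # Robbins-Monro scale tuning towards ~0.3 acceptance
      lam <- lam * exp((acc - 0.3) / sqrt(i))
      if (i >= 200 && i %% 100 == 0) {
        emp <- stats::cov(hist[max(1, i - 999):i, , drop = FALSE])
        if (all(is.finite(emp)) && all(diag(emp) > 0)) {
          S2 <- emp + diag(1e-10, p)
          ch <- tryCatch(chol(S2), error = function(e) NULL)
          if (!is.null(ch)) { S <- S2; chol_S <- ch }
        }
      }
    }
  }
  list(draws = hist[(n_burn + 1):n_steps, , drop = FALSE],
       acceptance = n_acc / (n_steps - n_burn))
}

## split-chain potential scale reduction factor
split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(x) {
    n <- length(x) %/% 2
    list(x[seq_len(n)], x[(n + 1):(2 * n)])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  mns <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(mns)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Sensitivity of the fit to the progenitor removal rate
#'
#' Repeats the point fit at the selected thresholds for each requested
#' removal rate `d`, reporting the SSR attained under each.
#'
#' @inheritParams ssr_objective
#' @param thresholds The thresholds at which to refit (typically the grid
#'   search optimum).
#' @return Data frame with one row per `d`: columns `d`, `ssr`, `r`, `S0`,
#'   `P0`.
#' @export
sensitivity_d <- function(traj, census, cfg = fit_config(),
                          thresholds = division_thresholds(0.3, 0.8)) {
  rows <- lapply(cfg$d_values, function(d) {
    f <- fit_point(thresholds, traj, census, cfg, d = d)
    data.frame(d = d, ssr = f$ssr, r = f$params$r, S0 = f$params$S0,
               P0 = f$params$P0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
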