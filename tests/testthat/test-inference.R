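# shared small synthetic study: true trajectory, thresholds (0.3, 0.8)
make_study <- function(seed = 1, sigma = 0.05) {
  spec <- paper_like_spec(seed = seed, census_sigma = sigma)
  list(spec = spec, census = generate_census(spec),
       thr = spec$thresholds, traj = spec$trajectory)
}

test_that("self-fit SSR vanishes and grows when r is perturbed", {
  st <- make_study(seed = 2, sigma = 0)
  cfg <- fit_config()
  ssr0 <- ssr_objective(st$spec$ode_params, st$thr, st$traj, st$census, cfg)
  expect_lt(ssr0, 1e-12)
  for (fac in c(0.5, 0.8, 1.25, 2)) {
    prm <- st$spec$ode_params
    prm$r <- prm$r * fac
    expect_gt(ssr_objective(prm, st$thr, st$traj, st$census, cfg), ssr0)
  }
})

test_that("expected SSR at truth scales with the noise variance", {
  cfg <- fit_config()
  mean_ssr <- function(sigma) {
    v <- vapply(1:30, function(k) {
      st <- make_study(seed = 100 + k, sigma = sigma)
      ssr_objective(st$spec$ode_params, st$thr, st$traj, st$census, cfg)
    }, numeric(1))
    mean(v)
  }
  ratio <- mean_ssr(0.1) / mean_ssr(0.05)  # doubling sigma ~ x4 in SSR
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})

test_that("noise-free point fit recovers the generating parameters", {
  st <- make_study(seed = 3, sigma = 0)
  fit <- fit_point(st$thr, st$traj, st$census, fit_config())
  expect_lt(abs(fit$params$r / 0.172 - 1), 1e-4)
  expect_lt(abs(fit$params$S0 / 5140 - 1), 1e-4)
  expect_lt(abs(fit$params$P0 / 1.01e5 - 1), 1e-4)
  expect_lt(fit$ssr, 1e-10)
})

test_that("noisy point fit recovers the division rate within 25%", {
  st <- make_study(seed = 4)
  fit <- fit_point(st$thr, st$traj, st$census, fit_config())
  expect_lt(abs(fit$params$r / 0.172 - 1), 0.25)
})

test_that("threshold grid search audits all 36 pairs and minimizes SSR", {
  st <- make_study(seed = 5, sigma = 0)
  gs <- grid_search_thresholds(st$traj, st$census, fit_config())
  expect_identical(nrow(gs$ssr_grid), 36L)
  expect_identical(anyDuplicated(gs$ssr_grid[c("c1", "c2")]), 0L)
  expect_true(all(gs$ssr_grid$c1 < gs$ssr_grid$c2))
  expect_equal(gs$ssr, min(gs$ssr_grid$ssr))
  # generator oracle: noise-free data identify the generating pair
  expect_equal(gs$thresholds$c1, 0.3)
  expect_equal(gs$thresholds$c2, 0.8)
})

test_that("MCMC is seed-reproducible with healthy acceptance and R-hat", {
  st <- make_study(seed = 6)
  cfg <- fast_cfg()
  pt <- fit_point(st$thr, st$traj, st$census, cfg)
  m1 <- run_mcmc(st$thr, st$traj, st$census, cfg, pt)
  m2 <- run_mcmc(st$thr, st$traj, st$census, cfg, pt)
  expect_identical(m1$samples, m2$samples)
  expect_gte(m1$acceptance_rate, 0.1)
  expect_lte(m1$acceptance_rate, 0.6)
  expect_lt(m1$rhat, 1.2)
  s <- m1$summary
  expect_true(all(s$q2.5 <= s$mean & s$mean <= s$q97.5))
  # posterior concentrates near the least-squares point
  expect_lt(abs(s$mean[s$parameter == "r"] / pt$params$r - 1), 0.5)
})

test_that("near-zero noise collapses the posterior around the point fit", {
  st <- make_study(seed = 8, sigma = 1e-4)
  cfg <- fast_cfg()
  pt <- fit_point(st$thr, st$traj, st$census, cfg)
  m <- run_mcmc(st$thr, st$traj, st$census, cfg, pt)
  s <- m$summary
  width <- (s$q97.5 - s$q2.5) / s$mean
  expect_true(all(width < 0.05))
})

test_that("d-sensitivity refits at each requested removal rate", {
  st <- make_study(seed = 9)
  cfg <- fit_config(d_values = c(0.1, 0.05, 0.2))
  tab <- sensitivity_d(st$traj, st$census, cfg, thresholds = st$thr)
  expect_equal(tab$d, c(0.1, 0.05, 0.2))
  expect_true(all(tab$ssr >= 0))
  # data generated under d = 0.1 fit best at d = 0.1 for this design
  expect_equal(tab$d[which.min(tab$ssr)], 0.1)
})

test_that("census ages before the model origin are rejected", {
  st <- make_study(seed = 10)
  census <- st$census
  census$age_weeks[1] <- 2
  expect_error(
    ssr_objective(st$spec$ode_params, st$thr, st$traj, census,
                  fit_config()),
    "before t0")
})
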