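test_that("pure self-renewal and pure differentiation match closed forms", {
  prm <- model_params(r = 0.3, d = 0.15, S0 = 1000, P0 = 500, t0 = 4)
  ages <- seq(4, 40, by = 2)

  all_ss <- function(t) list(p = rep(1, length(t)), q = rep(0, length(t)),
                             pp = rep(0, length(t)))
  for (method in c("grid", "lsoda")) {
    tr <- integrate_model(prm, all_ss, ages, method = method)
    expect_equal(tr$S, 1000 * exp(0.3 * (ages - 4)), tolerance = 1e-6)
    expect_equal(tr$P, 500 * exp(-0.15 * (ages - 4)), tolerance = 1e-6)
    expect_equal(tr$KSL, tr$S + tr$P)
  }

  all_pp <- function(t) list(p = rep(0, length(t)), q = rep(0, length(t)),
                             pp = rep(1, length(t)))
  tr <- integrate_model(prm, all_pp, ages, method = "lsoda")
  expect_equal(tr$S, 1000 * exp(-0.3 * (ages - 4)), tolerance = 1e-6)
})

test_that("solver S matches the quadrature closed form for smooth schedules", {
  prm <- model_params(r = 0.25, d = 0.1, S0 = 2000, P0 = 1e5, t0 = 4)
  ages <- c(4, 10, 25, 50, 72)
  set.seed(88)
  for (k in 1:5) {
    fr <- random_fraction_fun(runif(6, -0.5, 0.5))
    tr <- integrate_model(prm, fr, ages, method = "lsoda")
    closed <- vapply(ages, function(t) {
      g <- integrate(function(s) {
        f <- fr(s); 2 * f$p + f$q - 1
      }, 4, t, rel.tol = 1e-10, subdivisions = 2000L)$value
      2000 * exp(0.25 * g)
    }, numeric(1))
    expect_equal(tr$S, closed, tolerance = 1e-6)
  }
})

test_that("grid and lsoda routes agree", {
  spec <- paper_like_spec()
  fr <- make_fraction_fun(spec$trajectory, spec$thresholds)
  ages <- seq(4, 72, by = 4)
  g <- integrate_model(spec$ode_params, fr, ages, method = "grid")
  l <- integrate_model(spec$ode_params, fr, ages, method = "lsoda")
  expect_equal(g$S, l$S, tolerance = 1e-6)
  expect_equal(g$P, l$P, tolerance = 1e-5)
})

test_that("tightening solver tolerance leaves the solution unchanged", {
  spec <- paper_like_spec()
  fr <- make_fraction_fun(spec$trajectory, spec$thresholds)
  ages <- seq(4, 72, by = 4)
  a <- integrate_model(spec$ode_params, fr, ages, method = "lsoda")
  b <- integrate_model(spec$ode_params, fr, ages, method = "lsoda",
                       rtol = 5e-9, atol = 5e-11)
  expect_equal(a$S, b$S, tolerance = 1e-6)
  expect_equal(a$P, b$P, tolerance = 1e-6)
})

test_that("compartments stay positive and KSL is the exact sum", {
  spec <- paper_like_spec()
  fr <- make_fraction_fun(spec$trajectory, spec$thresholds)
  tr <- integrate_model(spec$ode_params, fr, seq(4, 72, 0.5))
  expect_true(all(tr$S > 0))
  expect_true(all(tr$P >= 0))
  expect_equal(tr$KSL, tr$S + tr$P, tolerance = 1e-12)
})

test_that("model preconditions are enforced", {
  prm <- model_params(r = 0.2, S0 = 100, P0 = 100, t0 = 4)
  fr <- function(t) list(p = 1, q = 0, pp = 0)
  expect_error(integrate_model(prm, fr, c(5, 10)), "equal t0")
  expect_error(integrate_model(prm, fr, c(4, 10, 8)), "ascending")
  expect_error(model_params(r = -1, S0 = 1, P0 = 1), "positive")
})

test_that("net growth rate is r-scaled balance of symmetric modes", {
  prm <- model_params(r = 0.4, S0 = 1, P0 = 1, t0 = 0)
  bal <- function(t) list(p = 0.3, q = 0.4, pp = 0.3)
  expect_equal(steady_growth_rate(prm, bal, 5), 0)
  ss <- function(t) list(p = 1, q = 0, pp = 0)
  expect_equal(steady_growth_rate(prm, ss, 5), 0.4)
  # at the old-age balance point the HSC pool plateaus
  spec <- paper_like_spec()
  fr <- make_fraction_fun(spec$trajectory, spec$thresholds)
  expect_lt(abs(steady_growth_rate(spec$ode_params, fr, 70)), 0.005)
})
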