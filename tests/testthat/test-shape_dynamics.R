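test_that("trajectory evaluation matches closed forms", {
  traj <- shape_trajectory(t0 = 4, alpha = c(3, 1, 1, 0), beta = c(2, 1, 1, 0),
                           check_positive = numeric(0))
  at_t0 <- eval_trajectory(traj, 4)
  expect_equal(at_t0$alpha, 4)  # b1 + b2
  expect_equal(at_t0$beta, 3)
  at_ln2 <- eval_trajectory(traj, 4 + log(2))
  expect_equal(at_ln2$alpha, 3 * 0.5 + 1)  # 2.5
  expect_error(eval_trajectory(traj, 3.9), "domain error")
})

test_that("trajectories with positive rates decay monotonically to zero", {
  traj <- shape_trajectory(t0 = 0, alpha = c(2, 0.5, 1, 0.01),
                           beta = c(1, 0.3, 0.5, 0.02),
                           check_positive = numeric(0))
  tt <- seq(0, 2500, by = 5)
  a <- eval_trajectory(traj, tt)$alpha
  expect_true(all(diff(a) < 0))
  expect_lt(a[length(a)], 1e-6)
  expect_true(all(is.finite(eval_trajectory(traj, seq(0, 100, 0.5))$alpha)))
})

test_that("parameter permutation leaves the evaluated curve unchanged", {
  t <- seq(4, 72, by = 2)
  traj1 <- shape_trajectory(4, alpha = c(0.9, 0.3, 0.28, 0.005),
                            beta = c(0.06, 0.3, 0.21, 0.002))
  traj2 <- shape_trajectory(4, alpha = c(0.28, 0.005, 0.9, 0.3),
                            beta = c(0.21, 0.002, 0.06, 0.3))
  expect_equal(eval_trajectory(traj1, t), eval_trajectory(traj2, t))
  # ordering convention: fast component stored first
  expect_gte(traj2$alpha[["a1"]], traj2$alpha[["a2"]])
})

test_that("noise-free estimates are recovered to numerical precision", {
  truth <- paper_like_spec()$trajectory
  ages <- c(4, 5, 6, 7, 8, 9, 15, 20, 22, 48, 52)
  ab <- eval_trajectory(truth, ages)
  est <- data.frame(age_weeks = ages, alpha = ab$alpha, beta = ab$beta)
  fit <- fit_trajectory(est)
  got <- eval_trajectory(fit, ages)
  expect_equal(got$alpha, ab$alpha, tolerance = 1e-6)
  expect_equal(got$beta, ab$beta, tolerance = 1e-6)
})

test_that("single-exponential truth is recovered through the nested start", {
  ages <- c(4, 6, 9, 15, 25, 40, 60)
  y <- 1.4 * exp(-0.08 * (ages - 4))
  est <- data.frame(age_weeks = ages, alpha = y, beta = y / 2)
  fit <- fit_trajectory(est)
  got <- eval_trajectory(fit, ages)
  expect_equal(got$alpha, y, tolerance = 1e-6)
  expect_equal(got$beta, y / 2, tolerance = 1e-6)
})

test_that("5% relative noise keeps the fitted curve within 15% of truth", {
  truth <- paper_like_spec()$trajectory
  ages <- c(4, 5, 6, 7, 8, 9, 15, 20, 22, 48, 52)
  ab <- eval_trajectory(truth, ages)
  set.seed(31)
  est <- data.frame(age_weeks = ages,
                    alpha = ab$alpha * (1 + 0.05 * rnorm(length(ages))),
                    beta = ab$beta * (1 + 0.05 * rnorm(length(ages))))
  fit <- suppressWarnings(fit_trajectory(est))
  got <- eval_trajectory(fit, ages)
  expect_lt(max(abs(got$alpha / ab$alpha - 1)), 0.15)
  expect_lt(max(abs(got$beta / ab$beta - 1)), 0.15)
})

test_that("biexponential SSR never exceeds the best single-exponential SSR", {
  ages <- c(4, 5, 7, 10, 15, 22, 35, 52)
  set.seed(12)
  for (k in 1:5) {
    y <- 0.8 * exp(-0.2 * (ages - 4)) + 0.3 * exp(-0.01 * (ages - 4)) +
      0.03 * rnorm(length(ages))
    est <- data.frame(age_weeks = ages, alpha = abs(y), beta = abs(y))
    fit <- suppressWarnings(fit_trajectory(est))
    # single-exponential reference by its own profiled least squares
    sing <- optim(c(abs(y[1]), 0.1), function(p)
      sum((abs(y) - p[1] * exp(-p[2] * (ages - 4)))^2),
      control = list(reltol = 1e-14, maxit = 5000))
    expect_lte(attr(fit, "ssr_alpha"), sing$value + 1e-10)
  }
})

test_that("trajectory fitting validates its preconditions", {
  est <- data.frame(age_weeks = c(4, 5, 6), alpha = 1:3, beta = 1:3)
  expect_error(fit_trajectory(est), "at least 4 distinct ages")
  est4 <- data.frame(age_weeks = c(4, 5, 6, 7), alpha = rep(1, 4),
                     beta = rep(1, 4))
  expect_error(fit_trajectory(est4, t0 = 5), "smallest")
})
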