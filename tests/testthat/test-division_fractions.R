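test_that("threshold constructor enforces the 0.1 grid and ordering", {
  thr <- division_thresholds(0.3, 0.8)
  expect_equal(thr$c1, 0.3)
  expect_error(division_thresholds(0.8, 0.3), "strictly less")
  expect_error(division_thresholds(0.35, 0.8), "domain error")
  expect_error(division_thresholds(0, 0.8), "domain error")
})

test_that("bin masses are uniform widths under Beta(1,1) and normalize", {
  u <- const_trajectory(1, 1)
  expect_equal(discretized_bin_mass(u, 5, 0.3), 0.1)
  b <- const_trajectory(2.3, 0.7)
  masses <- vapply(seq(0, 0.9, 0.1),
                   function(x) discretized_bin_mass(b, 5, x), numeric(1))
  expect_equal(sum(masses), 1, tolerance = 1e-12)
  expect_error(discretized_bin_mass(b, 5, 0.35), "domain error")
})

test_that("first bin mass matches numerical quadrature of the density", {
  traj <- const_trajectory(2, 5)
  q <- integrate(function(x) dbeta(x, 2, 5), 0, 0.1, rel.tol = 1e-12)$value
  expect_equal(discretized_bin_mass(traj, 1, 0.0), q, tolerance = 1e-10)
})

test_that("discretized cumulative equals the continuous CDF (telescoping)", {
  u <- const_trajectory(1, 1)
  expect_equal(cumulative_below(u, 2, 0.3), 0.3, tolerance = 1e-14)
  set.seed(2024)
  for (k in 1:25) {
    a <- exp(runif(1, -2, 2)); b <- exp(runif(1, -2, 2))
    traj <- const_trajectory(a, b)
    c <- sample(seq(0.1, 0.9, 0.1), 1)
    expect_equal(cumulative_below(traj, 1, c), pbeta(c, a, b),
                 tolerance = 1e-12)
  }
  # complement at the top of the grid
  traj <- const_trajectory(0.4, 0.3)
  expect_equal(cumulative_below(traj, 1, 0.9),
               1 - discretized_bin_mass(traj, 1, 0.9), tolerance = 1e-12)
})

test_that("uniform distribution yields the closed-form fraction split", {
  u <- const_trajectory(1, 1)
  fr <- division_fractions_at(u, 3, division_thresholds(0.3, 0.8))
  expect_equal(fr$p, 0.2)
  expect_equal(fr$q, 0.5)
  expect_equal(fr$pp, 0.3)
})

test_that("fractions form a probability vector with threshold monotonicity", {
  traj <- paper_like_spec()$trajectory
  set.seed(5)
  for (k in 1:20) {
    t <- runif(1, 4, 72)
    c1 <- round(sample(seq(0.1, 0.7, 0.1), 1), 1)
    c2 <- round(sample(seq(c1 + 0.1, 0.9, 0.1), 1), 1)
    fr <- division_fractions_at(traj, t, division_thresholds(c1, c2))
    expect_equal(fr$p + fr$q + fr$pp, 1, tolerance = 1e-12)
    expect_true(all(c(fr$p, fr$q, fr$pp) >= 0))
    if (c2 < 0.85) {  # p nonincreasing in c2, pp nondecreasing in c1
      fr2 <- division_fractions_at(traj, t,
                                   division_thresholds(c1, c2 + 0.1))
      expect_lte(fr2$p, fr$p + 1e-15)
      expect_gte(fr2$pp, fr$pp - 1e-15)
    }
  }
})

test_that("mass concentrated near 1 drives the S-S fraction to 1", {
  traj <- const_trajectory(500, 1)
  fr <- division_fractions_at(traj, 1, division_thresholds(0.3, 0.8))
  expect_gt(fr$p, 0.999)
})

test_that("fraction time course is smooth, normalized and age-decreasing in S-S", {
  traj <- paper_like_spec()$trajectory
  thr <- division_thresholds(0.3, 0.8)
  tc <- fraction_timecourse(traj, thr, seq(4, 72, by = 0.5))
  expect_equal(tc$p_ss + tc$q_sp + tc$pp, rep(1, nrow(tc)), tolerance = 1e-12)
  expect_lt(max(abs(diff(tc$p_ss))), 0.02)  # no jumps on a 0.5-week grid
  at <- fraction_timecourse(traj, thr, c(10, 70))
  expect_lt(at$p_ss[2], at$p_ss[1])  # self-renewal declines with age
  expect_gt(at$pp[2], at$pp[1])      # symmetric differentiation rises

  const <- fraction_timecourse(const_trajectory(2, 3), thr, 1:10)
  expect_equal(var(const$p_ss), 0)
})

test_that("the calibrated truth reproduces the reference fractions", {
  # generator calibration anchors: 52.4%/24.9% at 10 wk, 41.6%/41.5% at 70 wk
  tc <- fraction_timecourse(paper_like_spec()$trajectory,
                            division_thresholds(0.3, 0.8), c(10, 70))
  expect_equal(tc$p_ss, c(0.524, 0.416), tolerance = 1e-6)
  expect_equal(tc$pp, c(0.249, 0.415), tolerance = 1e-6)
})
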