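# shared fixtures: tiny trajectories and in-memory CSV round trips

# trajectory that evaluates to a fixed Beta(alpha, beta) at every age
const_trajectory <- function(alpha, beta, t0 = 0) {
  shape_trajectory(t0 = t0,
                   alpha = c(b1 = alpha, a1 = 0, b2 = 0, a2 = 0),
                   beta = c(b1 = beta, a1 = 0, b2 = 0, a2 = 0),
                   check_positive = numeric(0))
}

# write a data frame to a temp CSV and return the path
tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# small, fast MCMC settings for tests
fast_cfg <- function(...) {
  fit_config(mcmc = list(n_chains = 2L, n_steps = 3000L, n_burn = 1000L,
                         seed = 1L), ...)
}

# a smooth random fraction schedule (p, q, pp all smooth, summing to 1)
random_fraction_fun <- function(coefs) {
  force(coefs)
  function(t) {
    u1 <- exp(sin(coefs[1] * t + coefs[2]))
    u2 <- exp(sin(coefs[3] * t + coefs[4]))
    u3 <- exp(sin(coefs[5] * t + coefs[6]))
    s <- u1 + u2 + u3
    list(p = u1 / s, q = u2 / s, pp = u3 / s)
  }
}
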