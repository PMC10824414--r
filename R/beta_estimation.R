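#' Clamp boundary proportions into the open unit interval
#'
#' Likelihoods under a beta density are undefined at exactly 0 or 1, so wells
#' in which no (or only) CD201+CD150+KSL cells were detected are mapped to
#' 0.001 and 0.999 respectively before maximum-likelihood fitting. Interior
#' values pass through unchanged.
#'
#' @param xs Numeric vector of proportions in \[0, 1\].
#' @param lower,upper Replacement values for exact 0 and exact 1.
#' @return Numeric vector of the same length, strictly inside (0, 1) whenever
#'   the inputs were in \[0, 1\].
#' @export
clamp_proportions <- function(xs, lower = 0.001, upper = 0.999) {
  bad <- which(!is.finite(xs) | xs < 0 | xs > 1)
  if (length(bad))
    stop("validation error: proportion outside [0, 1] at position(s) ",
         paste(bad, collapse = ", "))
  xs[xs == 0] <- lower
  xs[xs == 1] <- upper
  xs
}

#' Maximum-likelihood fit of a beta distribution
#'
#' Maximizes the beta log-likelihood in (log alpha, log beta), which keeps
#' both shapes positive without explicit constraints. The optimizer starts at
#' the method-of-moments estimate plus a fixed sequence of deterministic
#' jittered restarts, so the fit is reproducible. Convergence is accepted when
#' the gradient norm of the log-likelihood falls below `grad_tol`.
#'
#' @param xs Numeric vector, length >= 2, strictly inside (0, 1)
#'   (apply [clamp_proportions()] first).
#' @param grad_tol Gradient-norm tolerance at the reported optimum.
#' @return A list with elements `alpha`, `beta`, `log_likelihood` and `n`.
#' @export
fit_beta_mle <- function(xs, grad_tol = 1e-6) {
  if (length(xs) < 2L) stop("need at least 2 observations")
  if (any(xs <= 0 | xs >= 1))
    stop("observations must lie strictly inside (0, 1); clamp first")
  if (stats::var(xs) == 0)
    stop("degenerate sample: all observations identical, likelihood unbounded")

  n <- length(xs)
  slx <- sum(log(xs))
  sl1x <- sum(log1p(-xs))
  negll <- function(lp) {
    a <- exp(lp[1]); b <- exp(lp[2])
    -(n * (lgamma(a + b) - lgamma(a) - lgamma(b)) +
        (a - 1) * slx + (b - 1) * sl1x)
  }
  grad_ab <- function(a, b) {
    # d loglik / d(alpha, beta) on the natural scale
    c(n * (digamma(a + b) - digamma(a)) + slx,
      n * (digamma(a + b) - digamma(b)) + sl1x)
  }

  mom <- beta_mom(xs)
  # deterministic restart sequence around the moment estimate
  starts <- list(log(mom),
                 log(mom) + c(0.5, -0.5),
                 log(mom) + c(-0.5, 0.5),
                 log(mom) + c(1, 1))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s, negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(o)) next
    # Newton-free polish with Nelder-Mead in case BFGS stalled
    o2 <- stats::optim(o$par, negll, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-15))
    if (o2$value < o$value) o <- o2
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("beta MLE failed to converge from all starts")
  a <- unname(exp(best$par[1])); b <- unname(exp(best$par[2]))
  # Newton polish on the natural scale (exact gradient and Hessian)
  for (i in 1:50) {
    g <- grad_ab(a, b)
    if (sqrt(sum(g^2)) < 1e-10 * max(1, n)) break
    H <- n * rbind(c(trigamma(a + b) - trigamma(a), trigamma(a + b)),
                   c(trigamma(a + b), trigamma(a + b) - trigamma(b)))
    step <- tryCatch(-solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    while (lam > 1e-8 && (a + lam * step[1] <= 0 || b + lam * step[2] <= 0))
      lam <- lam / 2
    a2 <- a + lam * step[1]; b2 <- b + lam * step[2]
    if (!is.finite(a2) || !is.finite(b2) || a2 <= 0 || b2 <= 0) break
    if (negll(log(c(a2, b2))) > negll(log(c(a, b))) + 1e-12 * n) break
    a <- a2; b <- b2
  }
  g <- grad_ab(a, b)
  if (sqrt(sum(g^2)) > grad_tol * max(1, n))
    stop("beta MLE did not reach a stationary point (|grad| = ",
         format(sqrt(sum(g^2))), ") after bounded restarts")
  list(alpha = unname(a), beta = unname(b),
       log_likelihood = -negll(log(c(a, b))), n = n)
}

## method-of-moments shapes, floored away from 0
beta_mom <- function(xs) {
  m <- mean(xs); v <- stats::var(xs)
  v <- min(v, m * (1 - m) * 0.999)  # keep the common factor positive
  k <- m * (1 - m) / v - 1
  c(alpha = max(m * k, 1e-3), beta = max((1 - m) * k, 1e-3))
}

#' Fit one beta distribution per age group
#'
#' Pools all wells across mice within each age, clamps boundary values, and
#' fits the shape pair (alpha_t, beta_t) by maximum likelihood. Ages with
#' fewer than two wells cannot be fitted and are skipped with a warning.
#'
#' @param table Well-proportion data frame as returned by
#'   [read_well_proportions()] or [generate_wells()].
#' @return A data frame, one row per fitted age, ordered by age ascending,
#'   with columns `age_weeks`, `alpha`, `beta`, `log_likelihood`, `n_wells`.
#' @export
fit_all_ages <- function(table) {
  validate_well_proportions(table)
  ages <- sort(unique(table$age_weeks))
  rows <- lapply(ages, function(a) {
    xs <- table$proportion[table$age_weeks == a]
    if (length(xs) < 2L) {
      warning("age ", a, " weeks has ", length(xs),
              " well(s); at least 2 required, skipping", call. = FALSE)
      return(NULL)
    }
    fit <- fit_beta_mle(clamp_proportions(xs))
    data.frame(age_weeks = a, alpha = fit$alpha, beta = fit$beta,
               log_likelihood = fit$log_likelihood, n_wells = fit$n)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no age group had at least 2 wells")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
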