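# Independent oracles used across the suite.  These deliberately avoid the
# package's optimizer and cdf code paths: densities are re-stated from the
# mass-allocation formula, maxima are located by exhaustive grid search.

# Unstandardized mass-allocation density: unit-normal base, mode at 0.
raw_fs_density <- function(eps, shape) {
  2 / (shape + 1 / shape) *
    ifelse(eps >= 0, dnorm(eps / shape), dnorm(shape * eps))
}

# Log-likelihood stated directly from the standardized density formula.
brute_loglik <- function(values, m, s, shape) {
  m1 <- sqrt(2 / pi) * (shape - 1 / shape)
  s1 <- sqrt(shape^2 - 1 + shape^-2 - m1^2)
  eps <- m1 + s1 * (values - m) / s
  sum(log(raw_fs_density(eps, shape) * s1 / s))
}

# Exhaustive 1-D ML over the shape with mean/sd fixed: coarse pass over
# log10(shape) in [-2, 2] at 1e-3 log-spacing, then a local refinement.
oracle_shape_grid <- function(values, m, s) {
  lg <- log(10) * seq(-2, 2, by = 1e-3)
  ll <- vapply(lg, function(l) brute_loglik(values, m, s, exp(l)), numeric(1))
  b <- lg[which.max(ll)]
  # refine locally, but never outside the shape box [0.01, 100]
  lg2 <- seq(max(b - 0.005, log(0.01)), min(b + 0.005, log(100)),
             length.out = 2001)
  ll2 <- vapply(lg2, function(l) brute_loglik(values, m, s, exp(l)),
                numeric(1))
  list(shape = exp(lg2[which.max(ll2)]), logLik = max(ll2),
       coarse_logLik = max(ll))
}

# Exhaustive 2-D ML over (sd, shape) with the mean constrained.
oracle_bounds_grid <- function(values, mu0) {
  s0 <- sd(values)
  ls <- seq(log(s0) - 2, log(s0) + 2, length.out = 161)
  lg <- seq(log(0.01), log(100), length.out = 161)
  best <- c(-Inf, NA, NA)
  for (a in ls) for (g in lg) {
    ll <- brute_loglik(values, mu0, exp(a), exp(g))
    if (ll > best[1]) best <- c(ll, a, g)
  }
  for (r in c(0.05, 0.005, 5e-4, 5e-5)) {
    ls2 <- seq(best[2] - r, best[2] + r, length.out = 41)
    lg2 <- seq(max(best[3] - r, log(0.01)), min(best[3] + r, log(100)),
               length.out = 41)
    for (a in ls2) for (g in lg2) {
      ll <- brute_loglik(values, mu0, exp(a), exp(g))
      if (ll > best[1]) best <- c(ll, a, g)
    }
  }
  list(sd = exp(best[2]), shape = exp(best[3]), logLik = best[1])
}

# Closed-form normal-normal conjugate posterior for the mean.
conjugate_posterior <- function(prior_mean, prior_sd, y, likelihood_sd) {
  w_prior <- 1 / prior_sd^2
  w_data <- length(y) / likelihood_sd^2
  list(mean = (w_prior * prior_mean + w_data * mean(y)) / (w_prior + w_data),
       sd = sqrt(1 / (w_prior + w_data)))
}
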