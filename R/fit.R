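#' Log-likelihood of a value vector under a skew normal
#'
#' Sum of log densities of `values` under `dist`.  If any density
#' underflows to zero the result is `-Inf`, propagated explicitly.
#'
#' @param values nonempty numeric vector of elicited values.
#' @param dist a [skewnorm()] object.
#' @return a single number (possibly `-Inf`).
#' @examples
#' sn_loglik(0, skewnorm(0, 1, 1))  # log standard-normal density at 0
#' @export
sn_loglik <- function(values, dist) {
  stopifnot(inherits(dist, "skewnorm"))
  if (length(values) == 0) stop("'values' must be nonempty", call. = FALSE)
  if (!all(is.finite(values))) stop("'values' must be finite", call. = FALSE)
  sum(dskewnorm(values, dist$mean, dist$sd, dist$shape, log = TRUE))
}

#' Constrained maximum-likelihood fit of the skew normal
#'
#' The central estimator of the elicitation pipeline.  Two constraint
#' patterns are supported, matching the two fitting stages of the
#' protocol:
#'
#' * `mean = NULL` (location stage): the returned mean and sd are the
#'   sample mean and sample standard deviation (denominator `n - 1`) of
#'   `values`, held fixed exactly, and only the shape \eqn{\gamma} is
#'   estimated by maximizing the log-likelihood over
#'   \eqn{\log\gamma \in [\log 0.01, \log 100]}.
#' * `mean = mu0` (uncertainty stage): the distribution mean is
#'   constrained to `mu0` exactly and scale and shape are estimated
#'   jointly, by a coarse grid over \eqn{(\log\sigma, \log\gamma)}
#'   followed by box-constrained quasi-Newton refinement.
#'
#' Because the family is moment-standardized, "mean" and "sd" here are
#' the true moments of the fitted distribution, not the location and
#' scale of the raw skewing construction.
#'
#' @param values numeric vector with at least 2 distinct finite values.
#' @param mean optional fixed distribution mean (the elicited location
#'   \eqn{\mu_0}); `NULL` fixes mean and sd at the sample moments.
#' @param shape_range search interval for \eqn{\gamma} (default
#'   `c(0.01, 100)`).
#' @return an object of class `"snorm_fit"`: a list with components
#'   `dist` (the fitted [skewnorm()]), `coefficients` (named vector
#'   `mean`, `sd`, `shape`), `logLik`, `n`, `values`, `constraint`
#'   (`"moments"` or `"mean"`) and `call`.
#' @examples
#' fit <- snorm_fit(rskewnorm(500, 5, 2, 2, seed = 1))
#' coef(fit)
#' summary(fit)
#' @seealso [fit_bounds()] for the bounds-based uncertainty stage,
#'   [chips_to_values()] for the chip-based location stage.
#' @export
snorm_fit <- function(values, mean = NULL, shape_range = c(0.01, 100)) {
  cl <- match.call()
  values <- as.numeric(values)
  if (length(values) < 2 || !all(is.finite(values)))
    stop("'values' must hold at least 2 finite values", call. = FALSE)
  if (length(unique(values)) < 2)
    stop("degenerate input: all values identical (zero sample variance)",
         call. = FALSE)
  lg_lo <- log(shape_range[1]); lg_hi <- log(shape_range[2])
  nll_at <- function(m, s, g) {
    ll <- sum(dskewnorm(values, m, s, g, log = TRUE))
    if (is.finite(ll)) -ll else 1e10
  }
  # 1-D minimization robust to the kinks the likelihood has wherever a
  # sample value crosses the mode: coarse grid, then golden section in
  # the bracketing interval
  refine1d <- function(f, lo, hi, n = 401) {
    xs <- seq(lo, hi, length.out = n)
    fs <- vapply(xs, f, numeric(1))
    i <- which.min(fs)
    opt <- stats::optimize(f, c(xs[max(i - 1, 1)], xs[min(i + 1, n)]),
                           tol = 1e-9)
    if (opt$objective <= fs[i]) opt$minimum else xs[i]
  }

  if (is.null(mean)) {
    m <- base::mean(values)
    s <- stats::sd(values)
    shape <- exp(refine1d(function(lg) nll_at(m, s, exp(lg)), lg_lo, lg_hi))
    constraint <- "moments"
  } else {
    if (length(mean) != 1L || !is.finite(mean))
      stop("'mean' must be a single finite number", call. = FALSE)
    m <- as.numeric(mean)
    s0 <- stats::sd(values)
    # coarse grid start, then box-constrained refinement
    ls_grid <- seq(log(s0) - 2, log(s0) + 2, length.out = 25)
    lg_grid <- seq(lg_lo, lg_hi, length.out = 41)
    grid <- expand.grid(ls = ls_grid, lg = lg_grid)
    vals <- mapply(function(ls, lg) nll_at(m, exp(ls), exp(lg)),
                   grid$ls, grid$lg)
    start <- as.numeric(grid[which.min(vals), ])
    fn <- function(p) {
      if (p[2] < lg_lo || p[2] > lg_hi) return(1e10)
      nll_at(m, exp(p[1]), exp(p[2]))
    }
    opt <- stats::optim(start, fn, method = "L-BFGS-B",
                        lower = c(log(s0) - 6, lg_lo),
                        upper = c(log(s0) + 6, lg_hi),
                        control = list(factr = 10, pgtol = 1e-12))
    par <- opt$par
    # coordinate-wise polish: reliable at kinks and on the shape box
    # boundary, where quasi-Newton steps stall
    for (sweep in 1:3) {
      par[1] <- refine1d(function(ls) nll_at(m, exp(ls), exp(par[2])),
                         log(s0) - 6, log(s0) + 6)
      par[2] <- refine1d(function(lg) nll_at(m, exp(par[1]), exp(lg)),
                         lg_lo, lg_hi)
    }
    if (fn(par) > opt$value) par <- opt$par
    s <- exp(par[1])
    shape <- exp(par[2])
    constraint <- "mean"
  }
  dist <- skewnorm(m, s, shape)
  structure(list(
    dist = dist,
    coefficients = c(mean = m, sd = s, shape = shape),
    logLik = sn_loglik(values, dist),
    n = length(values),
    values = values,
    constraint = constraint,
    call = cl
  ), class = "snorm_fit")
}

#' Bounds sample for the uncertainty stage
#'
#' Deterministic weighted sample encoding a location estimate with its
#' reasonable bounds: the location `mu0` repeated `n_center` times,
#' followed by the lower bound and the upper bound each repeated
#' `n_bound` times (100/10/10 by default, length 120).
#'
#' @param mu0 location estimate; must satisfy `lower < mu0 < upper`.
#' @param lower,upper reasonable lower and upper bound for the estimate.
#' @param n_center,n_bound repeat counts, both >= 1.
#' @return numeric vector of length `n_center + 2 * n_bound`, in the
#'   order centers, lowers, uppers.
#' @examples
#' table(bounds_sample(10, 8, 14))
#' @export
bounds_sample <- function(mu0, lower, upper, n_center = 100, n_bound = 10) {
  if (!all(is.finite(c(mu0, lower, upper))))
    stop("'mu0', 'lower', 'upper' must be finite", call. = FALSE)
  if (!(lower < mu0 && mu0 < upper))
    stop("bounds must bracket the estimate: lower < mu0 < upper",
         call. = FALSE)
  if (n_center < 1 || n_bound < 1)
    stop("'n_center' and 'n_bound' must be >= 1", call. = FALSE)
  c(rep(mu0, n_center), rep(lower, n_bound), rep(upper, n_bound))
}

#' Fit a full prior from a location estimate and reasonable bounds
#'
#' The uncertainty stage of the protocol: builds the weighted
#' [bounds_sample()] and fits scale and shape by maximum likelihood with
#' the distribution mean constrained to `mu0` exactly (see
#' [snorm_fit()]).  Symmetric bounds give shape ~ 1; an upper bound
#' farther from `mu0` than the lower bound gives right skew
#' (shape > 1).
#'
#' @inheritParams bounds_sample
#' @param shape_range passed to [snorm_fit()].
#' @return an `"snorm_fit"` object whose `dist` has mean exactly `mu0`.
#' @examples
#' coef(fit_bounds(10, 8, 14))
#' @export
fit_bounds <- function(mu0, lower, upper, n_center = 100, n_bound = 10,
                       shape_range = c(0.01, 100)) {
  snorm_fit(bounds_sample(mu0, lower, upper, n_center, n_bound),
            mean = mu0, shape_range = shape_range)
}
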