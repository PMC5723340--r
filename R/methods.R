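# S3 methods for "snorm_fit" objects.

#' @export
print.snorm_fit <- function(x, digits = 4, ...) {
  cat("Skew normal fit (",
      if (x$constraint == "moments")
        "mean and sd fixed at sample moments" else "mean constrained",
      ")\n", sep = "")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  print(round(x$coefficients, digits))
  cat("log-likelihood:", format(x$logLik, digits = digits),
      " n =", x$n, "\n")
  invisible(x)
}

#' @export
coef.snorm_fit <- function(object, ...) object$coefficients

#' @export
logLik.snorm_fit <- function(object, ...) {
  structure(object$logLik,
            df = if (object$constraint == "moments") 1L else 2L,
            nobs = object$n, class = "logLik")
}

#' @export
summary.snorm_fit <- function(object, ...) {
  d <- object$dist
  probs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  out <- list(
    coefficients = object$coefficients,
    constraint = object$constraint,
    logLik = object$logLik,
    n = object$n,
    mode = sn_mode(d),
    quantiles = stats::setNames(
      qskewnorm(probs, d$mean, d$sd, d$shape),
      paste0(100 * probs, "%")),
    call = object$call
  )
  class(out) <- "summary.snorm_fit"
  out
}

#' @export
print.summary.snorm_fit <- function(x, digits = 4, ...) {
  cat("Skew normal fit (constraint: ", x$constraint, ")\n", sep = "")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  print(round(x$coefficients, digits))
  cat("mode:", format(x$mode, digits = digits),
      "  log-likelihood:", format(x$logLik, digits = digits),
      "  n =", x$n, "\n\nQuantiles:\n")
  print(round(x$quantiles, digits))
  invisible(x)
}

#' @export
quantile.snorm_fit <- function(x, probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                               ...) {
  d <- x$dist
  stats::setNames(qskewnorm(probs, d$mean, d$sd, d$shape),
                  paste0(format(100 * probs, trim = TRUE), "%"))
}

#' @export
simulate.snorm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  d <- object$dist
  rskewnorm(nsim, d$mean, d$sd, d$shape, seed = seed)
}

#' Quantile residuals of a skew normal fit
#'
#' Normal quantile residuals `qnorm(F(x))` of the fitted distribution at
#' the input values; approximately standard normal when the fit is
#' adequate.
#' @param object an `"snorm_fit"` object.
#' @param ... unused.
#' @export
residuals.snorm_fit <- function(object, ...) {
  d <- object$dist
  stats::qnorm(pskewnorm(object$values, d$mean, d$sd, d$shape))
}

#' @export
plot.snorm_fit <- function(x, n_points = 400, ...) {
  d <- x$dist
  lo <- min(x$values, qskewnorm(0.001, d$mean, d$sd, d$shape))
  hi <- max(x$values, qskewnorm(0.999, d$mean, d$sd, d$shape))
  xs <- seq(lo, hi, length.out = n_points)
  graphics::hist(x$values, freq = FALSE, breaks = "FD",
                 main = "Skew normal fit", xlab = "value",
                 border = "grey70", ...)
  graphics::lines(xs, dskewnorm(xs, d$mean, d$sd, d$shape), lwd = 2,
                  col = "steelblue")
  graphics::abline(v = d$mean, lty = 2, col = "grey40")
  invisible(x)
}
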