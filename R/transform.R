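#' Linear scale specifications
#'
#' Experts are free to reason on whatever scale suits them (per product,
#' per product type, per region, totals).  A scale spec records the
#' linear map \eqn{\theta^* = a\theta + b} from that expert scale to a
#' common reference scale, so a panel elicited on mixed scales can be
#' harmonized afterwards.  Under this map a distribution's mean becomes
#' \eqn{a\mu + b} and its sd \eqn{|a|\sigma}; the skewness parameter is
#' unchanged for `a > 0` and reciprocal for `a < 0` (mirror).
#'
#' @param a multiplier, finite and nonzero (e.g. the number of units
#'   aggregated).
#' @param b offset, finite (default 0).
#' @param label scale name, kept for audit trails.
#' @return an object of class `"scale_spec"`.
#' @examples
#' per_product <- scale_spec(104, label = "per product")
#' transform_estimate(1.8, per_product)          # total: 187.2
#' @export
scale_spec <- function(a, b = 0, label = "") {
  if (length(a) != 1L || !is.finite(a) || a == 0)
    stop("'a' must be a single finite nonzero number", call. = FALSE)
  if (length(b) != 1L || !is.finite(b))
    stop("'b' must be a single finite number", call. = FALSE)
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 label = as.character(label)),
            class = "scale_spec")
}

#' @export
print.scale_spec <- function(x, ...) {
  cat(sprintf("Scale spec%s: theta* = %g * theta + %g\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$a, x$b))
  invisible(x)
}

#' Transform a point estimate between scales
#'
#' Applies `a * theta + b` (or its inverse when `inverse = TRUE`).
#'
#' @param theta numeric estimate(s) on the expert scale.
#' @param spec a [scale_spec()].
#' @param inverse if TRUE, map from the reference scale back to the
#'   expert scale.
#' @return transformed numeric value(s).
#' @export
transform_estimate <- function(theta, spec, inverse = FALSE) {
  stopifnot(inherits(spec, "scale_spec"))
  if (inverse) (theta - spec$b) / spec$a else spec$a * theta + spec$b
}

#' Transform a skew normal distribution between scales
#'
#' Affine closure of the moment-standardized family: the mean maps to
#' `a * mean + b`, the sd to `|a| * sd`, and the shape is preserved for
#' `a > 0` or inverted (`1/shape`, the mirror image) for `a < 0`.  A
#' sample pushed through the affine map is distributed exactly as the
#' transformed distribution.
#'
#' @param dist a [skewnorm()] object.
#' @inheritParams transform_estimate
#' @return a transformed [skewnorm()] object.
#' @export
transform_distribution <- function(dist, spec, inverse = FALSE) {
  stopifnot(inherits(dist, "skewnorm"), inherits(spec, "scale_spec"))
  a <- spec$a; b <- spec$b
  if (inverse) { b <- -spec$b / spec$a; a <- 1 / spec$a }
  skewnorm(mean = a * dist$mean + b,
           sd = abs(a) * dist$sd,
           shape = if (a > 0) dist$shape else 1 / dist$shape)
}

#' Re-express a record on another scale
#'
#' Converts a point estimate or a [skewnorm()] distribution stated on
#' scale `from` to scale `to`, routing through the common reference
#' scale: first `a*theta + b` with `from`, then the inverse map of `to`.
#'
#' @param x a numeric estimate or a [skewnorm()] object.
#' @param from,to [scale_spec()] objects; each maps its scale to the
#'   common reference scale.
#' @return `x` expressed on the `to` scale, same type as the input.
#' @export
convert_scale <- function(x, from, to) {
  stopifnot(inherits(from, "scale_spec"), inherits(to, "scale_spec"))
  if (inherits(x, "skewnorm")) {
    transform_distribution(transform_distribution(x, from), to,
                           inverse = TRUE)
  } else {
    transform_estimate(transform_estimate(x, from), to, inverse = TRUE)
  }
}

#' Harmonize a panel of experts onto a common scale
#'
#' Each expert's record (a point estimate or an elicited [skewnorm()])
#' stated on its own scale is re-expressed on the target scale; order is
#' preserved and the original scale labels are kept as an attribute for
#' audit.
#'
#' @param values list (or numeric vector) of records; each element a
#'   number or a [skewnorm()].
#' @param scales a single [scale_spec()] or a list of them, one per
#'   record.
#' @param target the [scale_spec()] of the common scale.
#' @return a list (or numeric vector, when all records are numeric) of
#'   harmonized records with attribute `"source_labels"`.
#' @examples
#' pp <- scale_spec(104, label = "per product")
#' pt <- scale_spec(9, label = "per type")
#' harmonize_panel(list(1.8, 2.1, 23, 24.5),
#'                 list(pp, pp, pt, pt), target = pp)
#' @export
harmonize_panel <- function(values, scales, target) {
  stopifnot(inherits(target, "scale_spec"))
  values <- as.list(values)
  if (inherits(scales, "scale_spec")) scales <- rep(list(scales),
                                                    length(values))
  if (length(scales) != length(values))
    stop("'scales' must match 'values' in length", call. = FALSE)
  out <- mapply(function(v, s) convert_scale(v, s, target), values, scales,
                SIMPLIFY = FALSE)
  labels <- vapply(scales, function(s) s$label, character(1))
  if (all(vapply(out, is.numeric, logical(1)))) out <- unlist(out)
  attr(out, "source_labels") <- labels
  out
}
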