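#' Elicitation records and expert panels
#'
#' An `elicitation_record` is one expert's audit-trailed pass through the
#' elicitation: the chip grid and location fit (if the expert used the
#' roulette), the bounds input and resulting prior, the scale the expert
#' reasoned on, and a log of every adjust/re-fit iteration.  An
#' `expert_panel` collects records for experts d = 1..D on a common
#' scale, optionally together with a posterior summary for comparison.
#'
#' @param expert_id unique expert identifier.
#' @param scale the [scale_spec()] the expert reasoned on.
#' @param step1_grid optional [roulette_grid()].
#' @param step2_fit optional `"snorm_fit"` from the location stage.
#' @param step2_accepted logical; did the expert accept the location fit.
#' @param step3_bounds optional list with `mu0`, `lower`, `upper` (on the
#'   common scale).
#' @param step4_prior optional [skewnorm()] prior; requires
#'   `step3_bounds`.
#' @param iterations list logging each adjust/re-fit cycle (elements
#'   `step`, `inputs`, `fit`).
#' @return an object of class `"elicitation_record"` /
#'   `"expert_panel"`.
#' @export
elicitation_record <- function(expert_id, scale,
                               step1_grid = NULL, step2_fit = NULL,
                               step2_accepted = FALSE,
                               step3_bounds = NULL, step4_prior = NULL,
                               iterations = list()) {
  stopifnot(inherits(scale, "scale_spec"))
  if (!is.null(step1_grid)) stopifnot(inherits(step1_grid, "roulette_grid"))
  if (!is.null(step2_fit)) stopifnot(inherits(step2_fit, "snorm_fit"))
  if (!is.null(step4_prior)) {
    stopifnot(inherits(step4_prior, "skewnorm"))
    if (is.null(step3_bounds))
      stop("'step4_prior' requires 'step3_bounds'", call. = FALSE)
  }
  if (!is.null(step3_bounds)) {
    need <- c("mu0", "lower", "upper")
    if (!all(need %in% names(step3_bounds)))
      stop("'step3_bounds' needs fields mu0, lower, upper", call. = FALSE)
    if (!(step3_bounds$lower < step3_bounds$mu0 &&
          step3_bounds$mu0 < step3_bounds$upper))
      stop("'step3_bounds' must satisfy lower < mu0 < upper", call. = FALSE)
  }
  structure(list(expert_id = as.character(expert_id), scale = scale,
                 step1_grid = step1_grid, step2_fit = step2_fit,
                 step2_accepted = isTRUE(step2_accepted),
                 step3_bounds = step3_bounds, step4_prior = step4_prior,
                 iterations = iterations),
            class = "elicitation_record")
}

#' @export
print.elicitation_record <- function(x, ...) {
  cat("Elicitation record for expert", x$expert_id, "\n")
  cat("  scale:", if (nzchar(x$scale$label)) x$scale$label else
      sprintf("a=%g b=%g", x$scale$a, x$scale$b), "\n")
  cat("  location stage:",
      if (is.null(x$step2_fit)) "direct estimate (grid skipped)"
      else sprintf("chip fit, mean %.4g", coef(x$step2_fit)[["mean"]]), "\n")
  if (!is.null(x$step4_prior))
    cat(sprintf("  prior: mean %.4g, sd %.4g, shape %.4g\n",
                x$step4_prior$mean, x$step4_prior$sd, x$step4_prior$shape))
  invisible(x)
}

#' @rdname elicitation_record
#' @param records list of `elicitation_record`s with unique expert ids.
#' @param common_scale the [scale_spec()] all priors are expressed on.
#' @param posterior optional [skewnorm()] posterior summary.
#' @export
expert_panel <- function(records, common_scale, posterior = NULL) {
  stopifnot(inherits(common_scale, "scale_spec"))
  ok <- vapply(records, inherits, logical(1), "elicitation_record")
  if (!all(ok)) stop("'records' must be elicitation_record objects",
                     call. = FALSE)
  ids <- vapply(records, function(r) r$expert_id, character(1))
  if (anyDuplicated(ids)) stop("expert ids must be unique", call. = FALSE)
  if (!is.null(posterior)) stopifnot(inherits(posterior, "skewnorm"))
  structure(list(records = records, common_scale = common_scale,
                 posterior = posterior),
            class = "expert_panel")
}

#' @export
print.expert_panel <- function(x, ...) {
  cat("Expert panel:", length(x$records), "experts on scale",
      if (nzchar(x$common_scale$label)) x$common_scale$label else "reference",
      "\n")
  for (r in x$records)
    if (!is.null(r$step4_prior))
      cat(sprintf("  %s: mean %.4g, sd %.4g, shape %.4g\n", r$expert_id,
                  r$step4_prior$mean, r$step4_prior$sd, r$step4_prior$shape))
  if (!is.null(x$posterior))
    cat(sprintf("  posterior: mean %.4g, sd %.4g, shape %.4g\n",
                x$posterior$mean, x$posterior$sd, x$posterior$shape))
  invisible(x)
}

#' Run the full elicitation pipeline for one expert
#'
#' Batch version of the five-step protocol.  Two entry paths: a chip
#' grid (the location is the mean of the shape-only chip fit) or a
#' direct location estimate `mu0` for experts who reason in the target
#' quantity straight away.  The location is then converted from the
#' expert's scale to the target scale, and the reasonable `bounds`
#' (stated on the target scale) complete the prior via [fit_bounds()].
#' The feedback loops of an interactive session are represented by the
#' `iterations` log: to "adjust", call again with edited inputs.
#'
#' @param grid optional [roulette_grid()] (location path 1).
#' @param mu0 optional direct location estimate on the expert scale
#'   (location path 2); exactly one of `grid`/`mu0` must be given.
#' @param bounds length-2 numeric, reasonable lower/upper bounds for the
#'   transformed location, on the target scale.
#' @param scale [scale_spec()] of the expert's own scale.
#' @param target_scale [scale_spec()] of the common scale for the prior.
#' @param expert_id identifier stored in the record.
#' @return an [elicitation_record()] whose `step4_prior` is the elicited
#'   prior on the target scale.
#' @examples
#' pp <- scale_spec(104, label = "per product")
#' rec <- run_five_steps(mu0 = 1.8, bounds = c(150, 260),
#'                       scale = pp, target_scale = scale_spec(1, label = "total"))
#' rec$step4_prior
#' @export
run_five_steps <- function(grid = NULL, mu0 = NULL, bounds, scale,
                           target_scale, expert_id = "expert") {
  stopifnot(inherits(scale, "scale_spec"),
            inherits(target_scale, "scale_spec"))
  if (is.null(grid) == is.null(mu0))
    stop("supply exactly one of 'grid' (chip path) or 'mu0' (direct path)",
         call. = FALSE)
  if (length(bounds) != 2L || bounds[1] >= bounds[2])
    stop("'bounds' must be c(lower, upper) with lower < upper", call. = FALSE)
  iterations <- list()

  step2_fit <- NULL
  if (!is.null(grid)) {
    values <- tryCatch(chips_to_values(grid), error = function(e)
      stop("step 1 (roulette): ", conditionMessage(e), call. = FALSE))
    step2_fit <- tryCatch(snorm_fit(values), error = function(e)
      stop("step 2 (location fit): ", conditionMessage(e), call. = FALSE))
    loc_own <- coef(step2_fit)[["mean"]]
    iterations <- c(iterations,
                    list(list(step = 2L, inputs = list(n_chips = length(values)),
                              fit = coef(step2_fit))))
  } else {
    loc_own <- as.numeric(mu0)
  }
  loc_target <- convert_scale(loc_own, from = scale, to = target_scale)
  fit4 <- tryCatch(fit_bounds(loc_target, bounds[1], bounds[2]),
                   error = function(e)
                     stop("step 4 (bounds fit): ", conditionMessage(e),
                          call. = FALSE))
  iterations <- c(iterations,
                  list(list(step = 4L,
                            inputs = list(mu0 = loc_target,
                                          lower = bounds[1],
                                          upper = bounds[2]),
                            fit = coef(fit4))))
  elicitation_record(
    expert_id = expert_id, scale = scale,
    step1_grid = grid, step2_fit = step2_fit,
    step2_accepted = !is.null(step2_fit),
    step3_bounds = list(mu0 = loc_target, lower = bounds[1],
                        upper = bounds[2]),
    step4_prior = fit4$dist,
    iterations = iterations)
}

#' Simulate a synthetic expert's chip placements
#'
#' Generates a reproducible chip grid as if an ideally calibrated expert
#' with beliefs `true_dist` had played the roulette: the first two chips
#' are the range-defining chips in the end columns, and the remaining
#' `n_chips - 2` chips are seeded draws from `true_dist` binned to the
#' nearest column (draws outside the range clamp to the end columns).
#' Chips sharing a column stack on successive rows.
#'
#' @param true_dist the generating [skewnorm()].
#' @param n_chips total chips including the two range chips, >= 7.
#' @param lower,upper grid range; must cover at least 99% of
#'   `true_dist`'s mass.
#' @param seed integer seed.
#' @param n_columns,n_rows grid dimensions.
#' @return a [roulette_grid()].
#' @examples
#' g <- simulate_expert(skewnorm(10, 1, 2), n_chips = 50,
#'                      lower = 6, upper = 15, seed = 3)
#' coef(snorm_fit(chips_to_values(g)))
#' @export
simulate_expert <- function(true_dist, n_chips, lower, upper, seed,
                            n_columns = 600, n_rows = 300) {
  stopifnot(inherits(true_dist, "skewnorm"))
  if (n_chips < 7) stop("'n_chips' must be >= 7", call. = FALSE)
  if (missing(seed)) stop("'seed' must be supplied explicitly", call. = FALSE)
  cover <- pskewnorm(upper, true_dist$mean, true_dist$sd, true_dist$shape) -
    pskewnorm(lower, true_dist$mean, true_dist$sd, true_dist$shape)
  if (cover < 0.99)
    stop(sprintf(
      "[lower, upper] covers only %.1f%% of the generating distribution; ",
      100 * cover), ">= 99% is required", call. = FALSE)
  draws <- sn_sample(true_dist, n_chips - 2L, seed = seed)
  cols <- round((draws - lower) / (upper - lower) * (n_columns - 1))
  cols <- pmin(pmax(cols, 0), n_columns - 1)
  cols <- c(0L, n_columns - 1L, as.integer(cols))
  rows <- stats::ave(cols, cols, FUN = seq_along) - 1L
  if (any(rows >= n_rows))
    stop("a column overflowed the grid height", call. = FALSE)
  roulette_grid(data.frame(column = cols, row = as.integer(rows)),
                lower = lower, upper = upper,
                n_columns = n_columns, n_rows = n_rows)
}

# ---- session persistence ------------------------------------------------

.session_version <- "1.0"

.sn_to_list <- function(d) if (is.null(d)) NULL else
  list(mean = d$mean, sd = d$sd, shape = d$shape)
.sn_from_list <- function(l) if (is.null(l)) NULL else
  skewnorm(l$mean, l$sd, l$shape)
.scale_to_list <- function(s) list(a = s$a, b = s$b, label = s$label)
.scale_from_list <- function(l) scale_spec(l$a, l$b, l$label)

.record_to_list <- function(r) {
  list(
    expert_id = r$expert_id,
    scale = .scale_to_list(r$scale),
    step1_grid = if (is.null(r$step1_grid)) NULL else list(
      n_columns = r$step1_grid$n_columns, n_rows = r$step1_grid$n_rows,
      lower = r$step1_grid$lower, upper = r$step1_grid$upper,
      chips = list(column = r$step1_grid$chips$column,
                   row = r$step1_grid$chips$row)),
    step2_fit = if (is.null(r$step2_fit)) NULL else list(
      coefficients = as.list(r$step2_fit$coefficients),
      logLik = r$step2_fit$logLik, n = r$step2_fit$n,
      constraint = r$step2_fit$constraint,
      values = r$step2_fit$values),
    step2_accepted = r$step2_accepted,
    step3_bounds = r$step3_bounds,
    step4_prior = .sn_to_list(r$step4_prior),
    iterations = r$iterations)
}

.record_from_list <- function(l) {
  step2 <- NULL
  if (!is.null(l$step2_fit)) {
    co <- unlist(l$step2_fit$coefficients)
    dist <- skewnorm(co[["mean"]], co[["sd"]], co[["shape"]])
    step2 <- structure(list(
      dist = dist, coefficients = co, logLik = l$step2_fit$logLik,
      n = l$step2_fit$n, values = as.numeric(l$step2_fit$values),
      constraint = l$step2_fit$constraint, call = NULL),
      class = "snorm_fit")
  }
  grid <- NULL
  if (!is.null(l$step1_grid)) {
    g <- l$step1_grid
    g$chips <- data.frame(column = unlist(g$chips$column),
                          row = unlist(g$chips$row))
    grid <- roulette_grid(as.data.frame(g$chips), lower = g$lower,
                          upper = g$upper, n_columns = g$n_columns,
                          n_rows = g$n_rows)
  }
  elicitation_record(
    expert_id = l$expert_id, scale = .scale_from_list(l$scale),
    step1_grid = grid, step2_fit = step2,
    step2_accepted = isTRUE(l$step2_accepted),
    step3_bounds = l$step3_bounds,
    step4_prior = .sn_from_list(l$step4_prior),
    iterations = if (is.null(l$iterations)) list() else l$iterations)
}

#' Save or load an elicitation session
#'
#' An [expert_panel()] round-trips through a versioned JSON session file
#' with full numeric precision, so parameters reload bit-exactly.
#' Loading revalidates every field through the package constructors and
#' refuses files written under an unsupported session version.
#'
#' @param panel an [expert_panel()].
#' @param path file path for the JSON session.
#' @return `save_session` the path, invisibly; `load_session` the
#'   reconstructed [expert_panel()].
#' @export
save_session <- function(panel, path) {
  stopifnot(inherits(panel, "expert_panel"))
  payload <- list(
    version = .session_version,
    common_scale = .scale_to_list(panel$common_scale),
    posterior = .sn_to_list(panel$posterior),
    records = lapply(panel$records, .record_to_list))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE),
    error = function(e) stop("cannot parse session file: ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(payload$version))
    stop("malformed session file: missing field 'version'", call. = FALSE)
  if (!identical(payload$version, .session_version))
    stop("unsupported session version '", payload$version,
         "' (this package reads version ", .session_version, ")",
         call. = FALSE)
  if (is.null(payload$common_scale))
    stop("malformed session file: missing field 'common_scale'",
         call. = FALSE)
  expert_panel(
    records = lapply(payload$records, .record_from_list),
    common_scale = .scale_from_list(payload$common_scale),
    posterior = .sn_from_list(payload$posterior))
}
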