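#' Digitized trial-roulette grids
#'
#' The first elicitation step captures an expert's location beliefs as
#' "chips" placed on a rectangular grid.  Columns discretize the value
#' axis, which runs in equal steps from the expert's reasonable lower
#' bound (leftmost column) to the reasonable upper bound (rightmost
#' column); rows only stack chips visually and carry no numeric meaning.
#' Each chip contributes one copy of its column's axis value to the
#' elicited value vector, so with `k` chips each chip carries `100/k`
#' percent of the elicited probability mass (5% each under the classic
#' 20-chip protocol).
#'
#' A grid is *fit-ready* when it holds at least 7 chips and both end
#' columns are occupied (the two range-defining chips); this is checked
#' by [chips_to_values()], not by the constructor, so partially filled
#' grids can be represented while an elicitation is in progress.
#'
#' @param chips a data frame (or matrix) with integer columns `column`
#'   and `row`, 0-based: `column` in `[0, n_columns)`, `row` in
#'   `[0, n_rows)`.  Duplicate cells are rejected; several chips may
#'   share a column on distinct rows.
#' @param lower,upper reasonable lower and upper bound of the elicited
#'   quantity; `upper > lower`.  They map exactly onto the first and last
#'   column.
#' @param n_columns,n_rows grid dimensions (default 600 x 300).
#' @return an object of class `"roulette_grid"`.
#' @examples
#' g <- roulette_grid(data.frame(column = c(0, 599, 120, 240, 300, 300, 420),
#'                               row    = c(0,   0,   0,   0,   0,   1,   0)),
#'                    lower = 8, upper = 14)
#' chips_to_values(g)
#' @seealso [roulette_axis()], [chips_to_values()], [read_chips()]
#' @export
roulette_grid <- function(chips, lower, upper, n_columns = 600, n_rows = 300) {
  if (upper <= lower) stop("'upper' must exceed 'lower'", call. = FALSE)
  if (n_columns < 2) stop("'n_columns' must be >= 2", call. = FALSE)
  chips <- as.data.frame(chips)
  if (nrow(chips) == 0) stop("'chips' must be nonempty", call. = FALSE)
  if (!all(c("column", "row") %in% names(chips)))
    stop("'chips' needs columns 'column' and 'row'", call. = FALSE)
  col <- chips$column
  row <- chips$row
  if (any(col != round(col)) || any(row != round(row)))
    stop("chip coordinates must be integers", call. = FALSE)
  if (any(col < 0) || any(col >= n_columns))
    stop("chip column out of range [0, n_columns)", call. = FALSE)
  if (any(row < 0) || any(row >= n_rows))
    stop("chip row out of range [0, n_rows)", call. = FALSE)
  if (anyDuplicated(chips[c("column", "row")]))
    stop("duplicate chip cells are not allowed", call. = FALSE)
  structure(list(
    n_columns = as.integer(n_columns), n_rows = as.integer(n_rows),
    lower = as.numeric(lower), upper = as.numeric(upper),
    chips = data.frame(column = as.integer(col), row = as.integer(row))
  ), class = "roulette_grid")
}

#' @export
print.roulette_grid <- function(x, ...) {
  cat(sprintf("Trial-roulette grid: %d x %d, axis [%g, %g], %d chips\n",
              x$n_columns, x$n_rows, x$lower, x$upper, nrow(x$chips)))
  invisible(x)
}

#' Value axis of a roulette grid
#'
#' Strictly increasing, equally spaced sequence of `n_columns` values
#' running from `lower` to `upper` inclusive; column `j` (0-based) of the
#' grid maps to element `j + 1`.
#'
#' @inheritParams roulette_grid
#' @return numeric vector of length `n_columns`.
#' @examples
#' roulette_axis(0, 1, 2)        # c(0, 1)
#' head(roulette_axis(8, 14, 600))
#' @export
roulette_axis <- function(lower, upper, n_columns = 600) {
  if (upper <= lower) stop("'upper' must exceed 'lower'", call. = FALSE)
  if (n_columns < 2) stop("'n_columns' must be >= 2", call. = FALSE)
  seq(lower, upper, length.out = n_columns)
}

#' Elicited value vector of a fit-ready grid
#'
#' Converts chip placements to the vector of axis values consumed by the
#' fitting step: one value per chip, stacked chips repeating their
#' column's value.  Requires a fit-ready grid: at least 7 chips, with the
#' range-defining chips present in the first and last column.
#'
#' @param grid a [roulette_grid()].
#' @return numeric vector, one element per chip, all within
#'   `[lower, upper]`.
#' @export
chips_to_values <- function(grid) {
  stopifnot(inherits(grid, "roulette_grid"))
  k <- nrow(grid$chips)
  if (k < 7)
    stop("grid is not fit-ready: the protocol requires a minimum of 7 chips (",
         k, " placed)", call. = FALSE)
  occ <- grid$chips$column
  if (!(0L %in% occ) || !((grid$n_columns - 1L) %in% occ))
    stop("grid is not fit-ready: the range-defining chips in the first and ",
         "last column are missing", call. = FALSE)
  axis <- roulette_axis(grid$lower, grid$upper, grid$n_columns)
  axis[occ + 1L]
}

#' Read and write chip files
#'
#' Chip placements are exchanged as plain CSV with header `column,row`
#' (0-based integers).  The axis bounds are not part of the file and must
#' be supplied alongside it.
#'
#' @param path file path.
#' @inheritParams roulette_grid
#' @param grid a [roulette_grid()] to write.
#' @return `read_chips` a validated [roulette_grid()]; `write_chips` the
#'   path, invisibly.
#' @export
read_chips <- function(path, lower, upper, n_columns = 600, n_rows = 300) {
  chips <- utils::read.csv(path)
  roulette_grid(chips, lower = lower, upper = upper,
                n_columns = n_columns, n_rows = n_rows)
}

#' @rdname read_chips
#' @export
write_chips <- function(grid, path) {
  stopifnot(inherits(grid, "roulette_grid"))
  utils::write.csv(grid$chips, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
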