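#' Construct a masked matrix
#'
#' A masked matrix pairs an `m x n` numeric matrix with a logical mask of the
#' same shape marking which entries are *given* (observed). All factorization
#' and algebra routines in this package ignore the values at non-given
#' positions; missingness is carried exclusively by the mask, never by
#' sentinel values.
#'
#' Every row and every column must retain at least one given entry: the
#' one-sided system solvers ([solve_right()], [solve_left()]) take a minimum
#' over given positions per row/column and would otherwise be undefined.
#'
#' @param values Numeric matrix. Entries at non-given positions may be `NA`.
#' @param given Logical matrix of the same shape, `TRUE` where the entry is
#'   observed. Defaults to `!is.na(values)`.
#' @return An object of class `"masked_matrix"`: a list with components
#'   `values` (numeric matrix, `NA` at non-given positions) and `given`
#'   (logical matrix).
#' @examples
#' R <- masked_matrix(matrix(c(1, NA, 3, 4), 2, 2))
#' R$given
#' @export
masked_matrix <- function(values, given = !is.na(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!is.matrix(given) || !is.logical(given) || !identical(dim(given), dim(values))) {
    stop("`given` must be a logical matrix with the same shape as `values`", call. = FALSE)
  }
  if (anyNA(given)) stop("`given` must not contain NA", call. = FALSE)
  if (any(is.na(values) & given)) {
    stop("given entries of `values` must not be NA", call. = FALSE)
  }
  if (any(!is.finite(values[given]))) {
    stop("given entries of `values` must be finite", call. = FALSE)
  }
  if (any(rowSums(given) == 0L)) {
    stop("every row must have at least one given entry", call. = FALSE)
  }
  if (any(colSums(given) == 0L)) {
    stop("every column must have at least one given entry", call. = FALSE)
  }
  vals <- values
  vals[!given] <- NA_real_
  structure(list(values = vals, given = given), class = "masked_matrix")
}

#' Coerce to a masked matrix
#'
#' Numeric matrices are interpreted with `NA` marking missing entries; a
#' `masked_matrix` passes through unchanged.
#'
#' @param x A numeric matrix (with `NA` for missing entries) or a
#'   `masked_matrix`.
#' @return A [masked_matrix()].
#' @export
as_masked_matrix <- function(x) {
  if (is_masked_matrix(x)) return(x)
  if (is.matrix(x) && is.numeric(x)) return(masked_matrix(x))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to masked_matrix", call. = FALSE)
}

#' @rdname as_masked_matrix
#' @export
is_masked_matrix <- function(x) inherits(x, "masked_matrix")

#' @export
dim.masked_matrix <- function(x) dim(x$values)

#' @export
print.masked_matrix <- function(x, ...) {
  d <- dim(x)
  n_missing <- sum(!x$given)
  cat(sprintf("masked_matrix: %d x %d, %d missing (%.1f%%)\n",
              d[1], d[2], n_missing, 100 * n_missing / prod(d)))
  utils::str(x$values, give.attr = FALSE)
  invisible(x)
}

# internal: dense values with NA at masked positions
masked_values <- function(R) {
  R <- as_masked_matrix(R)
  R$values
}
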