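#' Tropical (max,+) matrix algebra
#'
#' In the tropical semiring the reals together with `-Inf` are equipped with
#' `max` as addition and ordinary `+` as multiplication. The additive
#' identity is `-Inf` ("bottom") and the multiplicative identity is 0.
#' Scalars are handled as 1x1 matrices, so `trop_add(2, 3)` is 3 and
#' `trop_mul(1, 1)` is 2.
#'
#' `-Inf` is admitted in these core operations (it is absorbed by `max` and
#' absorbing for `+`), but it is rejected by the factorization routines,
#' where subtractions of the greatest-subsolution formula would be undefined.
#'
#' @param A,B Numeric matrices (or scalars, treated as 1x1 matrices).
#'   `trop_add` requires identical shapes; `trop_mul` requires
#'   `ncol(A) == nrow(B)`.
#' @return A numeric matrix: the entrywise maximum for `trop_add`, the
#'   (max,+) product with entries `max_k(A[i,k] + B[k,j])` for `trop_mul`.
#' @examples
#' trop_add(2, 3)            # 3
#' trop_mul(1, 1)            # 2
#' A <- matrix(c(0, 2, 1, 3), 2, 2)
#' trop_mul(A, matrix(0, 2, 2))
#' @seealso [greatest_subsolution()], [trop_leq()], [b_norm()]
#' @export
trop_add <- function(A, B) {
  A <- as_trop_matrix(A)
  B <- as_trop_matrix(B)
  if (!identical(dim(A), dim(B))) {
    stop(sprintf("shape mismatch: %dx%d vs %dx%d",
                 nrow(A), ncol(A), nrow(B), ncol(B)), call. = FALSE)
  }
  pmax(A, B)
}

#' @rdname trop_add
#' @export
trop_mul <- function(A, B) {
  A <- as_trop_matrix(A)
  B <- as_trop_matrix(B)
  if (ncol(A) != nrow(B)) {
    stop(sprintf("inner dimension mismatch: %dx%d times %dx%d",
                 nrow(A), ncol(A), nrow(B), ncol(B)), call. = FALSE)
  }
  out <- matrix(-Inf, nrow(A), ncol(B))
  for (k in seq_len(ncol(A))) {
    out <- pmax(out, outer(A[, k], B[k, ], `+`))
  }
  out
}

#' Tropical identity matrix
#'
#' The multiplicative identity of the (max,+) matrix semiring: 0 on the
#' diagonal and `-Inf` off the diagonal, so `trop_mul(trop_identity(m), A)`
#' returns `A` unchanged.
#'
#' @param n Positive integer dimension.
#' @return An `n x n` numeric matrix.
#' @export
trop_identity <- function(n) {
  E <- matrix(-Inf, n, n)
  diag(E) <- 0
  E
}

#' Tropical partial order
#'
#' `z` precedes `w` in the tropical order exactly when `z (+) w = w`, i.e.
#' when `z <= w` entrywise. This is the order under which the greatest
#' subsolution of a max-plus linear system is maximal.
#'
#' @param z,w Numeric matrices (or scalars) of identical shape.
#' @param tol Non-negative absolute slack allowed per entry; the exact order
#'   uses `tol = 0`.
#' @return `TRUE` if every entry of `z` is at most the corresponding entry of
#'   `w` (plus `tol`).
#' @export
trop_leq <- function(z, w, tol = 0) {
  z <- as_trop_matrix(z)
  w <- as_trop_matrix(w)
  if (!identical(dim(z), dim(w))) {
    stop(sprintf("shape mismatch: %dx%d vs %dx%d",
                 nrow(z), ncol(z), nrow(w), ncol(w)), call. = FALSE)
  }
  all(z <= w + tol)
}

#' b-norm of a matrix
#'
#' The sum of absolute values of the entries, the objective minimized during
#' factorization as `b_norm(R - U (x) V)`. On a [masked_matrix()] the sum runs
#' over the given entries only: masked entries have no defined residual (they
#' are the prediction targets) and carry no weight in the objective.
#'
#' @param W A numeric matrix or a [masked_matrix()].
#' @return A non-negative scalar; zero iff all (given) entries are zero.
#' @export
b_norm <- function(W) {
  if (is_masked_matrix(W)) {
    sum(abs(W$values[W$given]))
  } else {
    W <- as_trop_matrix(W)
    sum(abs(W))
  }
}

#' Greatest subsolution of a one-sided max-plus linear system
#'
#' For `A` (`m x n`) and `c` (length `m`), the inequality system
#' `A (x) x` tropically-below `c` always has solutions; the greatest one is
#' `x[i] = min_j (c[j] - A[j, i])`. When the equation `A (x) x = c` is
#' solvable at all, this vector attains it exactly.
#'
#' @param A Numeric `m x n` matrix with finite entries.
#' @param c Numeric vector of length `m` (or an `m x 1` matrix).
#' @return Numeric vector `x` of length `n` satisfying
#'   `trop_leq(trop_mul(A, cbind(x)), cbind(c))`, maximal entrywise among all
#'   such vectors.
#' @examples
#' A <- matrix(0, 2, 2)
#' greatest_subsolution(A, c(1, 2))  # c(1, 1)
#' @export
greatest_subsolution <- function(A, c) {
  A <- as_trop_matrix(A)
  c <- as.numeric(c)
  if (length(c) != nrow(A)) {
    stop(sprintf("length of c (%d) must equal nrow(A) (%d)",
                 length(c), nrow(A)), call. = FALSE)
  }
  if (any(!is.finite(A)) || any(!is.finite(c))) {
    stop("greatest_subsolution requires finite entries", call. = FALSE)
  }
  apply(c - A, 2, min)
}

#' Masked (min,+) matrix product
#'
#' The (min,+) product restricted to index triples whose operands are both
#' given: entry `(i, j)` is `min_k (A[i,k] + B[k,j])` over the `k` with both
#' `A[i,k]` and `B[k,j]` observed. On fully observed inputs this is the
#' ordinary (min,+) product. It is the mechanism by which the factorization
#' solves linear systems while skipping unknown values.
#'
#' Unlike the one-sided solvers, this product needs no row/column coverage:
#' only per-entry admissibility matters, so plain `NA`-matrices are accepted
#' without the [masked_matrix()] coverage invariant.
#'
#' @param A,B [masked_matrix()] objects or numeric matrices with `NA` for
#'   missing entries, with `ncol(A) == nrow(B)`.
#' @return A dense numeric matrix. An entry with no admissible `k` signals an
#'   error.
#' @export
min_plus_masked <- function(A, B) {
  A <- split_masked(A)
  B <- split_masked(B)
  if (ncol(A$values) != nrow(B$values)) {
    stop(sprintf("inner dimension mismatch: %dx%d times %dx%d",
                 nrow(A$values), ncol(A$values),
                 nrow(B$values), ncol(B$values)), call. = FALSE)
  }
  Av <- A$values; Av[!A$given] <- Inf
  Bv <- B$values; Bv[!B$given] <- Inf
  out <- matrix(Inf, nrow(Av), ncol(Bv))
  for (k in seq_len(ncol(Av))) {
    out <- pmin(out, outer(Av[, k], Bv[k, ], `+`))
  }
  if (any(!is.finite(out))) {
    bad <- which(!is.finite(out), arr.ind = TRUE)[1, ]
    stop(sprintf("entry (%d, %d) has no index k with both operands given",
                 bad[1], bad[2]), call. = FALSE)
  }
  out
}

#' One-sided system solvers with missing data
#'
#' `solve_right` returns the greatest subsolution `V` of `U (x) X = R`
#' column by column, skipping the masked entries of `R`:
#' `V[k, j] = min over given i of (R[i, j] - U[i, k])`. `solve_left` is the
#' mirror for `Y (x) V = R`: `U[i, k] = min over given j of (R[i, j] -
#' V[k, j])`, which equals the transpose of `solve_right(t(V), t(R))`.
#'
#' After either solve the reconstruction `trop_mul(U, V)` lies tropically
#' below `R` at every given entry, and if the (fully observed) system is
#' attainable the reconstruction equals `R` exactly.
#'
#' @param U Fully observed numeric `m x r` matrix of finite entries.
#' @param V Fully observed numeric `r x n` matrix of finite entries.
#' @param R A [masked_matrix()] or numeric matrix with `NA`s. `solve_right`
#'   needs a given entry in every column, `solve_left` in every row (each
#'   solver takes a minimum along its own direction only, so the full
#'   row-and-column coverage invariant is not required here).
#' @return `solve_right`: the `r x n` matrix `V`; `solve_left`: the `m x r`
#'   matrix `U`.
#' @export
solve_right <- function(U, R) {
  U <- as_trop_matrix(U)
  R <- split_masked(R)
  if (nrow(U) != nrow(R$values)) {
    stop("nrow(U) must equal nrow(R)", call. = FALSE)
  }
  if (any(!is.finite(U))) stop("U must have finite entries", call. = FALSE)
  cpp_solve_right(U, R$values, R$given)
}

#' @rdname solve_right
#' @export
solve_left <- function(V, R) {
  V <- as_trop_matrix(V)
  R <- split_masked(R)
  if (ncol(V) != ncol(R$values)) {
    stop("ncol(V) must equal ncol(R)", call. = FALSE)
  }
  if (any(!is.finite(V))) stop("V must have finite entries", call. = FALSE)
  cpp_solve_left(V, R$values, R$given)
}

# internal: values + given mask without the coverage invariant
split_masked <- function(x) {
  if (is_masked_matrix(x)) return(list(values = x$values, given = x$given))
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expected a numeric matrix or masked_matrix", call. = FALSE)
  }
  list(values = x, given = !is.na(x))
}

# internal: accept scalars/vectors as matrices, validate numeric, forbid NaN
as_trop_matrix <- function(x) {
  if (is_masked_matrix(x)) {
    stop("this operation requires a dense matrix; use the masked variant",
         call. = FALSE)
  }
  if (!is.matrix(x)) {
    if (is.numeric(x) && length(x) == 1L) {
      x <- matrix(x, 1, 1)
    } else {
      stop("expected a numeric matrix or scalar", call. = FALSE)
    }
  }
  if (!is.numeric(x)) stop("expected a numeric matrix", call. = FALSE)
  if (anyNA(x)) {
    stop("dense tropical matrices must not contain NA/NaN; ",
         "represent missing entries with masked_matrix()", call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}
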