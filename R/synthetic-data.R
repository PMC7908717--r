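#' Generate a tropical low-rank matrix
#'
#' Draws ground-truth factors U (`m x rank`) and V (`rank x n`) with i.i.d.
#' Uniform(0, 1) entries and returns their (max,+) product
#' `R = U (x) V`. Every entry of `R` is the sum of two Uniform(0, 1) draws
#' and hence lies in `[0, 2)`, and `R` has tropical rank at most `rank` by
#' construction, so it is exactly attainable by a factorization of that rank.
#'
#' @param m,n Matrix dimensions.
#' @param rank Tropical rank of the construction; at most `min(m, n)`.
#' @param seed Optional integer seed; generation is deterministic given it.
#' @return A list with the dense matrix `R` and the ground-truth factors `U`
#'   and `V`.
#' @examples
#' sim <- generate_tropical_lowrank(200, 100, rank = 3, seed = 1)
#' range(sim$R)
#' @export
generate_tropical_lowrank <- function(m, n, rank, seed = NULL) {
  m <- as.integer(m); n <- as.integer(n); rank <- as.integer(rank)
  if (m < 1L || n < 1L) stop("`m` and `n` must be positive", call. = FALSE)
  if (rank < 1L || rank > min(m, n)) {
    stop("`rank` must be in 1..min(m, n)", call. = FALSE)
  }
  draw <- function() {
    U <- matrix(stats::runif(m * rank), m, rank)
    V <- matrix(stats::runif(rank * n), rank, n)
    list(R = trop_mul(U, V), U = U, V = V)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Mask entries of a matrix for train/test evaluation
#'
#' Hides a fraction of the entries to form a training matrix, keeping the
#' true values of the hidden entries aside as the test set. `"uniform"` mode
#' masks `round(fraction * m * n)` positions sampled uniformly without
#' replacement — the missing-completely-at-random protocol. The
#' `"structured_block"` mode masks (approximately) a contiguous block of rows
#' by columns of the same total count, a structured not-missing-at-random
#' stress pattern.
#'
#' Masks that would leave a row or column with no observed entry are redrawn
#' (up to 100 attempts) so that the training matrix always satisfies the
#' coverage invariant of [masked_matrix()].
#'
#' @param R Fully observed numeric matrix (e.g. from
#'   [generate_tropical_lowrank()]).
#' @param fraction Fraction of entries to hide, in `[0, 1)`.
#' @param mode `"uniform"` or `"structured_block"`.
#' @param seed Optional integer seed; masking is deterministic given it.
#' @return A list with `masked` (the training [masked_matrix()], `NA` at
#'   hidden positions), `test_mask` (logical matrix, `TRUE` at hidden
#'   positions), and `held_out` (numeric matrix holding the true values at
#'   hidden positions and `NA` elsewhere, kept separate from the training
#'   object so the fit cannot see them).
#' @export
apply_mask <- function(R, fraction, mode = c("uniform", "structured_block"),
                       seed = NULL) {
  R <- as_trop_matrix(R)
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction >= 1) {
    stop("`fraction` must be in [0, 1)", call. = FALSE)
  }
  m <- nrow(R); n <- ncol(R)
  count <- round(fraction * m * n)

  build <- function() {
    if (count == 0L) {
      return(matrix(FALSE, m, n))
    }
    for (attempt in seq_len(100L)) {
      mask <- switch(mode,
                     uniform = uniform_mask(m, n, count),
                     structured_block = block_mask(m, n, count))
      if (all(rowSums(!mask) > 0L) && all(colSums(!mask) > 0L)) return(mask)
    }
    stop("could not draw a mask leaving every row and column observed ",
         "after 100 attempts; lower `fraction`", call. = FALSE)
  }
  test_mask <- if (is.null(seed)) build() else withr::with_seed(seed, build())

  train <- R
  train[test_mask] <- NA_real_
  held_out <- matrix(NA_real_, m, n)
  held_out[test_mask] <- R[test_mask]
  list(masked = masked_matrix(train), test_mask = test_mask,
       held_out = held_out)
}

uniform_mask <- function(m, n, count) {
  mask <- matrix(FALSE, m, n)
  mask[sample.int(m * n, count)] <- TRUE
  mask
}

# Contiguous block of a rows x b cols with a * b >= count, trimmed in
# column-major order to exactly `count` positions; block offset is random so
# repeated draws can satisfy the coverage constraint.
block_mask <- function(m, n, count) {
  a <- max(1L, min(m - 1L, round(sqrt(count * m / n))))
  b <- max(1L, min(n - 1L, ceiling(count / a)))
  while (a * b < count && a < m - 1L) {
    a <- a + 1L
    b <- max(1L, min(n - 1L, ceiling(count / a)))
  }
  if (a * b < count) {
    stop("`fraction` too high for a structured block on this shape",
         call. = FALSE)
  }
  top <- sample.int(m - a + 1L, 1L)
  left <- sample.int(n - b + 1L, 1L)
  mask <- matrix(FALSE, m, n)
  block <- matrix(FALSE, a, b)
  block[seq_len(count)] <- TRUE  # column-major fill keeps the block contiguous
  mask[top:(top + a - 1L), left:(left + b - 1L)] <- block
  mask
}

#' Simulate a complete masked-completion problem
#'
#' Convenience wrapper chaining [generate_tropical_lowrank()] and
#' [apply_mask()]: the synthetic regime used throughout the package's own
#' validation (tropical rank-3 matrices with 20% of entries hidden uniformly
#' at random).
#'
#' @inheritParams generate_tropical_lowrank
#' @inheritParams apply_mask
#' @return A list with `masked`, `test_mask`, `held_out` (as [apply_mask()]),
#'   plus the full matrix `R` and ground-truth factors `U`, `V`.
#' @export
simulate_stmf_data <- function(m, n, rank, fraction = 0.2,
                               mode = c("uniform", "structured_block"),
                               seed = NULL) {
  mode <- match.arg(mode)
  sim <- generate_tropical_lowrank(m, n, rank, seed = seed)
  masked <- apply_mask(sim$R, fraction, mode = mode,
                       seed = if (is.null(seed)) NULL else seed + 1L)
  c(masked, sim)
}
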