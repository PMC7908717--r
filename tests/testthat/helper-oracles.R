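# Brute-force reference implementations, independent of the package's
# vectorized/compiled code paths: plain loops over the defining formulas.

oracle_trop_mul <- function(A, B) {
  out <- matrix(NA_real_, nrow(A), ncol(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(B))) {
      out[i, j] <- max(A[i, ] + B[, j])
    }
  }
  out
}

# (min,+) product skipping NA operands; Inf where no admissible index
oracle_min_plus <- function(A, B) {
  out <- matrix(NA_real_, nrow(A), ncol(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(B))) {
      terms <- A[i, ] + B[, j]
      terms <- terms[!is.na(terms)]
      out[i, j] <- if (length(terms)) min(terms) else Inf
    }
  }
  out
}

# greatest subsolution of U (x) X = R per column, skipping NA entries of R
oracle_solve_right <- function(U, R) {
  r <- ncol(U); n <- ncol(R)
  V <- matrix(NA_real_, r, n)
  for (j in seq_len(n)) {
    for (k in seq_len(r)) {
      diffs <- R[, j] - U[, k]
      V[k, j] <- min(diffs, na.rm = TRUE)
    }
  }
  V
}

# distance correlation evaluated by explicit loops over the defining sums
oracle_dcor <- function(X, Y) {
  n <- nrow(X)
  D <- function(M) {
    out <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) out[i, j] <- sqrt(sum((M[i, ] - M[j, ])^2))
    }
    out
  }
  center <- function(D) {
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        A[i, j] <- D[i, j] - mean(D[i, ]) - mean(D[, j]) + mean(D)
      }
    }
    A
  }
  A <- center(D(X)); B <- center(D(Y))
  v2xy <- sum(A * B) / n^2
  vx <- sqrt(sum(A * A) / n^2)
  vy <- sqrt(sum(B * B) / n^2)
  if (vx * vy == 0) return(0)
  sqrt(v2xy / (vx * vy))
}

rand_int_matrix <- function(m, n, lo = -5L, hi = 5L) {
  matrix(sample(lo:hi, m * n, replace = TRUE), m, n)
}

# drop a fraction of entries (NA) while keeping row/column coverage
rand_masked <- function(M, fraction = 0.25) {
  repeat {
    drop <- matrix(stats::runif(length(M)) < fraction, nrow(M), ncol(M))
    if (all(rowSums(!drop) > 0) && all(colSums(!drop) > 0)) break
  }
  M[drop] <- NA_real_
  masked_matrix(M)
}
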