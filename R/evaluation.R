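#' Double-center a distance matrix
#'
#' Subtracts the row means and column means and adds back the grand mean:
#' `A[i, j] = D[i, j] - rowmean_i - colmean_j + grandmean`. The result has
#' all row and column means equal to zero; applied to pairwise Euclidean
#' distance matrices it yields the centered matrices entering the
#' distance-covariance formula.
#'
#' @param D Square numeric matrix (a pairwise distance matrix).
#' @return A numeric matrix of the same shape with zero row/column means.
#' @export
double_center <- function(D) {
  D <- as_trop_matrix(D)
  if (nrow(D) != ncol(D)) {
    stop("`D` must be square", call. = FALSE)
  }
  rm <- rowMeans(D)
  cm <- colMeans(D)
  D - outer(rm, rep(1, ncol(D))) - outer(rep(1, nrow(D)), cm) + mean(D)
}

#' Distance correlation between two matrices
#'
#' An association measure built from pairwise distances: rows of `X` and `Y`
#' are paired observations; `A` and `B` are their doubly-centered Euclidean
#' distance matrices; the squared distance covariance is
#' `V2_XY = mean(A * B)`, the distance variances are `V_X = sqrt(mean(A^2))`
#' and `V_Y = sqrt(mean(B^2))`, and
#' `dcor(X, Y) = sqrt(V2_XY / (V_X * V_Y))`. Unlike Pearson or Spearman
#' correlation it detects non-linear association, and the population value is
#' zero only under independence. The sample value lies in `[0, 1]`, is
#' symmetric, equals 1 when `Y` is a translation of `X`, and is defined as 0
#' when either argument has zero distance variance (all rows identical).
#'
#' @param X,Y Numeric matrices (or vectors, treated as one-column matrices)
#'   with the same number of rows `n >= 2`.
#' @return A scalar in `[0, 1]`.
#' @examples
#' X <- matrix(rnorm(40), 20, 2)
#' distance_correlation(X, X)      # 1
#' distance_correlation(X, X + 5)  # 1: distances are translation-invariant
#' @export
distance_correlation <- function(X, Y) {
  X <- as_obs_matrix(X)
  Y <- as_obs_matrix(Y)
  if (nrow(X) != nrow(Y)) {
    stop("`X` and `Y` must have the same number of rows", call. = FALSE)
  }
  if (nrow(X) < 2L) stop("need at least two rows", call. = FALSE)
  A <- double_center(as.matrix(stats::dist(X)))
  B <- double_center(as.matrix(stats::dist(Y)))
  v2xy <- mean(A * B)
  vx <- sqrt(mean(A * A))
  vy <- sqrt(mean(B * B))
  if (vx * vy == 0) return(0)
  # numerical guard: the ratio is in [0, 1] up to floating-point error
  r2 <- v2xy / (vx * vy)
  sqrt(min(1, max(0, r2)))
}

as_obs_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expected a numeric matrix or vector", call. = FALSE)
  }
  if (anyNA(x)) stop("observation matrices must not contain NA", call. = FALSE)
  x
}

#' Root-mean-square error over selected positions
#'
#' @param truth,pred Numeric matrices of identical shape.
#' @param mask Logical matrix selecting the positions to evaluate (for matrix
#'   completion: `TRUE` at entries hidden during training gives the test
#'   error, the complement the training error).
#' @return `sqrt(mean((truth - pred)^2))` over the selected positions.
#' @export
rmse_masked <- function(truth, pred, mask) {
  truth <- as_trop_matrix(truth)
  pred <- as_trop_matrix(pred)
  if (!identical(dim(truth), dim(pred)) || !identical(dim(truth), dim(mask))) {
    stop("`truth`, `pred` and `mask` must have identical shapes", call. = FALSE)
  }
  if (!is.logical(mask)) stop("`mask` must be logical", call. = FALSE)
  if (!any(mask)) stop("`mask` selects no positions", call. = FALSE)
  sqrt(mean((truth[mask] - pred[mask])^2))
}

#' Per-row Euclidean reconstruction errors
#'
#' The Euclidean norm of each row of `X - Y`, optionally after centering both
#' matrices column-wise (subtracting each matrix's own column means).
#' Distance correlation cannot compare individual rows because it centers
#' the whole matrix; the centered row norms fill that role — they measure how
#' well each row's *pattern* is reconstructed, discounting feature-wise
#' offsets (for expression data, gene-wise baseline shifts).
#'
#' @param X,Y Numeric matrices of identical shape.
#' @param centered If `TRUE` (default), subtract column means from each
#'   matrix before differencing.
#' @return Numeric vector with one non-negative value per row.
#' @export
centered_row_errors <- function(X, Y, centered = TRUE) {
  X <- as_obs_matrix(X)
  Y <- as_obs_matrix(Y)
  if (!identical(dim(X), dim(Y))) {
    stop("`X` and `Y` must have identical shapes", call. = FALSE)
  }
  if (centered) {
    X <- scale(X, center = TRUE, scale = FALSE)
    Y <- scale(Y, center = TRUE, scale = FALSE)
  }
  sqrt(rowSums((X - Y)^2))
}

#' Evaluate a completed matrix against the truth
#'
#' Bundles the package's evaluation statistics for one model/data pair:
#' distance correlation between the full original and reconstructed matrices,
#' RMSE at the held-out (test) and observed (training) positions, and raw
#' plus centered per-row Euclidean errors.
#'
#' @param truth Fully observed numeric matrix of true values.
#' @param pred Completed matrix (e.g. from [predict.stmf_model()]).
#' @param test_mask Logical matrix, `TRUE` at entries hidden during training.
#' @return A list of class `"stmf_evaluation"` with fields `dcor`,
#'   `rmse_test`, `rmse_train`, `row_errors_raw`, `row_errors_centered`.
#' @export
evaluate_completion <- function(truth, pred, test_mask) {
  structure(list(
    dcor = distance_correlation(truth, pred),
    rmse_test = rmse_masked(truth, pred, test_mask),
    rmse_train = rmse_masked(truth, pred, !test_mask),
    row_errors_raw = centered_row_errors(truth, pred, centered = FALSE),
    row_errors_centered = centered_row_errors(truth, pred, centered = TRUE)
  ), class = "stmf_evaluation")
}

#' @export
print.stmf_evaluation <- function(x, ...) {
  cat(sprintf("dcor: %.4f | test RMSE: %.4f | train RMSE: %.4f\n",
              x$dcor, x$rmse_test, x$rmse_train))
  cat(sprintf("row errors (centered): median %.4f, max %.4f\n",
              stats::median(x$row_errors_centered),
              max(x$row_errors_centered)))
  invisible(x)
}

#' Classical NMF baseline
#'
#' Rank-r non-negative matrix factorization by multiplicative updates under
#' the Frobenius objective (the classical Lee-Seung rules), used as the
#' standard-linear-algebra baseline in [compare_methods()]. Classical NMF has
#' no native notion of a missing entry, so [nmf_impute()] fills masked
#' positions with their column means over the observed entries (falling back
#' to the global observed mean) before fitting — the harness convention for
#' giving the baseline a complete input.
#'
#' @param X Non-negative numeric matrix without missing entries.
#' @param rank Factorization rank.
#' @param max_iter Number of multiplicative update iterations (default 500).
#' @param seed Optional integer seed for the Uniform(0, 1) initialization.
#' @param eps Small constant guarding divisions (default `1e-9`).
#' @return A list with non-negative factors `W` (`m x rank`) and `H`
#'   (`rank x n`) and the reconstruction `WH`.
#' @export
nmf_baseline <- function(X, rank, max_iter = 500L, seed = NULL, eps = 1e-9) {
  X <- as_trop_matrix(X)
  if (any(X < 0)) stop("NMF requires non-negative input", call. = FALSE)
  m <- nrow(X); n <- ncol(X)
  init <- function() list(W = matrix(stats::runif(m * rank), m, rank),
                          H = matrix(stats::runif(rank * n), rank, n))
  f <- if (is.null(seed)) init() else withr::with_seed(seed, init())
  W <- f$W; H <- f$H
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X)) / (crossprod(W, W %*% H) + eps)
    W <- W * (X %*% t(H)) / (W %*% H %*% t(H) + eps)
  }
  list(W = W, H = H, WH = W %*% H)
}

#' @rdname nmf_baseline
#' @param R A [masked_matrix()] (or numeric matrix with `NA`s).
#' @export
nmf_impute <- function(R, rank, max_iter = 500L, seed = NULL) {
  R <- as_masked_matrix(R)
  X <- R$values
  col_means <- colMeans(X, na.rm = TRUE)
  col_means[is.nan(col_means)] <- mean(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    miss <- !R$given[, j]
    X[miss, j] <- col_means[j]
  }
  nmf_baseline(X, rank, max_iter = max_iter, seed = seed)
}

#' Compare tropical factorization with the NMF baseline
#'
#' Runs the train/test protocol used throughout the package's validation:
#' per repetition, hide `mask_fraction` of the entries of `truth` uniformly
#' at random, fit the tropical factorization and the NMF baseline at equal
#' rank on the remaining entries, and evaluate both on the full matrix
#' (distance correlation) and on the hidden entries (test RMSE). Each
#' repetition draws its own mask and initialization from a seed derived from
#' `seed`, so a repetition is a fresh instance of the same regime.
#'
#' @param truth Fully observed numeric matrix (ground truth).
#' @param rank Factorization rank used by both methods.
#' @param repetitions Number of masked repetitions (default 10).
#' @param mask_fraction Fraction of entries hidden per repetition
#'   (default 0.2).
#' @param seed Integer seed from which per-repetition seeds are derived.
#' @param max_iter Sweep/iteration budget passed to both methods.
#' @param mode Masking mode, see [apply_mask()].
#' @param ... Further arguments to [stmf()] (e.g. `ordering`).
#' @return A list of class `"stmf_comparison"`: `runs`, a data frame with one
#'   row per method and repetition (`method`, `rep`, `seed`, `rmse_train`,
#'   `rmse_test`, `dcor`), and `summary`, the per-method median/min/max of
#'   each statistic.
#' @export
compare_methods <- function(truth, rank, repetitions = 10L,
                            mask_fraction = 0.2, seed = 1L, max_iter = 100L,
                            mode = c("uniform", "structured_block"), ...) {
  truth <- as_trop_matrix(truth)
  mode <- match.arg(mode)
  repetitions <- as.integer(repetitions)
  rows <- vector("list", 2L * repetitions)
  for (rep_i in seq_len(repetitions)) {
    rep_seed <- as.integer(seed) + 1000L * (rep_i - 1L)
    split <- apply_mask(truth, mask_fraction, mode = mode, seed = rep_seed)

    fit <- stmf(split$masked, rank = rank, max_iter = max_iter,
                seed = rep_seed, ...)
    ev_s <- evaluate_completion(truth, predict(fit), split$test_mask)

    nm <- nmf_impute(split$masked, rank = rank, max_iter = 5L * max_iter,
                     seed = rep_seed)
    ev_n <- evaluate_completion(truth, nm$WH, split$test_mask)

    rows[[2L * rep_i - 1L]] <- data.frame(
      method = "STMF", rep = rep_i, seed = rep_seed,
      rmse_train = ev_s$rmse_train, rmse_test = ev_s$rmse_test,
      dcor = ev_s$dcor)
    rows[[2L * rep_i]] <- data.frame(
      method = "NMF", rep = rep_i, seed = rep_seed,
      rmse_train = ev_n$rmse_train, rmse_test = ev_n$rmse_test,
      dcor = ev_n$dcor)
  }
  runs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(runs, runs$method), function(d) {
    data.frame(method = d$method[1],
               stat = c("median", "min", "max"),
               rmse_train = c(stats::median(d$rmse_train), min(d$rmse_train), max(d$rmse_train)),
               rmse_test = c(stats::median(d$rmse_test), min(d$rmse_test), max(d$rmse_test)),
               dcor = c(stats::median(d$dcor), min(d$dcor), max(d$dcor)))
  }))
  rownames(summ) <- NULL
  structure(list(runs = runs, summary = summ), class = "stmf_comparison")
}

#' @export
print.stmf_comparison <- function(x, ...) {
  cat("matrix-completion comparison (per-method summary over repetitions):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
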