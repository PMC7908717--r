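#' Configuration for sparse tropical matrix factorization
#'
#' Collects and validates the tuning parameters of [stmf()].
#'
#' @param rank Positive integer factorization rank `r`; must not exceed the
#'   smaller dimension of the fitted matrix.
#' @param max_iter Maximum number of sweeps over the given entries (default
#'   500). Fitting stops earlier after a sweep that accepts no update, since
#'   no later sweep could improve under the acceptance rule.
#' @param init Initialization strategy for the left factor: `"random_acol"`
#'   (each column of U averages a random subset of data columns) or
#'   `"uniform_random"` (i.i.d. Uniform(0,1) entries).
#' @param acol_subset_size Number of data columns averaged per initialized
#'   column under Random Acol; default `max(1, ceiling(n / 5))`.
#' @param ordering Column-ordering strategy applied before fitting:
#'   `"column_min_increasing"` (default; sort columns so their minima over
#'   given entries are non-decreasing), `"column_max_increasing"`,
#'   `"column_mean_increasing"`, or `"none"`.
#' @param seed Integer seed driving initialization; `NULL` leaves the RNG
#'   state untouched (results then depend on the session RNG).
#' @param improvement_tolerance Non-negative margin by which a candidate
#'   update must decrease the training b-norm to be accepted. The default 0
#'   demands a strict decrease, which is what guarantees a monotone error
#'   trace.
#' @param update_order Which per-entry update is attempted first:
#'   `"ulf_first"` (default: left-factor update, then right on failure) or
#'   `"urf_first"`.
#' @return A list of class `"stmf_config"`.
#' @export
stmf_config <- function(rank,
                        max_iter = 500L,
                        init = c("random_acol", "uniform_random"),
                        acol_subset_size = NULL,
                        ordering = c("column_min_increasing",
                                     "column_max_increasing",
                                     "column_mean_increasing", "none"),
                        seed = NULL,
                        improvement_tolerance = 0,
                        update_order = c("ulf_first", "urf_first")) {
  rank <- as.integer(rank)
  if (length(rank) != 1L || is.na(rank) || rank < 1L) {
    stop("`rank` must be a positive integer", call. = FALSE)
  }
  max_iter <- as.integer(max_iter)
  if (length(max_iter) != 1L || is.na(max_iter) || max_iter < 1L) {
    stop("`max_iter` must be a positive integer", call. = FALSE)
  }
  init <- match.arg(init)
  ordering <- match.arg(ordering)
  update_order <- match.arg(update_order)
  if (!is.null(acol_subset_size)) {
    acol_subset_size <- as.integer(acol_subset_size)
    if (is.na(acol_subset_size) || acol_subset_size < 1L) {
      stop("`acol_subset_size` must be a positive integer", call. = FALSE)
    }
  }
  if (!is.numeric(improvement_tolerance) || length(improvement_tolerance) != 1L ||
      is.na(improvement_tolerance) || improvement_tolerance < 0) {
    stop("`improvement_tolerance` must be a non-negative number", call. = FALSE)
  }
  structure(list(rank = rank, max_iter = max_iter, init = init,
                 acol_subset_size = acol_subset_size, ordering = ordering,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 improvement_tolerance = as.numeric(improvement_tolerance),
                 update_order = update_order),
            class = "stmf_config")
}

#' Random Acol initialization
#'
#' Builds each column of the initial left factor U as the entrywise average,
#' over given entries only, of a random subset of columns of the data matrix.
#' Averaging data columns starts the factors inside the range of the data,
#' which works markedly better here than unstructured random starts.
#' A row with no given entry across a sampled subset falls back to the row's
#' mean over all its given entries (the coverage invariant guarantees one).
#'
#' @param R A [masked_matrix()] (or numeric matrix with `NA`s).
#' @param rank Number of columns of the initialized factor.
#' @param subset_size Number of data columns averaged per factor column;
#'   default `max(1, ceiling(n / 5))`.
#' @param seed Optional integer seed; the sampling is deterministic given it.
#' @return An `m x rank` numeric matrix without missing entries.
#' @export
random_acol_init <- function(R, rank, subset_size = NULL, seed = NULL) {
  R <- as_masked_matrix(R)
  n <- ncol(R$values)
  if (is.null(subset_size)) subset_size <- max(1L, ceiling(n / 5))
  subset_size <- as.integer(subset_size)
  if (subset_size < 1L || subset_size > n) {
    stop("`subset_size` must be between 1 and ncol(R)", call. = FALSE)
  }
  row_fallback <- rowMeans(R$values, na.rm = TRUE)
  draw <- function() {
    U <- matrix(NA_real_, nrow(R$values), rank)
    for (k in seq_len(rank)) {
      cols <- sample.int(n, subset_size)
      col_mean <- rowMeans(R$values[, cols, drop = FALSE], na.rm = TRUE)
      col_mean[is.nan(col_mean)] <- row_fallback[is.nan(col_mean)]
      U[, k] <- col_mean
    }
    U
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Reorder matrix columns by a per-column statistic
#'
#' Sorting columns so that their minima (or maxima, or means) over the given
#' entries increase is the first step of the fitting algorithm: the per-entry
#' updates visit entries in matrix order, and on tropical low-rank data
#' ascending columns give the sweep a consistently better starting structure.
#'
#' @param R A [masked_matrix()] (or numeric matrix with `NA`s).
#' @param strategy One of `"column_min_increasing"`, `"column_max_increasing"`,
#'   `"column_mean_increasing"`, `"none"`.
#' @return A list with components `matrix` (the permuted [masked_matrix()])
#'   and `permutation` (integer vector `p` such that column `j` of the output
#'   is column `p[j]` of the input; the identity for `"none"`). The sort is
#'   stable, so already-ordered input yields the identity permutation.
#' @export
order_columns <- function(R, strategy = c("column_min_increasing",
                                          "column_max_increasing",
                                          "column_mean_increasing", "none")) {
  R <- as_masked_matrix(R)
  strategy <- match.arg(strategy)
  n <- ncol(R$values)
  if (strategy == "none") {
    return(list(matrix = R, permutation = seq_len(n)))
  }
  stat_fun <- switch(strategy,
    column_min_increasing  = function(x) min(x, na.rm = TRUE),
    column_max_increasing  = function(x) max(x, na.rm = TRUE),
    column_mean_increasing = function(x) mean(x, na.rm = TRUE))
  keys <- apply(R$values, 2, stat_fun)
  perm <- order(keys)  # stable for ties
  out <- masked_matrix(R$values[, perm, drop = FALSE],
                       R$given[, perm, drop = FALSE])
  list(matrix = out, permutation = perm)
}

#' Single factor-entry updates
#'
#' One step of the per-entry update machinery, exposed for inspection. At a
#' given entry `(i, j)` of `R`, the active latent index `k*` is the smallest
#' `k` maximizing `U[i, k] + V[k, j]` (the term realizing the (max,+)
#' reconstruction there). The left-factor update (ULF) sets
#' `U[i, k*] <- R[i, j] - V[k*, j]`, so the reconstruction can attain
#' `R[i, j]` through the active term, then recomputes all of `V` as the
#' greatest subsolution via [solve_right()]; the right-factor update (URF)
#' mirrors it, setting `V[k*, j] <- R[i, j] - U[i, k*]` and recomputing `U`
#' via [solve_left()]. Both return candidate factors without judging
#' acceptance — [stmf()] accepts a candidate only when it strictly lowers the
#' training b-norm.
#'
#' @param i,j Row and column (1-based) of a given entry of `R`.
#' @param U,V Current factor matrices (`m x r` and `r x n`), finite entries.
#' @param R A [masked_matrix()] (or numeric matrix with `NA`s).
#' @return A list with candidate `U`, `V`, and `error` (the training b-norm
#'   of the candidate pair).
#' @export
ulf_update <- function(i, j, U, V, R) {
  R <- as_masked_matrix(R)
  check_update_args(i, j, U, V, R)
  cpp_ulf_update(as.integer(i), as.integer(j), U, V, R$values, R$given)
}

#' @rdname ulf_update
#' @export
urf_update <- function(i, j, U, V, R) {
  R <- as_masked_matrix(R)
  check_update_args(i, j, U, V, R)
  cpp_urf_update(as.integer(i), as.integer(j), U, V, R$values, R$given)
}

check_update_args <- function(i, j, U, V, R) {
  if (!R$given[i, j]) {
    stop(sprintf("(%d, %d) is not a given entry of R", i, j), call. = FALSE)
  }
  if (any(!is.finite(U)) || any(!is.finite(V))) {
    stop("factor matrices must have finite entries", call. = FALSE)
  }
  invisible(NULL)
}

#' Fit a sparse tropical matrix factorization
#'
#' Factorizes a partially observed matrix `R` as `U (x) V` over the (max,+)
#' semiring, minimizing the b-norm of the residual at the given entries. The
#' procedure: (1) reorder columns per the `ordering` strategy; (2) initialize
#' U; (3) compute V as the greatest subsolution of `U (x) X = R`; (4) sweep
#' the given entries in row-major order up to `max_iter` times, at each entry
#' attempting a left-factor update and, if it does not improve the objective,
#' a right-factor update ([ulf_update()]/[urf_update()]); a candidate is
#' accepted only when the training b-norm strictly decreases, which makes the
#' recorded error trace non-increasing by construction. Fitting stops after a
#' sweep with no accepted update or after `max_iter` sweeps.
#'
#' Because every accepted factor pair ends in a greatest-subsolution
#' recomputation, the reconstruction stays tropically below `R` at the given
#' entries throughout.
#'
#' @param R A [masked_matrix()] or numeric matrix with `NA` marking missing
#'   entries. Every row and column must contain at least one observed entry.
#' @param rank Factorization rank; see [stmf_config()].
#' @param ... Further parameters passed to [stmf_config()] (`max_iter`,
#'   `init`, `seed`, `ordering`, ...).
#' @param config An [stmf_config()]; overrides `rank` and `...` when given.
#' @param init_U Optional explicit `m x rank` initial left factor (columns in
#'   the post-ordering column order of `R`), bypassing the `init` strategy —
#'   useful for warm starts and oracle-initialization experiments.
#' @return An object of class `"stmf_model"`: a list with factor matrices `U`
#'   (`m x rank`) and `V` (`rank x n`, columns in fitting order), the `rank`,
#'   the `column_permutation` applied before fitting, the non-increasing
#'   `error_trace` of training b-norms (after the initial solve and after
#'   each sweep), the number of `sweeps` run, and the `config`.
#' @examples
#' sim <- generate_tropical_lowrank(20, 10, rank = 2, seed = 1)
#' masked <- apply_mask(sim$R, fraction = 0.2, seed = 1)
#' fit <- stmf(masked$masked, rank = 2, max_iter = 20, seed = 1)
#' completed <- predict(fit)
#' @seealso [predict.stmf_model()], [latent_component()], [evaluate_completion()]
#' @export
stmf <- function(R, rank, ..., config = NULL, init_U = NULL) {
  R <- as_masked_matrix(R)
  if (is.null(config)) {
    config <- stmf_config(rank = rank, ...)
  } else if (!inherits(config, "stmf_config")) {
    stop("`config` must be an stmf_config object", call. = FALSE)
  }
  m <- nrow(R$values); n <- ncol(R$values)
  if (config$rank > min(m, n)) {
    stop(sprintf("rank (%d) exceeds min(m, n) = %d", config$rank, min(m, n)),
         call. = FALSE)
  }

  ord <- order_columns(R, config$ordering)
  Ro <- ord$matrix

  if (is.null(init_U)) {
    init_U <- switch(config$init,
      random_acol = random_acol_init(Ro, config$rank,
                                     subset_size = config$acol_subset_size,
                                     seed = config$seed),
      uniform_random = {
        draw <- function() matrix(stats::runif(m * config$rank), m, config$rank)
        if (is.null(config$seed)) draw() else withr::with_seed(config$seed, draw())
      })
  } else {
    init_U <- as_trop_matrix(init_U)
    if (!identical(dim(init_U), c(m, config$rank))) {
      stop("`init_U` must be an m x rank matrix", call. = FALSE)
    }
    if (any(!is.finite(init_U))) {
      stop("`init_U` must have finite entries", call. = FALSE)
    }
  }

  fit <- cpp_stmf_fit(Ro$values, Ro$given, init_U,
                      config$max_iter, config$improvement_tolerance,
                      config$update_order == "urf_first")

  structure(list(U = fit$U, V = fit$V, rank = config$rank,
                 column_permutation = ord$permutation,
                 error_trace = fit$error_trace, sweeps = fit$sweeps,
                 config = config),
            class = "stmf_model")
}

#' @export
print.stmf_model <- function(x, ...) {
  tr <- x$error_trace
  cat(sprintf("stmf_model: %d x %d, rank %d\n", nrow(x$U), ncol(x$V), x$rank))
  cat(sprintf("  sweeps: %d, training b-norm: %.6g (initial %.6g)\n",
              x$sweeps, tr[length(tr)], tr[1]))
  invisible(x)
}

#' Complete a matrix from a fitted model
#'
#' Returns the full (max,+) reconstruction `U (x) V` with the column
#' permutation applied during fitting inverted, so entries align with the
#' original input: values at observed positions are the model approximation,
#' values at masked positions are the predictions.
#'
#' @param object A fitted `"stmf_model"`.
#' @param ... Unused.
#' @return An `m x n` numeric matrix in the original row/column order.
#' @export
predict.stmf_model <- function(object, ...) {
  P <- trop_mul(object$U, object$V)
  inv <- integer(length(object$column_permutation))
  inv[object$column_permutation] <- seq_along(object$column_permutation)
  P[, inv, drop = FALSE]
}

#' Single-component reconstruction
#'
#' The i-th latent matrix: the outer (max,+) product of column `i` of U and
#' row `i` of V, whose `(p, q)` entry is the plain sum `U[p, i] + V[i, q]`.
#' It shows which part of the data the i-th latent component explains; the
#' entrywise maximum of all `rank` latent matrices is exactly the full
#' reconstruction returned by [predict.stmf_model()].
#'
#' @param model A fitted `"stmf_model"`.
#' @param i Component index in `1..rank`.
#' @return A list of class `"stmf_latent"` with `index` and `values` (an
#'   `m x n` matrix in original column order).
#' @export
latent_component <- function(model, i) {
  if (!inherits(model, "stmf_model")) {
    stop("`model` must be an stmf_model", call. = FALSE)
  }
  i <- as.integer(i)
  if (is.na(i) || i < 1L || i > model$rank) {
    stop(sprintf("component index must be in 1..%d", model$rank), call. = FALSE)
  }
  comp <- outer(model$U[, i], model$V[i, ], `+`)
  inv <- integer(length(model$column_permutation))
  inv[model$column_permutation] <- seq_along(model$column_permutation)
  structure(list(index = i, values = comp[, inv, drop = FALSE]),
            class = "stmf_latent")
}
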