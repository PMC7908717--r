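test_that("Random Acol averages sampled data columns over given entries", {
  withr::with_seed(1, {
    R <- matrix(runif(60), 10, 6)
  })
  # subset of all columns: every initialized column is the vector of row means
  U <- random_acol_init(R, rank = 3, subset_size = 6, seed = 1)
  expect_equal(U, matrix(rowMeans(R), 10, 3))
  # one data column, singleton subsets: all factor columns equal it
  R1 <- matrix(1:10 + 0, 10, 1)
  expect_equal(random_acol_init(R1, rank = 2, subset_size = 1, seed = 3),
               cbind(R1, R1), ignore_attr = TRUE)
  # deterministic given the seed
  Rm <- withr::with_seed(2, rand_masked(matrix(runif(60), 10, 6)))
  expect_identical(random_acol_init(Rm, 2, seed = 99),
                   random_acol_init(Rm, 2, seed = 99))
  # masked entries do not enter the averages
  U2 <- random_acol_init(Rm, 2, subset_size = 6, seed = 5)
  expect_equal(U2[, 1], rowMeans(Rm$values, na.rm = TRUE))
  expect_false(anyNA(U2))
})

test_that("column ordering sorts the per-column statistic over given entries", {
  R <- rbind(c(3, 1, 2),
             c(9, 9, 9))
  ord <- order_columns(R, "column_min_increasing")
  expect_identical(ord$permutation, c(2L, 3L, 1L))
  expect_identical(ord$matrix$values[1, ], c(1, 2, 3))
  # already sorted: stable identity permutation
  sorted <- order_columns(ord$matrix, "column_min_increasing")
  expect_identical(sorted$permutation, 1:3)
  expect_identical(order_columns(R, "none")$permutation, 1:3)
  # masked statistics use the given subset only
  Rm <- masked_matrix(rbind(c(10, 1), c(0, NA)))
  keys_min <- apply(Rm$values, 2, min, na.rm = TRUE)     # 0, 1
  expect_identical(order_columns(Rm, "column_min_increasing")$permutation,
                   order(keys_min))
  keys_mean <- apply(Rm$values, 2, mean, na.rm = TRUE)   # 5, 1
  expect_identical(order_columns(Rm, "column_mean_increasing")$permutation,
                   order(keys_mean))
  expect_error(order_columns(R, "alphabetical"), "arg")
})

test_that("single-entry updates attain the target entry and stay feasible", {
  # 1x1x1 hand case: the left update writes R - V into U, re-solve is exact
  res <- ulf_update(1, 1, matrix(0, 1, 1), matrix(0, 1, 1), matrix(4, 1, 1))
  expect_identical(res$U, matrix(4, 1, 1))
  expect_identical(res$V, matrix(0, 1, 1))
  expect_identical(res$error, 0)
  res2 <- urf_update(1, 1, matrix(0, 1, 1), matrix(0, 1, 1), matrix(4, 1, 1))
  expect_identical(res2$V, matrix(4, 1, 1))
  expect_identical(res2$U, matrix(0, 1, 1))
  expect_identical(res2$error, 0)

  withr::with_seed(41, {
    for (rep in 1:5) {
      R <- rand_masked(matrix(runif(35, 0, 2), 7, 5))
      U <- matrix(runif(14), 7, 2)
      V <- solve_right(U, R)
      given_idx <- which(R$given, arr.ind = TRUE)
      pick <- given_idx[sample(nrow(given_idx), 1), ]
      # feasibility at every given entry propagates through the re-solve
      for (step in list(ulf_update, urf_update)) {
        cand <- step(pick[1], pick[2], U, V, R)
        P <- trop_mul(cand$U, cand$V)
        expect_true(all(P[R$given] <= R$values[R$given] + 1e-9))
        # reported error is the masked residual b-norm
        expect_equal(cand$error, sum(abs(R$values[R$given] - P[R$given])))
      }
      # transpose duality: URF on R corresponds to ULF on the transpose
      urf <- urf_update(pick[1], pick[2], U, V, R)
      ulf_t <- ulf_update(pick[2], pick[1], t(V), t(U),
                          masked_matrix(t(R$values)))
      expect_equal(urf$V, t(ulf_t$U))
      expect_equal(urf$U, t(ulf_t$V))
    }
  })
  expect_error(ulf_update(1, 2, matrix(0, 2, 1), matrix(0, 1, 2),
                          masked_matrix(matrix(c(1, 2, NA, 3), 2, 2))),
               "not a given entry")
})

test_that("an attainable system is fit exactly by the initial solve", {
  withr::with_seed(51, {
    U0 <- matrix(runif(20), 10, 2)
    V0 <- matrix(runif(12), 2, 6)
    R <- trop_mul(U0, V0)
  })
  fit <- stmf(R, rank = 2, max_iter = 5, ordering = "none", init_U = U0)
  expect_lt(fit$error_trace[1], 1e-9)
  expect_lt(b_norm(R - predict(fit)), 1e-9)
})

test_that("fitting is monotone, deterministic, and validates its inputs", {
  sim <- simulate_stmf_data(20, 10, rank = 3, seed = 8)
  fit1 <- stmf(sim$masked, rank = 3, max_iter = 30, seed = 8)
  fit2 <- stmf(sim$masked, rank = 3, max_iter = 30, seed = 8)
  expect_identical(fit1$U, fit2$U)
  expect_identical(fit1$V, fit2$V)
  expect_identical(fit1$error_trace, fit2$error_trace)
  expect_true(all(diff(fit1$error_trace) <= 0))
  # factors contain no missing or infinite values
  expect_true(all(is.finite(fit1$U)))
  expect_true(all(is.finite(fit1$V)))
  # reconstruction stays tropically below R at the given entries
  P <- predict(fit1)
  g <- sim$masked$given
  expect_true(all(P[g] <= sim$masked$values[g] + 1e-9))
  expect_error(stmf(sim$masked, rank = 99), "rank")
  expect_error(stmf(sim$masked, rank = 0), "rank")
})

test_that("prediction inverts the column permutation applied during fitting", {
  sim <- simulate_stmf_data(15, 8, rank = 2, seed = 13)
  fit <- stmf(sim$masked, rank = 2, max_iter = 30, seed = 13,
              ordering = "column_min_increasing")
  expect_false(identical(fit$column_permutation, 1:8))  # regime reorders
  P <- predict(fit)
  # column j of the prediction is the reconstruction of original column j
  recon <- trop_mul(fit$U, fit$V)
  expect_identical(P[, fit$column_permutation], recon)
  # approximation respects the training data in original coordinates
  g <- sim$masked$given
  expect_true(all(P[g] <= sim$masked$values[g] + 1e-9))
})

test_that("latent components recombine to the full reconstruction", {
  sim <- simulate_stmf_data(15, 10, rank = 3, seed = 17)
  fit <- stmf(sim$masked, rank = 3, max_iter = 30, seed = 17)
  comps <- lapply(1:3, function(i) latent_component(fit, i)$values)
  # each entry of component i is the plain sum U[p, i] + V[i, q]
  inv <- order(fit$column_permutation)
  expect_equal(comps[[2]],
               outer(fit$U[, 2], fit$V[2, ], `+`)[, inv])
  expect_identical(pmax(comps[[1]], pmax(comps[[2]], comps[[3]])),
                   predict(fit))
  expect_error(latent_component(fit, 4), "1..3")
  # rank-1 model: the single component is the whole reconstruction
  fit1 <- stmf(sim$masked, rank = 1, max_iter = 10, seed = 17)
  expect_identical(latent_component(fit1, 1)$values, predict(fit1))
})

test_that("swapping the ULF/URF attempt order leaves the fit quality unchanged", {
  final_errors <- function(order_name) {
    vapply(1:10, function(s) {
      sim <- simulate_stmf_data(20, 12, rank = 2, seed = 100 + s)
      fit <- stmf(sim$masked, rank = 2, max_iter = 50, seed = 100 + s,
                  update_order = order_name)
      fit$error_trace[length(fit$error_trace)]
    }, numeric(1))
  }
  ulf_first <- final_errors("ulf_first")
  urf_first <- final_errors("urf_first")
  m1 <- median(ulf_first); m2 <- median(urf_first)
  expect_lt(abs(m1 - m2), 0.25 * max(m1, m2, 1e-6))
})
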