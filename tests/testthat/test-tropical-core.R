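test_that("tropical addition is entrywise max with semiring scalar behavior", {
  expect_identical(trop_add(2, 3), matrix(3, 1, 1))
  A <- rand_int_matrix(3, 3) + 0
  expect_identical(trop_add(A, A), A)                  # idempotent
  B <- rand_int_matrix(3, 3) + 0
  expect_identical(trop_add(A, B), trop_add(B, A))     # commutative
  expect_identical(trop_add(A, B), pmax(A, B))         # entrywise comparison
  expect_error(trop_add(matrix(0, 2, 2), matrix(0, 2, 3)), "shape")
})

test_that("tropical product matches brute-force enumeration and its identity", {
  expect_identical(trop_mul(1, 1), matrix(2, 1, 1))
  A <- matrix(c(0, 2, 1, 3), 2, 2)  # rows (0,1), (2,3)
  expect_identical(trop_mul(A, matrix(0, 2, 2)),
                   matrix(c(1, 3, 1, 3), 2, 2))
  expect_identical(trop_mul(trop_identity(2), A), A)
  withr::with_seed(42, {
    for (rep in 1:20) {
      X <- rand_int_matrix(3, 4) + 0
      Y <- rand_int_matrix(4, 2) + 0
      expect_equal(trop_mul(X, Y), oracle_trop_mul(X, Y))
    }
  })
  expect_error(trop_mul(matrix(0, 2, 3), matrix(0, 2, 3)), "dimension")
})

test_that("tropical product is associative and distributes over addition", {
  withr::with_seed(7, {
    for (rep in 1:25) {
      A <- rand_int_matrix(4, 3) + 0
      B <- rand_int_matrix(3, 4) + 0
      C <- rand_int_matrix(4, 2) + 0
      expect_identical(trop_mul(trop_mul(A, B), C),
                       trop_mul(A, trop_mul(B, C)))
      B2 <- rand_int_matrix(3, 4) + 0
      expect_identical(trop_mul(A, trop_add(B, B2)),
                       trop_add(trop_mul(A, B), trop_mul(A, B2)))
    }
  })
})

test_that("masked (min,+) product skips unknown values", {
  # fully given input reduces to the plain (min,+) product
  withr::with_seed(3, {
    for (rep in 1:10) {
      A <- rand_int_matrix(3, 4) + 0
      B <- rand_int_matrix(4, 3) + 0
      expect_equal(min_plus_masked(A, B), oracle_min_plus(A, B))
    }
  })
  # row 1 can only use k = 1 (second operand entry missing)
  A <- matrix(c(0, 0, NA, 1), 2, 2)
  B <- matrix(c(5, 0), 2, 1)
  expect_identical(min_plus_masked(A, B), matrix(c(5, 1), 2, 1))
  # single given entry: the min is that one admissible sum
  A1 <- matrix(c(NA, 7, NA), 1, 3)
  B1 <- matrix(c(1, 2, 3), 3, 1)
  expect_identical(min_plus_masked(A1, B1), matrix(9, 1, 1))
  # no admissible index at some (i, j) is an error
  A2 <- matrix(c(1, NA, NA, 1), 2, 2)
  B2 <- matrix(c(NA, 1, 1, NA), 2, 2)
  expect_error(min_plus_masked(A2, B2), "no index k")
})

test_that("greatest subsolution solves small systems by the closed form", {
  # 1x1 system is exactly solvable
  x <- greatest_subsolution(matrix(0, 1, 1), 5)
  expect_identical(x, 5)
  expect_identical(trop_mul(matrix(0, 1, 1), matrix(x, 1, 1)), matrix(5, 1, 1))
  # hand evaluation: min(1 - 0, 2 - 0) = 1 in both coordinates
  expect_identical(greatest_subsolution(matrix(0, 2, 2), c(1, 2)), c(1, 1))
  expect_error(greatest_subsolution(matrix(0, 2, 2), c(1, 2, 3)), "length")
})

test_that("greatest subsolution is feasible and grid-maximal", {
  withr::with_seed(11, {
    for (rep in 1:30) {
      n <- sample(2:3, 1)
      A <- rand_int_matrix(3, n) + 0
      c_vec <- as.numeric(rand_int_matrix(3, 1))
      x <- greatest_subsolution(A, c_vec)
      expect_true(trop_leq(trop_mul(A, cbind(x)), cbind(c_vec)))
      # brute-force oracle: every point of the unit grid above x is infeasible
      deltas <- as.matrix(expand.grid(rep(list(0:1), n)))
      deltas <- deltas[rowSums(deltas) > 0, , drop = FALSE]
      for (d in seq_len(nrow(deltas))) {
        xp <- x + deltas[d, ]
        expect_false(trop_leq(trop_mul(A, cbind(xp)), cbind(c_vec)))
      }
    }
  })
})

test_that("one-sided solvers skip masked entries and attain solvable systems", {
  # exact attainment on a fully observed tropical product
  withr::with_seed(21, {
    U0 <- matrix(runif(12), 6, 2)
    V0 <- matrix(runif(8), 2, 4)
    R <- trop_mul(U0, V0)
    V <- solve_right(U0, R)
    expect_lt(b_norm(R - trop_mul(U0, V)), 1e-9)
    U <- solve_left(V0, R)
    expect_lt(b_norm(R - trop_mul(U, V0)), 1e-9)
  })
  # scalar case: plain subtraction
  expect_identical(solve_right(matrix(2, 1, 1), matrix(7, 1, 1)),
                   matrix(5, 1, 1))
  # min over given rows only: masked row of R is skipped
  U1 <- matrix(c(0, 1), 2, 1)
  expect_identical(solve_right(U1, matrix(c(3, NA), 2, 1)), matrix(3, 1, 1))
  # a column with no given entry cannot be solved for
  expect_error(solve_right(matrix(0, 2, 1), matrix(c(3, NA, NA, NA), 2, 2)),
               "no given entries")
  expect_error(solve_left(matrix(0, 1, 2), matrix(c(3, NA, NA, NA), 2, 2)),
               "no given entries")
  # mirror identity through transposition
  withr::with_seed(22, {
    V2 <- matrix(runif(6), 2, 3)
    R2 <- rand_masked(matrix(runif(12), 4, 3))
    left <- solve_left(V2, R2)
    right_t <- t(solve_right(t(V2), masked_matrix(t(R2$values))))
    expect_equal(left, right_t)
  })
  # random masked instances against the loop oracle
  withr::with_seed(23, {
    for (rep in 1:10) {
      U3 <- matrix(runif(15), 5, 3)
      R3 <- rand_masked(matrix(runif(20), 5, 4))
      expect_equal(solve_right(U3, R3), oracle_solve_right(U3, R3$values))
    }
  })
})

test_that("solver feasibility holds at every given entry", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      U <- matrix(runif(12), 6, 2)
      R <- rand_masked(matrix(runif(24, 0, 2), 6, 4))
      V <- solve_right(U, R)
      P <- trop_mul(U, V)
      expect_true(all(P[R$given] <= R$values[R$given] + 1e-9))
    }
  })
})

test_that("b-norm sums absolute values over given entries only", {
  expect_identical(b_norm(matrix(0, 3, 3)), 0)
  W <- matrix(c(1, 3, -2, 0), 2, 2)
  expect_identical(b_norm(W), 6)
  expect_identical(b_norm(-W), b_norm(W))
  Wm <- masked_matrix(matrix(c(1, NA, -2, 4), 2, 2))
  expect_identical(b_norm(Wm), 7)
})

test_that("the tropical order is the entrywise order", {
  A <- rand_int_matrix(3, 3) + 0
  expect_true(trop_leq(A, A))
  expect_true(trop_leq(matrix(1, 1, 1), matrix(2, 1, 1)))
  expect_false(trop_leq(matrix(2, 1, 1), matrix(1, 1, 1)))
  withr::with_seed(5, {
    for (rep in 1:10) {
      z <- rand_int_matrix(2, 3) + 0
      w <- rand_int_matrix(2, 3) + 0
      expect_identical(trop_leq(z, w), all(z <= w))
      # definitional form: z below w iff z (+) w = w
      expect_identical(trop_leq(z, w), identical(trop_add(z, w), w))
    }
  })
  expect_error(trop_leq(matrix(0, 1, 2), matrix(0, 2, 1)), "shape")
})

test_that("dense tropical matrices reject NaN and masked matrices enforce coverage", {
  expect_error(trop_add(matrix(c(1, NA), 1, 2), matrix(0, 1, 2)), "masked_matrix")
  expect_error(masked_matrix(matrix(c(NA, 1, NA, 2), 2, 2)), "row")
  expect_error(masked_matrix(matrix(c(1, 2, NA, NA), 2, 2)), "column")
})
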