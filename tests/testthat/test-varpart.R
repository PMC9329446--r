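test_that("two-matrix partitioning satisfies its defining identities", {
  Y <- randMatrix(20, 3, seed = 30)
  X1 <- randMatrix(20, 2, seed = 31)
  X2 <- randMatrix(20, 2, seed = 32)
  vp <- varpart2(Y, X1, X2, labels = c("E", "S"))
  f <- fractions(vp)
  expect_named(f, c("E", "S", "ES"))
  expect_lt(abs(sum(f) + residualFraction(vp) - 1), 1e-12)
  # unique + unique + shared equals the joint adjusted R2
  a12 <- cuvarp:::simpleAdjR2(Y, cbind(X1, X2))
  expect_equal(sum(f), a12, tolerance = 1e-12)
  # total collinearity: duplicated matrix has no unique parts
  vd <- varpart2(Y, X1, X1)
  expect_equal(unname(fractions(vd)[1:2]), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(fractions(vd)[3]), cuvarp:::simpleAdjR2(Y, X1),
               tolerance = 1e-12)
})

test_that("two-matrix fractions agree with the vegan reference", {
  Y <- randMatrix(25, 3, seed = 33)
  X1 <- randMatrix(25, 2, seed = 34)
  X2 <- randMatrix(25, 2, seed = 35)
  vp <- varpart2(Y, X1, X2)
  v <- vegan::varpart(Y, X1, X2)$part$indfract$Adj.R.square
  expect_equal(unname(c(fractions(vp), residualFraction(vp))), v,
               tolerance = 1e-10)
})

test_that("perfect-fit limit concentrates the partition in unique1", {
  x1 <- randMatrix(100, 1, seed = 36)
  x2 <- randMatrix(100, 1, seed = 37)
  vp <- varpart2(x1, x1, x2)
  f <- fractions(vp)
  expect_lt(abs(f[[1]] - 1), 0.05)
  expect_lt(abs(f[[2]]), 0.05)
  expect_lt(abs(f[[3]]), 0.05)
  expect_lt(abs(residualFraction(vp)), 0.05)
})

test_that("three-matrix partitioning closes and matches vegan", {
  Y <- randMatrix(30, 3, seed = 38)
  X1 <- randMatrix(30, 2, seed = 39)
  X2 <- randMatrix(30, 2, seed = 40)
  X3 <- randMatrix(30, 2, seed = 41)
  vp <- varpart3(Y, X1, X2, X3, labels = c("A", "E", "S"))
  f <- fractions(vp)
  expect_named(f, c("A", "E", "S", "AE", "AS", "ES", "AES"))
  expect_lt(abs(sum(f) + residualFraction(vp) - 1), 1e-12)
  # vegan orders the pairwise-shared fractions as [1&2], [2&3], [1&3]
  v <- vegan::varpart(Y, X1, X2, X3)$part$indfract$Adj.R.square
  expect_equal(unname(c(f, residualFraction(vp))),
               v[c(1, 2, 3, 4, 6, 5, 7, 8)], tolerance = 1e-10)
  expect_error(varpart3(matrix(1, 30, 1), X1, X2, X3), "constant")
})

test_that("orthogonal predictor designs leave shared fractions near zero", {
  set.seed(42)
  n <- 300
  basis <- qr.Q(qr(matrix(rnorm(n * 3), n, 3))) * sqrt(n - 1)
  y <- basis %*% c(1, 1, 1) + rnorm(n)
  vp <- varpart3(matrix(y), basis[, 1, drop = FALSE],
                 basis[, 2, drop = FALSE], basis[, 3, drop = FALSE],
                 labels = c("A", "E", "S"))
  f <- fractions(vp)
  expect_true(all(abs(f[c("AE", "AS", "ES", "AES")]) < 0.05))
})

test_that("fraction tests cover simple and unique effects, never shared", {
  x1 <- randMatrix(40, 1, seed = 43)
  x2 <- randMatrix(40, 1, seed = 44)
  y <- 2 * x1 + 0.3 * randMatrix(40, 1, seed = 45)
  tf <- testFractions(y, list(E = x1, S = x2), nPerm = 199, seed = 8)
  expect_named(tf, c("simple_E", "unique_E", "simple_S", "unique_S"))
  expect_true(all(vapply(tf, pValue, 0) >= 1 / 200))
  expect_lte(pValue(tf$simple_E), 0.01)
  expect_lte(pValue(tf$unique_E), 0.01)
  expect_gt(pValue(tf$unique_S), 0.05)
})

test_that("chi-squared class comparison follows the textbook statistic", {
  r0 <- chisqFractionCompare(c(25, 25, 25, 25), c(25, 25, 25, 25))
  expect_equal(r0@statistic, 0)
  r <- chisqFractionCompare(c(10, 20, 30, 40), c(25, 25, 25, 25),
                            labels = c("uE", "uS", "shared", "resid"))
  expect_equal(r@statistic, 20)
  expect_equal(r@df, 3L)
  expect_error(chisqFractionCompare(c(1, 2), c(0, 3)), "positive")
  expect_error(chisqFractionCompare(c(1, 2), c(1, 2, 3)), "equal length")
})
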