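test_that("PCoA reproduces the brute-force double-centering oracle", {
  xy <- sampleTable(data.frame(row.names = c("a", "b", "c"),
                               x = c(0, 3, 0), y = c(0, 0, 4)))
  d <- euclideanMatrix(xy)
  o <- pcoa(d)
  # total SS about the centroid
  expect_equal(sum(eigenvalues(o)), 16 + 2 / 3, tolerance = 1e-10)
  # reconstruction: score distances reproduce the input
  rec <- as.matrix(dist(as.matrix(tableData(scoreTable(o)))))
  expect_lt(max(abs(rec - distValues(d))), 1e-8)
  # eigenvalues match the independent oracle
  e <- bruteForcePcoa(distValues(d))
  expect_equal(eigenvalues(o), e$values[e$values > 1e-8 * max(e$values)],
               tolerance = 1e-10)
})

test_that("PCoA scores equal the oracle eigenvectors up to fixed sign", {
  set.seed(4)
  d <- gowerMatrix(mixedTable(8, seed = 4))
  o <- pcoa(d)
  e <- bruteForcePcoa(distValues(d))
  keep <- which(e$values > 1e-8 * max(abs(e$values)))
  orc <- sweep(e$vectors[, keep, drop = FALSE], 2, sqrt(e$values[keep]), `*`)
  got <- as.matrix(tableData(scoreTable(o)))
  expect_equal(ncol(got), length(keep))
  for (j in seq_len(ncol(got)))
    expect_lt(min(max(abs(got[, j] - orc[, j])),
                  max(abs(got[, j] + orc[, j]))), 1e-8)
  # sign convention: largest-magnitude loading is positive
  for (j in seq_len(ncol(got)))
    expect_gt(got[which.max(abs(got[, j])), j], 0)
})

test_that("PCoA of Euclidean distances spans the centred coordinates", {
  m <- randMatrix(10, 3, seed = 5)
  o <- pcoa(euclideanMatrix(quantTable(m)))
  sc <- as.matrix(tableData(scoreTable(o)))
  cx <- scale(m, scale = FALSE)
  # projecting the scores on the centred coordinates loses nothing
  resid <- qr.resid(qr(cx), sc)
  expect_lt(max(abs(resid)), 1e-8)
  expect_equal(ncol(sc), qr(cx)$rank)
})

test_that("degenerate all-zero distances give zero retained axes", {
  d <- distanceMatrix(matrix(0, 3, 3), ids = c("a", "b", "c"))
  o <- pcoa(d)
  expect_length(eigenvalues(o), 0)
  expect_equal(ncol(tableData(scoreTable(o))), 0)
})

test_that("total variance equals the PCA eigenvalue sum", {
  m <- randMatrix(15, 4, seed = 6)
  expect_equal(pcaTotalVariance(quantTable(m)),
               sum(eigen(cov(m))$values), tolerance = 1e-10)
  # constant columns contribute nothing; single column is its variance
  expect_equal(pcaTotalVariance(cbind(m, const = 5)),
               pcaTotalVariance(m))
  expect_equal(pcaTotalVariance(m[, 1, drop = FALSE]), var(m[, 1]))
  expect_error(pcaTotalVariance(m[1, , drop = FALSE]), "two rows")
})

test_that("RDA trace R2 equals the SS-weighted per-column OLS oracle", {
  Y <- randMatrix(20, 3, seed = 7)
  X <- randMatrix(20, 2, seed = 8)
  f <- rdaFit(Y, X)
  tot <- colSums(scale(Y, scale = FALSE)^2)
  r2s <- vapply(1:3, function(j) summary(lm(Y[, j] ~ X))$r.squared, 0)
  expect_equal(f@r2, sum(r2s * tot) / sum(tot), tolerance = 1e-10)
})

test_that("RDA agrees with the vegan reference on R2, adjR2 and pseudo-F", {
  Y <- randMatrix(25, 4, seed = 9)
  X <- randMatrix(25, 3, seed = 10)
  f <- rdaFit(Y, X)
  v <- vegan::RsquareAdj(vegan::rda(Y ~ X))
  expect_equal(f@r2, v$r.squared, tolerance = 1e-10)
  expect_equal(adjR2(f), v$adj.r.squared, tolerance = 1e-10)
  # pseudo-F against the variance-ratio identity on an exact construction:
  # fitted and residual SS equal by design -> r2 = 1/2, F = 8 at n=10, m=1
  x <- c(1, -1, rep(0, 8))
  z <- c(0, 0, 1, -1, rep(0, 6)) * sqrt(sum(x^2) / 2)
  f2 <- rdaFit(matrix(x + z), matrix(x))
  expect_equal(f2@r2, 0.5, tolerance = 1e-12)
  expect_equal(f2@pseudoF, 8, tolerance = 1e-10)
})

test_that("RDA degenerate and boundary cases behave as specified", {
  x <- randMatrix(30, 1, seed = 11)
  f <- rdaFit(2 * x, x)                     # perfect fit
  expect_equal(f@r2, 1)
  expect_equal(adjR2(f), 1)
  y <- matrix(c(1, -1, 0, 0), dimnames = list(paste0("s", 1:4), "y"))
  xo <- matrix(c(0, 0, 1, -1))              # centred, orthogonal to y
  expect_equal(rdaFit(y, xo)@r2, 0)
  # covariate identical to predictor absorbs it completely
  f3 <- rdaFit(randMatrix(20, 2, seed = 12), x = randMatrix(20, 1, seed = 13),
               w = randMatrix(20, 1, seed = 13))
  expect_equal(f3@m, 0L)
  expect_equal(f3@r2, 0)
  expect_error(rdaFit(matrix(1, 10, 1), randMatrix(10, 1, 14)), "constant")
  expect_error(rdaFit(randMatrix(4, 1, 15), randMatrix(4, 3, 16)), "small")
})

test_that("R2 is invariant under invertible reparameterisation of X", {
  Y <- randMatrix(20, 2, seed = 17)
  X <- randMatrix(20, 3, seed = 18)
  set.seed(19)
  A <- matrix(rnorm(9), 3, 3)
  while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3, 3)
  expect_equal(rdaFit(Y, X)@r2, rdaFit(Y, X %*% A)@r2, tolerance = 1e-10)
})

test_that("Ezekiel adjustment matches hand values and is monotone", {
  expect_equal(adjustedR2(0.5, 10, 2), 1 - 0.5 * 9 / 7)
  expect_equal(adjustedR2(1, 10, 3), 1)
  expect_equal(adjustedR2(0.42, 10, 0), 0.42)
  expect_error(adjustedR2(0.5, 4, 3), "n > m")
  r2s <- seq(0.1, 0.9, 0.1)
  a <- vapply(r2s, adjustedR2, 0, n = 20, m = 3)
  expect_true(all(diff(a) > 0))
  ms <- 1:6
  b <- vapply(ms, function(m) adjustedR2(0.5, 20, m), 0)
  expect_true(all(diff(b) < 0))
})
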