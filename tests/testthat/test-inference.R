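test_that("every design kind returns bijections honouring its restrictions", {
  set.seed(20)
  designs <- list(
    permutationDesign("free"),
    permutationDesign("blocks", blocks = rep(c("b1", "b2"), each = 4)),
    permutationDesign("series", blocks = rep(c("t1", "t2"), each = 4)),
    permutationDesign("split_plot", blocks = rep(c("s1", "s2"), each = 4)))
  for (d in designs) for (i in 1:25) {
    p <- generatePermutation(d, 8)
    expect_identical(sort(p), 1:8)
  }
  # blocks never leak rows across blocks
  d <- permutationDesign("blocks", blocks = rep(c("b1", "b2"), each = 4))
  for (i in 1:25) {
    p <- generatePermutation(d, 8)
    expect_true(all(p[1:4] %in% 1:4) && all(p[5:8] %in% 5:8))
  }
})

test_that("series orbit is exactly the cyclic shifts (mirror doubles it)", {
  d <- permutationDesign("series", blocks = rep("b", 4))
  orb <- enumeratePermutations(d, 4)
  expect_equal(nrow(orb), 4)
  set.seed(21)
  draws <- unique(t(replicate(2000, generatePermutation(d, 4))))
  expect_equal(nrow(draws), 4)
  expect_true(all(apply(draws, 1, function(r)
    any(apply(orb, 1, identical, as.integer(r))))))
  dm <- permutationDesign("series", blocks = rep("b", 4), mirror = TRUE)
  expect_equal(nrow(enumeratePermutations(dm, 4)), 8)
})

test_that("split-plot draws keep blocks adjacent and internally ordered", {
  d <- permutationDesign("split_plot", blocks = c("s1", "s1", "s2", "s2"))
  set.seed(22)
  for (i in 1:50) {
    p <- generatePermutation(d, 4)
    # the rows of s1 (1,2) stay adjacent and in order wherever they land
    pos <- which(p %in% 1:2)
    expect_equal(diff(pos), 1)
    expect_identical(p[pos], 1:2)
  }
  expect_equal(nrow(enumeratePermutations(d, 4)), 2)
  # with within-block shifts both levels are active
  d2 <- permutationDesign("split_plot", blocks = rep(c("a", "b"), each = 3),
                          shiftWithin = TRUE)
  expect_equal(nrow(enumeratePermutations(d2, 6)), 2 * 3 * 3)
  expect_error(permutationDesign("split_plot",
                                 blocks = c("a", "a", "b")) |>
                 generatePermutation(3), "equal block sizes")
})

test_that("exhaustive mode reproduces full-enumeration exact p-values", {
  set.seed(23)
  y <- matrix(rnorm(4), dimnames = list(paste0("s", 1:4), "y"))
  x <- matrix(rnorm(4))
  t <- permutationTest(y, x, nPerm = 999, seed = 1)
  expect_true(t@exhaustive)
  expect_equal(t@nPerm, 24L)
  # independent oracle: enumerate all 24 row orders by hand
  perms <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  fOf <- function(p) {
    yc <- scale(y[p, , drop = FALSE], scale = FALSE)
    xc <- scale(x, scale = FALSE)
    fit <- xc %*% solve(crossprod(xc), crossprod(xc, yc))
    r2 <- sum(fit^2) / sum(yc^2)
    (r2 / 1) / ((1 - r2) / 2)
  }
  fObs <- fOf(1:4)
  pExact <- mean(apply(perms, 1, fOf) >= fObs - 1e-12)
  expect_equal(t@pValue, pExact)
})

test_that("Monte Carlo p-values respect the estimator floor and the seed", {
  x <- randMatrix(30, 1, seed = 24)
  y <- 2 * x + randMatrix(30, 1, seed = 25) * 0.01
  t1 <- permutationTest(y, x, nPerm = 999, seed = 7, exhaustive = "never")
  expect_gte(t1@pValue, 1 / 1000)
  t2 <- permutationTest(y, x, nPerm = 999, seed = 7, exhaustive = "never")
  expect_identical(t1, t2)
  expect_error(permutationTest(y, x, nPerm = 99), "seed")
})

test_that("Freedman-Lane partial tests reject true covariate-borne signal", {
  set.seed(26)
  w <- matrix(rnorm(50))
  y <- 3 * w + matrix(rnorm(50), 50, 1) * 0.5  # y depends on w only
  x <- matrix(rnorm(50))
  t <- permutationTest(y, x, w, nPerm = 199, seed = 3)
  expect_gt(t@pValue, 0.05)   # x has nothing beyond w
  y2 <- 3 * w + 2 * x + matrix(rnorm(50), 50, 1) * 0.5
  t2 <- permutationTest(y2, x, w, nPerm = 199, seed = 3)
  expect_lte(t2@pValue, 0.01)
})

test_that("BH adjustment matches the hand step-up and its properties", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrAdjust(0.2), 0.2)
  set.seed(27)
  p <- runif(20)
  a <- fdrAdjust(p)
  expect_true(all(a >= p))
  expect_true(all(diff(fdrAdjust(sort(p))[order(order(sort(p)))]) >= 0) ||
                !is.unsorted(fdrAdjust(sort(p))))
  expect_error(fdrAdjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("forward selection finds planted signal and rejects pure noise", {
  set.seed(28)
  x1 <- rnorm(100)
  y <- matrix(2 * x1 + rnorm(100), dimnames = list(NULL, "y"))
  cand <- cbind(signal = x1, noise = rnorm(100))
  sel <- forwardSelect(y, cand, alpha = 0.05, nPerm = 199, seed = 5)
  expect_identical(selectedVariables(sel), "signal")
  # adjusted R2 of the selected model is non-decreasing over steps
  ent <- sel@steps[sel@steps$entered, ]
  expect_true(all(ent$adjR2Gain >= -1e-12) || nrow(ent) <= 1)
  # identical seed, identical result
  sel2 <- forwardSelect(y, cand, alpha = 0.05, nPerm = 199, seed = 5)
  expect_identical(sel, sel2)
  # pure-noise candidates with a noise response: nothing enters
  y0 <- matrix(rnorm(100))
  sel0 <- forwardSelect(y0, cand, alpha = 0.05, nPerm = 199, seed = 6)
  expect_length(selectedVariables(sel0), 0)
  expect_identical(sel0@stopReason, "alpha_fail")
})
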