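test_that("the generator is bit-reproducible and shape-correct", {
  p <- synthParams(nSites = 15, nNative = 10, nAlien = 4, seed = 70)
  b1 <- simulateRiverscape(p)
  b2 <- simulateRiverscape(p)
  expect_identical(tableData(b1@native), tableData(b2@native))
  expect_identical(tableData(b1@environment), tableData(b2@environment))
  expect_identical(b1@truth$native$realizedShares,
                   b2@truth$native$realizedShares)
  expect_equal(dim(b1@native), c(15L, 10L))
  expect_equal(dim(b1@alien), c(15L, 4L))
  expect_equal(ncol(b1@coords), 1L)   # 1-D transect
  expect_identical(sampleIDs(b1@native), sampleIDs(b1@coords))
  expect_equal(nrow(b1@nativeTraits), 10L)
  expect_identical(unname(variableKinds(b1@environment)[1:4]),
                   c("factor", "ordinal", "ordinal", "quantitative"))
})

test_that("response links produce the declared value types", {
  pc <- synthParams(nSites = 15, responseModel = "poisson-counts", seed = 71)
  cnts <- as.matrix(tableData(simulateRiverscape(pc)@native))
  expect_true(all(cnts >= 0 & cnts == round(cnts)))
  pb <- synthParams(nSites = 15, responseModel = "binary-threshold", seed = 71)
  bin <- as.matrix(tableData(simulateRiverscape(pb)@native))
  expect_true(all(bin %in% c(0, 1)))
})

test_that("realised latent shares track the design closely at large n", {
  p <- synthParams(nSites = 1000, responseModel = "gaussian-latent", seed = 72)
  b <- simulateRiverscape(p)
  expect_lt(max(abs(b@truth$native$realizedShares - p@sharesNative)), 0.02)
  expect_lt(max(abs(b@truth$alien$realizedShares - p@sharesAlien)), 0.02)
})

test_that("design-share layout matches the two-predictor fraction keys", {
  p <- synthParams()
  ef <- expectedFractions(p)
  expect_identical(names(ef), c("E", "S", "ES", "residual"))
  expect_equal(unname(ef), c(0.3, 0.2, 0.1, 0.4))
  # zero-noise design has zero residual
  p0 <- synthParams(sharesNative = c(env = 0.5, space = 0.3, shared = 0.2,
                                     noise = 0))
  expect_equal(expectedFractions(p0)[["residual"]], 0)
  # keys line up with what varpart2 emits
  b <- simulateRiverscape(synthParams(nSites = 30, seed = 73,
                                      responseModel = "gaussian-latent"))
  vp <- varpart2(b@native, b@truth$native$channels$E,
                 b@truth$native$channels$S, labels = c("E", "S"))
  expect_identical(names(fractions(vp)), setdiff(names(ef), "residual"))
})

test_that("invalid share vectors are rejected", {
  expect_error(synthParams(sharesNative = c(env = 0.5, space = 0.3,
                                            shared = 0.3, noise = 0.1)),
               "sum to 1")
  expect_error(synthParams(sharesAlien = c(env = -0.1, space = 0.5,
                                           shared = 0.2, noise = 0.4)),
               "non-negative")
})

test_that("bundles round-trip through their on-disk layout", {
  b <- simulateRiverscape(synthParams(nSites = 12, nNative = 6, nAlien = 3,
                                      seed = 74))
  dir <- withr::local_tempdir()
  writeBundle(b, dir)
  expect_true(all(file.exists(file.path(dir,
    c("native.csv", "alien.csv", "env.csv", "coords.csv",
      "native_traits.csv", "alien_traits.csv", "env_schema.yaml",
      "traits_schema.yaml", "truth.json")))))
  env <- readSampleTable(file.path(dir, "env.csv"),
                         readSchema(file.path(dir, "env_schema.yaml")))
  expect_identical(tableData(env), tableData(b@environment))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$seed, 74)
  expect_equal(unlist(truth$sharesNative), b@truth$params@sharesNative)
})
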