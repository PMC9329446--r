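test_that("taxonomic indices match hand-evaluated distributions", {
  u <- taxonomicIndices(c(5, 5, 5, 5))
  expect_equal(unname(u), c(4, log(4), 1, 4), tolerance = 1e-10)
  expect_equal(taxonomicIndices(c(1, 3))[["H"]],
               -(0.25 * log(0.25) + 0.75 * log(0.75)), tolerance = 1e-10)
  mono <- taxonomicIndices(c(0, 7, 0))
  expect_equal(unname(mono[c("S", "H", "N2")]), c(1, 0, 1))
  expect_true(is.na(mono[["J"]]))   # 0/0, reported missing not zero
  expect_error(taxonomicIndices(c(0, 0)), "all-zero")
})

test_that("Hill-number ordering N2 <= exp(H) <= S holds on random vectors", {
  set.seed(60)
  for (i in 1:50) {
    v <- rpois(sample(3:12, 1), lambda = 3) + ifelse(runif(1) < 0.5, 0, 1)
    if (sum(v) == 0) v[1] <- 1
    r <- taxonomicIndices(v)
    expect_lte(r[["N2"]], exp(r[["H"]]) + 1e-10)
    expect_lte(exp(r[["H"]]), r[["S"]] + 1e-10)
  }
})

test_that("Rao Q matches hand sums, closed forms, and invariances", {
  d2 <- distanceMatrix(matrix(c(0, 1, 1, 0), 2, 2), ids = c("a", "b"))
  expect_equal(raoQ(c(a = 1, b = 1), d2), 0.5)
  # identical traits: zero entropy
  d0 <- distanceMatrix(matrix(0, 3, 3), ids = c("a", "b", "c"))
  expect_equal(raoQ(c(a = 2, b = 1, c = 5), d0), 0)
  # constant-distance closed form c * (1 - sum p^2), exact
  set.seed(61)
  for (i in 1:20) {
    k <- sample(3:7, 1)
    cc <- runif(1, 0.5, 3)
    dm <- matrix(cc, k, k); diag(dm) <- 0
    ids <- paste0("sp", 1:k)
    d <- distanceMatrix(dm, ids = ids)
    p <- runif(k)
    q <- raoQ(setNames(p, ids), d)
    expect_equal(q, cc * (1 - sum((p / sum(p))^2)), tolerance = 1e-12)
    # invariant to rescaling the counts
    expect_equal(raoQ(setNames(10 * p, ids), d), q, tolerance = 1e-12)
  }
  expect_error(raoQ(c(x = 1, y = 1), d2), "do not match")
})

test_that("trait space embeds Gower distances faithfully", {
  tr <- mixedTable(7, seed = 62)
  ts <- traitSpace(tr)
  g <- gowerMatrix(tr)
  e <- bruteForcePcoa(distValues(g))
  if (all(e$values > -1e-8 * max(e$values))) {
    # Euclidean-embeddable: the score distances reproduce Gower
    expect_lt(max(abs(distValues(ts@speciesDistance) - distValues(g))), 1e-8)
  }
  # identical trait rows are at distance zero
  d2 <- tr@data[c(1, 1, 3, 4), ]
  rownames(d2) <- paste0("t", 1:4)
  tr2 <- sampleTable(d2, kinds = variableKinds(tr),
                     levels = variableLevels(tr))
  ts2 <- traitSpace(tr2)
  expect_lt(distValues(ts2@speciesDistance)["t1", "t2"], 1e-8)
  # one quantitative trait: scores are an affine image of the values
  t1 <- sampleTable(data.frame(row.names = c("a", "b", "c"),
                               size = c(1, 4, 9)))
  sc <- tableData(traitSpace(t1)@speciesScores)
  expect_equal(abs(cor(sc[[1]], c(1, 4, 9))), 1, tolerance = 1e-10)
})

test_that("community-weighted means respect their arithmetic identities", {
  comm <- sampleTable(data.frame(row.names = c("siteA", "siteB"),
                                 sp1 = c(1, 0), sp2 = c(3, 0)))
  tr <- sampleTable(data.frame(row.names = c("sp1", "sp2"),
                               size = c(2, 4), sex = c("S", "H")),
                    kinds = c(size = "quantitative", sex = "factor"))
  w <- cwm(comm, tr)
  expect_equal(tableData(w)["siteA", "size"], 0.25 * 2 + 0.75 * 4)
  # factor level-proportion columns partition unity
  expect_equal(tableData(w)["siteA", "sex.S"] + tableData(w)["siteA", "sex.H"], 1)
  # zero-abundance site flagged missing
  expect_true(all(is.na(tableData(w)["siteB", ])))
  # all species sharing a value pins the CWM to it
  tr2 <- sampleTable(data.frame(row.names = c("sp1", "sp2"), size = c(3, 3)))
  comm2 <- sampleTable(data.frame(row.names = paste0("s", 1:3),
                                  sp1 = c(1, 2, 5), sp2 = c(4, 1, 0)))
  expect_equal(tableData(cwm(comm2, tr2))$size, rep(3, 3))
  # CWM of a quantitative trait stays inside the species range
  set.seed(63)
  comm3 <- sampleTable(as.data.frame(matrix(rpois(40, 2), 8, 5,
    dimnames = list(paste0("s", 1:8), paste0("sp", 1:5)))))
  tr3 <- sampleTable(data.frame(row.names = paste0("sp", 1:5),
                                x = runif(5, -2, 7)))
  got <- tableData(cwm(comm3, tr3))$x
  ok <- !is.na(got)
  expect_true(all(got[ok] >= min(tr3@data$x) - 1e-12 &
                    got[ok] <= max(tr3@data$x) + 1e-12))
  expect_error(cwm(comm, tr2), NA)
  trBad <- sampleTable(data.frame(row.names = c("sp1", "spX"), size = c(1, 2)))
  expect_error(cwm(comm, trBad), "do not match")
})

test_that("per-site diversity table assembles taxonomic and Rao columns", {
  b <- simulateRiverscape(synthParams(nSites = 12, nNative = 8, nAlien = 3,
                                      seed = 64))
  dt <- diversityTable(b@native, b@alien, b@nativeTraits, b@alienTraits)
  expect_identical(rownames(dt), sampleIDs(b@native))
  expect_true(all(c("S", "H", "J", "N2", "Q_natives", "Q_aliens", "Q_all")
                  %in% colnames(dt)))
  expect_true(all(dt$Q_natives >= 0, na.rm = TRUE))
})
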