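test_that("component construction honours alignment, sources and axis counts", {
  b <- simulateRiverscape(synthParams(nSites = 18, nNative = 8, nAlien = 3,
                                      seed = 80))
  comps <- buildComponents(b@native, b@alien, b@environment, b@coords)
  expect_named(comps, c("H", "A", "E", "S"))
  for (cs in comps)
    expect_identical(sampleIDs(scoreTable(cs)), sampleIDs(b@native))
  expect_identical(vapply(comps, function(c) c@source, ""),
                   c(H = "pcoa", A = "pcoa", E = "pcoa", S = "dbmem"))
  # axis counts equal the positive-eigenvalue counts of an independent oracle
  for (nm in c("H", "A", "E")) {
    tab <- list(H = b@native, A = b@alien, E = b@environment)[[nm]]
    e <- bruteForcePcoa(distValues(gowerMatrix(tab)))
    expect_equal(ncol(tableData(scoreTable(comps[[nm]]))),
                 sum(e$values > 1e-8 * max(abs(e$values))))
  }
  # misaligned input is refused
  shuffled <- sampleTable(tableData(b@alien)[rev(sampleIDs(b@alien)), ])
  expect_error(buildComponents(b@native, shuffled, b@environment, b@coords),
               "alignRows")
})

test_that("consensus selection retains planted axes and logs fallbacks", {
  b <- simulateRiverscape(synthParams(nSites = 80,
                                      responseModel = "gaussian-latent",
                                      seed = 81))
  comps <- buildComponents(b@native, b@alien, b@environment, b@coords)
  sel <- suppressWarnings(selectAxes(comps, alpha = 0.05, nPerm = 199,
                                     seed = 9, maxAxes = 6))
  # strong designed signal: natives and environment keep at least one axis
  # through actual selection (not fallback)
  expect_false("H" %in% sel@fallback)
  expect_false("E" %in% sel@fallback)
  expect_true(all(lengths(sel@axes) >= 1))
  expect_equal(nrow(sel@selectionLog), 12)   # all ordered role pairs
  for (r in names(sel@axes))
    expect_identical(colnames(tableData(sel@scores[[r]])),
                     colnames(tableData(scoreTable(comps[[r]])))[sel@axes[[r]]])
  # pure-noise components fall back to axis 1 with a warning
  set.seed(82)
  noise <- lapply(c("H", "A", "E", "S"), function(r)
    new("ComponentSet", role = r,
        fullScores = quantTable(randMatrix(20, 4, seed = 82 + match(r, c("H","A","E","S")))),
        source = if (r == "S") "dbmem" else "pcoa",
        eigenvalues = rep(1, 4)))
  names(noise) <- c("H", "A", "E", "S")
  w <- testthat::capture_warnings(
    sn <- selectAxes(noise, alpha = 0.05, nPerm = 49, seed = 3))
  expect_true(any(grepl("falling back to axis 1", w)))
  expect_true(all(vapply(sn@axes[sn@fallback], identical, TRUE, 1L)))
})

test_that("reciprocal partitioning returns four closed partitionings", {
  b <- simulateRiverscape(synthParams(nSites = 40,
                                      responseModel = "gaussian-latent",
                                      seed = 83))
  comps <- buildComponents(b@native, b@alien, b@environment, b@coords)
  tabs <- lapply(comps, function(c) {
    st <- scoreTable(c)
    k <- min(2L, ncol(st))
    new("SampleTable", data = tableData(st)[, seq_len(k), drop = FALSE],
        kinds = st@kinds[seq_len(k)], weights = st@weights[seq_len(k)],
        levels = st@levels[seq_len(k)])
  })
  rv <- reciprocalVarpart(tabs, nPerm = 99, seed = 4)
  expect_length(rv$varparts, 4)
  for (r in names(rv$varparts)) {
    vp <- rv$varparts[[r]]
    expect_length(fractions(vp), 7)
    expect_lt(abs(sum(fractions(vp)) + residualFraction(vp) - 1), 1e-12)
    expect_equal(rv$totals[[r]], totalVariance(vp))
  }
  expect_equal(rv$grandTotal, sum(rv$totals))
  # tests attach to simple and unique effects only
  expect_named(rv$tests$H, c("simple_A", "unique_A", "simple_E", "unique_E",
                             "simple_S", "unique_S"))
  # the noisier-by-design aliens keep a larger residual than natives
  expect_gt(residualFraction(rv$varparts$A), residualFraction(rv$varparts$H))
})

test_that("cumulative assembly reproduces the worked region arithmetic", {
  mk <- function(resp, preds, fr, resid, total)
    new("VarpartResult", responseLabel = resp, predictorLabels = preds,
        fractions = fr, residual = resid, totalVariance = total,
        scale = "proportion")
  fr0 <- function(preds) {
    nm <- c(preds, paste0(preds[1], preds[2]), paste0(preds[1], preds[3]),
            paste0(preds[2], preds[3]), paste0(preds, collapse = ""))
    setNames(rep(0, 7), nm)
  }
  frH <- fr0(c("A", "E", "S"))
  frH[c("A", "E", "S", "AE")] <- c(0.1, 0.2, 0.1, 0.2)
  vps <- list(
    H = mk("H", c("A", "E", "S"), frH, 0.4, 10),
    A = mk("A", c("H", "E", "S"), fr0(c("H", "E", "S")), 1, 5),
    E = mk("E", c("H", "A", "S"), fr0(c("H", "A", "S")), 1, 5),
    S = mk("S", c("H", "A", "E"), fr0(c("H", "A", "E")), 1, 5))
  res <- assembleCuvarp(vps)
  reg <- setNames(regions(res)$value, regions(res)$subset)
  expect_equal(reg[["H"]], 4)     # 0.4 x 10
  expect_equal(reg[["HA"]], 1)    # H's unique-A x 10 + A's unique-H x 5
  expect_equal(reg[["HE"]], 2)
  expect_equal(reg[["HS"]], 1)
  expect_equal(reg[["HAE"]], 2)   # H's shared-AE x 10
  expect_equal(unname(reg[c("A", "E", "S")]), c(5, 5, 5))
  expect_equal(sum(regions(res)$value), 25)
  expect_equal(grandTotal(res), 25)
  expect_equal(res@residualSum, 19)
  expect_equal(res@explainedSum, 6)
  # all-zero explained: only singletons carry value
  vps0 <- lapply(vps, function(v) { v@fractions[] <- 0; v@residual <- 1; v })
  res0 <- assembleCuvarp(vps0)
  expect_equal(sum(regions(res0)$value[regions(res0)$size > 1]), 0)
  expect_equal(res0@residualSum, grandTotal(res0))
})

test_that("assembly closes to the grand total on fuzzed partitionings", {
  roles <- c("H", "A", "E", "S")
  for (seed in 1:100) {
    set.seed(seed)
    totals <- runif(4, 0.5, 20)
    vps <- setNames(lapply(seq_along(roles), function(i)
      randomVarpart3(roles[i], setdiff(roles, roles[i]), totals[i],
                     seed = seed * 10 + i)), roles)
    res <- assembleCuvarp(vps)
    expect_lt(abs(sum(regions(res)$value) - grandTotal(res)), 1e-9)
    expect_equal(nrow(regions(res)), 15)
    # negative fractions are preserved in the region values
    expect_equal(res@explainedSum + res@residualSum, grandTotal(res),
                 tolerance = 1e-9)
  }
})

test_that("average (AVARP) regions are means of per-response percents", {
  roles <- c("H", "A", "E", "S")
  vps <- setNames(lapply(seq_along(roles), function(i)
    randomVarpart3(roles[i], setdiff(roles, roles[i]), 4, seed = 200 + i)),
    roles)
  # two-response toy: fractions .2 and .4 for the same region average to .3
  vps$H@fractions[["AE"]] <- vps$H@fractions[["AE"]] +
    (0.2 - vps$H@fractions[["AE"]])
  vps$H@residual <- 1 - sum(vps$H@fractions)
  vps$A@fractions[["HE"]] <- 0.4
  vps$A@residual <- 1 - sum(vps$A@fractions)
  res <- assembleAvarp(vps)
  reg <- setNames(regions(res)$value, regions(res)$subset)
  # region {H,A,E}: mean of H:"AE", A:"HE", E:"HA"
  expect_equal(reg[["HAE"]],
               mean(c(0.2, 0.4, vps$E@fractions[["HA"]])))
  # per-response closure before averaging
  for (v in vps) expect_lt(abs(sum(fractions(v)) + residualFraction(v) - 1),
                           1e-12)
  # four identical partitionings: averages equal each table's own fractions
  same <- setNames(lapply(seq_along(roles), function(i) {
    v <- vps$H
    v@responseLabel <- roles[i]
    v@predictorLabels <- setdiff(roles, roles[i])
    names(v@fractions) <- c(v@predictorLabels,
      paste0(v@predictorLabels[1], v@predictorLabels[2]),
      paste0(v@predictorLabels[1], v@predictorLabels[3]),
      paste0(v@predictorLabels[2], v@predictorLabels[3]),
      paste0(v@predictorLabels, collapse = ""))
    v
  }), roles)
  resSame <- assembleAvarp(same)
  regSame <- setNames(regions(resSame)$value, regions(resSame)$subset)
  expect_equal(regSame[["HA"]], same$H@fractions[["A"]])
  expect_equal(regSame[["H"]], same$H@residual)
})

test_that("diagram export floors, flags and round-trips regions", {
  roles <- c("H", "A", "E", "S")
  vps <- setNames(lapply(seq_along(roles), function(i)
    randomVarpart3(roles[i], setdiff(roles, roles[i]), 3, seed = 300 + i)),
    roles)
  # force the triple-shared region negative in every response, preserving
  # closure by compensating in a pairwise fraction
  for (r in roles) {
    f <- vps[[r]]@fractions
    delta <- f[[7]] + 0.02
    f[[7]] <- -0.02; f[[4]] <- f[[4]] + delta
    vps[[r]]@fractions <- f
  }
  res <- assembleCuvarp(vps)
  spec <- exportDiagram(res, floorNegatives = TRUE)
  expect_equal(nrow(regions(spec)), 15)   # 2^4 - 1, always
  neg <- regions(res)$value < 0
  expect_true(any(neg))
  expect_true(all(regions(spec)$value[neg] == 0))
  expect_true(all(!regions(spec)$rendered[neg]))
  dir <- withr::local_tempdir()
  jf <- file.path(dir, "diagram.json"); sf <- file.path(dir, "diagram.svg")
  exportDiagram(res, jsonFile = jf, svgFile = sf)
  back <- readDiagramJSON(jf)
  expect_equal(regions(back)$value, regions(spec)$value, tolerance = 1e-12)
  expect_identical(regions(back)$rendered, regions(spec)$rendered)
  svg <- readLines(sf)
  hidden <- regions(spec)$subset[!regions(spec)$rendered]
  if (length(hidden))
    expect_false(any(grepl(paste0(">", hidden[1], " "), svg, fixed = TRUE)))
})

test_that("printed-total percent arithmetic is exact", {
  pct <- variationPercents(160.0, 56.442)
  expect_equal(round(pct[["explained"]], 2), 64.72)
  expect_equal(round(pct[["residual"]], 2), 35.28)
  expect_equal(sum(pct), 100)
})

test_that("CWM-AVARP runs end to end on simulated data", {
  b <- simulateRiverscape(synthParams(nSites = 40, nNative = 10, nAlien = 4,
                                      responseModel = "poisson-counts",
                                      seed = 90))
  res <- suppressWarnings(
    cwmAvarp(b@native, b@alien, b@nativeTraits, b@alienTraits,
             b@environment, b@coords, nPerm = 49, seed = 5, maxAxes = 3))
  expect_s4_class(res, "CuvarpResult")
  expect_identical(res@variant, "average")
  expect_equal(nrow(regions(res)), 15)
  for (v in res@varparts)
    expect_lt(abs(sum(fractions(v)) + residualFraction(v) - 1), 1e-12)
})
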