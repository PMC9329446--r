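#' @include AllClasses.R utils.R dissimilarity.R ordination.R inference.R varpart.R spatial_mem.R diversity_traits.R
NULL

#' Build the four CUVARP component score tables
#'
#' Step one of the cumulative partitioning: the native community (H), alien
#' community (A) and environment (E) tables are each embedded by PCoA of
#' their Gower dissimilarities, keeping positive-eigenvalue axes; the
#' spatial component (S) is the db-MEM basis of the coordinates (automatic
#' truncation threshold).  The resulting "all-axes" score tables play the
#' roles H-all, A-all, E-all, S-all in the selection step.
#'
#' @param native,alien,environment sites-by-variables
#'   \linkS4class{SampleTable}s, row-aligned.
#' @param coords transect or plane coordinates, row-aligned with the rest.
#' @return Named list of four \linkS4class{ComponentSet}s (\code{H},
#'   \code{A}, \code{E}, \code{S}).
#' @seealso \code{\link{selectAxes}}, \code{\link{reciprocalVarpart}}
#' @export
buildComponents <- function(native, alien, environment, coords) {
  tabs <- list(H = native, A = alien, E = environment, S = coords)
  ids <- rownames(native@data)
  for (nm in names(tabs))
    if (!identical(rownames(tabs[[nm]]@data), ids))
      stop("tables are not row-aligned; run alignRows() first (offender: ",
           nm, ")")
  out <- list()
  for (nm in c("H", "A", "E")) {
    ord <- pcoa(gowerMatrix(tabs[[nm]]), keep = "positive")
    out[[nm]] <- methods::new("ComponentSet", role = nm,
                              fullScores = ord@scores, source = "pcoa",
                              eigenvalues = ord@eigenvalues)
  }
  mem <- dbmem(coords, threshold = "auto")
  out$S <- methods::new("ComponentSet", role = "S",
                        fullScores = mem@scores, source = "dbmem",
                        eigenvalues = mem@eigenvalues)
  out
}

#' Consensus axis selection across reciprocal analyses
#'
#' Step two: for every ordered pair of roles, the predictor role's full axis
#' set is forward-selected (FDR-guarded, double stopping rule) against the
#' response role's full score table.  An axis is retained for a role when it
#' is selected in at least one analysis where its matrix serves as
#' predictor -- an automated stand-in for the interactive consensus between
#' reciprocal analyses.  A role whose union ends empty falls back to axis 1
#' with a logged warning, so every component enters the partitioning.
#' Fully deterministic given the seed.
#'
#' @param components output of \code{\link{buildComponents}}.
#' @param alpha significance level for forward selection.
#' @param nPerm permutations per candidate test.
#' @param seed mandatory seed.
#' @param design permutation design passed to the tests.
#' @param maxAxes optional cap on the number of candidate axes per role
#'   (leading axes first), to bound the selection cost on wide tables.
#' @return A \linkS4class{SelectedComponents}.
#' @export
selectAxes <- function(components, alpha = 0.05, nPerm = 199L, seed,
                       design = permutationDesign("free"), maxAxes = NULL) {
  if (missing(seed)) stop("a seed is mandatory for any stochastic command")
  roles <- names(components)
  keep <- stats::setNames(vector("list", length(roles)), roles)
  logRows <- list()
  pairIdx <- 0L
  for (pred in roles) for (resp in setdiff(roles, pred)) {
    pairIdx <- pairIdx + 1L
    candTab <- components[[pred]]@fullScores
    if (!is.null(maxAxes) && ncol(candTab@data) > maxAxes)
      candTab <- methods::new("SampleTable",
                              data = candTab@data[, seq_len(maxAxes), drop = FALSE],
                              kinds = candTab@kinds[seq_len(maxAxes)],
                              weights = candTab@weights[seq_len(maxAxes)],
                              levels = candTab@levels[seq_len(maxAxes)])
    sel <- forwardSelect(components[[resp]]@fullScores, candTab,
                         alpha = alpha, nPerm = nPerm,
                         seed = deriveSeed(seed, pairIdx), design = design)
    idx <- match(sel@selected, colnames(components[[pred]]@fullScores@data))
    keep[[pred]] <- sort(union(keep[[pred]], idx))
    logRows[[pairIdx]] <- data.frame(
      predictor = pred, response = resp,
      selected = paste(sort(idx), collapse = ","),
      stopReason = sel@stopReason, adjR2 = sel@finalAdjR2,
      stringsAsFactors = FALSE)
  }
  fallback <- character(0)
  for (r in roles) if (!length(keep[[r]])) {
    keep[[r]] <- 1L
    fallback <- c(fallback, r)
    warning("role ", r, ": no axis selected in any analysis; ",
            "falling back to axis 1")
  }
  scoresList <- lapply(roles, function(r) {
    full <- components[[r]]@fullScores
    idx <- keep[[r]]
    methods::new("SampleTable", data = full@data[, idx, drop = FALSE],
                 kinds = full@kinds[idx], weights = full@weights[idx],
                 levels = full@levels[idx])
  })
  names(scoresList) <- roles
  methods::new("SelectedComponents",
               axes = lapply(keep, as.integer), scores = scoresList,
               selectionLog = do.call(rbind, logRows), fallback = fallback)
}

#' Reciprocal three-predictor variation partitionings
#'
#' Step four: each role's selected-axes table is used in turn as the
#' response matrix with the other three as predictors, giving four
#' three-matrix partitionings with tested simple and conditional effects.
#' Totals are the selected-axes table variances (summed PCA eigenvalues);
#' their sum is the grand total variation of the data.
#'
#' @param selected a \linkS4class{SelectedComponents} (or any named list of
#'   row-aligned all-quantitative score tables).
#' @param design permutation design for the fraction tests.
#' @param nPerm permutations per test.
#' @param seed mandatory seed.
#' @param test run the permutation tests (disable for speed when only the
#'   fractions are needed).
#' @return List with \code{varparts} (named \linkS4class{VarpartResult}s),
#'   \code{tests} (per-role named lists of \linkS4class{TestResult}s, when
#'   enabled), \code{totals} and \code{grandTotal}.
#' @export
reciprocalVarpart <- function(selected, design = permutationDesign("free"),
                              nPerm = 999L, seed, test = TRUE) {
  if (missing(seed)) stop("a seed is mandatory for any stochastic command")
  tabs <- if (methods::is(selected, "SelectedComponents")) selected@scores
          else selected
  roles <- names(tabs)
  stopifnot(length(roles) == 4L)
  varparts <- list(); tests <- list()
  totals <- stats::setNames(numeric(length(roles)), roles)
  for (i in seq_along(roles)) {
    r <- roles[i]
    others <- roles[-i]
    vp <- varpart3(tabs[[r]], tabs[[others[1L]]], tabs[[others[2L]]],
                   tabs[[others[3L]]], labels = others, responseLabel = r)
    varparts[[r]] <- vp
    totals[r] <- vp@totalVariance
    if (test)
      tests[[r]] <- testFractions(tabs[[r]],
                                  stats::setNames(tabs[others], others),
                                  design = design, nPerm = nPerm,
                                  seed = deriveSeed(seed, i), labels = others)
  }
  list(varparts = varparts, tests = if (test) tests else NULL,
       totals = totals, grandTotal = sum(totals))
}

#' Assemble the cumulative (CUVARP) diagram regions
#'
#' Step five: the four reciprocal partitionings are merged into one
#' variance-unit diagram over the non-empty subsets of the roles.  Each
#' singleton region \{X\} is X's residual fraction times X's total (the
#' non-overlap areas are unexplained variation); each larger region
#' \eqn{T} receives, from every member X taken as response, X's fraction
#' keyed by the other members of \eqn{T}, in X's variance units -- e.g.
#' region \{H,E\} = H's unique-E fraction x total_H + E's unique-H fraction
#' x total_E.  Negative fractions enter the sums as-is, so the regions add
#' up exactly to the grand total.  Percents are regions over the grand
#' total.
#'
#' @param varparts named list of four three-predictor
#'   \linkS4class{VarpartResult}s, one per role as response (labels must be
#'   reciprocal).
#' @param totals named per-role total variances; defaults to the
#'   partitionings' own response totals.
#' @return A \linkS4class{CuvarpResult} (cumulative variant).
#' @seealso \code{\link{assembleAvarp}}, \code{\link{exportDiagram}}
#' @export
assembleCuvarp <- function(varparts, totals = NULL) {
  roles <- names(varparts)
  if (length(roles) != 4L) stop("expected four reciprocal partitionings")
  for (r in roles)
    if (!setequal(varparts[[r]]@predictorLabels, setdiff(roles, r)))
      stop("inconsistent role sets: response ", r,
           " must have the other three roles as predictors")
  if (is.null(totals))
    totals <- vapply(varparts, totalVariance, numeric(1))[roles]
  subsets <- labelSubsets(roles)
  rows <- lapply(subsets, function(T) {
    lab <- fractionKey(T)
    value <- if (length(T) == 1L) {
      varparts[[T]]@residual * totals[[T]]
    } else {
      sum(vapply(T, function(X) {
        rest <- varparts[[X]]@predictorLabels[
          varparts[[X]]@predictorLabels %in% setdiff(T, X)]
        varparts[[X]]@fractions[[fractionKey(rest)]] * totals[[X]]
      }, numeric(1)))
    }
    data.frame(subset = lab, size = length(T), value = value,
               stringsAsFactors = FALSE)
  })
  reg <- do.call(rbind, rows)
  grand <- sum(totals)
  reg$percent <- 100 * reg$value / grand
  residSum <- sum(reg$value[reg$size == 1L])
  ## absorb roundoff so the closure invariant holds exactly
  drift <- grand - sum(reg$value)
  reg$value[nrow(reg)] <- reg$value[nrow(reg)] + drift
  reg$percent <- 100 * reg$value / grand
  methods::new("CuvarpResult", varparts = varparts, totals = totals,
               grandTotal = grand, regions = reg,
               explainedSum = grand - residSum, residualSum = residSum,
               variant = "cumulative")
}

#' Assemble average (AVARP) diagram regions
#'
#' The averaged variant: each region holds the mean, over its member roles
#' taken as responses, of the corresponding fraction of that response's own
#' total, expressed as percent.  Singleton regions are each role's own
#' residual percent.  Used with community-weighted-mean inputs this is the
#' CWM-AVARP diagram.
#'
#' @inheritParams assembleCuvarp
#' @return A \linkS4class{CuvarpResult} (average variant; values are mean
#'   fractions, percents are values x 100).
#' @export
assembleAvarp <- function(varparts, totals = NULL) {
  roles <- names(varparts)
  if (length(roles) != 4L) stop("expected four reciprocal partitionings")
  if (is.null(totals))
    totals <- vapply(varparts, totalVariance, numeric(1))[roles]
  subsets <- labelSubsets(roles)
  rows <- lapply(subsets, function(T) {
    vals <- vapply(T, function(X) {
      if (length(T) == 1L) varparts[[X]]@residual
      else {
        rest <- varparts[[X]]@predictorLabels[
          varparts[[X]]@predictorLabels %in% setdiff(T, X)]
        varparts[[X]]@fractions[[fractionKey(rest)]]
      }
    }, numeric(1))
    data.frame(subset = fractionKey(T), size = length(T),
               value = mean(vals), stringsAsFactors = FALSE)
  })
  reg <- do.call(rbind, rows)
  reg$percent <- 100 * reg$value
  residMean <- 100 * mean(vapply(roles, function(r) varparts[[r]]@residual,
                                 numeric(1)))
  methods::new("CuvarpResult", varparts = varparts, totals = totals,
               grandTotal = sum(totals), regions = reg,
               explainedSum = 100 - residMean, residualSum = residMean,
               variant = "average")
}

#' Explained and residual percentages of a grand total
#'
#' The percent arithmetic of the cumulative diagram: given the grand total
#' variation and the summed residual (non-overlap) variation, returns the
#' explained and residual percentages.
#'
#' @param total grand total variation (variance units).
#' @param residual summed residual variation, same units.
#' @return Named numeric \code{c(explained, residual)} in percent.
#' @examples
#' variationPercents(160.0, 56.442)   # explained 64.72, residual 35.28
#' @export
variationPercents <- function(total, residual) {
  if (total <= 0) stop("total must be positive")
  c(explained = 100 * (total - residual) / total,
    residual = 100 * residual / total)
}

#' Community-weighted-means average variation partitioning (CWM-AVARP)
#'
#' Embeds functional traits in the cumulative framework: the native and
#' alien community tables are replaced by their community-weighted mean
#' trait tables (\code{\link{cwm}}), the four components are rebuilt and
#' selected as usual, and the reciprocal partitionings are assembled as an
#' average diagram.
#'
#' @param native,alien sites-by-species tables.
#' @param nativeTraits,alienTraits species-by-traits tables aligned to each
#'   community.
#' @param environment,coords the remaining component tables.
#' @param alpha,nPerm,seed,design,maxAxes as in \code{\link{selectAxes}}.
#' @return A \linkS4class{CuvarpResult} (average variant).
#' @export
cwmAvarp <- function(native, alien, nativeTraits, alienTraits, environment,
                     coords, alpha = 0.05, nPerm = 199L, seed,
                     design = permutationDesign("free"), maxAxes = NULL) {
  if (missing(seed)) stop("a seed is mandatory for any stochastic command")
  cwmH <- cwm(native, nativeTraits)
  cwmA <- cwm(alien, alienTraits)
  ## CWM is undefined where a community has zero total abundance; those
  ## sites cannot enter the reciprocal analysis
  ok <- !(rowSums(is.na(cwmH@data)) > 0 | rowSums(is.na(cwmA@data)) > 0)
  if (!all(ok)) {
    warning(sum(!ok), " site(s) dropped: zero total abundance leaves the ",
            "community-weighted mean undefined")
    subsetRows <- function(st) methods::new("SampleTable",
      data = st@data[ok, , drop = FALSE], kinds = st@kinds,
      weights = st@weights, levels = st@levels)
    cwmH <- subsetRows(cwmH); cwmA <- subsetRows(cwmA)
    environment <- subsetRows(environment); coords <- subsetRows(coords)
  }
  comps <- buildComponents(cwmH, cwmA, environment, coords)
  sel <- selectAxes(comps, alpha = alpha, nPerm = nPerm,
                    seed = deriveSeed(seed, 1L), design = design,
                    maxAxes = maxAxes)
  rv <- reciprocalVarpart(sel, design = design, nPerm = nPerm,
                          seed = deriveSeed(seed, 2L), test = FALSE)
  assembleAvarp(rv$varparts, rv$totals)
}

#' Export a CUVARP diagram specification
#'
#' Produces the renderable region list: a JSON region spec (subset, value,
#' percent, rendered flag) suitable for proportional-Euler renderers, and a
#' non-proportional labelled SVG with four ellipses.  Regions with zero
#' value -- and, when \code{floorNegatives} is on, negative regions floored
#' to zero -- carry \code{rendered = FALSE}: they stay in the JSON but are
#' omitted from the drawing.
#'
#' @param result a \linkS4class{CuvarpResult}.
#' @param floorNegatives floor negative region values to zero for rendering
#'   (the numbers in the result object itself are never clamped).
#' @param jsonFile,svgFile optional output paths.
#' @return A \linkS4class{DiagramSpec}, invisibly when files are written.
#' @export
exportDiagram <- function(result, floorNegatives = TRUE, jsonFile = NULL,
                          svgFile = NULL) {
  stopifnot(methods::is(result, "CuvarpResult"))
  reg <- result@regions[, c("subset", "value", "percent")]
  floored <- floorNegatives & reg$value < 0
  if (any(floored)) { reg$value[floored] <- 0; reg$percent[floored] <- 0 }
  reg$rendered <- reg$value > 0
  spec <- methods::new("DiagramSpec", regions = reg,
                       title = if (result@variant == "cumulative")
                         "Cumulative variation partitioning" else
                         "Average variation partitioning",
                       scaleNote = if (result@variant == "cumulative")
                         "variance units; percents of grand total" else
                         "mean fraction of own total; percents",
                       flooredNegatives = any(floored))
  if (!is.null(jsonFile)) writeDiagramJSON(spec, jsonFile)
  if (!is.null(svgFile)) writeDiagramSVG(spec, svgFile)
  if (is.null(jsonFile) && is.null(svgFile)) spec else invisible(spec)
}

#' Write / read a diagram specification as JSON
#'
#' @param spec a \linkS4class{DiagramSpec}.
#' @param path output (input) path.
#' @return \code{writeDiagramJSON}: \code{path} invisibly;
#'   \code{readDiagramJSON}: the round-tripped \linkS4class{DiagramSpec}.
#' @export
writeDiagramJSON <- function(spec, path) {
  stopifnot(methods::is(spec, "DiagramSpec"))
  jsonlite::write_json(list(
    title = spec@title, scale = spec@scaleNote,
    floored_negatives = spec@flooredNegatives,
    regions = spec@regions), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDiagramJSON
#' @export
readDiagramJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("DiagramSpec",
               regions = as.data.frame(j$regions),
               title = j$title, scaleNote = j$scale,
               flooredNegatives = j$floored_negatives)
}

## Non-proportional 4-ellipse SVG with a legend of rendered region labels.
writeDiagramSVG <- function(spec, path) {
  reg <- spec@regions[spec@regions$rendered, , drop = FALSE]
  singles <- unique(unlist(strsplit(spec@regions$subset[
    nchar(spec@regions$subset) == min(nchar(spec@regions$subset))], "")))
  cols <- c("#e41a1c66", "#377eb866", "#4daf4a66", "#98400066")
  ell <- list(c(200, 190, 150, 90, -40), c(280, 190, 150, 90, -40),
              c(200, 230, 150, 90, 40), c(280, 230, 150, 90, 40))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<svg xmlns="http://www.w3.org/2000/svg" width="520" height="%d">',
    sprintf('<text x="20" y="24" font-size="15" font-family="sans-serif">%s</text>',
            spec@title))
  lines[2] <- sprintf(lines[2], 360 + 16 * nrow(reg))
  for (i in seq_along(singles)) {
    e <- ell[[min(i, 4L)]]
    lines <- c(lines, sprintf(
      '<ellipse cx="%d" cy="%d" rx="%d" ry="%d" transform="rotate(%d %d %d)" fill="%s" stroke="black"/>',
      e[1], e[2], e[3], e[4], e[5], e[1], e[2], cols[min(i, 4L)]))
    lines <- c(lines, sprintf(
      '<text x="%d" y="%d" font-size="14" font-family="sans-serif" font-weight="bold">%s</text>',
      e[1] + round(0.8 * e[3]) * (if (e[5] < 0) -1 else 1), e[2] - e[4], singles[i]))
  }
  y <- 350
  for (i in seq_len(nrow(reg))) {
    y <- y + 16
    lines <- c(lines, sprintf(
      '<text x="30" y="%d" font-size="12" font-family="monospace">%-5s %8.3f  (%.2f%%)</text>',
      y, reg$subset[i], reg$value[i], reg$percent[i]))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}
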