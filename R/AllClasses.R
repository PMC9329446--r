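#' @include AllGenerics.R
NULL

.KINDS <- c("quantitative", "ordinal", "factor", "binary")

## ---------------------------------------------------------------- SampleTable

#' SampleTable: a row-identified table of mixed-type variables
#'
#' The universal data carrier of the package: community (sites x species),
#' environment, trait, coordinate and ordination-score tables are all
#' \code{SampleTable}s.  Each column carries a declared kind
#' (\code{quantitative}, \code{ordinal}, \code{factor}, \code{binary}), a
#' non-negative Gower weight, and -- for factors and ordinals -- a finite
#' level set.  Missing values are allowed and propagate as \code{NA}; they are
#' handled downstream by Gower pairwise deletion, never silently zeroed.
#'
#' @slot data a \code{data.frame}; row names are the unique sample (or
#'   species) identifiers.  Quantitative columns are numeric, ordinal and
#'   binary columns integer, factor columns character.
#' @slot kinds named character vector, one entry per column.
#' @slot weights named numeric vector of non-negative Gower weights.
#' @slot levels named list of declared level vectors; ordinal levels are the
#'   admissible integer codes in rank order, factor levels the admissible
#'   labels.
#'
#' @seealso \code{\link{sampleTable}}, \code{\link{readSampleTable}},
#'   \code{\link{gowerMatrix}}
#' @export
setClass("SampleTable",
  slots = c(data = "data.frame", kinds = "character",
            weights = "numeric", levels = "list"))

setValidity("SampleTable", function(object) {
  d <- object@data
  ids <- rownames(d)
  if (is.null(ids) || anyDuplicated(ids))
    return("row identifiers must be present and unique")
  cols <- colnames(d)
  if (!identical(sort(names(object@kinds)), sort(cols)) && ncol(d) > 0)
    return("every column needs exactly one kind entry")
  if (!all(object@kinds %in% .KINDS))
    return(sprintf("kinds must be one of: %s", paste(.KINDS, collapse = ", ")))
  if (any(object@weights < 0)) return("weights must be non-negative")
  if (ncol(d) > 0 && !any(object@weights > 0))
    return("at least one weight must be positive")
  for (cn in cols) {
    v <- d[[cn]]
    k <- object@kinds[[cn]]
    if (k == "quantitative" && !is.numeric(v))
      return(sprintf("column '%s' declared quantitative but not numeric", cn))
    if (k %in% c("ordinal", "binary") && !is.numeric(v))
      return(sprintf("column '%s' declared %s but not integer-coded", cn, k))
    if (k == "binary" && !all(v[!is.na(v)] %in% c(0, 1)))
      return(sprintf("binary column '%s' has values outside {0,1}", cn))
    if (k == "factor") {
      lev <- object@levels[[cn]]
      bad <- setdiff(unique(v[!is.na(v)]), lev)
      if (length(bad))
        return(sprintf("column '%s' has value(s) outside declared levels: %s",
                       cn, paste(bad, collapse = ", ")))
    }
    if (k == "ordinal" && length(object@levels[[cn]])) {
      lev <- as.numeric(object@levels[[cn]])
      bad <- setdiff(unique(v[!is.na(v)]), lev)
      if (length(bad))
        return(sprintf("ordinal column '%s' has code(s) outside declared levels: %s",
                       cn, paste(bad, collapse = ", ")))
    }
  }
  TRUE
})

#' Construct a SampleTable
#'
#' @param data a \code{data.frame} (or matrix) with row names as identifiers;
#'   if row names are absent the first column may be promoted with
#'   \code{idColumn}.
#' @param kinds named character vector of column kinds, or a single kind
#'   recycled to all columns (default \code{"quantitative"}).
#' @param weights named numeric vector of Gower weights (default 1).
#' @param levels named list of declared level sets for factor/ordinal columns;
#'   defaults to the observed values.
#' @param idColumn optional name of a column holding the row identifiers.
#' @return A validated \linkS4class{SampleTable}.
#' @examples
#' st <- sampleTable(data.frame(row.names = c("s1", "s2"),
#'                              depth = c(0.5, 2), hab = c("R", "L")),
#'                   kinds = c(depth = "quantitative", hab = "factor"))
#' variableKinds(st)
#' @export
sampleTable <- function(data, kinds = "quantitative", weights = NULL,
                        levels = NULL, idColumn = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!is.null(idColumn)) {
    ids <- as.character(data[[idColumn]])
    if (anyDuplicated(ids))
      stop("duplicated row identifier(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    data[[idColumn]] <- NULL
    rownames(data) <- ids
  }
  cols <- colnames(data)
  if (length(kinds) == 1L && is.null(names(kinds)))
    kinds <- stats::setNames(rep(kinds, length(cols)), cols)
  kinds <- kinds[cols]
  names(kinds) <- cols
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(cols)), cols)
  weights <- weights[cols]; names(weights) <- cols
  if (is.null(levels)) levels <- list()
  lv <- stats::setNames(vector("list", length(cols)), cols)
  for (cn in cols) {
    k <- kinds[[cn]]
    v <- data[[cn]]
    if (k == "factor") {
      v <- as.character(v)
      lev <- levels[[cn]]
      if (is.null(lev)) lev <- sort(unique(v[!is.na(v)]))
      lv[[cn]] <- as.character(lev)
      data[[cn]] <- v
    } else if (k %in% c("ordinal", "binary")) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "" & v != "NA")
      if (length(bad))
        stop(sprintf("column '%s': non-coercible value '%s' in row '%s'",
                     cn, v[bad[1]], rownames(data)[bad[1]]))
      if (any(abs(vn - round(vn)) > 1e-9, na.rm = TRUE))
        stop(sprintf("column '%s' declared %s but holds non-integer values", cn, k))
      data[[cn]] <- as.integer(round(vn))
      lev <- levels[[cn]]
      if (k == "ordinal")
        lv[[cn]] <- if (is.null(lev)) sort(unique(vn[!is.na(vn)])) else as.numeric(lev)
      else lv[[cn]] <- c(0, 1)
    } else {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "" & v != "NA")
      if (length(bad))
        stop(sprintf("column '%s': non-coercible value '%s' in row '%s'",
                     cn, v[bad[1]], rownames(data)[bad[1]]))
      data[[cn]] <- vn
      lv[[cn]] <- numeric(0)
    }
  }
  methods::new("SampleTable", data = data, kinds = kinds,
               weights = weights, levels = lv)
}

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "SampleTable", function(x) rownames(x@data))
#' @rdname tableData
#' @export
setMethod("tableData", "SampleTable", function(x) x@data)
#' @rdname variableKinds
#' @export
setMethod("variableKinds", "SampleTable", function(x) x@kinds)
#' @rdname variableWeights
#' @export
setMethod("variableWeights", "SampleTable", function(x) x@weights)
#' @rdname variableLevels
#' @export
setMethod("variableLevels", "SampleTable", function(x) x@levels)

#' @describeIn sampleTable dimensions (so \code{nrow}/\code{ncol} work)
#' @param x a \code{SampleTable}
#' @export
setMethod("dim", "SampleTable", function(x) dim(x@data))

setMethod("show", "SampleTable", function(object) {
  k <- table(factor(object@kinds, levels = .KINDS))
  cat(sprintf("SampleTable: %d samples x %d variables (%s)\n",
              nrow(object@data), ncol(object@data),
              paste(sprintf("%d %s", k, names(k))[k > 0], collapse = ", ")))
  if (nrow(object@data)) {
    n <- min(4L, nrow(object@data))
    print(utils::head(object@data, n))
    if (nrow(object@data) > n) cat("...\n")
  }
})

## ------------------------------------------------------------ DistanceMatrix

#' DistanceMatrix: symmetric pairwise dissimilarities
#'
#' @slot values square numeric matrix with identical row/column names (the
#'   ids), symmetric to 1e-12, zero diagonal, non-negative.
#' @slot metadata list of provenance notes (e.g. the Gower conventions used).
#' @seealso \code{\link{gowerMatrix}}, \code{\link{euclideanMatrix}},
#'   \code{\link{pcoa}}
#' @export
setClass("DistanceMatrix",
  slots = c(values = "matrix", metadata = "list"))

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("row and column ids must be present and identical")
  if (anyNA(v)) return("distances must not be missing")
  if (any(v < -1e-12)) return("distances must be non-negative")
  if (max(abs(v - t(v))) > 1e-12) return("matrix must be symmetric (tol 1e-12)")
  if (any(abs(diag(v)) > 1e-12)) return("diagonal must be zero")
  TRUE
})

distanceMatrix <- function(values, ids = rownames(values), metadata = list()) {
  values <- as.matrix(values)
  dimnames(values) <- list(ids, ids)
  values <- (values + t(values)) / 2
  diag(values) <- 0
  methods::new("DistanceMatrix", values = values, metadata = metadata)
}

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "DistanceMatrix", function(x) rownames(x@values))

#' Distance values as a plain matrix
#'
#' @param x a \linkS4class{DistanceMatrix}.
#' @return The symmetric numeric matrix of dissimilarities.
#' @export
distValues <- function(x) {
  stopifnot(methods::is(x, "DistanceMatrix"))
  x@values
}

setMethod("show", "DistanceMatrix", function(object) {
  v <- object@values
  cat(sprintf("DistanceMatrix: %d ids, range [%.4g, %.4g]\n",
              nrow(v), min(v), max(v)))
  if (length(object@metadata))
    cat("  notes:", paste(names(object@metadata), collapse = ", "), "\n")
})

## ---------------------------------------------------------------- Ordination

#' Ordination: principal coordinates / components of a table or distance
#'
#' @slot ids ordered identifiers.
#' @slot eigenvalues retained eigenvalues, non-increasing, all above the
#'   relative tolerance.
#' @slot scores a \linkS4class{SampleTable} of axis scores (columns
#'   \code{Axis1..AxisK}); column k has sum of squares equal to eigenvalue k.
#' @slot keptAxisPolicy the retention policy used (\code{"positive"} or
#'   \code{"nonzero"}; both drop eigenvalues within tolerance of zero).
#' @seealso \code{\link{pcoa}}
#' @export
setClass("Ordination",
  slots = c(ids = "character", eigenvalues = "numeric",
            scores = "SampleTable", keptAxisPolicy = "character"))

setValidity("Ordination", function(object) {
  ev <- object@eigenvalues
  if (is.unsorted(rev(ev), strictly = FALSE)) return("eigenvalues must be non-increasing")
  if (length(ev) != ncol(object@scores@data))
    return("one score column per retained eigenvalue")
  TRUE
})

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "Ordination", function(x) x@ids)
#' @rdname eigenvalues
#' @export
setMethod("eigenvalues", "Ordination", function(x) x@eigenvalues)
#' @rdname scoreTable
#' @export
setMethod("scoreTable", "Ordination", function(x) x@scores)

setMethod("show", "Ordination", function(object) {
  cat(sprintf("Ordination: %d samples, %d retained axes (policy: %s)\n",
              length(object@ids), length(object@eigenvalues),
              object@keptAxisPolicy))
  if (length(object@eigenvalues))
    cat("  eigenvalues:",
        paste(signif(utils::head(object@eigenvalues, 6), 4), collapse = ", "),
        if (length(object@eigenvalues) > 6) "..." else "", "\n")
})

## -------------------------------------------------------------------- RdaFit

#' RdaFit: a (partial) redundancy-analysis fit
#'
#' Multivariate least squares of a centred response matrix on predictors,
#' optionally after residualising response and predictors on covariates.
#' Explained variance is the trace ratio; the pseudo-F is the variance-ratio
#' statistic tested by permutation elsewhere.
#'
#' @slot r2 explained proportion of total (residualised) variance.
#' @slot adjR2 Ezekiel-adjusted R2 (NA when covariates are present; partial
#'   adjusted fractions are obtained by subtraction, see \code{\link{varpart2}}).
#' @slot pseudoF variance-ratio statistic (NA when the predictors are fully
#'   absorbed by the covariates).
#' @slot dfModel,dfResid model and residual degrees of freedom.
#' @slot n,m,q sample size, effective predictor rank, covariate rank.
#' @slot fittedVariance,residualVariance trace variances (divisor n - 1).
#' @seealso \code{\link{rdaFit}}, \code{\link{permutationTest}}
#' @export
setClass("RdaFit",
  slots = c(r2 = "numeric", adjR2 = "numeric", pseudoF = "numeric",
            dfModel = "integer", dfResid = "integer",
            n = "integer", m = "integer", q = "integer",
            fittedVariance = "numeric", residualVariance = "numeric"))

setValidity("RdaFit", function(object) {
  if (object@r2 < -1e-12 || object@r2 > 1 + 1e-12) return("r2 must lie in [0,1]")
  tot <- object@fittedVariance + object@residualVariance
  if (tot > 0 && abs(object@r2 - object@fittedVariance / tot) > 1e-8)
    return("r2 must equal fittedVariance / totalVariance")
  if (!is.na(object@adjR2) && object@m >= 1L && object@adjR2 > object@r2 + 1e-12)
    return("adjusted R2 cannot exceed R2 for m >= 1")
  TRUE
})

#' @rdname adjR2
#' @export
setMethod("adjR2", "RdaFit", function(x) x@adjR2)

setMethod("show", "RdaFit", function(object) {
  cat(sprintf("RdaFit: n = %d, m = %d%s\n", object@n, object@m,
              if (object@q > 0) sprintf(", q = %d (partial)", object@q) else ""))
  cat(sprintf("  R2 = %.4f  adjR2 = %s  pseudo-F = %s (df %d, %d)\n",
              object@r2,
              ifelse(is.na(object@adjR2), "NA", sprintf("%.4f", object@adjR2)),
              ifelse(is.na(object@pseudoF), "NA", sprintf("%.3f", object@pseudoF)),
              object@dfModel, object@dfResid))
})

## --------------------------------------------------------- PermutationDesign

#' PermutationDesign: free or restricted row-exchange scheme
#'
#' Restricted schemes mirror split-plot field designs: \code{blocks} permutes
#' freely within blocks, \code{series} applies a single cyclic shift within
#' each block (time series / linear transects), and \code{split_plot}
#' exchanges whole blocks while preserving (or cyclically shifting) each
#' block's internal series order.
#'
#' @slot kind one of \code{"free"}, \code{"blocks"}, \code{"series"},
#'   \code{"split_plot"}.
#' @slot blockLabels per-row block labels (ignored for \code{free}).
#' @slot allowMirror for series-type shifts, also allow the mirrored series.
#' @slot wholePlotOrder declared order of whole-plot labels (split_plot).
#' @slot shiftWithin for \code{split_plot}: additionally cyclic-shift the
#'   within-block series (both permutation levels active).
#' @seealso \code{\link{permutationDesign}}, \code{\link{generatePermutation}}
#' @export
setClass("PermutationDesign",
  slots = c(kind = "character", blockLabels = "character",
            allowMirror = "logical", wholePlotOrder = "character",
            shiftWithin = "logical"))

setValidity("PermutationDesign", function(object) {
  if (!object@kind %in% c("free", "blocks", "series", "split_plot"))
    return("kind must be free, blocks, series or split_plot")
  TRUE
})

setMethod("show", "PermutationDesign", function(object) {
  cat(sprintf("PermutationDesign: %s%s%s\n", object@kind,
              if (length(object@blockLabels))
                sprintf(" (%d rows, %d blocks)", length(object@blockLabels),
                        length(unique(object@blockLabels))) else "",
              if (object@kind == "series" && object@allowMirror) ", mirrored" else ""))
})

## ---------------------------------------------------------------- TestResult

#' TestResult: a Monte Carlo permutation test outcome
#'
#' @slot statistic observed pseudo-F.
#' @slot pValue permutation p-value; bounded below by 1/(nPerm + 1) in Monte
#'   Carlo mode, exact when the orbit was enumerated.
#' @slot nPerm number of permutations drawn (or orbit size when exhaustive).
#' @slot seed RNG seed used.
#' @slot scheme summary string of the permutation design.
#' @slot exhaustive whether the full permutation orbit was enumerated.
#' @export
setClass("TestResult",
  slots = c(statistic = "numeric", pValue = "numeric", nPerm = "integer",
            seed = "integer", scheme = "character", exhaustive = "logical"))

setValidity("TestResult", function(object) {
  if (!is.na(object@pValue) &&
      (object@pValue <= 0 || object@pValue > 1)) return("p-value must lie in (0,1]")
  TRUE
})

#' @rdname pValue
#' @export
setMethod("pValue", "TestResult", function(x) x@pValue)

setMethod("show", "TestResult", function(object) {
  cat(sprintf("TestResult: pseudo-F = %.4f, p = %.4g (%s, %d %s, seed %d)\n",
              object@statistic, object@pValue, object@scheme, object@nPerm,
              if (object@exhaustive) "arrangements, exhaustive" else "permutations",
              object@seed))
})

## ----------------------------------------------------------- SelectionResult

#' SelectionResult: outcome of FDR-guarded forward selection
#'
#' @slot selected selected column names in selection order.
#' @slot steps per-candidate-test records: step, candidate, adjusted-R2 gain,
#'   raw and FDR-adjusted p, and whether the candidate entered the model.
#' @slot stopReason \code{"alpha_fail"}, \code{"adjr2_ceiling"} or
#'   \code{"exhausted"}.
#' @slot fullAdjR2 adjusted R2 of the all-candidate model (the ceiling of the
#'   double stopping rule).
#' @slot finalAdjR2 adjusted R2 of the selected model.
#' @seealso \code{\link{forwardSelect}}
#' @export
setClass("SelectionResult",
  slots = c(selected = "character", steps = "data.frame",
            stopReason = "character", fullAdjR2 = "numeric",
            finalAdjR2 = "numeric"))

#' @rdname selectedVariables
#' @export
setMethod("selectedVariables", "SelectionResult", function(x) x@selected)

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d selected (%s); stop: %s; adjR2 %.4f of ceiling %.4f\n",
              length(object@selected),
              if (length(object@selected)) paste(object@selected, collapse = ", ") else "none",
              object@stopReason, object@finalAdjR2, object@fullAdjR2))
})

## ------------------------------------------------------------- VarpartResult

#' VarpartResult: adjusted-R2-scale variation partitioning
#'
#' Fractions of one response matrix's variance attributed to every non-empty
#' subset of 2 or 3 predictor matrices, plus the residual.  Fractions are on
#' the adjusted-R2 (proportion) scale and may be negative; they are never
#' clamped here (only the diagram layer floors them, with a flag).  The
#' variance-unit view is \code{fractions(x) * totalVariance(x)}.
#'
#' @slot responseLabel,predictorLabels labels of the matrices involved.
#' @slot fractions named numeric vector keyed by concatenated predictor
#'   labels: unique fractions (\code{"E"}), pairwise shared (\code{"ES"}),
#'   triple shared (\code{"AES"}).
#' @slot residual unexplained fraction; fractions + residual = 1 to 1e-12.
#' @slot totalVariance total variance of the response table (divisor n - 1).
#' @slot scale \code{"proportion"} (the native scale of the object).
#' @seealso \code{\link{varpart2}}, \code{\link{varpart3}},
#'   \code{\link{assembleCuvarp}}
#' @export
setClass("VarpartResult",
  slots = c(responseLabel = "character", predictorLabels = "character",
            fractions = "numeric", residual = "numeric",
            totalVariance = "numeric", scale = "character"))

setValidity("VarpartResult", function(object) {
  k <- length(object@predictorLabels)
  if (!k %in% 2:3) return("2 or 3 predictor matrices required")
  if (length(object@fractions) != 2^k - 1)
    return("one fraction per non-empty predictor subset")
  if (abs(sum(object@fractions) + object@residual - 1) > 1e-12)
    return("fractions + residual must sum to 1 (tol 1e-12)")
  TRUE
})

#' @rdname fractions
#' @export
setMethod("fractions", "VarpartResult", function(x) x@fractions)
#' @rdname residualFraction
#' @export
setMethod("residualFraction", "VarpartResult", function(x) x@residual)
#' @rdname totalVariance
#' @export
setMethod("totalVariance", "VarpartResult", function(x) x@totalVariance)

setMethod("show", "VarpartResult", function(object) {
  cat(sprintf("VarpartResult: %s ~ %s (total variance %.4g)\n",
              object@responseLabel,
              paste(object@predictorLabels, collapse = " + "),
              object@totalVariance))
  f <- c(object@fractions, residual = object@residual)
  for (i in seq_along(f))
    cat(sprintf("  %-10s %8.4f  (%6.2f%%)\n", names(f)[i], f[i], 100 * f[i]))
})

## --------------------------------------------------------------- ChiSqResult

#' ChiSqResult: chi-squared comparison of explained-variance classes
#'
#' @slot statistic sum of (O - E)^2 / E over classes.
#' @slot df degrees of freedom (number of classes - 1).
#' @slot classes class labels.
#' @slot observed,expected percentage vectors compared.
#' @seealso \code{\link{chisqFractionCompare}}
#' @export
setClass("ChiSqResult",
  slots = c(statistic = "numeric", df = "integer", classes = "character",
            observed = "numeric", expected = "numeric"))

setValidity("ChiSqResult", function(object) {
  if (object@df != length(object@classes) - 1L) return("df must equal classes - 1")
  if (object@statistic < 0) return("statistic must be non-negative")
  TRUE
})

setMethod("show", "ChiSqResult", function(object) {
  cat(sprintf("ChiSqResult: X2 = %.4f, df = %d\n", object@statistic, object@df))
})

## ------------------------------------------------------------------ MemBasis

#' MemBasis: distance-based Moran eigenvector maps
#'
#' Spatial eigenfunctions from PCoA of the truncated geographic distance
#' matrix (within-threshold distances kept, beyond-threshold distances set to
#' four times the threshold).  Positive-eigenvalue axes only.
#'
#' @slot scores \linkS4class{SampleTable} of MEM scores (\code{MEM1..MEMk});
#'   columns centred and mutually orthogonal.
#' @slot eigenvalues positive eigenvalues, non-increasing.
#' @slot truncationThreshold the distance threshold used (input units).
#' @seealso \code{\link{dbmem}}
#' @export
setClass("MemBasis",
  slots = c(scores = "SampleTable", eigenvalues = "numeric",
            truncationThreshold = "numeric"))

setValidity("MemBasis", function(object) {
  if (any(object@eigenvalues <= 0)) return("eigenvalues must be positive")
  sc <- as.matrix(object@scores@data)
  if (ncol(sc) && max(abs(colMeans(sc))) > 1e-10)
    return("MEM columns must be centred (tol 1e-10)")
  TRUE
})

#' @rdname eigenvalues
#' @export
setMethod("eigenvalues", "MemBasis", function(x) x@eigenvalues)
#' @rdname scoreTable
#' @export
setMethod("scoreTable", "MemBasis", function(x) x@scores)

setMethod("show", "MemBasis", function(object) {
  cat(sprintf("MemBasis: %d sites, %d positive MEM axes, truncation %.4g (beyond set to %.4g)\n",
              nrow(object@scores@data), length(object@eigenvalues),
              object@truncationThreshold, 4 * object@truncationThreshold))
})

## ---------------------------------------------------------------- TraitSpace

#' TraitSpace: species embedded in functional-trait space
#'
#' Gower dissimilarities of the mixed-type trait table, embedded by PCoA
#' (all axes above tolerance); species distances are Euclidean in the full
#' retained score space and feed Rao quadratic entropy.
#'
#' @slot speciesScores trait-PCoA axis scores, one row per species.
#' @slot speciesDistance Euclidean \linkS4class{DistanceMatrix} on the scores.
#' @seealso \code{\link{traitSpace}}, \code{\link{raoQ}}
#' @export
setClass("TraitSpace",
  slots = c(speciesScores = "SampleTable", speciesDistance = "DistanceMatrix"))

setMethod("show", "TraitSpace", function(object) {
  cat(sprintf("TraitSpace: %d species, %d trait axes\n",
              nrow(object@speciesScores@data), ncol(object@speciesScores@data)))
})

## -------------------------------------------------------------- ComponentSet

#' ComponentSet: one role's full ordination-score table
#'
#' One of the four CUVARP components: natives (H), aliens (A), environment
#' (E) -- each from Gower + PCoA -- or space (S) from db-MEM.
#'
#' @slot role single-letter role label.
#' @slot fullScores all retained axis scores ("H-all"-style table).
#' @slot source \code{"pcoa"} or \code{"dbmem"}.
#' @slot eigenvalues the retained eigenvalues.
#' @seealso \code{\link{buildComponents}}
#' @export
setClass("ComponentSet",
  slots = c(role = "character", fullScores = "SampleTable",
            source = "character", eigenvalues = "numeric"))

setValidity("ComponentSet", function(object) {
  if (!object@source %in% c("pcoa", "dbmem"))
    return("source must be pcoa or dbmem")
  TRUE
})

#' @rdname scoreTable
#' @export
setMethod("scoreTable", "ComponentSet", function(x) x@fullScores)

setMethod("show", "ComponentSet", function(object) {
  cat(sprintf("ComponentSet %s: %d axes via %s\n", object@role,
              ncol(object@fullScores@data), object@source))
})

## -------------------------------------------------------- SelectedComponents

#' SelectedComponents: consensus-selected axes per role
#'
#' @slot axes named list mapping each role to its retained 1-based axis
#'   indices.
#' @slot scores named list of reduced score \linkS4class{SampleTable}s.
#' @slot selectionLog per-analysis forward-selection records (predictor role,
#'   response role, selected axes, stop reason).
#' @slot fallback roles whose retained set was empty and fell back to axis 1.
#' @seealso \code{\link{selectAxes}}
#' @export
setClass("SelectedComponents",
  slots = c(axes = "list", scores = "list", selectionLog = "data.frame",
            fallback = "character"))

setMethod("show", "SelectedComponents", function(object) {
  cat("SelectedComponents:\n")
  for (r in names(object@axes))
    cat(sprintf("  %s: {%s}%s\n", r, paste(object@axes[[r]], collapse = ","),
                if (r %in% object@fallback) " [fallback]" else ""))
})

## -------------------------------------------------------------- CuvarpResult

#' CuvarpResult: assembled cumulative variation partitioning
#'
#' The four reciprocal \linkS4class{VarpartResult}s assembled into diagram
#' regions over the non-empty subsets of the roles.  In the cumulative
#' variant each singleton region is a role's residual variance, every larger
#' region sums the reciprocal conditional fractions in variance units, and
#' all regions add up to the grand total.  In the average (AVARP) variant
#' regions hold the mean over contributing responses of the fraction of that
#' response's own total, expressed as percent.
#'
#' @slot varparts named list of the four VarpartResults (one per role as
#'   response).
#' @slot totals per-role total variance of the selected-axes tables.
#' @slot grandTotal sum of totals.
#' @slot regions data.frame: subset label, member count, value, percent.
#' @slot explainedSum,residualSum explained and residual totals (variance
#'   units for the cumulative variant, percent for the average variant).
#' @slot variant \code{"cumulative"} or \code{"average"}.
#' @seealso \code{\link{assembleCuvarp}}, \code{\link{assembleAvarp}},
#'   \code{\link{exportDiagram}}
#' @export
setClass("CuvarpResult",
  slots = c(varparts = "list", totals = "numeric", grandTotal = "numeric",
            regions = "data.frame", explainedSum = "numeric",
            residualSum = "numeric", variant = "character"))

setValidity("CuvarpResult", function(object) {
  k <- length(object@totals)
  if (nrow(object@regions) != 2^k - 1)
    return("one region per non-empty role subset")
  if (object@variant == "cumulative") {
    if (abs(sum(object@regions$value) - object@grandTotal) > 1e-9)
      return("regions must sum to the grand total (tol 1e-9)")
    if (abs(object@explainedSum + object@residualSum - object@grandTotal) > 1e-9)
      return("explained + residual must equal the grand total")
  }
  TRUE
})

#' @rdname regions
#' @export
setMethod("regions", "CuvarpResult", function(x) x@regions)
#' @rdname grandTotal
#' @export
setMethod("grandTotal", "CuvarpResult", function(x) x@grandTotal)

setMethod("show", "CuvarpResult", function(object) {
  if (object@variant == "cumulative") {
    cat(sprintf("CuvarpResult (cumulative): grand total %.4g\n", object@grandTotal))
    cat(sprintf("  explained %.4g (%.2f%%), residual %.4g (%.2f%%)\n",
                object@explainedSum, 100 * object@explainedSum / object@grandTotal,
                object@residualSum, 100 * object@residualSum / object@grandTotal))
  } else {
    cat("CuvarpResult (average percents, AVARP variant)\n")
    cat(sprintf("  mean explained %.2f%%, mean residual %.2f%%\n",
                object@explainedSum, object@residualSum))
  }
  r <- object@regions[order(-abs(object@regions$value)), ]
  n <- min(8L, nrow(r))
  for (i in seq_len(n))
    cat(sprintf("  %-5s %10.4g  (%6.2f%%)\n", r$subset[i], r$value[i], r$percent[i]))
  if (nrow(r) > n) cat("  ...\n")
})

## --------------------------------------------------------------- DiagramSpec

#' DiagramSpec: renderable region list of a CUVARP diagram
#'
#' @slot regions data.frame: subset, value, percent, rendered (regions whose
#'   value is zero -- or negative and floored -- carry rendered = FALSE and
#'   are omitted from the drawing, but stay in the JSON).
#' @slot title diagram title.
#' @slot scaleNote note on the value scale (variance units vs mean percents).
#' @slot flooredNegatives whether negative regions were floored to zero.
#' @seealso \code{\link{exportDiagram}}
#' @export
setClass("DiagramSpec",
  slots = c(regions = "data.frame", title = "character",
            scaleNote = "character", flooredNegatives = "logical"))

#' @rdname regions
#' @export
setMethod("regions", "DiagramSpec", function(x) x@regions)

setMethod("show", "DiagramSpec", function(object) {
  cat(sprintf("DiagramSpec: '%s', %d regions (%d rendered)\n", object@title,
              nrow(object@regions), sum(object@regions$rendered)))
})

## --------------------------------------------------------------- SynthParams

#' SynthParams: design of a synthetic riverscape dataset
#'
#' Defines the generating conditions of a four-table dataset with known
#' variance structure: a one-dimensional river transect of sites, a mixed
#' environment table (habitat factor, impact and flow ordinals, quantitative
#' distance-to-dam), native and alien community tables whose latent site
#' scores carry designed environmental / spatial / shared / residual variance
#' shares, and mixed-type trait tables.
#'
#' @slot nSites,nNative,nAlien dimensions.
#' @slot sharesNative,sharesAlien named numeric (env, space, shared, noise),
#'   each summing to 1; the aliens default to a doubled noise share.
#' @slot responseModel \code{"gaussian-latent"}, \code{"poisson-counts"} or
#'   \code{"binary-threshold"}.
#' @slot nEnvVars,nTraits environment and trait column counts.
#' @slot transect \code{"regular"} or \code{"irregular"} site spacing.
#' @slot seed RNG seed; the bundle is bit-reproducible given the seed.
#' @seealso \code{\link{synthParams}}, \code{\link{simulateRiverscape}}
#' @export
setClass("SynthParams",
  slots = c(nSites = "integer", nNative = "integer", nAlien = "integer",
            sharesNative = "numeric", sharesAlien = "numeric",
            responseModel = "character", nEnvVars = "integer",
            transect = "character", nTraits = "integer", seed = "integer"))

setValidity("SynthParams", function(object) {
  for (s in list(object@sharesNative, object@sharesAlien)) {
    if (!identical(names(s), c("env", "space", "shared", "noise")))
      return("shares must be named env, space, shared, noise")
    if (any(s < 0)) return("shares must be non-negative")
    if (abs(sum(s) - 1) > 1e-8) return("shares must sum to 1")
  }
  if (object@nSites < 5L) return("nSites must be at least 5")
  if (object@nNative < 1L || object@nAlien < 1L) return("species counts must be >= 1")
  if (!object@responseModel %in%
      c("gaussian-latent", "poisson-counts", "binary-threshold"))
    return("unknown response model")
  if (!object@transect %in% c("regular", "irregular"))
    return("transect must be regular or irregular")
  TRUE
})

setMethod("show", "SynthParams", function(object) {
  cat(sprintf("SynthParams: %d sites, %d native + %d alien species, %s, seed %d\n",
              object@nSites, object@nNative, object@nAlien,
              object@responseModel, object@seed))
  cat("  native shares:", paste(sprintf("%s=%.3g", names(object@sharesNative),
                                        object@sharesNative), collapse = " "), "\n")
  cat("  alien shares: ", paste(sprintf("%s=%.3g", names(object@sharesAlien),
                                        object@sharesAlien), collapse = " "), "\n")
})

## ---------------------------------------------------------------- SynthBundle

#' SynthBundle: a generated four-table dataset with stored truth
#'
#' @slot native,alien,environment,coords,nativeTraits,alienTraits the six
#'   generated \linkS4class{SampleTable}s, row-aligned on sites (traits on
#'   species).
#' @slot truth list holding the \linkS4class{SynthParams}, the true channel
#'   score tables per community (the oracle predictors for recovery tests),
#'   and the realised latent variance shares.
#' @seealso \code{\link{simulateRiverscape}}, \code{\link{expectedFractions}}
#' @export
setClass("SynthBundle",
  slots = c(native = "SampleTable", alien = "SampleTable",
            environment = "SampleTable", coords = "SampleTable",
            nativeTraits = "SampleTable", alienTraits = "SampleTable",
            truth = "list"))

setValidity("SynthBundle", function(object) {
  ids <- rownames(object@native@data)
  for (nm in c("alien", "environment", "coords"))
    if (!identical(rownames(methods::slot(object, nm)@data), ids))
      return(sprintf("'%s' rows not aligned with native table", nm))
  TRUE
})

setMethod("show", "SynthBundle", function(object) {
  cat(sprintf("SynthBundle: %d sites; native %d sp., alien %d sp.; %d env vars; seed %d\n",
              nrow(object@native@data), ncol(object@native@data),
              ncol(object@alien@data), ncol(object@environment@data),
              object@truth$params@seed))
})
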