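#' @include AllGenerics.R
NULL

#' Row identifiers of a data container
#'
#' Returns the ordered sample (site) or species identifiers carried by a
#' container: the row ids of a \linkS4class{SampleTable}, the ids of a
#' \linkS4class{DistanceMatrix}, or the ids of an \linkS4class{Ordination}.
#'
#' @param x a container object.
#' @return Character vector of identifiers, in storage order.
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' Underlying data of a SampleTable
#'
#' @param x a \linkS4class{SampleTable}.
#' @return A \code{data.frame} with row names equal to \code{sampleIDs(x)}.
#' @export
setGeneric("tableData", function(x) standardGeneric("tableData"))

#' Declared variable kinds
#'
#' @param x a \linkS4class{SampleTable}.
#' @return Named character vector mapping each column to one of
#'   \code{"quantitative"}, \code{"ordinal"}, \code{"factor"}, \code{"binary"}.
#' @export
setGeneric("variableKinds", function(x) standardGeneric("variableKinds"))

#' Declared Gower weights
#'
#' @param x a \linkS4class{SampleTable}.
#' @return Named numeric vector of non-negative column weights.
#' @export
setGeneric("variableWeights", function(x) standardGeneric("variableWeights"))

#' Declared level sets for factor and ordinal columns
#'
#' @param x a \linkS4class{SampleTable}.
#' @return Named list of level vectors (empty for quantitative columns).
#' @export
setGeneric("variableLevels", function(x) standardGeneric("variableLevels"))

#' Eigenvalues of an ordination or eigenvector basis
#'
#' @param x an \linkS4class{Ordination} or \linkS4class{MemBasis}.
#' @return Numeric vector of retained eigenvalues, non-increasing.
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' Score table of an ordination, eigenvector basis, or component set
#'
#' @param x an \linkS4class{Ordination}, \linkS4class{MemBasis} or
#'   \linkS4class{ComponentSet}.
#' @return A \linkS4class{SampleTable} of axis scores.
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' Adjusted R-squared of a fitted model
#'
#' @param x an \linkS4class{RdaFit}.
#' @return Ezekiel-adjusted explained variance (\code{NA} for conditioned
#'   models, where the adjusted value is only defined by subtraction of
#'   unconditioned fits; see \code{\link{varpart2}}).
#' @export
setGeneric("adjR2", function(x) standardGeneric("adjR2"))

#' Variation-partitioning fractions
#'
#' @param x a \linkS4class{VarpartResult}.
#' @return Named numeric vector of adjusted-R-squared-scale fractions, one per
#'   non-empty predictor subset; names concatenate predictor labels
#'   (e.g. \code{"E"}, \code{"S"}, \code{"ES"}).
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))

#' Residual fraction of a variation partitioning
#'
#' @param x a \linkS4class{VarpartResult}.
#' @return The unexplained fraction on the adjusted-R-squared scale.
#' @export
setGeneric("residualFraction", function(x) standardGeneric("residualFraction"))

#' Total variance of the response table behind a partitioning
#'
#' @param x a \linkS4class{VarpartResult}.
#' @return Sum of response-column sample variances (divisor n - 1).
#' @export
setGeneric("totalVariance", function(x) standardGeneric("totalVariance"))

#' Diagram regions of a cumulative partitioning
#'
#' @param x a \linkS4class{CuvarpResult} or \linkS4class{DiagramSpec}.
#' @return A \code{data.frame} with one row per non-empty subset of the roles,
#'   holding the region value and its percentage of the grand total.
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' Grand total variation of a cumulative partitioning
#'
#' @param x a \linkS4class{CuvarpResult}.
#' @return Sum over roles of the selected-axes table variances.
#' @export
setGeneric("grandTotal", function(x) standardGeneric("grandTotal"))

#' Permutation p-value
#'
#' @param x a \linkS4class{TestResult}.
#' @return Monte Carlo (or exact, when the permutation orbit was enumerated)
#'   p-value.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' Selected variables of a forward selection
#'
#' @param x a \linkS4class{SelectionResult}.
#' @return Character vector of selected column names, in selection order.
#' @export
setGeneric("selectedVariables", function(x) standardGeneric("selectedVariables"))
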