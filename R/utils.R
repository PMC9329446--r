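#' @include AllClasses.R
NULL

## Evaluate `expr` with a locally seeded RNG, restoring global state after.
withSeed <- function(seed, expr) {
  hasOld <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hasOld) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (hasOld) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic sub-seed derivation; stays below 2^31 - 1.
deriveSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483647)
}

## Numeric design matrix from a SampleTable (or matrix-like).  Quantitative,
## ordinal and binary columns enter as numbers; factor columns are expanded
## into one indicator per non-reference level (R2 is invariant to the
## parameterisation, so the dropped reference is immaterial).
asPredictorMatrix <- function(x) {
  if (methods::is(x, "SampleTable")) {
    d <- x@data
    out <- list()
    for (cn in colnames(d)) {
      if (x@kinds[[cn]] == "factor") {
        lev <- x@levels[[cn]]
        if (length(lev) > 1L)
          for (l in lev[-1L])
            out[[paste0(cn, ".", l)]] <- as.numeric(d[[cn]] == l)
      } else out[[cn]] <- as.numeric(d[[cn]])
    }
    m <- if (length(out)) do.call(cbind, out) else
      matrix(0, nrow(d), 0)
    rownames(m) <- rownames(d)
    m
  } else {
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    m
  }
}

## SampleTable from an all-numeric score matrix.
scoresAsTable <- function(m, ids = rownames(m), prefix = NULL) {
  m <- as.matrix(m)
  if (!is.null(prefix) && ncol(m) > 0)
    colnames(m) <- paste0(prefix, seq_len(ncol(m)))
  d <- as.data.frame(m)
  rownames(d) <- ids
  sampleTable(d, kinds = "quantitative")
}

## All non-empty subsets of a label vector, ordered by size then position.
labelSubsets <- function(labels) {
  k <- length(labels)
  out <- list()
  for (size in seq_len(k)) {
    cmb <- utils::combn(k, size)
    for (j in seq_len(ncol(cmb))) out[[length(out) + 1L]] <- labels[cmb[, j]]
  }
  out
}

## Canonical fraction key: concatenated labels (single-character labels join
## directly, as in "ES"; longer labels join with "+").
fractionKey <- function(labels) {
  sep <- if (all(nchar(labels) == 1L)) "" else "+"
  paste(labels, collapse = sep)
}

stopWithStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}
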