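#' @include AllClasses.R utils.R
NULL

#' Gower dissimilarity for mixed variable types
#'
#' Computes the weighted Gower dissimilarity
#' \deqn{d_{ij} = \frac{\sum_k w_k \delta_{ijk} s_{ijk}}
#'                     {\sum_k w_k \delta_{ijk}}}
#' where for quantitative and ordinal columns
#' \eqn{s_{ijk} = |x_{ik} - x_{jk}| / range_k} (range over non-missing
#' values; 0 when the range is zero), for factor and binary columns
#' \eqn{s_{ijk}} is 0 on agreement and 1 otherwise, and
#' \eqn{\delta_{ijk} = 0} whenever either value is missing (pairwise
#' deletion with weight renormalisation).  All dissimilarities lie in
#' [0, 1].
#'
#' Conventions (recorded in the result's metadata): ordinal columns are
#' treated as integer ranks range-normalised like quantitative variables --
#' the Podani ordinal correction is not applied; community count columns
#' passed here are simply quantitative columns range-scaled per species.
#'
#' @param table a \linkS4class{SampleTable} with at least two rows and one
#'   positively weighted column.
#' @return A \linkS4class{DistanceMatrix}.
#' @examples
#' st <- sampleTable(data.frame(row.names = c("r1", "r2", "r3"),
#'                              q = c(0, 5, 10), f = c("A", "A", "B")),
#'                   kinds = c(q = "quantitative", f = "factor"))
#' distValues(gowerMatrix(st))["r1", "r2"]   # 0.25
#' @seealso \code{\link{euclideanMatrix}}, \code{\link{pcoa}}
#' @export
gowerMatrix <- function(table) {
  stopifnot(methods::is(table, "SampleTable"))
  d <- table@data
  n <- nrow(d)
  if (n < 2L) stop("Gower needs at least two rows")
  w <- table@weights
  if (any(w < 0)) stop("negative weight(s): ",
                       paste(names(w)[w < 0], collapse = ", "))
  use <- names(w)[w > 0]
  if (!length(use)) stop("need at least one column with positive weight")
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (cn in use) {
    v <- d[[cn]]
    k <- table@kinds[[cn]]
    ok <- !is.na(v)
    delta <- outer(ok, ok, `&`)
    if (k %in% c("quantitative", "ordinal")) {
      if (!any(ok)) {
        if (k == "quantitative" || k == "ordinal")
          stop(sprintf("column '%s' is all-missing", cn))
      }
      rng <- diff(range(v[ok]))
      s <- if (rng > 0) abs(outer(as.numeric(v), as.numeric(v), `-`)) / rng
           else matrix(0, n, n)
    } else {
      s <- outer(v, v, `!=`) * 1
    }
    s[!delta] <- 0
    num <- num + w[[cn]] * delta * s
    den <- den + w[[cn]] * delta
  }
  offdiag <- row(den) != col(den)
  if (any(den[offdiag] == 0)) {
    bad <- which(den == 0 & offdiag, arr.ind = TRUE)[1L, ]
    stop(sprintf("rows '%s' and '%s' share no comparable column",
                 rownames(d)[bad[1L]], rownames(d)[bad[2L]]))
  }
  vals <- num / den
  diag(vals) <- 0
  distanceMatrix(vals, ids = rownames(d),
                 metadata = list(
                   method = "gower",
                   ordinal_treatment = "integer ranks, range-normalised (no Podani correction)",
                   missing = "pairwise deletion with weight renormalisation"))
}

#' Euclidean distance matrix
#'
#' @param table a \linkS4class{SampleTable} whose columns are all
#'   quantitative with no missing values (e.g. spatial coordinates or
#'   ordination scores).
#' @return A \linkS4class{DistanceMatrix} of pairwise Euclidean distances.
#' @examples
#' xy <- sampleTable(data.frame(row.names = c("a", "b"),
#'                              x = c(0, 3), y = c(0, 4)))
#' distValues(euclideanMatrix(xy))["a", "b"]   # 5
#' @export
euclideanMatrix <- function(table) {
  stopifnot(methods::is(table, "SampleTable"))
  if (!all(table@kinds == "quantitative"))
    stop("Euclidean distances require all-quantitative columns")
  m <- as.matrix(table@data)
  if (anyNA(m)) stop("Euclidean distances do not admit missing values")
  distanceMatrix(as.matrix(stats::dist(m)), ids = rownames(m),
                 metadata = list(method = "euclidean"))
}

#' Write / read a DistanceMatrix as square CSV
#'
#' The format is a square table with the ids as both header row and first
#' column.
#'
#' @param x a \linkS4class{DistanceMatrix}.
#' @param path output (input) path.
#' @return \code{writeDistanceMatrix}: \code{path}, invisibly;
#'   \code{readDistanceMatrix}: a \linkS4class{DistanceMatrix}.
#' @export
writeDistanceMatrix <- function(x, path) {
  stopifnot(methods::is(x, "DistanceMatrix"))
  out <- cbind(id = rownames(x@values), as.data.frame(x@values))
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  distanceMatrix(m, ids = ids)
}
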