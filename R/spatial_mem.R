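#' @include AllClasses.R utils.R dissimilarity.R ordination.R
NULL

#' Distance-based Moran eigenvector maps
#'
#' Builds spatial eigenfunctions from site coordinates: Euclidean distance
#' matrix; truncation at threshold \code{t} (distances beyond \code{t}
#' replaced by \code{4t}, the classical db-MEM constant); PCoA of the
#' truncated matrix; positive-eigenvalue axes retained as MEM scores.  The
#' automatic threshold is the largest edge of the minimum spanning tree of
#' the distance graph -- the smallest truncation that keeps the graph
#' connected, which for a one-dimensional transect equals the maximum
#' nearest-neighbour gap.
#'
#' @param coords a \linkS4class{SampleTable} with 1 or 2 quantitative
#'   coordinate columns, at least 3 sites.
#' @param threshold \code{"auto"} (MST largest edge) or a positive number in
#'   coordinate units.
#' @param detrend remove the linear trend of the (centred) coordinates from
#'   the MEM scores before returning them.  Default off.
#' @return A \linkS4class{MemBasis} with columns \code{MEM1..MEMk}.
#' @examples
#' tr <- sampleTable(data.frame(row.names = paste0("s", 1:5), x = 0:4))
#' dbmem(tr)@truncationThreshold   # 1: the max nearest-neighbour gap
#' @export
dbmem <- function(coords, threshold = "auto", detrend = FALSE) {
  stopifnot(methods::is(coords, "SampleTable"))
  if (!ncol(coords@data) %in% 1:2)
    stop("db-MEM expects 1- or 2-column coordinates")
  n <- nrow(coords@data)
  if (n < 3L) stop("db-MEM needs at least 3 sites")
  D <- euclideanMatrix(coords)
  dv <- D@values
  if (identical(threshold, "auto")) {
    st <- vegan::spantree(stats::as.dist(dv))
    t <- max(st$dist)
  } else {
    t <- as.numeric(threshold)
    if (!is.finite(t) || t < 0) stop("threshold must be non-negative")
  }
  if (t <= 0) stop("degenerate spanning tree: zero truncation threshold")
  trunc <- dv
  trunc[trunc > t] <- 4 * t
  diag(trunc) <- 0
  ord <- pcoa(distanceMatrix(trunc, ids = rownames(dv)), keep = "positive")
  sc <- as.matrix(ord@scores@data)
  if (detrend && ncol(sc)) {
    X <- scale(as.matrix(coords@data), center = TRUE, scale = FALSE)
    sc <- qr.resid(qr(cbind(1, X)), sc)
  }
  methods::new("MemBasis",
               scores = scoresAsTable(sc, ids = rownames(dv), prefix = "MEM"),
               eigenvalues = ord@eigenvalues,
               truncationThreshold = t)
}
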