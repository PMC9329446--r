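#' @include AllClasses.R utils.R
NULL

.EIG_RTOL <- 1e-8   # relative eigenvalue tolerance: |lambda| <= rtol * max|lambda| is zero

#' Principal coordinates analysis of a distance matrix
#'
#' Gower double-centering \eqn{G = -\frac{1}{2} J D^2 J} (J the centering
#' projector) followed by eigendecomposition.  Axes are retained when their
#' eigenvalue exceeds the relative tolerance \code{1e-8 * max|eigenvalue|};
#' the \code{"positive"} and \code{"nonzero"} policies coincide under this
#' rule (semimetric numerical noise is dropped either way; no Lingoes or
#' Cailliez correction is applied by default).  Scores are eigenvectors
#' scaled by the square root of their eigenvalue, so pairwise score
#' distances reproduce a Euclidean-embeddable input.  Eigenvector signs are
#' fixed so each axis's largest-magnitude loading is positive.
#'
#' @param d a \linkS4class{DistanceMatrix}.
#' @param keep axis-retention policy, \code{"positive"} or \code{"nonzero"}.
#' @return An \linkS4class{Ordination} with score columns
#'   \code{Axis1..AxisK}.
#' @examples
#' xy <- sampleTable(data.frame(row.names = c("a", "b", "c"),
#'                              x = c(0, 3, 0), y = c(0, 0, 4)))
#' sum(eigenvalues(pcoa(euclideanMatrix(xy))))   # 16.667, the total SS
#' @export
pcoa <- function(d, keep = c("positive", "nonzero")) {
  keep <- match.arg(keep)
  stopifnot(methods::is(d, "DistanceMatrix"))
  D <- d@values
  n <- nrow(D)
  if (n < 2L) stop("PCoA needs at least two ids")
  G <- -0.5 * D^2
  rm <- rowMeans(G); gm <- mean(G)
  G <- G - outer(rm, rm, `+`) + gm
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- .EIG_RTOL * max(abs(e$values), 0)
  sel <- which(e$values > tol)
  ev <- e$values[sel]
  if (length(sel)) {
    V <- e$vectors[, sel, drop = FALSE]
    for (j in seq_len(ncol(V))) {
      i <- which.max(abs(V[, j]))
      if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    sc <- sweep(V, 2, sqrt(ev), `*`)
  } else {
    sc <- matrix(0, n, 0)
  }
  rownames(sc) <- rownames(D)
  methods::new("Ordination", ids = rownames(D), eigenvalues = ev,
               scores = scoresAsTable(sc, prefix = "Axis"),
               keptAxisPolicy = keep)
}

#' Total variance of a table, as summed PCA eigenvalues
#'
#' The total variation of an all-quantitative table equals the sum of its
#' column sample variances (divisor n - 1), which is also the sum of its PCA
#' eigenvalues.  This is the variance budget each component table brings to
#' the cumulative diagram.
#'
#' @param t a \linkS4class{SampleTable} with quantitative columns, or a
#'   numeric matrix.
#' @return A single non-negative number.
#' @export
pcaTotalVariance <- function(t) {
  m <- if (methods::is(t, "SampleTable")) {
    if (!all(t@kinds == "quantitative"))
      stop("total variance requires all-quantitative columns")
    as.matrix(t@data)
  } else as.matrix(t)
  if (nrow(m) < 2L) stop("need at least two rows")
  if (anyNA(m)) stop("missing values not allowed")
  sum(apply(m, 2, stats::var))
}

#' Ezekiel-adjusted explained variance
#'
#' \deqn{R^2_{adj} = 1 - (1 - R^2)\frac{n - 1}{n - m - 1}}
#' The only scale on which variation-partitioning fractions are additive;
#' may be negative.  With \code{m = 0} the input is returned unchanged.
#'
#' @param r2 explained proportion in [0, 1].
#' @param n sample size; must exceed \code{m + 1}.
#' @param m number of (effective, i.e. rank of the design) predictors.
#' @return The adjusted value.
#' @examples
#' adjustedR2(0.5, n = 10, m = 2)   # 0.3571
#' @export
adjustedR2 <- function(r2, n, m) {
  if (r2 < 0 || r2 > 1) stop("r2 must lie in [0,1]")
  if (m == 0L) return(r2)
  if (n <= m + 1) stop("need n > m + 1 for the Ezekiel adjustment")
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

## Internal engine shared by rdaFit and the permutation refits.  Builds the
## residualising (covariate) and fitting (predictor) decompositions once;
## statForY() then prices any response matrix in O(n * m) flops.
rdaEngine <- function(x, w = NULL, n) {
  ones <- matrix(1, n, 1)
  qw <- if (is.null(w) || ncol(w) == 0L) qr(ones) else qr(cbind(ones, w))
  q <- qw$rank - 1L
  Xr <- qr.resid(qw, x)
  qx <- if (ncol(Xr) && max(abs(Xr)) > 1e-12) qr(Xr, tol = 1e-9) else NULL
  m <- if (is.null(qx)) 0L else qx$rank
  dfResid <- n - m - q - 1L
  list(qw = qw, qx = qx, m = m, q = q, dfResid = dfResid,
       statForY = function(y) {
         yr <- qr.resid(qw, y)
         ssTot <- sum(yr^2)
         ssFit <- if (m > 0L) sum(qr.fitted(qx, yr)^2) else 0
         ## a residualised total at rounding-noise level means a constant
         ## (or fully absorbed) response
         r2 <- if (ssTot > 1e-24 * max(1, sum(y^2))) ssFit / ssTot
               else NA_real_
         if (!is.na(r2)) r2 <- min(max(r2, 0), 1)   # clip rounding overshoot
         f <- if (m > 0L && dfResid > 0L && !is.na(r2) && r2 < 1)
           (r2 / m) / ((1 - r2) / dfResid)
         else if (!is.na(r2) && r2 >= 1) Inf else NA_real_
         list(r2 = r2, f = f, ssTot = ssTot, ssFit = ssFit)
       })
}

#' Redundancy analysis with optional covariates
#'
#' Multivariate least squares of the centred response matrix on the
#' predictors: response columns are centred (not standardised); when
#' covariates are supplied, response and predictors are first replaced by
#' their residuals on the covariates (plus intercept), so the fit carries
#' the partial (conditional) effect.  The fit uses a rank-revealing QR
#' decomposition: collinear predictors reduce the effective rank
#' \code{m} instead of erroring.  \code{r2} is the trace ratio
#' fitted-SS / total-SS, and the pseudo-F is
#' \deqn{F = \frac{R^2 / m}{(1 - R^2) / (n - m - q - 1)}}
#' The Ezekiel-adjusted R2 is reported for unconditioned fits only; partial
#' adjusted fractions are obtained by subtraction of unconditioned adjusted
#' R2s (see \code{\link{varpart2}}), never by plugging m + q into the
#' Ezekiel formula.
#'
#' @param y response: \linkS4class{SampleTable} or numeric matrix (rows
#'   aligned with \code{x}).
#' @param x predictors (factor columns of a SampleTable are expanded to
#'   indicators).
#' @param w optional covariates, same forms as \code{x}.
#' @return An \linkS4class{RdaFit}.
#' @seealso \code{\link{permutationTest}}, \code{\link{varpart2}}
#' @export
rdaFit <- function(y, x, w = NULL) {
  Y <- asPredictorMatrix(y)
  X <- asPredictorMatrix(x)
  W <- if (is.null(w)) NULL else asPredictorMatrix(w)
  n <- nrow(Y)
  if (nrow(X) != n || (!is.null(W) && nrow(W) != n))
    stop("response, predictors and covariates must share rows")
  if (anyNA(Y) || anyNA(X) || (!is.null(W) && anyNA(W)))
    stop("missing values not allowed in RDA inputs")
  eng <- rdaEngine(X, W, n)
  if (eng$dfResid < 1L)
    stop(sprintf("sample size too small: n = %d leaves no residual df for m = %d, q = %d",
                 n, eng$m, eng$q))
  st <- eng$statForY(Y)
  if (is.na(st$r2)) stop("constant response")
  adj <- if (eng$q == 0L) adjustedR2(st$r2, n, eng$m) else NA_real_
  methods::new("RdaFit",
               r2 = st$r2, adjR2 = adj, pseudoF = st$f,
               dfModel = eng$m, dfResid = eng$dfResid,
               n = as.integer(n), m = eng$m, q = eng$q,
               fittedVariance = st$ssFit / (n - 1),
               residualVariance = (st$ssTot - st$ssFit) / (n - 1))
}

## Simple adjusted R2 of y ~ x (no covariates), Ezekiel on the effective rank.
simpleAdjR2 <- function(y, x) {
  f <- rdaFit(y, x)
  adjustedR2(f@r2, f@n, f@m)
}

## Partial adjusted R2 by the Peres-Neto subtraction:
## adj(y ~ x + w) - adj(y ~ w).  With w NULL this is the simple adjusted R2.
partialAdjR2 <- function(y, x, w = NULL) {
  if (is.null(w) || ncol(asPredictorMatrix(w)) == 0L) return(simpleAdjR2(y, x))
  X <- asPredictorMatrix(x)
  W <- asPredictorMatrix(w)
  simpleAdjR2(y, cbind(W, X)) - simpleAdjR2(y, W)
}
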