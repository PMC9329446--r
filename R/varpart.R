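#' @include AllClasses.R utils.R ordination.R inference.R
NULL

#' Variation partitioning between two predictor matrices
#'
#' Partitions the adjusted explained variance of a response matrix between
#' two predictor matrices: from the Ezekiel-adjusted R2 of the three
#' unconditioned fits (each predictor alone, both together) the unique
#' fractions are obtained by subtraction (Peres--Neto convention) and the
#' shared fraction by inclusion--exclusion:
#' \deqn{unique_1 = adj(x_1 \cup x_2) - adj(x_2)}
#' \deqn{shared = adj(x_1) + adj(x_2) - adj(x_1 \cup x_2)}
#' \deqn{residual = 1 - adj(x_1 \cup x_2)}
#' Fractions may be negative and are reported as-is (closure to 1 is exact).
#'
#' @param y response matrix or \linkS4class{SampleTable}.
#' @param x1,x2 predictor matrices.
#' @param labels length-2 predictor labels (default \code{c("X1","X2")}).
#' @param responseLabel label of the response.
#' @return A \linkS4class{VarpartResult} with fractions keyed
#'   \code{label1}, \code{label2}, \code{label1label2}.
#' @seealso \code{\link{varpart3}}, \code{\link{testFractions}}
#' @export
varpart2 <- function(y, x1, x2, labels = c("X1", "X2"),
                     responseLabel = "Y") {
  stopifnot(length(labels) == 2L)
  a1 <- simpleAdjR2(y, x1)
  a2 <- simpleAdjR2(y, x2)
  a12 <- simpleAdjR2(y, cbind(asPredictorMatrix(x1), asPredictorMatrix(x2)))
  fr <- c(a12 - a2, a12 - a1, a1 + a2 - a12)
  names(fr) <- c(fractionKey(labels[1L]), fractionKey(labels[2L]),
                 fractionKey(labels))
  methods::new("VarpartResult",
               responseLabel = responseLabel, predictorLabels = labels,
               fractions = fr, residual = 1 - a12,
               totalVariance = pcaTotalVariance(asPredictorMatrix(y)),
               scale = "proportion")
}

#' Variation partitioning among three predictor matrices
#'
#' The seven fractions (three unique, three pairwise-shared, one
#' triple-shared) plus residual, from inclusion--exclusion over the seven
#' unconditioned adjusted R2s (single, pairwise and all-three models).  The
#' unique fractions are additionally computed directly as partial models,
#' \eqn{adj(all) - adj(other\ two)}, and must agree with the
#' inclusion--exclusion solution to 1e-12 (internal consistency check of the
#' subtraction scheme).
#'
#' @param y response matrix or \linkS4class{SampleTable}.
#' @param x1,x2,x3 predictor matrices.
#' @param labels length-3 predictor labels.
#' @param responseLabel label of the response.
#' @return A \linkS4class{VarpartResult} with seven fractions keyed by
#'   concatenated labels (\code{"A"}, \code{"AE"}, \code{"AES"}, ...).
#' @export
varpart3 <- function(y, x1, x2, x3, labels = c("X1", "X2", "X3"),
                     responseLabel = "Y") {
  stopifnot(length(labels) == 3L)
  m1 <- asPredictorMatrix(x1); m2 <- asPredictorMatrix(x2)
  m3 <- asPredictorMatrix(x3)
  f1 <- simpleAdjR2(y, m1); f2 <- simpleAdjR2(y, m2); f3 <- simpleAdjR2(y, m3)
  f12 <- simpleAdjR2(y, cbind(m1, m2)); f13 <- simpleAdjR2(y, cbind(m1, m3))
  f23 <- simpleAdjR2(y, cbind(m2, m3))
  f123 <- simpleAdjR2(y, cbind(m1, m2, m3))
  ## regions: u1, u2, u3, s12, s13, s23, s123; each model R2 is the sum of
  ## the regions its predictors cover
  M <- rbind(c(1, 0, 0, 1, 1, 0, 1),    # f1
             c(0, 1, 0, 1, 0, 1, 1),    # f2
             c(0, 0, 1, 0, 1, 1, 1),    # f3
             c(1, 1, 0, 1, 1, 1, 1),    # f12
             c(1, 0, 1, 1, 1, 1, 1),    # f13
             c(0, 1, 1, 1, 1, 1, 1),    # f23
             c(1, 1, 1, 1, 1, 1, 1))    # f123
  reg <- solve(M, c(f1, f2, f3, f12, f13, f23, f123))
  uniqueDirect <- c(f123 - f23, f123 - f13, f123 - f12)
  if (max(abs(reg[1:3] - uniqueDirect)) > 1e-12)
    stop("internal inconsistency: partial-model unique fractions disagree ",
         "with inclusion-exclusion beyond 1e-12")
  reg[1:3] <- uniqueDirect
  nm <- c(fractionKey(labels[1L]), fractionKey(labels[2L]),
          fractionKey(labels[3L]),
          fractionKey(labels[c(1L, 2L)]), fractionKey(labels[c(1L, 3L)]),
          fractionKey(labels[c(2L, 3L)]), fractionKey(labels))
  fr <- stats::setNames(reg, nm)
  residual <- 1 - f123
  ## enforce exact closure against roundoff in the linear solve
  fr[length(fr)] <- 1 - residual - sum(fr[-length(fr)])
  methods::new("VarpartResult",
               responseLabel = responseLabel, predictorLabels = labels,
               fractions = fr, residual = residual,
               totalVariance = pcaTotalVariance(asPredictorMatrix(y)),
               scale = "proportion")
}

#' Permutation tests of the testable fractions
#'
#' Tests each predictor matrix's simple effect (RDA of the response on that
#' matrix alone) and its unique/conditional effect (partial RDA given the
#' remaining matrices).  Shared fractions are not permutation-testable and
#' deliberately receive no entry.
#'
#' @param y response.
#' @param xs list of 2 or 3 predictor matrices.
#' @param design permutation design.
#' @param nPerm permutations per test.
#' @param seed mandatory seed; sub-seeds derived per test.
#' @param labels predictor labels (default names of \code{xs} or X1..).
#' @return Named list of \linkS4class{TestResult}s with keys
#'   \code{simple_<label>} and \code{unique_<label>}.
#' @export
testFractions <- function(y, xs, design = permutationDesign("free"),
                          nPerm = 999L, seed, labels = NULL) {
  if (missing(seed)) stop("a seed is mandatory for any stochastic command")
  if (length(xs) < 2L || length(xs) > 3L)
    stop("testFractions handles 2 or 3 predictor matrices")
  if (is.null(labels))
    labels <- if (!is.null(names(xs))) names(xs) else paste0("X", seq_along(xs))
  mats <- lapply(xs, asPredictorMatrix)
  out <- list()
  k <- 0L
  for (i in seq_along(mats)) {
    k <- k + 1L
    out[[paste0("simple_", labels[i])]] <-
      permutationTest(y, mats[[i]], NULL, design = design, nPerm = nPerm,
                      seed = deriveSeed(seed, k))
    k <- k + 1L
    others <- do.call(cbind, mats[-i])
    out[[paste0("unique_", labels[i])]] <-
      permutationTest(y, mats[[i]], others, design = design, nPerm = nPerm,
                      seed = deriveSeed(seed, k))
  }
  out
}

#' Chi-squared comparison of explained-variance classes
#'
#' Compares two percentage distributions over classes of explained variance
#' (e.g. unique-E, unique-S, shared, residual) with the statistic
#' \eqn{\chi^2 = \sum_i (O_i - E_i)^2 / E_i}, df = number of classes - 1.
#'
#' @param observed,expected percentage vectors of equal length >= 2;
#'   expected must be positive elementwise.
#' @param labels optional class labels.
#' @return A \linkS4class{ChiSqResult}.
#' @examples
#' chisqFractionCompare(c(10, 20, 30, 40), c(25, 25, 25, 25))@statistic  # 20
#' @export
chisqFractionCompare <- function(observed, expected, labels = NULL) {
  if (length(observed) != length(expected))
    stop("observed and expected must have equal length")
  if (length(observed) < 2L) stop("need at least two classes")
  if (any(expected <= 0)) stop("expected class values must be positive")
  if (is.null(labels)) labels <- paste0("class", seq_along(observed))
  methods::new("ChiSqResult",
               statistic = sum((observed - expected)^2 / expected),
               df = length(observed) - 1L,
               classes = as.character(labels),
               observed = as.numeric(observed),
               expected = as.numeric(expected))
}
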