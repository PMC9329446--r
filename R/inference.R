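#' @include AllClasses.R utils.R ordination.R
NULL

#' Construct a permutation design
#'
#' @param kind \code{"free"}, \code{"blocks"}, \code{"series"} or
#'   \code{"split_plot"}.
#' @param blocks per-row block labels (whole plots).  For \code{series} and
#'   \code{split_plot}, rows of a block must be contiguous and in declared
#'   time order.  A \code{series} design without labels treats all rows as
#'   one series.
#' @param mirror for series-type shifts, additionally allow the mirrored
#'   (reversed) series.  Default off.
#' @param wholePlotOrder optional declared order of whole-plot labels
#'   (defaults to order of appearance).
#' @param shiftWithin for \code{split_plot}: also cyclic-shift each block's
#'   internal series when exchanging whole plots.  Default off (within-block
#'   order preserved), i.e. permutation at the whole-plot level only.
#' @return A \linkS4class{PermutationDesign}.
#' @examples
#' permutationDesign("series", blocks = rep("tr1", 8))
#' @export
permutationDesign <- function(kind = c("free", "blocks", "series", "split_plot"),
                              blocks = NULL, mirror = FALSE,
                              wholePlotOrder = NULL, shiftWithin = FALSE) {
  kind <- match.arg(kind)
  methods::new("PermutationDesign", kind = kind,
               blockLabels = if (is.null(blocks)) character(0) else as.character(blocks),
               allowMirror = isTRUE(mirror),
               wholePlotOrder = if (is.null(wholePlotOrder)) character(0)
                                else as.character(wholePlotOrder),
               shiftWithin = isTRUE(shiftWithin))
}

## Per-block row positions, in declared whole-plot order; validates the
## design against n.
designBlocks <- function(design, n) {
  labs <- design@blockLabels
  if (design@kind == "free") return(list(seq_len(n)))
  if (!length(labs)) {
    if (design@kind == "series") return(list(seq_len(n)))
    stop("design kind '", design@kind, "' requires block labels")
  }
  if (length(labs) != n)
    stop(sprintf("block labels cover %d rows but data has %d", length(labs), n))
  ord <- if (length(design@wholePlotOrder)) design@wholePlotOrder else unique(labs)
  if (!setequal(ord, unique(labs))) stop("wholePlotOrder inconsistent with labels")
  bl <- lapply(ord, function(l) which(labs == l))
  if (design@kind %in% c("series", "split_plot"))
    for (b in bl) if (length(b) > 1L && any(diff(b) != 1L))
      stop("series rows within a block must be contiguous")
  if (design@kind == "split_plot" &&
      length(unique(lengths(bl))) != 1L)
    stop("split_plot requires equal block sizes for whole-plot exchange")
  bl
}

## One cyclic-shift arrangement of 1..b (optionally mirrored first).
seriesArrangement <- function(b, shift, mirrored = FALSE) {
  s <- seq_len(b)
  if (mirrored) s <- rev(s)
  if (shift > 0) s <- c(s[(shift + 1L):b], s[seq_len(shift)])
  s
}

#' Draw one permutation under a design
#'
#' Returns a 1-based index vector \code{p} so that \code{data[p, ]} is the
#' permuted arrangement.  \code{free} draws a uniform permutation;
#' \code{blocks} permutes freely within each block; \code{series} applies a
#' single uniform cyclic shift within each block (a mirrored shift is also
#' allowed when the design says so); \code{split_plot} exchanges whole
#' blocks by a free permutation of block labels, preserving (or, if
#' requested, cyclically shifting) each block's internal order.  Uses the
#' current RNG state; seed via \code{set.seed} or the \code{seed} arguments
#' of the test functions.
#'
#' @param design a \linkS4class{PermutationDesign}.
#' @param n number of rows.
#' @return An integer permutation of \code{1:n}.
#' @seealso \code{\link{permutationTest}}, \code{\link{enumeratePermutations}}
#' @export
generatePermutation <- function(design, n) {
  kind <- design@kind
  if (kind == "free") return(sample.int(n))
  bl <- designBlocks(design, n)
  p <- integer(n)
  if (kind == "blocks") {
    for (idx in bl) p[idx] <- idx[sample.int(length(idx))]
  } else if (kind == "series") {
    for (idx in bl) {
      b <- length(idx)
      mir <- design@allowMirror && b > 2L && stats::runif(1) < 0.5
      p[idx] <- idx[seriesArrangement(b, sample.int(b, 1L) - 1L, mir)]
    }
  } else {  # split_plot
    nb <- length(bl)
    bp <- sample.int(nb)
    for (j in seq_len(nb)) {
      src <- bl[[bp[j]]]
      if (design@shiftWithin) {
        b <- length(src)
        mir <- design@allowMirror && b > 2L && stats::runif(1) < 0.5
        src <- src[seriesArrangement(b, sample.int(b, 1L) - 1L, mir)]
      }
      p[bl[[j]]] <- src
    }
  }
  p
}

#' Enumerate the full permutation orbit of a design
#'
#' Exhaustive enumeration of every distinct arrangement the design can
#' produce (the identity included), used for exact p-values on small data.
#'
#' @param design a \linkS4class{PermutationDesign}.
#' @param n number of rows.
#' @param limit refuse orbits larger than this (default 1e5).
#' @return Integer matrix, one distinct permutation per row.
#' @export
enumeratePermutations <- function(design, n, limit = 1e5) {
  sz <- orbitSize(design, n)
  if (sz > limit) stop(sprintf("orbit size %.3g exceeds limit %g", sz, limit))
  allPerms <- function(v) {
    if (length(v) <= 1L) return(matrix(v, nrow = 1L))
    do.call(rbind, lapply(seq_along(v), function(i) {
      rest <- allPerms(v[-i])
      cbind(v[i], rest, deparse.level = 0)
    }))
  }
  crossJoin <- function(partsList, n) {
    ## partsList: per block, candidate sub-arrangements (arr: rows of source
    ## positions) and the row positions they fill (pos); returns every
    ## combination assembled into a full permutation row.
    out <- matrix(0L, 1L, n)
    for (k in seq_along(partsList)) {
      arr <- partsList[[k]]$arr
      pos <- partsList[[k]]$pos
      grown <- matrix(0L, nrow(out) * nrow(arr), n)
      r <- 0L
      for (i in seq_len(nrow(out))) for (j in seq_len(nrow(arr))) {
        r <- r + 1L
        row <- out[i, ]
        row[pos] <- arr[j, ]
        grown[r, ] <- row
      }
      out <- grown
    }
    out
  }
  kind <- design@kind
  if (kind == "free") {
    m <- allPerms(seq_len(n))
  } else {
    bl <- designBlocks(design, n)
    parts <- lapply(bl, function(idx) {
      b <- length(idx)
      arr <- switch(kind,
        blocks = {
          sub <- allPerms(seq_len(b))
          matrix(idx[sub], nrow(sub), b)
        },
        series = ,
        split_plot = {
          shifts <- lapply(0:(b - 1L), function(s) idx[seriesArrangement(b, s)])
          if (design@allowMirror)
            shifts <- c(shifts, lapply(0:(b - 1L), function(s)
              idx[seriesArrangement(b, s, mirrored = TRUE)]))
          unique(do.call(rbind, shifts))
        })
      if (kind == "split_plot" && !design@shiftWithin)
        arr <- matrix(idx, 1L, b)
      list(arr = arr, pos = idx)
    })
    m <- crossJoin(parts, n)
    if (kind == "split_plot") {
      nb <- length(bl)
      bsz <- length(bl[[1L]])
      bperms <- allPerms(seq_len(nb))
      res <- vector("list", nrow(bperms) * nrow(m))
      r <- 0L
      for (i in seq_len(nrow(bperms))) for (j in seq_len(nrow(m))) {
        p <- integer(n)
        for (k in seq_len(nb))
          p[bl[[k]]] <- m[j, bl[[bperms[i, k]]]]
        r <- r + 1L
        res[[r]] <- p
      }
      m <- do.call(rbind, res)
    }
  }
  unique(m)
}

## Upper bound on the number of distinct arrangements.
orbitSize <- function(design, n) {
  kind <- design@kind
  if (kind == "free") return(factorial(n))
  bl <- designBlocks(design, n)
  sizes <- lengths(bl)
  switch(kind,
    blocks = prod(factorial(sizes)),
    series = prod(ifelse(design@allowMirror & sizes > 2L, 2 * sizes,
                         pmax(sizes, 1))),
    split_plot = factorial(length(bl)) *
      if (design@shiftWithin)
        prod(ifelse(design@allowMirror & sizes > 2L, 2 * sizes, pmax(sizes, 1)))
      else 1)
}

#' Monte Carlo permutation test of a (partial) RDA
#'
#' Tests the pseudo-F of \code{rdaFit(y, x, w)} against its permutation
#' null.  With covariates, permutation follows Freedman--Lane: the rows of
#' the residuals of the reduced model (response on covariates) are permuted
#' under \code{design}, added back to the reduced-model fit, and the full
#' model is refit.  Without covariates this reduces to permuting the
#' centred response rows.  The p-value is
#' \eqn{(\#\{F^* \ge F_{obs}\} + 1) / (n_{perm} + 1)}; when the design's
#' orbit has at most \code{nPerm} distinct arrangements, the orbit is
#' enumerated instead and the p-value is exact (the identity arrangement
#' included).  Deterministic given \code{seed}.
#'
#' @param y,x,w response, predictors, optional covariates (as in
#'   \code{\link{rdaFit}}).
#' @param design a \linkS4class{PermutationDesign} (default free).
#' @param nPerm number of permutations (paper-style default 999).
#' @param seed mandatory RNG seed.
#' @param exhaustive \code{"auto"} (enumerate when the orbit fits in
#'   \code{nPerm}), \code{"never"}, or \code{"always"}.
#' @return A \linkS4class{TestResult}.
#' @export
permutationTest <- function(y, x, w = NULL, design = permutationDesign("free"),
                            nPerm = 999L, seed,
                            exhaustive = c("auto", "never", "always")) {
  exhaustive <- match.arg(exhaustive)
  if (missing(seed)) stop("a seed is mandatory for any stochastic command")
  nPerm <- as.integer(nPerm)
  if (nPerm < 1L) stop("nPerm must be at least 1")
  Y <- asPredictorMatrix(y)
  X <- asPredictorMatrix(x)
  W <- if (is.null(w)) NULL else asPredictorMatrix(w)
  n <- nrow(Y)
  eng <- rdaEngine(X, W, n)
  if (eng$dfResid < 1L) stop("sample size too small for the permutation test")
  obs <- eng$statForY(Y)
  if (is.na(obs$r2)) stop("constant response")
  fitted0 <- qr.fitted(eng$qw, Y)
  resid0 <- qr.resid(eng$qw, Y)
  tol <- 1e-12 * max(1, abs(obs$f))
  sz <- orbitSize(design, n)
  doExact <- switch(exhaustive,
                    auto = is.finite(sz) && sz <= nPerm,
                    always = TRUE, never = FALSE)
  if (doExact) {
    perms <- enumeratePermutations(design, n)
    fs <- apply(perms, 1L, function(p)
      eng$statForY(fitted0 + resid0[p, , drop = FALSE])$f)
    p <- mean(fs >= obs$f - tol)
    nUsed <- nrow(perms)
  } else {
    exceed <- withSeed(seed, {
      cnt <- 0L
      for (i in seq_len(nPerm)) {
        prm <- generatePermutation(design, n)
        f <- eng$statForY(fitted0 + resid0[prm, , drop = FALSE])$f
        if (!is.na(f) && f >= obs$f - tol) cnt <- cnt + 1L
      }
      cnt
    })
    p <- (exceed + 1) / (nPerm + 1)
    nUsed <- nPerm
  }
  methods::new("TestResult", statistic = obs$f, pValue = p,
               nPerm = as.integer(nUsed), seed = as.integer(seed),
               scheme = designSummary(design), exhaustive = doExact)
}

designSummary <- function(design) {
  paste0(design@kind,
         if (length(design@blockLabels))
           sprintf("[%d blocks]", length(unique(design@blockLabels))) else "",
         if (design@allowMirror) "+mirror" else "",
         if (design@kind == "split_plot" && design@shiftWithin) "+shift" else "")
}

#' Benjamini--Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, capped at 1, order-preserving with the input.
#' Thin wrapper over \code{stats::p.adjust(method = "BH")} with input
#' validation.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03, 0.04))   # all 0.04
#' @export
fdrAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Forward selection with FDR control and a double stopping rule
#'
#' Greedy selection of predictor columns for a multivariate response.  At
#' each step every remaining candidate is tested by a partial permutation
#' test conditioning on the already-selected columns (and any covariates);
#' the step's p-values are FDR-adjusted over the step's candidate set, and
#' among candidates passing \code{alpha} the one with the largest adjusted-R2
#' gain (Peres--Neto subtraction) enters, ties broken by column order.
#' Selection stops when no candidate passes \code{alpha}
#' (\code{"alpha_fail"}), when the best admissible model would exceed the
#' adjusted R2 of the full all-candidate model (\code{"adjr2_ceiling"} --
#' the second stopping criterion guarding against overfitting), or when all
#' candidates are in (\code{"exhausted"}).
#'
#' @param y response (\linkS4class{SampleTable} or matrix).
#' @param candidates candidate predictor columns.
#' @param w optional covariates conditioned on throughout.
#' @param alpha significance level on FDR-adjusted p-values.
#' @param nPerm permutations per candidate test.
#' @param seed mandatory seed; per-test sub-seeds are derived
#'   deterministically.
#' @param design permutation design for the tests.
#' @return A \linkS4class{SelectionResult}.
#' @export
forwardSelect <- function(y, candidates, w = NULL, alpha = 0.05,
                          nPerm = 199L, seed,
                          design = permutationDesign("free")) {
  if (missing(seed)) stop("a seed is mandatory for any stochastic command")
  C <- asPredictorMatrix(candidates)
  if (ncol(C) < 1L) stop("need at least one candidate column")
  if (is.null(colnames(C))) colnames(C) <- paste0("V", seq_len(ncol(C)))
  W <- if (is.null(w)) NULL else asPredictorMatrix(w)
  fullAdj <- partialAdjR2(y, C, W)
  selected <- character(0)
  curAdj <- 0
  steps <- list()
  reason <- NULL
  testCounter <- 0L
  repeat {
    remaining <- setdiff(colnames(C), selected)
    if (!length(remaining)) { reason <- "exhausted"; break }
    selMat <- C[, selected, drop = FALSE]
    covNow <- if (is.null(W)) {
      if (length(selected)) selMat else NULL
    } else cbind(W, selMat)
    gains <- numeric(length(remaining))
    praw <- numeric(length(remaining))
    for (i in seq_along(remaining)) {
      cand <- C[, remaining[i], drop = FALSE]
      gains[i] <- partialAdjR2(y, cbind(selMat, cand), W) -
        (if (length(selected)) partialAdjR2(y, selMat, W) else 0)
      testCounter <- testCounter + 1L
      praw[i] <- permutationTest(y, cand, covNow, design = design,
                                 nPerm = nPerm,
                                 seed = deriveSeed(seed, testCounter))@pValue
    }
    pfdr <- fdrAdjust(praw)
    eligible <- which(pfdr <= alpha)
    stepRec <- data.frame(step = length(selected) + 1L, candidate = remaining,
                          adjR2Gain = gains, pRaw = praw, pFdr = pfdr,
                          entered = FALSE, stringsAsFactors = FALSE)
    if (!length(eligible)) {
      steps[[length(steps) + 1L]] <- stepRec
      reason <- "alpha_fail"; break
    }
    best <- eligible[which.max(gains[eligible])]
    candAdj <- curAdj + gains[best]
    ## Double stopping rule: selection stops once the cumulative adjusted R2
    ## reaches the full all-candidate model's adjusted R2.  The first
    ## significant candidate is retained even when it alone attains the
    ## ceiling -- a sparse strong predictor can push the one-variable
    ## adjusted R2 above the noise-penalised full model, and rejecting the
    ## entire signal on that account would defeat the guard's purpose.
    ceilingHit <- candAdj >= fullAdj - 1e-12
    if (ceilingHit && length(selected)) {
      steps[[length(steps) + 1L]] <- stepRec
      reason <- "adjr2_ceiling"; break
    }
    stepRec$entered[best] <- TRUE
    steps[[length(steps) + 1L]] <- stepRec
    selected <- c(selected, remaining[best])
    curAdj <- candAdj
    if (ceilingHit) { reason <- "adjr2_ceiling"; break }
  }
  methods::new("SelectionResult",
               selected = selected,
               steps = if (length(steps)) do.call(rbind, steps)
                       else data.frame(step = integer(0), candidate = character(0),
                                       adjR2Gain = numeric(0), pRaw = numeric(0),
                                       pFdr = numeric(0), entered = logical(0)),
               stopReason = reason,
               fullAdjR2 = fullAdj,
               finalAdjR2 = curAdj)
}
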