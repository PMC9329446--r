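#' @include AllClasses.R utils.R dissimilarity.R ordination.R
NULL

#' Taxonomic diversity indices of one abundance vector
#'
#' Species richness S, Shannon entropy H (natural log), Pielou evenness
#' J = H / ln(S), and Hill's N2 (inverse Simpson, the effective number of
#' dominant species).  For a monoculture (S = 1) the evenness is undefined
#' (0/0) and reported missing rather than zero.
#'
#' @param counts non-negative abundance vector with at least one positive
#'   entry (binary presence/absence is accepted and treated as abundance).
#' @return Named numeric vector \code{c(S, H, J, N2)}.
#' @examples
#' taxonomicIndices(c(5, 5, 5, 5))   # S 4, H log(4), J 1, N2 4
#' @export
taxonomicIndices <- function(counts) {
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all-zero abundance vector")
  S <- sum(counts > 0)
  H <- as.numeric(vegan::diversity(counts, index = "shannon"))
  N2 <- as.numeric(vegan::diversity(counts, index = "invsimpson"))
  J <- if (S >= 2L) H / log(S) else NA_real_
  c(S = S, H = H, J = J, N2 = N2)
}

#' Functional trait space of a species pool
#'
#' Gower dissimilarities of the mixed-type trait table, embedded by PCoA
#' keeping all axes above tolerance; species distances are then Euclidean in
#' the full retained score space.  When the Gower matrix is
#' Euclidean-embeddable these distances reproduce it.
#'
#' @param traits species-by-traits \linkS4class{SampleTable} (>= 2 species).
#' @return A \linkS4class{TraitSpace}.
#' @seealso \code{\link{raoQ}}
#' @export
traitSpace <- function(traits) {
  stopifnot(methods::is(traits, "SampleTable"))
  if (nrow(traits@data) < 2L) stop("need at least two species")
  g <- gowerMatrix(traits)
  ord <- pcoa(g, keep = "nonzero")
  sc <- ord@scores
  d <- if (ncol(sc@data)) euclideanMatrix(sc)
       else distanceMatrix(matrix(0, nrow(traits@data), nrow(traits@data)),
                           ids = rownames(traits@data))
  methods::new("TraitSpace", speciesScores = sc, speciesDistance = d)
}

#' Rao quadratic entropy
#'
#' Abundance-weighted mean pairwise trait distance over ordered pairs:
#' \deqn{Q = \sum_i \sum_j d_{ij} p_i p_j}
#' with \eqn{p} the relative abundances and \eqn{d_{ii} = 0}.  Distances are
#' plain Euclidean distances in trait space (not squared), so with all
#' pairwise distances equal to \eqn{c}, \eqn{Q = c (1 - \sum p_i^2)} exactly.
#' Invariant to rescaling the counts.
#'
#' @param counts abundance vector named by (or ordered as) the species ids
#'   of \code{d}.
#' @param d species \linkS4class{DistanceMatrix} (e.g. from
#'   \code{\link{traitSpace}}).
#' @return The quadratic entropy, in the distance's units.
#' @examples
#' d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a","b"), c("a","b")))
#' raoQ(c(a = 1, b = 1), distanceMatrix(d))   # 0.5
#' @export
raoQ <- function(counts, d) {
  stopifnot(methods::is(d, "DistanceMatrix"))
  ids <- rownames(d@values)
  if (!is.null(names(counts))) {
    if (!setequal(names(counts), ids))
      stop("abundance names do not match the distance ids")
    counts <- counts[ids]
  } else if (length(counts) != length(ids)) {
    stop("abundance vector length does not match the distance ids")
  }
  counts <- as.numeric(counts)
  if (any(counts < 0) || sum(counts) == 0)
    stop("counts must be non-negative with a positive sum")
  p <- counts / sum(counts)
  drop(p %*% d@values %*% p)
}

#' Community-weighted mean traits
#'
#' Per site, trait values averaged with the species' relative abundances:
#' quantitative and ordinal traits give \eqn{\sum_i p_i x_i}; a factor trait
#' yields one column per level holding the summed relative abundance of
#' species carrying that level (the level-proportion columns partition 1);
#' binary traits behave as 0/1 quantitative, i.e. a proportion.  Sites with
#' zero total abundance get a missing row.
#'
#' @param community sites-by-species \linkS4class{SampleTable} (counts or
#'   presence/absence).
#' @param traits species-by-traits \linkS4class{SampleTable}; its rows must
#'   be exactly the community's species columns.
#' @return An all-quantitative \linkS4class{SampleTable} of CWM values, rows
#'   aligned with the community sites.
#' @examples
#' comm <- sampleTable(data.frame(row.names = "site1", sp1 = 1, sp2 = 3))
#' tr <- sampleTable(data.frame(row.names = c("sp1", "sp2"), size = c(2, 4)))
#' tableData(cwm(comm, tr))$size   # 3.5
#' @export
cwm <- function(community, traits) {
  stopifnot(methods::is(community, "SampleTable"),
            methods::is(traits, "SampleTable"))
  spp <- colnames(community@data)
  if (!setequal(spp, rownames(traits@data)))
    stop("community species and trait rows do not match")
  td <- traits@data[spp, , drop = FALSE]
  A <- as.matrix(community@data)
  tot <- rowSums(A)
  P <- A / ifelse(tot > 0, tot, NA)   # zero-abundance sites become NA rows
  out <- list()
  for (cn in colnames(td)) {
    k <- traits@kinds[[cn]]
    if (k == "factor") {
      for (l in traits@levels[[cn]])
        out[[paste0(cn, ".", l)]] <- as.numeric(P %*% (td[[cn]] == l))
    } else {
      out[[cn]] <- as.numeric(P %*% as.numeric(td[[cn]]))
    }
  }
  d <- as.data.frame(out)
  rownames(d) <- rownames(A)
  sampleTable(d, kinds = "quantitative")
}

#' Per-site diversity table
#'
#' Taxonomic indices of the native component per site plus Rao quadratic
#' entropies computed on the corresponding community subsets in their trait
#' spaces: natives, aliens, and (optionally) the pooled community.
#'
#' @param native,alien sites-by-species \linkS4class{SampleTable}s.
#' @param nativeTraits,alienTraits matching trait tables (optional; Rao
#'   columns are produced when given).
#' @return A \code{data.frame} with columns \code{S, H, J, N2} and any of
#'   \code{Q_natives, Q_aliens, Q_all}, one row per site (Rao is missing for
#'   sites where the subset has zero abundance).
#' @export
diversityTable <- function(native, alien = NULL, nativeTraits = NULL,
                           alienTraits = NULL) {
  stopifnot(methods::is(native, "SampleTable"))
  A <- as.matrix(native@data)
  base <- t(apply(A, 1L, function(v)
    if (sum(v) > 0) taxonomicIndices(v) else c(S = 0, H = NA, J = NA, N2 = NA)))
  out <- as.data.frame(base)
  raoCol <- function(comm, traits) {
    ts <- traitSpace(traits)
    M <- as.matrix(comm@data)[, sampleIDs(ts@speciesDistance), drop = FALSE]
    apply(M, 1L, function(v) if (sum(v) > 0) raoQ(v, ts@speciesDistance)
          else NA_real_)
  }
  if (!is.null(nativeTraits)) out$Q_natives <- raoCol(native, nativeTraits)
  if (!is.null(alien) && !is.null(alienTraits))
    out$Q_aliens <- raoCol(alien, alienTraits)
  if (!is.null(alien) && !is.null(nativeTraits) && !is.null(alienTraits)) {
    allComm <- sampleTable(cbind(native@data, alien@data))
    allTraits <- methods::new("SampleTable",
      data = rbind(nativeTraits@data, alienTraits@data),
      kinds = nativeTraits@kinds, weights = nativeTraits@weights,
      levels = mapply(function(a, b) unique(c(a, b)), nativeTraits@levels,
                      alienTraits@levels, SIMPLIFY = FALSE))
    out$Q_all <- raoCol(allComm, allTraits)
  }
  rownames(out) <- rownames(A)
  out
}
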