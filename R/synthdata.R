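#' @include AllClasses.R utils.R spatial_mem.R
NULL

#' Construct synthetic riverscape parameters
#'
#' Defaults describe the emulated study system: a one-dimensional river
#' transect of 20 sampling sites, 22 native and 6 alien mollusk-like
#' species, count responses, a four-variable mixed environment table
#' (habitat factor R/L/C, Impact ordinal 0--7, Flow ordinal 1--5,
#' quantitative distance-to-dam), 11 mixed-type traits, native latent
#' variance shares (env, space, shared, noise) = (0.30, 0.20, 0.10, 0.40)
#' and an alien community with a doubled noise share
#' (0.10, 0.05, 0.05, 0.80), reflecting aliens' weaker dependence on the
#' measured predictors.
#'
#' @param nSites,nNative,nAlien dimensions.
#' @param sharesNative,sharesAlien named numeric (env, space, shared,
#'   noise) summing to 1.
#' @param responseModel \code{"poisson-counts"} (default),
#'   \code{"gaussian-latent"} or \code{"binary-threshold"}.  Recovery of the
#'   design shares is certified for the Gaussian latent model; count and
#'   binary links degrade it.
#' @param nEnvVars number of environment columns (>= 4).
#' @param transect \code{"regular"} or \code{"irregular"} spacing.
#' @param nTraits number of trait columns (>= 4).
#' @param seed RNG seed.
#' @return A \linkS4class{SynthParams}.
#' @export
synthParams <- function(nSites = 20L, nNative = 22L, nAlien = 6L,
                        sharesNative = c(env = 0.30, space = 0.20,
                                         shared = 0.10, noise = 0.40),
                        sharesAlien = c(env = 0.10, space = 0.05,
                                        shared = 0.05, noise = 0.80),
                        responseModel = "poisson-counts",
                        nEnvVars = 4L, transect = "regular",
                        nTraits = 11L, seed = 1L) {
  methods::new("SynthParams",
               nSites = as.integer(nSites), nNative = as.integer(nNative),
               nAlien = as.integer(nAlien),
               sharesNative = sharesNative[c("env", "space", "shared", "noise")],
               sharesAlien = sharesAlien[c("env", "space", "shared", "noise")],
               responseModel = responseModel, nEnvVars = as.integer(nEnvVars),
               transect = transect, nTraits = as.integer(nTraits),
               seed = as.integer(seed))
}

## Orthonormal spatial channel vectors: k mutually orthogonal unit-variance
## columns inside the span of the leading MEM axes.  Restricting to the
## broad-scale (leading) eigenfunctions mimics real communities, whose
## spatial structure concentrates at large scales rather than spreading over
## the full fine-scale spectrum.
spanChannels <- function(memScores, k, lead = 6L) {
  M <- as.matrix(memScores)
  if (ncol(M) < k) stop("MEM basis too small for the requested channels")
  M <- M[, seq_len(min(max(k, lead), ncol(M))), drop = FALSE]
  Mn <- qr.Q(qr(M))                       # orthonormal basis of the subspace
  Q <- qr.Q(qr(matrix(stats::rnorm(ncol(Mn) * k), ncol(Mn), k)))
  Z <- Mn %*% Q
  sweep(Z, 2, apply(Z, 2, stats::sd), `/`)
}

## One unit-variance vector exactly orthogonal to span(1, M): a non-spatial
## environmental gradient.
nonSpatialChannel <- function(memScores) {
  M <- as.matrix(memScores)
  v <- qr.resid(qr(cbind(1, M)), stats::rnorm(nrow(M)))
  v / stats::sd(v)
}

#' Simulate a riverscape dataset with known variance structure
#'
#' Generates the four aligned site tables (native community, alien
#' community, environment, transect coordinates) plus mixed-type trait
#' tables, with the latent community structure built from orthogonal
#' variance channels so the designed shares are recoverable:
#' \itemize{
#'   \item coordinates: a 1-D transect (regular or irregular spacing);
#'   \item spatial basis: db-MEM scores of the coordinates;
#'   \item per community, two latent dimensions, each a
#'     \eqn{\sqrt{share}}-weighted sum of a purely non-spatial environmental
#'     channel, a purely spatial channel, and a spatially structured shared
#'     channel (all unit-variance and mutually orthogonal by construction);
#'   \item species: random loadings on the two latents plus matched
#'     Gaussian noise carrying the designed noise share, then passed through
#'     the response model (identity, Poisson log-link counts, or a 0/1
#'     threshold);
#'   \item environment: the shared and environmental channels discretised
#'     into the habitat factor, Impact and Flow ordinals and a quantitative
#'     distance-to-dam;
#'   \item traits: mixed-type columns drawn from species archetypes.
#' }
#' The truth slot stores the parameters, the exact channel score tables per
#' community (the oracle predictors for recovery tests) and the realised
#' latent shares.  Bit-reproducible given the seed.
#'
#' @param params a \linkS4class{SynthParams}.
#' @return A \linkS4class{SynthBundle}.
#' @seealso \code{\link{expectedFractions}}
#' @export
simulateRiverscape <- function(params) {
  stopifnot(methods::is(params, "SynthParams"))
  methods::validObject(params)
  withSeed(params@seed, {
    n <- params@nSites
    ids <- sprintf("s%02d", seq_len(n))
    x <- if (params@transect == "regular") as.numeric(0:(n - 1))
         else sort(stats::runif(n, 0, n - 1)) + seq_len(n) * 1e-6
    coords <- sampleTable(data.frame(row.names = ids, x = x))
    mem <- dbmem(coords)
    M <- as.matrix(mem@scores@data)

    makeCommunity <- function(shares, nSpecies) {
      ## two latent dimensions with identical share structure
      Zs <- spanChannels(M, 4L)          # spatial-only + shared, 2 dims each
      zS <- Zs[, 1:2]; zSh <- Zs[, 3:4]
      zE <- cbind(nonSpatialChannel(cbind(M, Zs)), 0)
      zE[, 2] <- qr.resid(qr(cbind(1, M, zE[, 1])), stats::rnorm(n))
      zE[, 2] <- zE[, 2] / stats::sd(zE[, 2])
      lat <- sqrt(shares[["env"]]) * zE + sqrt(shares[["space"]]) * zS +
        sqrt(shares[["shared"]]) * zSh   # n x 2, each var = 1 - noise
      b <- matrix(stats::runif(2 * nSpecies, 0.5, 1.5) *
                    sample(c(-1, 1), 2 * nSpecies, replace = TRUE),
                  2, nSpecies)
      g <- sqrt(colSums(b^2))
      signal <- lat %*% b
      eps <- matrix(stats::rnorm(n * nSpecies), n, nSpecies)
      latentY <- signal + sweep(eps, 2, g * sqrt(shares[["noise"]]), `*`)
      y <- switch(params@responseModel,
        "gaussian-latent" = latentY,
        "poisson-counts" = {
          eta <- sweep(latentY, 2, g, `/`)      # back to unit scale
          matrix(stats::rpois(n * nSpecies, exp(0.8 * eta)), n, nSpecies)
        },
        "binary-threshold" = (latentY > 0) * 1L)
      sd2 <- function(m) sum(apply(m, 2, stats::var))
      list(y = y,
           channels = list(
             E = cbind(zE, zSh), S = cbind(zS, zSh),
             Epure = zE, Spure = zS, shared = zSh),
           realized = c(
             env = sd2(sqrt(shares[["env"]]) * zE %*% b) / sd2(latentY),
             space = sd2(sqrt(shares[["space"]]) * zS %*% b) / sd2(latentY),
             shared = sd2(sqrt(shares[["shared"]]) * zSh %*% b) / sd2(latentY),
             noise = sd2(sweep(eps, 2, g * sqrt(shares[["noise"]]), `*`)) /
               sd2(latentY)))
    }

    natv <- makeCommunity(params@sharesNative, params@nNative)
    alin <- makeCommunity(params@sharesAlien, params@nAlien)

    spNames <- function(prefix, k) sprintf("%s%02d", prefix, seq_len(k))
    natNames <- spNames("nat", params@nNative)
    alnNames <- spNames("ais", params@nAlien)
    nativeTab <- scoresAsTable(natv$y, ids = ids)
    colnames(nativeTab@data) <- natNames
    nativeTab <- sampleTable(nativeTab@data)
    alienTab <- scoresAsTable(alin$y, ids = ids)
    colnames(alienTab@data) <- alnNames
    alienTab <- sampleTable(alienTab@data)

    ## environment table: spatially shared + independent gradients,
    ## discretised into the field's variable typology
    mix <- function(a, wA = 0.7) {
      v <- wA * a + sqrt(1 - wA^2) * stats::rnorm(n)
      as.numeric(scale(v))
    }
    ordBin <- function(v, levels) {
      br <- stats::quantile(v, probs = seq(0, 1, length.out = length(levels) + 1))
      br[1] <- -Inf; br[length(br)] <- Inf
      levels[cut(v, breaks = unique(br), labels = FALSE)]
    }
    envShared <- natv$channels$shared
    envPure <- natv$channels$Epure
    hmix <- mix(envShared[, 1])
    habBr <- stats::quantile(hmix, c(0, 0.45, 0.8, 1))
    habBr[1] <- -Inf; habBr[4] <- Inf
    ed <- data.frame(row.names = ids,
      Hab = c("R", "L", "C")[cut(hmix, breaks = habBr, labels = FALSE)],
      Impact = ordBin(mix(envPure[, 1]), 0:7),
      Flow = ordBin(mix(envPure[, 2]), 1:5),
      Dis_dam = round(pmax(50, 2500 + 1400 * mix(envShared[, 2]))))
    if (params@nEnvVars > 4L)
      for (j in seq_len(params@nEnvVars - 4L))
        ed[[paste0("Env", j + 4L)]] <- mix(envPure[, 1 + j %% 2])
    envTab <- sampleTable(ed, kinds = c(Hab = "factor", Impact = "ordinal",
                                        Flow = "ordinal",
                                        Dis_dam = "quantitative",
                                        if (params@nEnvVars > 4L)
                                          stats::setNames(rep("quantitative",
                                                              params@nEnvVars - 4L),
                                                          paste0("Env", 5:params@nEnvVars))),
                          levels = list(Hab = c("R", "L", "C"), Impact = 0:7,
                                        Flow = 1:5))

    makeTraits <- function(spp, origin) {
      k <- length(spp)
      arch <- stats::rnorm(k)   # species archetype axis
      ordFrom <- function(levels, w = 0.6) {
        v <- w * arch + sqrt(1 - w^2) * stats::rnorm(k)
        br <- stats::quantile(v, seq(0, 1, length.out = length(levels) + 1))
        br[1] <- -Inf; br[length(br)] <- Inf
        levels[cut(v, breaks = unique(br), labels = FALSE)]
      }
      facFrom <- function(levels) sample(levels, k, replace = TRUE)
      td <- data.frame(row.names = spp,
        SizeM = ordFrom(1:6), Nooff = ordFrom(1:4), Sexmat = ordFrom(1:3),
        Light = ordFrom(1:3),
        Sexes = facFrom(c("S", "H")),
        Ovipos = facFrom(c("OV", "CAP", "BE", "No")),
        FeedT = facFrom(c("SCR", "SS", "SF", "F", "SEDF")),
        Food = facFrom(c("DAP", "CDA", "MAB")),
        Habitat = facFrom(c("Rheo", "Lent", "Phyt", "Ubi")),
        Taxon = facFrom(c("PG", "G", "U", "V")),
        Origin = rep(origin, k))
      td <- td[, seq_len(min(params@nTraits, ncol(td))), drop = FALSE]
      kinds <- c(SizeM = "ordinal", Nooff = "ordinal", Sexmat = "ordinal",
                 Light = "ordinal", Sexes = "factor", Ovipos = "factor",
                 FeedT = "factor", Food = "factor", Habitat = "factor",
                 Taxon = "factor", Origin = "factor")
      sampleTable(td, kinds = kinds[colnames(td)],
                  levels = list(SizeM = 1:6, Nooff = 1:4, Sexmat = 1:3,
                                Light = 1:3, Sexes = c("S", "H"),
                                Ovipos = c("OV", "CAP", "BE", "No"),
                                FeedT = c("SCR", "SS", "SF", "F", "SEDF"),
                                Food = c("DAP", "CDA", "MAB"),
                                Habitat = c("Rheo", "Lent", "Phyt", "Ubi"),
                                Taxon = c("PG", "G", "U", "V"),
                                Origin = c("NAT", "AIS"))[colnames(td)])
    }

    truth <- list(
      params = params,
      native = list(
        channels = lapply(natv$channels, scoresAsTable, ids = ids,
                          prefix = "Ch"),
        realizedShares = natv$realized),
      alien = list(
        channels = lapply(alin$channels, scoresAsTable, ids = ids,
                          prefix = "Ch"),
        realizedShares = alin$realized))

    methods::new("SynthBundle",
                 native = nativeTab, alien = alienTab,
                 environment = envTab, coords = coords,
                 nativeTraits = makeTraits(natNames, "NAT"),
                 alienTraits = makeTraits(alnNames, "AIS"),
                 truth = truth)
  })
}

#' Designed fractions in variation-partitioning layout
#'
#' Relabels the design shares of a community as the fraction keys of a
#' two-predictor \linkS4class{VarpartResult} (environment and space), for
#' direct comparison with a recovered partitioning.
#'
#' @param params a \linkS4class{SynthParams}.
#' @param component \code{"native"} or \code{"alien"}.
#' @return Named numeric \code{c(E, S, ES, residual)}.
#' @examples
#' expectedFractions(synthParams())   # E 0.3, S 0.2, ES 0.1, residual 0.4
#' @export
expectedFractions <- function(params, component = c("native", "alien")) {
  component <- match.arg(component)
  s <- if (component == "native") params@sharesNative else params@sharesAlien
  c(E = unname(s[["env"]]), S = unname(s[["space"]]),
    ES = unname(s[["shared"]]), residual = unname(s[["noise"]]))
}

#' Write a simulated bundle to a directory
#'
#' Writes the four site tables and the trait tables as CSV, the environment
#' and trait schemas as YAML sidecars, and the truth (parameters and
#' realised shares) as JSON.
#'
#' @param bundle a \linkS4class{SynthBundle}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  stopifnot(methods::is(bundle, "SynthBundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeSampleTable(bundle@native, file.path(dir, "native.csv"))
  writeSampleTable(bundle@alien, file.path(dir, "alien.csv"))
  writeSampleTable(bundle@environment, file.path(dir, "env.csv"))
  writeSampleTable(bundle@coords, file.path(dir, "coords.csv"))
  writeSampleTable(bundle@nativeTraits, file.path(dir, "native_traits.csv"))
  writeSampleTable(bundle@alienTraits, file.path(dir, "alien_traits.csv"))
  tableSchema(bundle@environment, file.path(dir, "env_schema.yaml"))
  tableSchema(bundle@nativeTraits, file.path(dir, "traits_schema.yaml"))
  p <- bundle@truth$params
  jsonlite::write_json(list(
    nSites = p@nSites, nNative = p@nNative, nAlien = p@nAlien,
    sharesNative = as.list(p@sharesNative),
    sharesAlien = as.list(p@sharesAlien),
    responseModel = p@responseModel, transect = p@transect, seed = p@seed,
    realizedSharesNative = as.list(bundle@truth$native$realizedShares),
    realizedSharesAlien = as.list(bundle@truth$alien$realizedShares)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
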