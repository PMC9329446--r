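# Shared fixture builders. All randomness is locally seeded so tests are
# order-independent.

mixedTable <- function(n = 6, seed = 1) {
  set.seed(seed)
  sampleTable(
    data.frame(row.names = sprintf("s%d", seq_len(n)),
               depth = round(runif(n, 0, 10), 2),
               impact = sample(0:7, n, replace = TRUE),
               hab = sample(c("R", "L", "C"), n, replace = TRUE),
               pres = sample(0:1, n, replace = TRUE)),
    kinds = c(depth = "quantitative", impact = "ordinal",
              hab = "factor", pres = "binary"),
    levels = list(impact = 0:7, hab = c("R", "L", "C")))
}

randMatrix <- function(n, k, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * k), n, k,
         dimnames = list(sprintf("s%d", seq_len(n)), sprintf("v%d", seq_len(k))))
}

quantTable <- function(m) sampleTable(as.data.frame(m))

regularTransect <- function(n) {
  sampleTable(data.frame(row.names = sprintf("s%02d", seq_len(n)),
                         x = as.numeric(seq_len(n) - 1)))
}

# Independent double-centering + eigendecomposition oracle for PCoA-type
# checks (kept deliberately separate from the package implementation).
bruteForcePcoa <- function(D) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (D^2) %*% J
  eigen((G + t(G)) / 2, symmetric = TRUE)
}

# Random self-consistent VarpartResult over 3 predictors, for assembly fuzzing.
randomVarpart3 <- function(response, predictors, total, seed) {
  set.seed(seed)
  f <- runif(7, -0.05, 0.2)
  resid <- runif(1, 0.2, 0.8)
  f <- f * (1 - resid) / sum(f)
  nm <- c(predictors,
          paste0(predictors[1], predictors[2]),
          paste0(predictors[1], predictors[3]),
          paste0(predictors[2], predictors[3]),
          paste0(predictors, collapse = ""))
  f <- setNames(f, nm)
  f[7] <- 1 - resid - sum(f[-7])
  new("VarpartResult", responseLabel = response,
      predictorLabels = predictors, fractions = f, residual = resid,
      totalVariance = total, scale = "proportion")
}
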