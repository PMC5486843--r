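## Generative twin-pair simulator for every model mechanism.
##
## Liabilities are built from explicit A/C/E factor draws (shared across
## twins as the factor type dictates), so boundary parameter values such as
## c2 = 0 or an MZ pair correlation of 1 are handled exactly; the model
## mechanisms (threshold exceedance, Bernoulli multiformity recoding,
## second-threshold recoding, independent form assignment, three-liability
## OR rule, causal structural transform) are applied to the simulated
## liabilities exactly as the analytic kernels define them.

## standard bivariate normal draws with correlation r (n x 2)
rBiv <- function(n, r) {
  u <- stats::rnorm(n)
  cbind(u, r * u + sqrt(max(1 - r^2, 0)) * stats::rnorm(n))
}

## one trait's liability pair (n x 2) under ACE for a zygosity group
rTraitPair <- function(n, ace, zygosity) {
  k <- zygCoef(zygosity)
  if (k == 1) {
    a <- stats::rnorm(n)
    A <- cbind(a, a)
  } else {
    a0 <- stats::rnorm(n)
    A <- sqrt(0.5) * a0 + sqrt(0.5) * cbind(stats::rnorm(n), stats::rnorm(n))
  }
  C <- stats::rnorm(n)
  sqrt(ace[1]) * A + sqrt(ace[2]) * C + sqrt(ace[3]) * cbind(stats::rnorm(n), stats::rnorm(n))
}

## bivariate-trait factor pair for the correlated-liabilities model:
## returns list(M = n x 2, C = n x 2) liabilities
rCorrelatedPair <- function(n, aceMdd, aceCud, rA, rC, rE, zygosity) {
  k <- zygCoef(zygosity)
  if (k == 1) {
    a <- rBiv(n, rA)
    A1 <- a; A2 <- a
  } else {
    a0 <- rBiv(n, rA)
    A1 <- sqrt(0.5) * a0 + sqrt(0.5) * rBiv(n, rA)
    A2 <- sqrt(0.5) * a0 + sqrt(0.5) * rBiv(n, rA)
  }
  Cc <- rBiv(n, rC)
  E1 <- rBiv(n, rE)
  E2 <- rBiv(n, rE)
  lia <- function(A, E) cbind(sqrt(aceMdd[1]) * A[, 1] + sqrt(aceMdd[2]) * Cc[, 1] +
                                sqrt(aceMdd[3]) * E[, 1],
                              sqrt(aceCud[1]) * A[, 2] + sqrt(aceCud[2]) * Cc[, 2] +
                                sqrt(aceCud[3]) * E[, 2])
  l1 <- lia(A1, E1)
  l2 <- lia(A2, E2)
  list(M = cbind(l1[, 1], l2[, 1]), C = cbind(l1[, 2], l2[, 2]))
}

## multivariate normal draws via eigendecomposition (handles PSD matrices)
rMVN <- function(n, sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(sigma))
  matrix(stats::rnorm(n * nrow(sigma)), n) %*% t(L)
}

simGroup <- function(model, params, n, zygosity) {
  if (n == 0)
    return(matrix(integer(0), 0, 4,
                  dimnames = list(NULL, c("mdd1", "cud1", "mdd2", "cud2"))))
  out <- if (model == "alternate_forms") {
    L <- rTraitPair(n, params$aceShared, zygosity)
    ab <- L > params$tShared
    cud <- matrix(stats::rbinom(2 * n, 1, params$p), n) * ab
    mdd <- matrix(stats::rbinom(2 * n, 1, params$r), n) * ab
    list(mdd = mdd, cud = cud)
  } else if (model == "three_independent") {
    Lm <- rTraitPair(n, params$aceMdd, zygosity) > params$tMdd
    Lc <- rTraitPair(n, params$aceCud, zygosity) > params$tCud
    Ls <- rTraitPair(n, params$aceShared, zygosity) > params$tShared
    list(mdd = (Lm | Ls) * 1L, cud = (Lc | Ls) * 1L)
  } else if (model %in% c("chance", "rm", "rm_mdd", "rm_cud")) {
    am <- rTraitPair(n, params$aceMdd, zygosity) > params$tMdd
    ac <- rTraitPair(n, params$aceCud, zygosity) > params$tCud
    p <- if (model %in% c("rm", "rm_mdd")) params$p else 0
    r <- if (model %in% c("rm", "rm_cud")) params$r else 0
    mdd <- (am | (ac & matrix(stats::rbinom(2 * n, 1, r), n))) * 1L
    cud <- (ac | (am & matrix(stats::rbinom(2 * n, 1, p), n))) * 1L
    list(mdd = mdd, cud = cud)
  } else if (model %in% c("em", "em_mdd", "em_cud")) {
    cuts <- emCuts(model, params)
    Lm <- rTraitPair(n, params$aceMdd, zygosity)
    Lc <- rTraitPair(n, params$aceCud, zygosity)
    bm <- (Lm > cuts$M[1]) + if (length(cuts$M) > 1) (Lm > cuts$M[2]) else 0
    bc <- (Lc > cuts$C[1]) + if (length(cuts$C) > 1) (Lc > cuts$C[2]) else 0
    twoM <- model %in% c("em", "em_mdd")
    twoC <- model %in% c("em", "em_cud")
    mdd <- ((bm >= 1) | (twoC & bc == 2)) * 1L
    cud <- ((bc >= 1) | (twoM & bm == 2)) * 1L
    list(mdd = mdd, cud = cud)
  } else if (model == "correlated_liabilities") {
    L <- rCorrelatedPair(n, params$aceMdd, params$aceCud,
                         params$rA, params$rC, params$rE, zygosity)
    list(mdd = (L$M > params$tMdd) * 1L, cud = (L$C > params$tCud) * 1L)
  } else if (model %in% c("reciprocal_causation", "mdd_causes_cud", "cud_causes_mdd")) {
    iCud <- if (model %in% c("reciprocal_causation", "cud_causes_mdd")) params$iCud else 0
    iMdd <- if (model %in% c("reciprocal_causation", "mdd_causes_cud")) params$iMdd else 0
    A <- solve(diag(2) - matrix(c(0, iCud, iMdd, 0), 2, 2, byrow = TRUE))
    epsM <- rTraitPair(n, params$aceMdd, zygosity)
    epsC <- rTraitPair(n, params$aceCud, zygosity)
    sc <- sqrt(rowSums(A^2))  # total-liability SDs (unit residual variances)
    tot <- function(tw) cbind((A[1, 1] * epsM[, tw] + A[1, 2] * epsC[, tw]) / sc[1],
                              (A[2, 1] * epsM[, tw] + A[2, 2] * epsC[, tw]) / sc[2])
    l1 <- tot(1)
    l2 <- tot(2)
    list(mdd = cbind(l1[, 1] > params$tMdd, l2[, 1] > params$tMdd) * 1L,
         cud = cbind(l1[, 2] > params$tCud, l2[, 2] > params$tCud) * 1L)
  } else if (model == "saturated") {
    blk <- jointBlocks(model, params, zygCoef(zygosity))
    X <- rMVN(n, rbind(cbind(blk$W, blk$B), cbind(blk$B, blk$W)))
    list(mdd = cbind(X[, 1] > params$tMdd, X[, 3] > params$tMdd) * 1L,
         cud = cbind(X[, 2] > params$tCud, X[, 4] > params$tCud) * 1L)
  } else stop("unknown model id: ", model)
  cbind(mdd1 = out$mdd[, 1], cud1 = out$cud[, 1],
        mdd2 = out$mdd[, 2], cud2 = out$cud[, 2])
}

#' Simulate twin pairs from a comorbidity model
#'
#' Draws pair liabilities from the model-implied zygosity-specific
#' structure and applies the model's phenotype mechanism.  Fully
#' reproducible given `seed`.
#'
#' @param model Model id or [NKModelSpec-class].
#' @param params Named parameter list on the natural scale.
#' @param nMz,nDz Number of MZ and DZ pairs.
#' @param seed Integer seed.
#' @return Data frame with one row per pair: `pairId`, `zygosity`, and
#'   binary `mdd1`, `cud1`, `mdd2`, `cud2`.
#' @examples
#' pars <- list(tMdd = 0.6, tCud = 1, aceMdd = c(.5, .1, .4), aceCud = c(.7, 0, .3))
#' d <- simulatePairs("chance", pars, nMz = 100, nDz = 100, seed = 1)
#' recordsToTable(d)
#' @export
simulatePairs <- function(model, params, nMz, nDz, seed) {
  spec <- if (is(model, "NKModelSpec")) model else modelSpec(model)
  validateParams(spec, params)
  stopifnot(nMz >= 0, nDz >= 0)
  withSeed(seed, function() {
    mz <- simGroup(spec@model, params, nMz, "MZ")
    dz <- simGroup(spec@model, params, nDz, "DZ")
    data.frame(pairId = seq_len(nMz + nDz),
               zygosity = rep(c("MZ", "DZ"), c(nMz, nDz)),
               rbind(mz, dz), stringsAsFactors = FALSE)
  })
}

#' Convert wide pair records to the long individual-level layout
#'
#' @param records Data frame from [simulatePairs()].
#' @return Data frame with columns `pair_id`, `zygosity`, `twin`, `mdd`,
#'   `cud` (two rows per pair), the long-format exchange layout.
#' @export
pairsToLong <- function(records) {
  long <- rbind(data.frame(pair_id = records$pairId, zygosity = records$zygosity,
                           twin = 1L, mdd = records$mdd1, cud = records$cud1),
                data.frame(pair_id = records$pairId, zygosity = records$zygosity,
                           twin = 2L, mdd = records$mdd2, cud = records$cud2))
  long[order(long$pair_id, long$twin), ]
}

#' Parameter-recovery experiment
#'
#' Repeated simulate-then-fit cycles under one generating model.  Each
#' replicate draws its seed from the master seed by a fixed counter scheme
#' (`seed + replicate`), simulates `nMz` + `nDz` pairs, refits the
#' generating model, and optionally fits a competitor set to record how
#' often the generating model attains the lowest AIC.
#'
#' @param model Model id or spec (the generating truth).
#' @param params Generating parameter list.
#' @param nMz,nDz Pairs per zygosity group per replicate.
#' @param nReplicates Number of replicates (0 gives an empty report).
#' @param seed Master seed.
#' @param method,control Passed to [fitTwinModel()].
#' @param competitors Optional character vector of model ids to fit
#'   alongside the generating model.
#' @return List with `estimates` (replicates x free parameters), `truth`,
#'   `bias`, `rmse`, `converged`, and (when competitors are given)
#'   `bestModel` per replicate.
#' @export
recoveryExperiment <- function(model, params, nMz, nDz, nReplicates, seed,
                               method = "pearson", control = list(),
                               competitors = NULL) {
  spec <- if (is(model, "NKModelSpec")) model else modelSpec(model)
  truth <- flattenParams(spec, params, freeOnly = TRUE)
  est <- matrix(NA_real_, nReplicates, length(truth),
                dimnames = list(NULL, names(truth)))
  conv <- logical(nReplicates)
  best <- character(nReplicates)
  for (i in seq_len(nReplicates)) {
    d <- simulatePairs(spec, params, nMz, nDz, seed = seed + i)
    tab <- recordsToTable(d)
    f <- fitTwinModel(spec, tab, method = method, control = control)
    est[i, ] <- flattenParams(spec, f@estimates, freeOnly = TRUE)[names(truth)]
    conv[i] <- f@converged
    if (!is.null(competitors)) {
      aics <- c(stats::setNames(f@aic, spec@model),
                vapply(competitors, function(m)
                  fitTwinModel(m, tab, method = method, control = control)@aic,
                  numeric(1)))
      best[i] <- names(aics)[which.min(aics)]
    }
  }
  na <- stats::setNames(rep(NA_real_, length(truth)), names(truth))
  out <- list(estimates = est, truth = truth,
              bias = if (nReplicates > 0) colMeans(est) - truth else na,
              rmse = if (nReplicates > 0)
                sqrt(colMeans((est - matrix(truth, nReplicates,
                                            length(truth), byrow = TRUE))^2))
                else na,
              converged = conv)
  if (!is.null(competitors)) out$bestModel <- best
  out
}
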