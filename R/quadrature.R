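## Deterministic multivariate-normal band probabilities for twin pairs.
##
## Every pair covariance used by the comorbidity models is exchangeable,
##   Sigma = [[W, B], [B, W]],
## with W the within-twin and B the cross-twin block.  B collects the
## contributions of the pair-shared factors (A and C), so the two twins are
## conditionally independent given a shared Gaussian factor S ~ N(0, B):
##   X_twin = S + V_twin,  V_twin ~ N(0, W - B) i.i.d.
## Band probabilities over the joint grid therefore reduce to a 1- or 2-dim
## expectation over S of products of per-twin band probabilities, each of
## which is a bivariate-normal rectangle.  The expectation is evaluated with
## Gauss-Hermite quadrature (Golub-Welsch nodes, deterministic); the node
## count adapts to the sharpness of the conditional probabilities so that
## cells are accurate to ~1e-6 even near boundary parameter values.

## Probabilists' Gauss-Hermite rule: nodes z and weights w with
## sum(w f(z)) ~ E[f(Z)], Z ~ N(0,1).
ghNodes <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1))
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(z = rev(e$values), w = rev(e$vectors[1, ]^2))
}

## Band probabilities for a single liability shared by both twins:
## bivariate normal with correlation r, identical cut points for each twin.
## Returns an (n+1) x (n+1) matrix over (twin1 band, twin2 band), exact
## (bivariate CDF differencing; the |r| = 1 degenerate case is exact too).
pairBandExact <- function(r, cuts) {
  r <- min(max(r, -1), 1)
  u <- c(cuts, Inf)
  n <- length(u)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) G[i, ] <- pbvn(u[i], u, r)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- G[i, j]
    if (i > 1) v <- v - G[i - 1, j]
    if (j > 1) v <- v - G[i, j - 1]
    if (i > 1 && j > 1) v <- v + G[i - 1, j - 1]
    P[i, j] <- v
  }
  P[P < 0] <- 0
  P
}

## Joint band probabilities for a bivariate-liability twin pair.
## W, B: 2x2 within- and cross-twin covariance blocks (unit-diagonal W);
## cutsM, cutsC: cut points for the two liabilities, shared by both twins.
## Returns an nb x nb matrix over per-twin band indices bm*(ncC+1)+bc+1.
pairRectProbs <- function(W, B, cutsM, cutsC, n = NULL) {
  eB <- eigen(B, symmetric = TRUE)
  if (min(eB$values) < -1e-8)
    stop("cross-twin covariance block is not positive semi-definite")
  V <- W - B
  eV <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(eV) < -1e-8)
    stop("within-twin residual covariance is not positive semi-definite")
  if (is.null(n)) {
    ratio <- sqrt(max(eB$values, 0) / max(min(eV), 1e-4))
    n <- if (ratio <= 2) 32 else if (ratio <= 3) 48 else if (ratio <= 4.5) 96 else 160
  }
  sd1 <- sqrt(max(V[1, 1], 1e-16))
  sd2 <- sqrt(max(V[2, 2], 1e-16))
  rho <- min(max(V[1, 2] / (sd1 * sd2), -1), 1)
  sd1 <- max(sd1, 1e-8)
  sd2 <- max(sd2, 1e-8)
  keep <- which(eB$values > 1e-12)
  if (length(keep) == 0) {
    S <- matrix(0, 1, 2)
    wts <- 1
  } else if (length(keep) == 1) {
    gh <- ghNodes(n)
    S <- outer(gh$z * sqrt(eB$values[keep]), eB$vectors[, keep])
    wts <- gh$w
  } else {
    gh <- ghNodes(n)
    g <- expand.grid(i = seq_len(n), j = seq_len(n))
    Z <- cbind(gh$z[g$i] * sqrt(eB$values[1]), gh$z[g$j] * sqrt(eB$values[2]))
    S <- Z %*% t(eB$vectors)
    wts <- gh$w[g$i] * gh$w[g$j]
  }
  u1 <- c(cutsM, Inf)
  u2 <- c(cutsC, Inf)
  n1 <- length(u1)
  n2 <- length(u2)
  ns <- nrow(S)
  G <- array(0, c(ns, n1, n2))
  for (i in seq_len(n1)) for (j in seq_len(n2))
    G[, i, j] <- pbvn((u1[i] - S[, 1]) / sd1, (u2[j] - S[, 2]) / sd2, rho)
  q <- matrix(0, ns, n1 * n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    v <- G[, i, j]
    if (i > 1) v <- v - G[, i - 1, j]
    if (j > 1) v <- v - G[, i, j - 1]
    if (i > 1 && j > 1) v <- v + G[, i - 1, j - 1]
    q[, (i - 1) * n2 + j] <- v
  }
  q[q < 0] <- 0
  t(q * wts) %*% q
}

#' Multivariate-normal band probabilities for a twin-pair covariance
#'
#' Computes the probability of every combination of liability bands for a
#' twin pair, given a pair covariance matrix (as produced by
#' [pairCovariance()]) and cut points for each liability.  Bands per
#' liability are the intervals of the real line delimited by the cut points;
#' both twins share the same cut points, as in all threshold models fitted
#' by this package.
#'
#' The computation is deterministic: exact bivariate-normal CDF differencing
#' for a single liability, and an adaptive Gauss-Hermite quadrature over the
#' pair-shared factors for bivariate liabilities (twins are conditionally
#' independent given the shared A and C factors).
#'
#' @param sigma Pair covariance matrix, 2x2 (one liability per twin) or 4x4
#'   (two liabilities per twin, ordered twin1-MDD, twin1-CUD, twin2-MDD,
#'   twin2-CUD).  Must be exchangeable in the two twins.
#' @param cuts A numeric vector of strictly increasing cut points (2x2 case)
#'   or a list of two such vectors, one per liability (4x4 case).
#' @return An array of band probabilities summing to 1: dimensions
#'   `(b1, b2)` over per-twin bands for a single liability, or
#'   `(bm1, bc1, bm2, bc2)` for two liabilities, where index 1 is the band
#'   below the first cut point.
#' @examples
#' ace <- c(a2 = 0.5, c2 = 0.2, e2 = 0.3)
#' sg <- pairCovariance(list(ace), zygosity = "MZ")
#' p <- mvnBandProbs(sg, cuts = 0.6)
#' sum(p)  # 1
#' @export
mvnBandProbs <- function(sigma, cuts) {
  d <- nrow(sigma)
  if (is.null(d) || !d %in% c(2, 4) || ncol(sigma) != d)
    stop("'sigma' must be a 2x2 or 4x4 covariance matrix")
  if (max(abs(diag(sigma) - 1)) > 1e-6)
    stop("'sigma' must have unit diagonal (standardised liabilities)")
  if (d == 2) {
    if (is.list(cuts)) cuts <- cuts[[1]]
    if (is.unsorted(cuts, strictly = TRUE)) stop("cut points must be strictly increasing")
    return(pairBandExact(sigma[1, 2], cuts))
  }
  h <- d / 2
  W <- sigma[seq_len(h), seq_len(h)]
  B <- sigma[seq_len(h), h + seq_len(h)]
  if (max(abs(sigma[h + seq_len(h), h + seq_len(h)] - W)) > 1e-8 ||
      max(abs(B - t(B))) > 1e-8)
    stop("'sigma' must be exchangeable in the two twins")
  if (!is.list(cuts) || length(cuts) != 2)
    stop("for a 4x4 covariance, 'cuts' must be a list of two cut-point vectors")
  if (any(vapply(cuts, function(v) is.unsorted(v, strictly = TRUE), logical(1))))
    stop("cut points must be strictly increasing")
  P <- pairRectProbs(W, B, cuts[[1]], cuts[[2]])
  n1 <- length(cuts[[1]]) + 1
  n2 <- length(cuts[[2]]) + 1
  out <- array(0, c(n1, n2, n1, n2))
  for (bm1 in seq_len(n1)) for (bc1 in seq_len(n2))
    for (bm2 in seq_len(n1)) for (bc2 in seq_len(n2))
      out[bm1, bc1, bm2, bc2] <- P[(bm1 - 1) * n2 + bc1, (bm2 - 1) * n2 + bc2]
  out
}

## Marginal band probabilities for one person, one liability.
bandProbs1 <- function(cuts) {
  diff(c(0, pnorm(cuts), 1))
}
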