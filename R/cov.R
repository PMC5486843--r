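## Twin-pair liability covariance construction.
##
## Liabilities are standardised (unit variance).  A trait's ACE shares
## (a2, c2, e2) determine the cross-twin same-trait covariance
## k*a2 + c2 with zygosity coefficient k = 1 (MZ) or 0.5 (DZ).  Cross-trait
## structure enters either through factor correlations (rA, rC, rE between
## the two traits' A, C and E factors; the correlated-liabilities model) or
## through a causal matrix B of regression coefficients between the total
## liabilities (direction-of-causation models), solved in closed form via
## (I - B)^-1 and re-standardised to unit diagonal.

zygCoef <- function(zygosity) {
  zygosity <- match.arg(zygosity, c("MZ", "DZ"))
  if (zygosity == "MZ") 1 else 0.5
}

checkAce <- function(ace, what = "ace") {
  if (length(ace) != 3 || any(is.na(ace)))
    stop("'", what, "' must be a numeric (a2, c2, e2) triple")
  if (any(ace < -1e-9) || abs(sum(ace) - 1) > 1e-6)
    stop("'", what, "' shares must be non-negative and sum to 1")
  pmax(as.numeric(ace), 0)
}

## W/B blocks for two traits with factor correlations (may all be 0).
corrBlocks <- function(aceMdd, aceCud, rA, rC, rE, k) {
  covA <- rA * sqrt(aceMdd[1] * aceCud[1])
  covC <- rC * sqrt(aceMdd[2] * aceCud[2])
  covE <- rE * sqrt(aceMdd[3] * aceCud[3])
  w <- covA + covC + covE
  W <- matrix(c(1, w, w, 1), 2)
  bx <- k * covA + covC
  B <- matrix(c(k * aceMdd[1] + aceMdd[2], bx,
                bx, k * aceCud[1] + aceCud[2]), 2)
  list(W = W, B = B)
}

## W/B blocks for the causal models: residual liabilities with independent
## ACE structure per trait, transformed by (I - B)^-1 per person and
## re-standardised.  scale = total-liability standard deviations before
## standardisation (used by the simulator).
causalBlocks <- function(aceMdd, aceCud, iCud, iMdd, k) {
  if (abs(1 - iCud * iMdd) < 1e-8)
    stop("causal coefficients make (I - B) singular")
  A <- solve(diag(2) - matrix(c(0, iCud, iMdd, 0), 2, 2, byrow = TRUE))
  We <- diag(2)
  Be <- diag(c(k * aceMdd[1] + aceMdd[2], k * aceCud[1] + aceCud[2]))
  W <- A %*% We %*% t(A)
  B <- A %*% Be %*% t(A)
  s <- sqrt(diag(W))
  D <- 1 / s
  list(W = W * outer(D, D), B = B * outer(D, D), scale = s, A = A)
}

#' Liability covariance matrix for one twin pair
#'
#' Builds the standardised pair covariance implied by per-trait ACE variance
#' shares plus optional cross-trait structure, for one zygosity group.
#' With one trait the result is 2x2 (twin1, twin2); with two traits it is
#' 4x4 ordered (twin1 MDD, twin1 CUD, twin2 MDD, twin2 CUD).
#'
#' @param ace A list of one or two (a2, c2, e2) share triples (MDD first).
#' @param cross Optional cross-trait structure: either
#'   `list(rA = , rC = , rE = )` factor correlations between the two traits'
#'   A/C/E factors, or `list(iCud = , iMdd = )` causal regression
#'   coefficients between the total liabilities (CUD -> MDD and MDD -> CUD;
#'   either may be 0).  For causal structure the supplied ACE triples are the
#'   residual shares and the result is re-standardised to unit diagonal.
#' @param zygosity "MZ" or "DZ".
#' @return Symmetric positive semi-definite covariance matrix with unit
#'   diagonal.
#' @examples
#' pairCovariance(list(c(1, 0, 0)), zygosity = "MZ")  # cross-twin cov 1
#' pairCovariance(list(c(.5, .1, .4), c(.7, 0, .3)),
#'                cross = list(iCud = 0.4, iMdd = 0), zygosity = "DZ")
#' @export
pairCovariance <- function(ace, cross = NULL, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  k <- zygCoef(zygosity)
  ace <- lapply(seq_along(ace), function(i) checkAce(ace[[i]], paste0("ace[[", i, "]]")))
  if (length(ace) == 1) {
    b <- k * ace[[1]][1] + ace[[1]][2]
    return(matrix(c(1, b, b, 1), 2))
  }
  if (length(ace) != 2) stop("'ace' must contain one or two share triples")
  if (is.null(cross)) cross <- list(rA = 0, rC = 0, rE = 0)
  if (all(c("iCud", "iMdd") %in% names(cross)) ||
      any(c("iCud", "iMdd") %in% names(cross))) {
    iCud <- if (is.null(cross$iCud)) 0 else cross$iCud
    iMdd <- if (is.null(cross$iMdd)) 0 else cross$iMdd
    blk <- causalBlocks(ace[[1]], ace[[2]], iCud, iMdd, k)
  } else {
    rA <- if (is.null(cross$rA)) 0 else cross$rA
    rC <- if (is.null(cross$rC)) 0 else cross$rC
    rE <- if (is.null(cross$rE)) 0 else cross$rE
    if (any(abs(c(rA, rC, rE)) > 1)) stop("factor correlations must lie in [-1, 1]")
    blk <- corrBlocks(ace[[1]], ace[[2]], rA, rC, rE, k)
  }
  sg <- rbind(cbind(blk$W, blk$B), cbind(blk$B, blk$W))
  ev <- eigen(sg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("resulting pair covariance is not positive semi-definite ",
         "(min eigenvalue ", signif(min(ev), 3), ")")
  sg
}
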