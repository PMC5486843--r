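## Descriptive comorbidity epidemiology, all computable from the collapsed
## pair-count table by integer arithmetic, plus ML tetrachoric twin
## correlations.

traitBit <- function(code, trait) {
  if (trait == "mdd") code %/% 2 else code %% 2
}

## per-category person-state codes
catStates <- function() {
  cats <- pairCategories()
  cbind(lo = cats$stateLo, hi = cats$stateHi)
}

#' Lifetime prevalence of a trait in the twin sample
#'
#' Affected individuals across both zygosity groups divided by the number
#' of individuals (twice the number of pairs).
#'
#' @param table A [ComorbidityTable-class].
#' @param trait "mdd" or "cud".
#' @return Proportion affected.
#' @examples
#' prevalence(ausTwinTable(), "cud")  # 0.1544
#' @export
prevalence <- function(table, trait = c("mdd", "cud")) {
  trait <- match.arg(trait)
  cts <- tableCounts(table)
  st <- catStates()
  n <- sum(cts)
  if (n == 0) stop("empty table: prevalence undefined")
  aff <- traitBit(st[, "lo"], trait) + traitBit(st[, "hi"], trait)
  sum(aff * rowSums(cts)) / (2 * n)
}

## individual-level 2x2 cross-tabulation (MDD x CUD)
crossTab <- function(table) {
  cts <- rowSums(tableCounts(table))
  st <- catStates()
  out <- matrix(0, 2, 2, dimnames = list(mdd = c("0", "1"), cud = c("0", "1")))
  for (k in seq_along(cts)) for (col in c("lo", "hi")) {
    s <- st[k, col]
    out[s %/% 2 + 1, s %% 2 + 1] <- out[s %/% 2 + 1, s %% 2 + 1] + cts[k]
  }
  out
}

#' Cross-trait comorbidity rates and crude odds ratio
#'
#' Assembles the individual-level MDD x CUD cross-tabulation from the pair
#' categories and reports the CUD rate conditional on MDD status plus the
#' crude (unadjusted) odds ratio.
#'
#' @param table A [ComorbidityTable-class].
#' @return List with `crossTab` (2x2 counts), `cudGivenMdd`,
#'   `cudGivenNoMdd`, and `crudeOr` (NA with a warning attribute when a
#'   margin is zero).
#' @examples
#' crossTraitRates(ausTwinTable())$cudGivenMdd  # 0.2432
#' @export
crossTraitRates <- function(table) {
  x <- crossTab(table)
  n11 <- x["1", "1"]; n10 <- x["1", "0"]; n01 <- x["0", "1"]; n00 <- x["0", "0"]
  or <- if (n10 == 0 || n01 == 0 || n11 + n10 == 0 || n01 + n00 == 0)
    NA_real_ else (n11 * n00) / (n10 * n01)
  list(crossTab = x,
       cudGivenMdd = if (n11 + n10 > 0) n11 / (n11 + n10) else NA_real_,
       cudGivenNoMdd = if (n01 + n00 > 0) n01 / (n01 + n00) else NA_real_,
       crudeOr = or)
}

#' Discordant-twin matched-pair analysis
#'
#' Selects pairs discordant for the exposure trait within one zygosity
#' group and compares the outcome trait between the exposed twin and the
#' unexposed co-twin.  The matched odds ratio is the ratio of
#' outcome-discordant pair counts (exposed-twin-only over co-twin-only),
#' which equals the conditional-logistic estimate for a single binary
#' within-pair exposure; its confidence interval is the exact binomial
#' interval on the discordant-pair proportion, transformed to the odds
#' scale.
#'
#' @param table A [ComorbidityTable-class].
#' @param zygosity "MZ" (the causally informative group) or "DZ".
#' @param exposure,outcome Distinct traits, "mdd" or "cud".
#' @param level Confidence level.
#' @return List with `nDiscordant`, `rateExposed`, `rateUnexposed`,
#'   `matchedOr` (NA when undefined), `ci`, and the outcome-discordant
#'   counts `bc`.
#' @examples
#' discordantPairs(ausTwinTable(), "MZ", exposure = "cud", outcome = "mdd")
#' @export
discordantPairs <- function(table, zygosity = c("MZ", "DZ"),
                            exposure = c("cud", "mdd"),
                            outcome = c("mdd", "cud"), level = 0.95) {
  zygosity <- match.arg(zygosity)
  exposure <- match.arg(exposure)
  outcome <- match.arg(outcome)
  if (exposure == outcome) stop("exposure and outcome must differ")
  cts <- tableCounts(table)[, zygosity]
  st <- catStates()
  n <- 0; nExpOut <- 0; nUnexpOut <- 0; b <- 0; cc <- 0
  for (k in seq_along(cts)) {
    eLo <- traitBit(st[k, "lo"], exposure)
    eHi <- traitBit(st[k, "hi"], exposure)
    if (eLo == eHi) next
    w <- cts[k]
    n <- n + w
    exposedState <- if (eLo == 1) st[k, "lo"] else st[k, "hi"]
    unexposedState <- if (eLo == 1) st[k, "hi"] else st[k, "lo"]
    oe <- traitBit(exposedState, outcome)
    ou <- traitBit(unexposedState, outcome)
    nExpOut <- nExpOut + w * oe
    nUnexpOut <- nUnexpOut + w * ou
    if (oe == 1 && ou == 0) b <- b + w
    if (oe == 0 && ou == 1) cc <- cc + w
  }
  if (n == 0)
    return(list(nDiscordant = 0L, rateExposed = NA_real_,
                rateUnexposed = NA_real_, matchedOr = NA_real_,
                ci = c(NA_real_, NA_real_), bc = c(b = 0, c = 0)))
  or <- if (cc == 0) NA_real_ else b / cc
  ci <- c(NA_real_, NA_real_)
  if (b + cc > 0) {
    bt <- stats::binom.test(b, b + cc, conf.level = level)
    ci <- bt$conf.int / (1 - bt$conf.int)
  }
  list(nDiscordant = as.integer(unname(n)), rateExposed = unname(nExpOut / n),
       rateUnexposed = unname(nUnexpOut / n), matchedOr = unname(or),
       ci = as.numeric(ci), bc = c(b = unname(b), c = unname(cc)))
}

## ML bivariate-normal threshold fit on one trait's pair margin
tetraPairFit <- function(nBoth, nOne, nNeither) {
  n <- nBoth + nOne + nNeither
  if (n == 0 || nBoth + nOne == 0 || nNeither + nOne == 0)
    return(list(r = NA_real_, threshold = NA_real_, boundary = TRUE))
  obj <- function(x) {
    P <- pairBandExact(tanh(x[2]), x[1])
    pr <- c(P[2, 2], P[1, 2] + P[2, 1], P[1, 1])
    o <- c(nBoth, nOne, nNeither)
    if (any(pr <= 0 & o > 0)) return(1e10)
    -2 * sum(o[o > 0] * log(pr[o > 0]))
  }
  prev <- (2 * nBoth + nOne) / (2 * n)
  ft <- stats::nlminb(c(stats::qnorm(1 - prev), atanh(0.5)), obj,
                      control = list(iter.max = 300, rel.tol = 1e-10))
  r <- tanh(ft$par[2])
  list(r = r, threshold = ft$par[1], boundary = abs(r) > 1 - 1e-4)
}

#' Tetrachoric twin correlations per trait and zygosity
#'
#' Maximum-likelihood bivariate-normal threshold fits on each trait's
#' unordered pair margin (both affected / one affected / neither),
#' with the threshold equated across twins.
#'
#' @param table A [ComorbidityTable-class].
#' @return Data frame with columns `trait`, `zygosity`, `r`, `threshold`,
#'   `boundary` (TRUE when the correlation hit the boundary or the margin
#'   was degenerate).
#' @examples
#' tetrachoricTwinCorrelations(ausTwinTable())
#' @export
tetrachoricTwinCorrelations <- function(table) {
  cts <- tableCounts(table)
  st <- catStates()
  out <- NULL
  for (trait in c("mdd", "cud")) for (z in c("MZ", "DZ")) {
    aff <- traitBit(st[, "lo"], trait) + traitBit(st[, "hi"], trait)
    nBoth <- sum(cts[aff == 2, z])
    nOne <- sum(cts[aff == 1, z])
    nNeither <- sum(cts[aff == 0, z])
    f <- tetraPairFit(nBoth, nOne, nNeither)
    out <- rbind(out, data.frame(trait = trait, zygosity = z, r = f$r,
                                 threshold = f$threshold, boundary = f$boundary,
                                 stringsAsFactors = FALSE))
  }
  out
}

## tetrachoric correlation of one 2x2 table (used for saturated starts)
tetrachoric2x2 <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  p1 <- (n11 + n10) / n
  p2 <- (n11 + n01) / n
  t1 <- stats::qnorm(1 - p1)
  t2 <- stats::qnorm(1 - p2)
  obj <- function(x) {
    r <- tanh(x)
    p <- c(bvnu(t1, t2, r),
           pnorm(-t1) - bvnu(t1, t2, r),
           pnorm(-t2) - bvnu(t1, t2, r))
    p <- c(p, 1 - sum(p))
    o <- c(n11, n10, n01, n00)
    if (any(p <= 0 & o > 0)) return(1e10)
    -2 * sum(o[o > 0] * log(p[o > 0]))
  }
  tanh(stats::optimize(obj, c(-5, 5))$minimum)
}
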