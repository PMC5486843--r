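## Shared fixtures and independent oracles used across test files.

studyTab <- ausTwinTable()

## independent bivariate-normal "both below" probability for exchangeable
## correlation r >= 0 via the shared-factor integral
orthBothBelow <- function(t, r) {
  stopifnot(r >= 0)
  if (r == 0) return(pnorm(t)^2)
  f <- function(s) dnorm(s) * pnorm((t - sqrt(r) * s) / sqrt(1 - r))^2
  integrate(f, -9, 9, rel.tol = 1e-10)$value
}

## independent pair band 2x2 oracle for one trait (equal thresholds)
pairBandOracle <- function(r, t) {
  bb <- orthBothBelow(t, r)
  m <- pnorm(t)
  matrix(c(bb, m - bb, m - bb, 1 - 2 * m + bb), 2)
}

## random valid parameter list for a model spec (natural scale)
randomParams <- function(spec) {
  unpackParams(spec, rnorm(spec@nFree))
}

## moderate, study-flavoured generating truths per model
truthFor <- function(model) {
  base <- list(tMdd = 0.66, tCud = 0.99,
               aceMdd = c(a2 = 0.46, c2 = 0.05, e2 = 0.49),
               aceCud = c(a2 = 0.74, c2 = 0.05, e2 = 0.21))
  switch(model,
    chance = base,
    rm = c(base, list(p = 0.10, r = 0.20)),
    rm_mdd = c(base, list(p = 0.10)),
    rm_cud = c(base, list(r = 0.22)),
    em = c(base, list(gapMdd2 = 1.3, gapCud2 = 1.0)),
    em_mdd = c(base, list(gapMdd2 = 1.3)),
    em_cud = c(base, list(gapCud2 = 0.8)),
    correlated_liabilities = c(base, list(rA = 0.45, rC = 0.2, rE = 0.15)),
    reciprocal_causation = c(base, list(iCud = 0.2, iMdd = 0.1)),
    mdd_causes_cud = c(base, list(iMdd = 0.25)),
    cud_causes_mdd = c(base, list(iCud = 0.28)),
    alternate_forms = list(tShared = -0.31,
                           aceShared = c(a2 = 0.67, c2 = 0.33, e2 = 0),
                           p = 0.27, r = 0.44),
    three_independent = list(tMdd = 0.75, tCud = 1.05, tShared = 1.6,
                             aceMdd = c(a2 = 0.45, c2 = 0.05, e2 = 0.5),
                             aceCud = c(a2 = 0.7, c2 = 0.05, e2 = 0.25),
                             aceShared = c(a2 = 0.6, c2 = 0.1, e2 = 0.3)),
    saturated = list(tMdd = 0.66, tCud = 0.99, rMzMdd = 0.5, rMzCud = 0.75,
                     rDzMdd = 0.25, rDzCud = 0.4, rWithin = 0.3),
    stop("no truth for ", model))
}

fastCtl <- list(restarts = 8, polish = 3)
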