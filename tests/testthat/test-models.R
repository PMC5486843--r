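test_that("model registry reproduces the degrees-of-freedom accounting", {
  reg <- nkModels()
  expect_equal(nrow(reg), 14)
  expect_equal(reg$df, 18L - reg$nFree)
  want <- c(alternate_forms = 14L, three_independent = 9L, rm = 10L,
            rm_mdd = 11L, rm_cud = 11L, em = 10L, em_mdd = 11L, em_cud = 11L,
            correlated_liabilities = 9L, reciprocal_causation = 10L,
            mdd_causes_cud = 11L, cud_causes_mdd = 11L, chance = 12L,
            saturated = 11L)
  expect_equal(setNames(reg$df, reg$model), want)
})

test_that("chance model factorises exactly into per-trait normals", {
  pars <- truthFor("chance")
  p4 <- personStateProbs("chance", pars)
  expect_equal(unname(p4["MDD1CUD1"]),
               pnorm(-pars$tMdd) * pnorm(-pars$tCud), tolerance = 1e-12)
  expect_equal(sum(p4), 1, tolerance = 1e-12)

  ## pair probabilities factorise into MDD-pattern x CUD-pattern before collapse
  for (z in c("MZ", "DZ")) {
    k <- if (z == "MZ") 1 else 0.5
    Pm <- pairBandOracle(k * pars$aceMdd[1] + pars$aceMdd[2], pars$tMdd)
    Pc <- pairBandOracle(k * pars$aceCud[1] + pars$aceCud[2], pars$tCud)
    want <- setNames(numeric(10), pairCategories()$label)
    for (m1 in 0:1) for (c1 in 0:1) for (m2 in 0:1) for (c2 in 0:1) {
      s1 <- 2 * m1 + c1
      s2 <- 2 * m2 + c2
      lab <- pairCategories()$label[pairCategories()$stateLo == min(s1, s2) &
                                      pairCategories()$stateHi == max(s1, s2)]
      want[lab] <- want[lab] + Pm[m1 + 1, m2 + 1] * Pc[c1 + 1, c2 + 1]
    }
    expect_equal(cellProbs("chance", pars, z), want, tolerance = 1e-7)
  }
})

test_that("twin independence: with e2 = 1 pair probabilities are products", {
  pars <- list(tMdd = 0.6, tCud = 1, aceMdd = c(0, 0, 1), aceCud = c(0, 0, 1))
  for (model in c("chance", "rm", "cud_causes_mdd")) {
    p <- c(pars, switch(model, rm = list(p = .1, r = .2),
                        cud_causes_mdd = list(iCud = .3), NULL))
    p4 <- personStateProbs(model, p)
    want <- setNames(numeric(10), pairCategories()$label)
    for (s1 in 0:3) for (s2 in 0:3) {
      lab <- pairCategories()$label[pairCategories()$stateLo == min(s1, s2) &
                                      pairCategories()$stateHi == max(s1, s2)]
      want[lab] <- want[lab] + p4[s1 + 1] * p4[s2 + 1]
    }
    for (z in c("MZ", "DZ"))
      expect_equal(cellProbs(model, p, z), want, tolerance = 1e-8)
  }
})

test_that("alternate forms matches an exhaustive enumeration oracle", {
  pars <- truthFor("alternate_forms")
  for (z in c("MZ", "DZ")) {
    k <- if (z == "MZ") 1 else 0.5
    rr <- k * pars$aceShared[1] + pars$aceShared[2]
    P2 <- if (rr >= 1 - 1e-12) {
      m <- pnorm(pars$tShared)
      matrix(c(m, 0, 0, 1 - m), 2)  # degenerate: twins share one liability value
    } else pairBandOracle(rr, pars$tShared)
    ## enumerate band x independent form assignment per twin
    formDist <- function(above) {
      if (!above) return(c(1, 0, 0, 0))
      p <- pars$p; r <- pars$r
      c((1 - p) * (1 - r), p * (1 - r), r * (1 - p), p * r)
    }
    want <- setNames(numeric(10), pairCategories()$label)
    for (b1 in 0:1) for (b2 in 0:1) for (s1 in 0:3) for (s2 in 0:3) {
      lab <- pairCategories()$label[pairCategories()$stateLo == min(s1, s2) &
                                      pairCategories()$stateHi == max(s1, s2)]
      want[lab] <- want[lab] + P2[b1 + 1, b2 + 1] *
        formDist(b1 == 1)[s1 + 1] * formDist(b2 == 1)[s2 + 1]
    }
    expect_equal(cellProbs("alternate_forms", pars, z), want, tolerance = 1e-7)
  }
})

test_that("cell probabilities are a proper distribution for every model", {
  set.seed(51)
  for (model in nkModels()$model) {
    spec <- modelSpec(model)
    for (rep in 1:5) {
      pars <- randomParams(spec)
      if (model == "saturated") {
        ## not every correlation pattern is a valid covariance; sample until
        ## one is (the fitter penalises invalid patterns the same way)
        ok <- function(p) !inherits(tryCatch({
          cellProbs(spec, p, "MZ")
          cellProbs(spec, p, "DZ")
        }, error = function(e) e), "error")
        while (!ok(pars)) pars <- randomParams(spec)
      }
      for (z in c("MZ", "DZ")) {
        p <- cellProbs(spec, pars, z)
        expect_equal(sum(p), 1, tolerance = 1e-6)
        expect_true(all(p >= -1e-12))
      }
      p4 <- personStateProbs(spec, pars)
      expect_equal(sum(p4), 1, tolerance = 1e-6)
    }
  }
})

test_that("nesting reductions hold numerically", {
  base <- truthFor("chance")
  maxAbs <- function(a, b) max(abs(a - b))
  for (z in c("MZ", "DZ")) {
    chance <- cellProbs("chance", base, z)
    expect_lt(maxAbs(cellProbs("rm", c(base, list(p = 0, r = 0)), z), chance), 1e-6)
    expect_lt(maxAbs(cellProbs("rm_cud", c(base, list(r = 0)), z), chance), 1e-6)
    expect_lt(maxAbs(cellProbs("em_cud", c(base, list(gapCud2 = 30)), z), chance), 1e-6)
    expect_lt(maxAbs(cellProbs("cud_causes_mdd", c(base, list(iCud = 0)), z), chance), 1e-6)
    expect_lt(maxAbs(cellProbs("correlated_liabilities",
                               c(base, list(rA = 0, rC = 0, rE = 0)), z), chance), 1e-6)
    expect_lt(maxAbs(cellProbs("reciprocal_causation",
                               c(base, list(iCud = 0.28, iMdd = 0)), z),
                     cellProbs("cud_causes_mdd", c(base, list(iCud = 0.28)), z)), 1e-6)
  }
})

test_that("comorbidity probability is monotone in the mechanism strength", {
  base <- truthFor("chance")
  comorbid <- function(model, extra) {
    personStateProbs(model, c(base, extra))["MDD1CUD1"]
  }
  rs <- seq(0, 0.9, by = 0.1)
  expect_true(all(diff(vapply(rs, function(r)
    comorbid("rm_cud", list(r = r)), numeric(1))) > 0))
  expect_true(all(diff(vapply(rs, function(i)
    comorbid("cud_causes_mdd", list(iCud = i)), numeric(1))) > 0))
  expect_true(all(diff(vapply(rs, function(a)
    comorbid("correlated_liabilities", list(rA = a, rC = 0, rE = 0)),
    numeric(1))) > 0))
})

test_that("pack/unpack is a bijection onto valid parameters", {
  expect_length(packParams(modelSpec("chance"), truthFor("chance")), 6)
  expect_length(packParams(modelSpec("rm"), truthFor("rm")), 8)
  set.seed(61)
  for (model in nkModels()$model) {
    spec <- modelSpec(model)
    expect_equal(length(freeParamNames(spec)), spec@nFree)
    for (rep in 1:10) {
      x <- rnorm(spec@nFree, sd = 1.5)
      pars <- unpackParams(spec, x)
      expect_silent(twincomorbid:::validateParams(spec, pars))
      ## pack uses non-negative square roots: round-trip through params
      x2 <- packParams(spec, pars)
      expect_equal(unpackParams(spec, x2), pars, tolerance = 1e-8)
    }
  }
})

test_that("parameters foreign to a model are rejected", {
  pars <- c(truthFor("chance"), list(p = 0.2))
  expect_error(personStateProbs("chance", pars), "not part of model")
  expect_error(cellProbs("chance", truthFor("chance")[-1], "MZ"), "missing")
})

test_that("the alternate-forms variant frees the shared E share", {
  sDefault <- modelSpec("alternate_forms")
  sFree <- modelSpec("alternate_forms", variant = "free")
  expect_equal(sDefault@df, 14L)
  expect_equal(sFree@df, 13L)
})
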