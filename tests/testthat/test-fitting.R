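test_that("deviance and Pearson statistics match independent arithmetic", {
  spec <- modelSpec("chance")
  pars <- truthFor("chance")
  cts <- tableCounts(studyTab)
  dev <- 0
  pea <- 0
  for (z in c("MZ", "DZ")) {
    pr <- cellProbs(spec, pars, z)
    o <- cts[, z]
    dev <- dev - 2 * sum(o * log(pr))
    e <- sum(o) * pr
    pea <- pea + sum((o - e)^2 / e)
  }
  expect_equal(neg2LogLik(spec, pars, studyTab), dev)
  expect_equal(pearsonStat(spec, pars, studyTab), pea)

  ## saturated plug-in is the minimal achievable deviance
  sat <- twincomorbid:::satDeviance(studyTab)
  expect_lt(sat, dev)
  set.seed(71)
  for (rep in 1:5)
    expect_gte(neg2LogLik(spec, randomParams(spec), studyTab), sat)

  ## closed form: uniform category probabilities on the MZ group alone
  o <- cts[, "MZ"]
  expect_equal(-2 * sum(o * log(0.1)), 2 * 565 * log(10))
})

test_that("ML chi2 equals deviance minus the saturated deviance", {
  f <- fitTwinModel("chance", studyTab, method = "ml", control = fastCtl)
  expect_equal(f@chi2, f@deviance - twincomorbid:::satDeviance(studyTab),
               tolerance = 1e-9)
  expect_equal(f@aic, f@chi2 - 2 * f@df)
  expect_equal(unname(colSums(f@expected)), c(565, 640), tolerance = 1e-6)
})

test_that("fitting is deterministic under fixed seeds", {
  f1 <- fitTwinModel("rm_cud", studyTab, control = fastCtl)
  f2 <- fitTwinModel("rm_cud", studyTab, control = fastCtl)
  expect_identical(f1@chi2, f2@chi2)
  expect_identical(f1@estimates, f2@estimates)
  expect_identical(f1@restarts, f2@restarts)
})

test_that("nested models dominate on the study table", {
  ctl <- fastCtl
  chi <- function(m) fitTwinModel(m, studyTab, control = ctl)@chi2
  tol <- 1e-4
  expect_lte(chi("rm"), chi("rm_cud") + tol)
  expect_lte(chi("rm_cud"), chi("chance") + tol)
  expect_lte(chi("reciprocal_causation"), chi("cud_causes_mdd") + tol)
  expect_lte(chi("cud_causes_mdd"), chi("chance") + tol)
})

test_that("chance-model fits recover generating thresholds from large samples", {
  truth <- truthFor("chance")
  d <- simulatePairs("chance", truth, nMz = 1e5, nDz = 1e5, seed = 81)
  f <- fitTwinModel("chance", recordsToTable(d), control = fastCtl)
  expect_lt(abs(f@estimates$tMdd - truth$tMdd), 0.02)
  expect_lt(abs(f@estimates$tCud - truth$tCud), 0.02)
  ## goodness of fit consistent with the null chi-square
  expect_gt(f@pValue, 0.001)
})

test_that("dropping C is free at the boundary and detected when real", {
  f <- fitTwinModel("rm_cud", studyTab, control = fastCtl)
  dc <- dropComponentTest(f, studyTab, control = fastCtl)
  expect_equal(dc$deltaDf, 2L)
  expect_lt(dc$deltaChi2, 0.05)  # both c2 estimates sit at 0 already
  expect_gt(dc$p, 0.05)

  ## simulated strong shared environment: the test must reject
  truth <- truthFor("chance")
  truth$aceMdd <- c(a2 = 0.3, c2 = 0.35, e2 = 0.35)
  truth$aceCud <- c(a2 = 0.4, c2 = 0.3, e2 = 0.3)
  d <- simulatePairs("chance", truth, nMz = 5e4, nDz = 5e4, seed = 82)
  f2 <- fitTwinModel("chance", recordsToTable(d), control = fastCtl)
  dc2 <- dropComponentTest(f2, recordsToTable(d), control = fastCtl)
  expect_lt(dc2$p, 1e-6)

  expect_error(dropComponentTest(
    fitTwinModel(modelSpec("chance", fix = list(c2Mdd = 0, c2Cud = 0)),
                 studyTab, control = fastCtl), studyTab), "already fixed")
})

test_that("profile intervals respect bounds and bracket the estimate", {
  f <- fitTwinModel("rm_cud", studyTab, control = fastCtl)
  ci <- profileCI(f, studyTab, "r")
  expect_lt(ci$lower, f@estimates$r)
  expect_gt(ci$upper, f@estimates$r)
  expect_false(ci$lowerAtBound)

  ## c2 estimated at the 0 boundary: lower limit exactly 0
  ci0 <- profileCI(f, studyTab, "c2Cud")
  expect_identical(ci0$lower, 0)
  expect_true(ci0$lowerAtBound)

  ## an interior threshold has an approximately symmetric interval
  fc <- fitTwinModel("chance", studyTab, control = fastCtl)
  cit <- profileCI(fc, studyTab, "tMdd")
  lo <- fc@estimates$tMdd - cit$lower
  hi <- cit$upper - fc@estimates$tMdd
  expect_lt(abs(lo - hi) / ((lo + hi) / 2), 0.25)
})

test_that("profile intervals cover the truth at roughly the nominal rate", {
  truth <- truthFor("chance")
  hit <- 0
  nrep <- 12
  for (i in seq_len(nrep)) {
    d <- simulatePairs("chance", truth, nMz = 1500, nDz = 1500, seed = 400 + i)
    tab <- recordsToTable(d)
    f <- fitTwinModel("chance", tab, control = list(restarts = 4, polish = 2))
    ci <- profileCI(f, tab, "tMdd", control = list(restarts = 1, polish = 1))
    if (!is.na(ci$lower) && !is.na(ci$upper) &&
        ci$lower <= truth$tMdd && truth$tMdd <= ci$upper) hit <- hit + 1
  }
  expect_gte(hit / nrep, 0.75)  # 95% nominal; binomial noise at n = 12
})

test_that("fitAllModels sorts, flags and preserves single-model requests", {
  cmp <- fitAllModels(studyTab, models = c("chance", "rm_cud"), control = fastCtl)
  tb <- comparisonTable(cmp)
  expect_equal(nrow(tb), 2)
  expect_equal(tb$model[1], "rm_cud")
  expect_true(all(diff(tb$aic) >= 0))
  expect_true(tb$rejected[tb$model == "chance"])

  one <- fitAllModels(studyTab, models = "rm_cud", control = fastCtl)
  expect_equal(nrow(comparisonTable(one)), 1)
  expect_equal(comparisonTable(one)$model, "rm_cud")
})
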