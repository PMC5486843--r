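## Model fitting on the 10 x 2 multinomial.
##
## Two fit statistics are supported.  "pearson" minimises the Pearson
## statistic sum((O - E)^2 / E) over both zygosity groups (minimum
## chi-square estimation; this is the convention that reproduces the
## published fit statistics for this study).  "ml" maximises the multinomial
## likelihood and reports the likelihood-ratio statistic
## 2 sum(O log(O / E)) against the saturated multinomial.  Either statistic
## is referred to a chi-square distribution with df = 18 - nFree, and
## AIC = chi2 - 2 df (Mx convention).

satDeviance <- function(table) {
  cts <- tableCounts(table)
  tot <- pairTotals(table)
  s <- 0
  for (z in c("MZ", "DZ")) {
    o <- cts[, z]
    s <- s - 2 * sum(o[o > 0] * log(o[o > 0] / tot[z]))
  }
  s
}

#' Multinomial deviance of a comorbidity model
#'
#' Minus twice the multinomial log-likelihood of a parameter list for a
#' [ComorbidityTable-class], summed over zygosity groups.  Returns `Inf`
#' when any category with observed counts has zero model probability.
#'
#' @param spec An [NKModelSpec-class] or model id.
#' @param params Named parameter list.
#' @param table A [ComorbidityTable-class].
#' @return The deviance value (scalar).
#' @export
neg2LogLik <- function(spec, params, table) {
  if (is.character(spec)) spec <- modelSpec(spec)
  cts <- tableCounts(table)
  d <- 0
  for (z in c("MZ", "DZ")) {
    pr <- cellProbs(spec, params, z)
    o <- cts[, z]
    if (any(pr <= 0 & o > 0)) return(Inf)
    d <- d - 2 * sum(o[o > 0] * log(pr[o > 0]))
  }
  d
}

#' Pearson goodness-of-fit statistic of a comorbidity model
#'
#' `sum((O - E)^2 / E)` over the 10 categories and both zygosity groups,
#' with expected counts `E = N_z * pi_z(params)`.  `Inf` when any expected
#' count is zero for a category with observations.
#'
#' @inheritParams neg2LogLik
#' @return The Pearson statistic (scalar).
#' @export
pearsonStat <- function(spec, params, table) {
  if (is.character(spec)) spec <- modelSpec(spec)
  cts <- tableCounts(table)
  tot <- pairTotals(table)
  s <- 0
  for (z in c("MZ", "DZ")) {
    e <- tot[z] * cellProbs(spec, params, z)
    o <- cts[, z]
    if (any(e <= 0 & o > 0)) return(Inf)
    use <- e > 0
    s <- s + sum((o[use] - e[use])^2 / e[use])
  }
  unname(s)
}

expectedCounts <- function(spec, params, table) {
  tot <- pairTotals(table)
  cbind(MZ = tot["MZ"] * cellProbs(spec, params, "MZ"),
        DZ = tot["DZ"] * cellProbs(spec, params, "DZ"))
}

## data-driven starting values
smartStart <- function(spec, table) {
  cts <- tableCounts(table)
  pm <- prevalence(table, "mdd")
  pc <- prevalence(table, "cud")
  tm <- stats::qnorm(1 - pm)
  tc <- stats::qnorm(1 - pc)
  ace <- c(a2 = 0.5, c2 = 0.1, e2 = 0.4)
  p <- list()
  for (b in spec@blocks) {
    p[[b$name]] <- switch(b$name,
      tMdd = tm, tCud = tc,
      tShared = if (spec@model == "alternate_forms")
                  stats::qnorm(1 - min(pm + pc, 0.9)) else max(tm, tc) + 0.4,
      aceMdd = ace, aceCud = c(a2 = 0.6, c2 = 0.1, e2 = 0.3),
      aceShared = if (!is.null(b$fixed)) {
        fx <- b$fixed
        free <- setdiff(simplexComps, names(fx))
        v <- stats::setNames(numeric(3), simplexComps)
        v[names(fx)] <- fx
        rem <- 1 - sum(fx)
        v[free] <- rem * c(0.7, 0.3, 0.3)[seq_along(free)] /
          sum(c(0.7, 0.3, 0.3)[seq_along(free)])
        v
      } else ace,
      p = 0.15, r = 0.15,
      gapMdd2 = 1, gapCud2 = 1,
      rA = 0.4, rC = 0.1, rE = 0.1,
      iCud = 0.2, iMdd = 0.1,
      rMzMdd = 0.5, rMzCud = 0.7, rDzMdd = 0.25, rDzCud = 0.35,
      rWithin = 0.3)
    if (!is.null(b$fixed) && b$type != "simplex") p[[b$name]] <- b$fixed
  }
  p
}

fitControl <- function(control = list()) {
  def <- list(restarts = 20, polish = 6, seed = 1, startSd = 0.6,
              iterMax = 500, relTol = 1e-10)
  def[names(control)] <- control
  def
}

#' Fit one comorbidity model to a ComorbidityTable
#'
#' Minimises the chosen fit statistic over the model's transformed
#' parameter space by deterministic multistart local optimisation: a
#' data-driven start plus seeded random perturbations are screened by
#' objective value and the best subset is polished with [stats::nlminb()].
#' Identical inputs give bit-identical results.
#'
#' @param model Model id (see [nkModels()]) or an [NKModelSpec-class].
#' @param table A [ComorbidityTable-class].
#' @param method `"pearson"` (minimum chi-square, default: the convention
#'   reproducing the published fits) or `"ml"` (maximum likelihood with the
#'   likelihood-ratio statistic).
#' @param fix Named list of parameters to fix (ignored when `model` is
#'   already a spec).
#' @param control List overriding any of: `restarts` (default 20 start
#'   points), `polish` (starts given full local optimisation, default 6),
#'   `seed` (RNG seed for start perturbations, default 1), `startSd`
#'   (perturbation scale), `iterMax`, `relTol`.
#' @param start Optional parameter list used as the primary start value in
#'   place of the data-driven start (e.g. estimates from a previous fit,
#'   for warm-started refits).
#' @return A [TwinModelFit-class].
#' @examples
#' fit <- fitTwinModel("chance", ausTwinTable(),
#'                     control = list(restarts = 4, polish = 2))
#' fit@chi2
#' @export
fitTwinModel <- function(model, table, method = c("pearson", "ml"),
                         fix = list(), control = list(), start = NULL) {
  method <- match.arg(method)
  spec <- if (is(model, "NKModelSpec")) model else modelSpec(model, fix = fix)
  ctl <- fitControl(control)
  stopifnot(is(table, "ComorbidityTable"))
  stat <- if (method == "pearson") pearsonStat else neg2LogLik
  obj <- function(x) {
    v <- tryCatch(stat(spec, unpackParams(spec, x), table),
                  error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  x0 <- packParams(spec, if (is.null(start)) smartStart(spec, table) else start)
  nf <- spec@nFree
  starts <- list(x0)
  if (ctl$restarts > 1 && nf > 0) {
    rng <- withSeed(ctl$seed, function()
      matrix(stats::rnorm((ctl$restarts - 1) * nf, sd = ctl$startSd),
             ncol = nf))
    for (i in seq_len(ctl$restarts - 1)) starts[[i + 1]] <- x0 + rng[i, ]
  }
  if (nf == 0) {
    par <- numeric(0)
    best <- list(par = par, objective = obj(par), convergence = 0L)
    log <- data.frame(start = 1L, objective = best$objective, polished = TRUE,
                      convergence = 0L)
  } else {
    vals <- vapply(starts, obj, numeric(1))
    ord <- order(vals)
    keep <- unique(c(ord[seq_len(min(ctl$polish, length(ord)))], 1L))
    best <- NULL
    log <- data.frame(start = seq_along(starts), objective = vals,
                      polished = FALSE, convergence = NA_integer_)
    for (i in keep) {
      r <- tryCatch(stats::nlminb(starts[[i]], obj,
                                  control = list(iter.max = ctl$iterMax,
                                                 rel.tol = ctl$relTol)),
                    error = function(e) NULL)
      if (is.null(r)) next
      log$objective[i] <- r$objective
      log$polished[i] <- TRUE
      log$convergence[i] <- r$convergence
      if (is.null(best) || r$objective < best$objective) best <- r
    }
    if (is.null(best))
      best <- list(par = x0, objective = obj(x0), convergence = 1L)
  }
  est <- unpackParams(spec, best$par)
  dev <- neg2LogLik(spec, est, table)
  chi2 <- if (method == "pearson") best$objective else dev - satDeviance(table)
  chi2 <- max(chi2, 0)
  p <- stats::pchisq(chi2, spec@df, lower.tail = FALSE)
  new("TwinModelFit", spec = spec, method = method, estimates = est,
      chi2 = chi2, df = spec@df, pValue = p, aic = chi2 - 2 * spec@df,
      deviance = dev, expected = expectedCounts(spec, est, table),
      converged = is.finite(best$objective) && best$objective < 1e9 &&
        identical(best$convergence, 0L),
      restarts = log)
}

## run code with a temporary RNG state
withSeed <- function(seed, fun) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  fun()
}

#' Fit and compare several comorbidity models
#'
#' Fits each requested model with [fitTwinModel()] and assembles a
#' comparison table sorted by AIC, flagging models rejected by the
#' goodness-of-fit test (p < 0.05) and models within 3 AIC units of the
#' best (substantial-support convention).
#'
#' @param table A [ComorbidityTable-class].
#' @param models Character vector of model ids (default: all 13 comorbidity
#'   models plus the saturated comparison model).
#' @param method,control Passed to [fitTwinModel()].
#' @return A [ModelComparison-class].
#' @export
fitAllModels <- function(table, models = nkModels()$model,
                         method = c("pearson", "ml"), control = list()) {
  method <- match.arg(method)
  fits <- list()
  for (m in models) fits[[m]] <- fitTwinModel(m, table, method = method,
                                              control = control)
  tb <- data.frame(model = names(fits),
                   label = vapply(fits, function(f) f@spec@label, character(1)),
                   chi2 = vapply(fits, function(f) f@chi2, numeric(1)),
                   df = vapply(fits, function(f) f@df, integer(1)),
                   p = vapply(fits, function(f) f@pValue, numeric(1)),
                   aic = vapply(fits, function(f) f@aic, numeric(1)),
                   converged = vapply(fits, function(f) f@converged, logical(1)),
                   stringsAsFactors = FALSE)
  tb <- tb[order(tb$aic), ]
  tb$deltaAic <- tb$aic - tb$aic[1]
  tb$rejected <- tb$p < 0.05
  tb$supported <- tb$deltaAic < 3
  rownames(tb) <- NULL
  new("ModelComparison", fits = fits, table = tb)
}

#' @rdname fitAllModels
#' @param comparison A [ModelComparison-class].
#' @return For `comparisonTable`, the comparison data frame.
#' @export
comparisonTable <- function(comparison) comparison@table

#' Likelihood-ratio test for dropping the shared environment
#'
#' Refits a model with the shared-environment share fixed at zero for both
#' trait liabilities and reports the nested difference test against the
#' original fit.
#'
#' @param fit A converged [TwinModelFit-class] whose model has free
#'   per-trait ACE components.
#' @param table The [ComorbidityTable-class] the fit used.
#' @param component Variance component to drop (only "C" is supported).
#' @param control Passed to [fitTwinModel()].
#' @return List with the restricted fit (`fit0`), `deltaChi2`, `deltaDf`
#'   and `p`.
#' @export
dropComponentTest <- function(fit, table, component = "C", control = list()) {
  component <- match.arg(component, "C")
  spec <- fit@spec
  targets <- intersect(c("aceMdd", "aceCud"),
                       vapply(spec@blocks, `[[`, character(1), "name"))
  if (length(targets) == 0)
    stop("model '", spec@model, "' has no per-trait ACE components")
  fixNames <- paste0("c2", sub("^ace", "", targets))
  already <- vapply(spec@blocks, function(b)
    b$type == "simplex" && "c2" %in% names(b$fixed), logical(1))
  if (any(already))
    stop("shared environment is already fixed in this specification")
  fix <- c(spec@fix, stats::setNames(as.list(rep(0, length(fixNames))), fixNames))
  fit0 <- fitTwinModel(modelSpec(spec@model, fix = fix), table,
                       method = fit@method, control = control)
  dChi2 <- max(fit0@chi2 - fit@chi2, 0)
  dDf <- fit0@df - fit@df
  list(fit0 = fit0, deltaChi2 = dChi2, deltaDf = dDf,
       p = stats::pchisq(dChi2, dDf, lower.tail = FALSE))
}

## natural-scale bounds for profiling, by block type
profileBounds <- function(block, fix = NULL) {
  switch(block$type,
    prob = c(0, 1),
    corr = c(-1, 1),
    gap = c(1e-6, 10),
    real = c(-Inf, Inf),
    simplex = c(0, 1 - sum(block$fixed)))
}

#' Profile-likelihood confidence interval for one parameter
#'
#' Inverts the fit-statistic difference test at the chi-square(1) critical
#' value: the interval contains the values v of the chosen parameter for
#' which refitting with the parameter fixed at v raises the fit statistic
#' by less than `qchisq(level, 1)`.  Intervals respect natural parameter
#' bounds and may touch them (e.g. a variance share estimated at 0).
#'
#' @param fit A converged [TwinModelFit-class].
#' @param table The [ComorbidityTable-class] the fit used.
#' @param param Name of a free scalar quantity: a scalar block (`"r"`,
#'   `"iCud"`, `"tMdd"`, ...) or a simplex component (`"a2Cud"`, `"c2Mdd"`, ...).
#' @param level Confidence level (default 0.95).
#' @param control Passed to the profiling refits (kept small by default).
#' @return List with `estimate`, `lower`, `upper`, `level`, and logical
#'   flags `lowerAtBound`, `upperAtBound`.
#' @export
profileCI <- function(fit, table, param, level = 0.95,
                      control = list(restarts = 2, polish = 1)) {
  spec <- fit@spec
  est <- flattenParams(spec, fit@estimates)
  if (!param %in% names(est)) stop("unknown parameter '", param, "'")
  vhat <- est[[param]]
  ## locate the block to get bounds
  m <- regmatches(param, regexec("^(a2|c2|e2)(Mdd|Cud|Shared)$", param))[[1]]
  blockName <- if (length(m)) paste0("ace", m[3]) else param
  block <- NULL
  for (b in spec@blocks) if (b$name == blockName) block <- b
  if (is.null(block)) stop("unknown parameter '", param, "'")
  bounds <- profileBounds(block)
  crit <- fit@chi2 + stats::qchisq(level, 1)
  prof <- function(v) {
    f <- tryCatch(fitTwinModel(modelSpec(spec@model,
                                         fix = c(spec@fix, stats::setNames(list(v), param))),
                               table, method = fit@method, control = control,
                               start = fit@estimates),
                  error = function(e) NULL)
    if (is.null(f)) 1e10 else f@chi2
  }
  searchLimit <- function(dir) {
    bound <- if (dir < 0) bounds[1] else bounds[2]
    if (is.infinite(bound)) bound <- vhat + dir * 2
    g <- function(v) prof(v) - crit
    gb <- g(bound)
    if (gb <= 0) return(list(limit = bound, atBound = TRUE))
    lo <- min(vhat, bound)
    hi <- max(vhat, bound)
    root <- tryCatch(stats::uniroot(g, lower = lo, upper = hi,
                                    tol = max(1e-4, 2e-3 * (hi - lo)),
                                    maxiter = 30)$root,
                     error = function(e) NA_real_)
    list(limit = root, atBound = FALSE)
  }
  lower <- searchLimit(-1)
  upper <- searchLimit(1)
  list(estimate = vhat, lower = lower$limit, upper = upper$limit,
       level = level, lowerAtBound = lower$atBound, upperAtBound = upper$atBound)
}
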