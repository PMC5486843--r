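## The comorbidity model family.
##
## Every model maps a parameter list to the 10-category probability vector
## per zygosity group by (i) building per-liability or joint pair band
## probabilities from the liability-threshold structure, (ii) mapping
## liability bands to phenotypes through the model's mechanism (threshold
## exceedance, probabilistic multiformity recoding, second-threshold
## recoding, form assignment, or the three-liability OR rule), and (iii)
## collapsing ordered pair states to the ten unordered categories.

nkModelIds <- c("alternate_forms", "three_independent", "rm", "rm_mdd",
                "rm_cud", "em", "em_mdd", "em_cud", "correlated_liabilities",
                "reciprocal_causation", "mdd_causes_cud", "cud_causes_mdd",
                "chance")

modelLabels <- c(
  alternate_forms = "Alternate forms",
  three_independent = "Three independent disorders",
  rm = "Random multiformity",
  rm_mdd = "RM of MDD",
  rm_cud = "RM of CUD",
  em = "Extreme multiformity",
  em_mdd = "EM of MDD",
  em_cud = "EM of CUD",
  correlated_liabilities = "Correlated liabilities",
  reciprocal_causation = "Reciprocal causation",
  mdd_causes_cud = "MDD causes CUD",
  cud_causes_mdd = "CUD causes MDD",
  chance = "Chance",
  saturated = "Saturated (twin correlations)")

#' The comorbidity model registry
#'
#' @return A data frame with one row per model: `model` id, `label`,
#'   model `class`, default free-parameter count `nFree` and goodness-of-fit
#'   degrees of freedom `df` (18 independent multinomial cells minus free
#'   parameters).
#' @examples
#' nkModels()
#' @export
nkModels <- function() {
  ids <- c(nkModelIds, "saturated")
  cls <- c(alternate_forms = "single liability",
           three_independent = "independent liability",
           rm = "multiformity", rm_mdd = "multiformity", rm_cud = "multiformity",
           em = "multiformity", em_mdd = "multiformity", em_cud = "multiformity",
           correlated_liabilities = "correlated liabilities",
           reciprocal_causation = "direction of causation",
           mdd_causes_cud = "direction of causation",
           cud_causes_mdd = "direction of causation",
           chance = "chance", saturated = "saturated")
  nf <- vapply(ids, function(m) modelSpec(m)@nFree, integer(1))
  data.frame(model = ids, label = unname(modelLabels[ids]), class = unname(cls[ids]),
             nFree = unname(nf), df = 18L - unname(nf), stringsAsFactors = FALSE)
}

## ---- parameter blocks ------------------------------------------------------

scalarBlock <- function(name, type) list(name = name, type = type, fixed = NULL)
simplexBlock <- function(name, fixed = NULL) list(name = name, type = "simplex",
                                                  fixed = fixed)

baseBivariate <- function() list(scalarBlock("tMdd", "real"),
                                 scalarBlock("tCud", "real"),
                                 simplexBlock("aceMdd"),
                                 simplexBlock("aceCud"))

modelBlockDefs <- function(model, variant = "default") {
  b <- baseBivariate()
  switch(model,
    chance = b,
    rm = c(b, list(scalarBlock("p", "prob"), scalarBlock("r", "prob"))),
    rm_mdd = c(b, list(scalarBlock("p", "prob"))),
    rm_cud = c(b, list(scalarBlock("r", "prob"))),
    em = c(b, list(scalarBlock("gapMdd2", "gap"), scalarBlock("gapCud2", "gap"))),
    em_mdd = c(b, list(scalarBlock("gapMdd2", "gap"))),
    em_cud = c(b, list(scalarBlock("gapCud2", "gap"))),
    correlated_liabilities = c(b, list(scalarBlock("rA", "corr"),
                                       scalarBlock("rC", "corr"),
                                       scalarBlock("rE", "corr"))),
    reciprocal_causation = c(b, list(scalarBlock("iCud", "corr"),
                                     scalarBlock("iMdd", "corr"))),
    mdd_causes_cud = c(b, list(scalarBlock("iMdd", "corr"))),
    cud_causes_mdd = c(b, list(scalarBlock("iCud", "corr"))),
    alternate_forms = list(
      scalarBlock("tShared", "real"),
      simplexBlock("aceShared",
                   fixed = if (variant == "default") c(e2 = 0) else NULL),
      scalarBlock("p", "prob"), scalarBlock("r", "prob")),
    three_independent = list(
      scalarBlock("tMdd", "real"), scalarBlock("tCud", "real"),
      scalarBlock("tShared", "real"),
      simplexBlock("aceMdd"), simplexBlock("aceCud"), simplexBlock("aceShared")),
    saturated = list(
      scalarBlock("tMdd", "real"), scalarBlock("tCud", "real"),
      scalarBlock("rMzMdd", "corr"), scalarBlock("rMzCud", "corr"),
      scalarBlock("rDzMdd", "corr"), scalarBlock("rDzCud", "corr"),
      scalarBlock("rWithin", "corr")),
    stop("unknown model id: ", model))
}

simplexComps <- c("a2", "c2", "e2")

## translate fix-list names (e.g. c2Mdd = 0, r = 0) onto the blocks
applyFixes <- function(blocks, fix) {
  for (nm in names(fix)) {
    val <- fix[[nm]]
    hit <- FALSE
    m <- regmatches(nm, regexec("^(a2|c2|e2)(Mdd|Cud|Shared)$", nm))[[1]]
    if (length(m)) {
      target <- paste0("ace", m[3])
      for (i in seq_along(blocks)) {
        if (blocks[[i]]$name == target) {
          fx <- blocks[[i]]$fixed
          fx <- fx[setdiff(names(fx), m[2])]
          blocks[[i]]$fixed <- c(fx, stats::setNames(val, m[2]))
          hit <- TRUE
        }
      }
    } else {
      for (i in seq_along(blocks)) {
        if (blocks[[i]]$name == nm && blocks[[i]]$type != "simplex") {
          blocks[[i]]$fixed <- val
          hit <- TRUE
        }
      }
    }
    if (!hit) stop("cannot fix '", nm, "': no such free parameter in this model")
  }
  blocks
}

blockFreeCount <- function(block) {
  if (block$type == "simplex") max(0L, 2L - length(block$fixed))
  else if (is.null(block$fixed)) 1L else 0L
}

#' Specify a comorbidity model
#'
#' @param model Model id (one of `nkModels()$model`).
#' @param fix Named list of parameters to fix, e.g. `list(r = 0)` or
#'   `list(c2Mdd = 0, c2Cud = 0)`.  Simplex components are addressed as
#'   `a2Mdd`, `c2Cud`, `e2Shared`, etc.
#' @param variant For `alternate_forms` only: `"default"` fixes the shared
#'   liability's non-shared environment share at 0 (4 free parameters,
#'   df 14, the parameterisation matching the published fit); `"free"`
#'   estimates the full ACE triple (5 free parameters, df 13).
#' @return An [NKModelSpec-class].
#' @examples
#' modelSpec("rm_cud")
#' modelSpec("cud_causes_mdd", fix = list(c2Mdd = 0, c2Cud = 0))
#' @export
modelSpec <- function(model, fix = list(), variant = c("default", "free")) {
  variant <- match.arg(variant)
  model <- match.arg(model, c(nkModelIds, "saturated"))
  blocks <- applyFixes(modelBlockDefs(model, variant), fix)
  nFree <- sum(vapply(blocks, blockFreeCount, integer(1)))
  new("NKModelSpec", model = model, label = unname(modelLabels[model]),
      blocks = blocks, fix = fix, nFree = as.integer(nFree),
      df = as.integer(18L - nFree))
}

## ---- pack / unpack ---------------------------------------------------------

#' Names of the free parameters of a model specification
#'
#' @param spec An [NKModelSpec-class].
#' @return Character vector naming each entry of the free parameter vector
#'   used by the optimiser, in pack order.
#' @export
freeParamNames <- function(spec) {
  out <- character(0)
  for (b in spec@blocks) {
    if (b$type == "simplex") {
      free <- setdiff(simplexComps, names(b$fixed))
      nfree <- blockFreeCount(b)
      suffix <- sub("^ace", "", b$name)
      if (nfree == 2) out <- c(out, paste0(free[1:2], suffix))
      else if (nfree == 1) out <- c(out, paste0(free[1], suffix))
    } else if (is.null(b$fixed)) {
      out <- c(out, b$name)
    }
  }
  out
}

## simplex helpers -------------------------------------------------------
unpackSimplex <- function(block, x) {
  fx <- block$fixed
  free <- setdiff(simplexComps, names(fx))
  out <- stats::setNames(numeric(3), simplexComps)
  out[names(fx)] <- fx
  nfree <- blockFreeCount(block)
  if (nfree == 2) {
    s <- 1 + x[1]^2 + x[2]^2
    out[free[1]] <- x[1]^2 / s
    out[free[2]] <- x[2]^2 / s
    out[free[3]] <- 1 / s
  } else if (nfree == 1) {
    rem <- 1 - sum(fx)
    f <- x[1]^2 / (1 + x[1]^2)
    out[free[1]] <- rem * f
    out[free[2]] <- rem * (1 - f)
  } else if (length(fx) == 2) {
    out[free] <- 1 - sum(fx)
  }
  if (min(out) < -1e-9) stop("simplex shares outside [0, 1]")
  pmax(out, 0)
}

packSimplex <- function(block, value) {
  fx <- block$fixed
  free <- setdiff(simplexComps, names(fx))
  nfree <- blockFreeCount(block)
  eps <- 1e-10
  if (nfree == 2) {
    e <- max(value[free[3]], eps)
    c(sqrt(max(value[free[1]], 0) / e), sqrt(max(value[free[2]], 0) / e))
  } else if (nfree == 1) {
    second <- max(value[free[2]], eps)
    sqrt(max(value[free[1]], 0) / second)
  } else {
    numeric(0)
  }
}

#' Map the optimiser's unconstrained vector to model parameters
#'
#' The transforms are total: any real vector maps to a valid parameter
#' list (variance shares on the simplex via squared-path ratios,
#' probabilities via the logistic, correlations and causal coefficients via
#' tanh, threshold gaps via exp).
#'
#' @param spec An [NKModelSpec-class].
#' @param x Numeric vector of length `spec@nFree`.
#' @return Named parameter list on the natural scale.
#' @export
unpackParams <- function(spec, x) {
  if (length(x) != spec@nFree)
    stop("parameter vector must have length ", spec@nFree)
  out <- list()
  i <- 0
  for (b in spec@blocks) {
    nf <- blockFreeCount(b)
    xs <- if (nf > 0) x[i + seq_len(nf)] else numeric(0)
    i <- i + nf
    out[[b$name]] <- switch(b$type,
      real = if (is.null(b$fixed)) xs else b$fixed,
      prob = if (is.null(b$fixed)) stats::plogis(xs) else b$fixed,
      corr = if (is.null(b$fixed)) tanh(xs) else b$fixed,
      gap = if (is.null(b$fixed)) exp(xs) else b$fixed,
      simplex = unpackSimplex(b, xs))
  }
  out
}

#' @rdname unpackParams
#' @param params Named parameter list (natural scale) valid for `spec`.
#' @return For `packParams`, the unconstrained free parameter vector.
#' @export
packParams <- function(spec, params) {
  out <- numeric(0)
  clamp <- function(v, lo, hi) min(max(v, lo), hi)
  for (b in spec@blocks) {
    if (blockFreeCount(b) == 0) next
    v <- params[[b$name]]
    if (is.null(v)) stop("missing parameter '", b$name, "'")
    out <- c(out, switch(b$type,
      real = v,
      prob = stats::qlogis(clamp(v, 1e-10, 1 - 1e-10)),
      corr = atanh(clamp(v, -1 + 1e-10, 1 - 1e-10)),
      gap = log(max(v, 1e-10)),
      simplex = packSimplex(b, v)))
  }
  unname(out)
}

## natural-scale summary of the parameters of a spec
flattenParams <- function(spec, params, freeOnly = FALSE) {
  out <- numeric(0)
  for (b in spec@blocks) {
    if (freeOnly && blockFreeCount(b) == 0) next
    v <- params[[b$name]]
    if (b$type == "simplex") {
      suffix <- sub("^ace", "", b$name)
      comps <- stats::setNames(v, paste0(simplexComps, suffix))
      if (freeOnly) {
        free <- setdiff(simplexComps, names(b$fixed))
        keep <- free[seq_len(blockFreeCount(b))]
        comps <- comps[paste0(keep, suffix)]
      }
      out <- c(out, comps)
    } else {
      out <- c(out, stats::setNames(v, b$name))
    }
  }
  out
}

## ---- parameter validation --------------------------------------------------

validateParams <- function(spec, params) {
  expected <- vapply(spec@blocks, `[[`, character(1), "name")
  extra <- setdiff(names(params), expected)
  if (length(extra))
    stop("parameter(s) not part of model '", spec@model, "': ",
         paste(extra, collapse = ", "))
  missing <- setdiff(expected, names(params))
  if (length(missing))
    stop("missing parameter(s) for model '", spec@model, "': ",
         paste(missing, collapse = ", "))
  for (b in spec@blocks) {
    v <- params[[b$name]]
    switch(b$type,
      simplex = checkAce(v, b$name),
      prob = if (v < 0 || v > 1) stop("'", b$name, "' must lie in [0, 1]"),
      corr = if (abs(v) > 1) stop("'", b$name, "' must lie in [-1, 1]"),
      gap = if (v <= 0) stop("'", b$name, "' must be positive (second threshold above the first)"),
      real = invisible(NULL))
    if (!is.null(b$fixed) && b$type != "simplex" && abs(v - b$fixed) > 1e-9)
      stop("'", b$name, "' is fixed at ", b$fixed, " in this specification")
  }
  invisible(TRUE)
}

## ---- mechanism: per-person band-to-state conditional matrices --------------

## rows index person liability bands, columns the 4 phenotype states
condMatrix <- function(model, params, nBandsM = 2, nBandsC = 2) {
  if (model %in% c("chance", "rm", "rm_mdd", "rm_cud")) {
    p <- if (model %in% c("rm", "rm_mdd")) params$p else 0
    r <- if (model %in% c("rm", "rm_cud")) params$r else 0
    C <- matrix(0, 4, 4)
    C[1, 1] <- 1                      # below both
    C[2, 2] <- 1 - r; C[2, 4] <- r    # above CUD only: MDD w.p. r
    C[3, 3] <- 1 - p; C[3, 4] <- p    # above MDD only: CUD w.p. p
    C[4, 4] <- 1                      # above both
    C
  } else if (model %in% c("em", "em_mdd", "em_cud")) {
    twoM <- model %in% c("em", "em_mdd")
    twoC <- model %in% c("em", "em_cud")
    C <- matrix(0, nBandsM * nBandsC, 4)
    for (bm in 0:(nBandsM - 1)) for (bc in 0:(nBandsC - 1)) {
      mdd <- (bm >= 1) || (twoC && bc == 2)
      cud <- (bc >= 1) || (twoM && bm == 2)
      C[bm * nBandsC + bc + 1, 2 * mdd + cud + 1] <- 1
    }
    C
  } else if (model == "alternate_forms") {
    p <- params$p
    r <- params$r
    C <- matrix(0, 2, 4)
    C[1, 1] <- 1
    C[2, ] <- c((1 - p) * (1 - r), p * (1 - r), r * (1 - p), p * r)
    C
  } else if (model == "three_independent") {
    C <- matrix(0, 8, 4)
    for (bm in 0:1) for (bc in 0:1) for (bs in 0:1)
      C[bm * 4 + bc * 2 + bs + 1, 2 * (bm | bs) + (bc | bs) + 1] <- 1
    C
  } else {
    diag(4)  # joint-liability models: band (m, c) is the state 2m + c
  }
}

emCuts <- function(model, params) {
  list(M = if (model %in% c("em", "em_mdd"))
             c(params$tMdd, params$tMdd + params$gapMdd2) else params$tMdd,
       C = if (model %in% c("em", "em_cud"))
             c(params$tCud, params$tCud + params$gapCud2) else params$tCud)
}

## W/B blocks for the joint-liability models
jointBlocks <- function(model, params, k) {
  if (model == "correlated_liabilities") {
    corrBlocks(params$aceMdd, params$aceCud, params$rA, params$rC, params$rE, k)
  } else if (model %in% c("reciprocal_causation", "mdd_causes_cud", "cud_causes_mdd")) {
    iCud <- if (model %in% c("reciprocal_causation", "cud_causes_mdd")) params$iCud else 0
    iMdd <- if (model %in% c("reciprocal_causation", "mdd_causes_cud")) params$iMdd else 0
    causalBlocks(params$aceMdd, params$aceCud, iCud, iMdd, k)
  } else {  # saturated
    rzm <- if (k == 1) params$rMzMdd else params$rDzMdd
    rzc <- if (k == 1) params$rMzCud else params$rDzCud
    w <- params$rWithin
    cr <- w * sign(rzm * rzc) * sqrt(abs(rzm * rzc))
    W <- matrix(c(1, w, w, 1), 2)
    B <- matrix(c(rzm, cr, cr, rzc), 2)
    if (min(eigen(B, symmetric = TRUE, only.values = TRUE)$values) < -1e-10 ||
        min(eigen(W - B, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop("saturated correlation pattern is not positive semi-definite")
    list(W = W, B = B)
  }
}

jointModels <- c("correlated_liabilities", "reciprocal_causation",
                 "mdd_causes_cud", "cud_causes_mdd", "saturated")

## ---- the model kernels -----------------------------------------------------

#' Twin-pair category probabilities under a comorbidity model
#'
#' Maps a model's parameters to the probability of each of the ten unordered
#' pair phenotype categories for one zygosity group.
#'
#' @param spec An [NKModelSpec-class] or model id string.
#' @param params Named parameter list on the natural scale (see
#'   [unpackParams()]).
#' @param zygosity "MZ" or "DZ".
#' @return Named probability 10-vector summing to 1.
#' @examples
#' sp <- modelSpec("chance")
#' pars <- list(tMdd = 0.6, tCud = 1, aceMdd = c(.5, .1, .4), aceCud = c(.7, 0, .3))
#' sum(cellProbs(sp, pars, "MZ"))
#' @export
cellProbs <- function(spec, params, zygosity = c("MZ", "DZ")) {
  if (is.character(spec)) spec <- modelSpec(spec)
  zygosity <- match.arg(zygosity)
  validateParams(spec, params)
  k <- zygCoef(zygosity)
  model <- spec@model
  if (model %in% jointModels) {
    blk <- jointBlocks(model, params, k)
    P <- pairRectProbs(blk$W, blk$B, params$tMdd, params$tCud)
  } else if (model == "alternate_forms") {
    ace <- params$aceShared
    Ps <- pairBandExact(k * ace[1] + ace[2], params$tShared)
    C <- condMatrix(model, params)
    P <- t(C) %*% Ps %*% C
  } else if (model == "three_independent") {
    bnd <- function(ace, t) pairBandExact(k * ace[1] + ace[2], t)
    Pm <- bnd(params$aceMdd, params$tMdd)
    Pc <- bnd(params$aceCud, params$tCud)
    Ps <- bnd(params$aceShared, params$tShared)
    C <- condMatrix(model, params)
    P <- t(C) %*% (Pm %x% Pc %x% Ps) %*% C
  } else {
    cuts <- emCuts(model, params)
    Pm <- pairBandExact(k * params$aceMdd[1] + params$aceMdd[2], cuts$M)
    Pc <- pairBandExact(k * params$aceCud[1] + params$aceCud[2], cuts$C)
    C <- condMatrix(model, params, length(cuts$M) + 1, length(cuts$C) + 1)
    P <- t(C) %*% (Pm %x% Pc) %*% C
  }
  stats::setNames(collapseOrdered(P), pairCategories()$label)
}

#' Marginal person phenotype-state probabilities under a comorbidity model
#'
#' The single-person joint phenotype distribution implied by a model,
#' i.e. the marginal of [cellProbs()] over one twin (identical for both
#' twins and both zygosity groups).
#'
#' @inheritParams cellProbs
#' @return Named probability 4-vector over the person states, in
#'   [personStates()] order.
#' @examples
#' pars <- list(tMdd = 0.6, tCud = 1, aceMdd = c(.5, .1, .4), aceCud = c(.7, 0, .3))
#' personStateProbs("chance", pars)
#' @export
personStateProbs <- function(spec, params) {
  if (is.character(spec)) spec <- modelSpec(spec)
  validateParams(spec, params)
  model <- spec@model
  if (model %in% jointModels) {
    blk <- jointBlocks(model, params, k = 1)
    q <- bandProbs2(blk$W[1, 2], params$tMdd, params$tCud)
    p4 <- as.vector(t(q))  # band (m, c) with c fastest = state code order
  } else if (model == "alternate_forms") {
    ace <- params$aceShared
    b <- bandProbs1(params$tShared)
    p4 <- as.vector(b %*% condMatrix(model, params))
  } else if (model == "three_independent") {
    bm <- bandProbs1(params$tMdd)
    bc <- bandProbs1(params$tCud)
    bs <- bandProbs1(params$tShared)
    p4 <- as.vector((bm %x% bc %x% bs) %*% condMatrix(model, params))
  } else {
    cuts <- emCuts(model, params)
    bm <- bandProbs1(cuts$M)
    bc <- bandProbs1(cuts$C)
    C <- condMatrix(model, params, length(cuts$M) + 1, length(cuts$C) + 1)
    p4 <- as.vector((bm %x% bc) %*% C)
  }
  stats::setNames(p4, personStates()$label)
}

## bivariate band matrix with different cuts per dimension (one person)
bandProbs2 <- function(r, cuts1, cuts2) {
  u1 <- c(cuts1, Inf)
  u2 <- c(cuts2, Inf)
  n1 <- length(u1)
  n2 <- length(u2)
  G <- matrix(0, n1, n2)
  for (i in seq_len(n1)) G[i, ] <- pbvn(u1[i], u2, min(max(r, -1), 1))
  P <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    v <- G[i, j]
    if (i > 1) v <- v - G[i - 1, j]
    if (j > 1) v <- v - G[i, j - 1]
    if (i > 1 && j > 1) v <- v + G[i - 1, j - 1]
    P[i, j] <- v
  }
  P[P < 0] <- 0
  P
}
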