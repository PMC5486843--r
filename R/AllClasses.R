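#' @import methods
NULL

#' ComorbidityTable: twin-pair phenotype counts
#'
#' Counts of twin pairs over the ten unordered pair phenotype categories
#' (see [pairCategories()]), split by zygosity (MZ, DZ).  This is the
#' universal input of every comorbidity model fit and of the descriptive
#' epidemiology functions.
#'
#' @slot counts 10 x 2 integer matrix; rows follow the canonical category
#'   order, columns are MZ and DZ.
#' @export
setClass("ComorbidityTable", representation(counts = "matrix"))

setValidity("ComorbidityTable", function(object) {
  cts <- object@counts
  cats <- pairCategories()
  if (!is.numeric(cts) || !identical(dim(cts), c(10L, 2L)))
    return("counts must be a 10 x 2 matrix")
  if (!identical(colnames(cts), c("MZ", "DZ")))
    return("counts columns must be MZ, DZ")
  if (!identical(rownames(cts), cats$label))
    return("counts rows must follow the canonical category order")
  if (any(is.na(cts)) || any(cts < 0) || any(cts != round(cts)))
    return("counts must be non-negative integers")
  TRUE
})

#' Construct a ComorbidityTable
#'
#' @param mz,dz Non-negative integer count vectors of length 10 in the
#'   canonical category order ([pairCategories()]), optionally named by the
#'   category labels (names are checked when present).
#' @return A [ComorbidityTable-class] object.
#' @examples
#' tab <- ComorbidityTable(mz = c(5, rep(1, 9)), dz = rep(2, 10))
#' pairTotals(tab)
#' @export
ComorbidityTable <- function(mz, dz) {
  cats <- pairCategories()
  fix <- function(v, what) {
    if (length(v) != 10) stop("'", what, "' must have 10 counts")
    if (!is.null(names(v))) {
      if (!setequal(names(v), cats$label))
        stop("'", what, "' names do not match the canonical category labels")
      v <- v[cats$label]
    }
    v
  }
  cts <- cbind(MZ = fix(mz, "mz"), DZ = fix(dz, "dz"))
  rownames(cts) <- cats$label
  storage.mode(cts) <- "integer"
  new("ComorbidityTable", counts = cts)
}

#' Counts of a ComorbidityTable
#'
#' @param x A [ComorbidityTable-class].
#' @return `tableCounts`: the 10 x 2 integer count matrix.
#' @export
tableCounts <- function(x) {
  stopifnot(is(x, "ComorbidityTable"))
  x@counts
}

#' @rdname tableCounts
#' @return `pairTotals`: named vector of pair totals per zygosity group.
#' @export
pairTotals <- function(x) colSums(tableCounts(x))

setMethod("show", "ComorbidityTable", function(object) {
  tot <- pairTotals(object)
  cat("ComorbidityTable:", tot["MZ"], "MZ and", tot["DZ"], "DZ twin pairs\n")
  print(object@counts)
})

#' NKModelSpec: identity and parameterisation of one comorbidity model
#'
#' Created by [modelSpec()]; holds the model id, the ordered free-parameter
#' blocks (with any fixed components), the free-parameter count and the
#' goodness-of-fit degrees of freedom (18 independent multinomial cells
#' minus free parameters).
#'
#' @slot model Model id (see [nkModels()]).
#' @slot label Human-readable model name.
#' @slot blocks Ordered list of parameter blocks.
#' @slot fix Named list of fixed parameter values.
#' @slot nFree Number of free parameters.
#' @slot df Goodness-of-fit degrees of freedom.
#' @export
setClass("NKModelSpec", representation(model = "character", label = "character",
                                       blocks = "list", fix = "list",
                                       nFree = "integer", df = "integer"))

setMethod("show", "NKModelSpec", function(object) {
  cat("NKModelSpec:", object@model, "(", object@label, ")\n")
  cat("  free parameters:", object@nFree, " df:", object@df, "\n")
  if (length(object@fix))
    cat("  fixed:", paste(names(object@fix), unlist(object@fix), sep = " = ",
                          collapse = ", "), "\n")
})

#' TwinModelFit: result of fitting one comorbidity model
#'
#' @slot spec The fitted [NKModelSpec-class].
#' @slot method Fit statistic minimised: "pearson" or "ml".
#' @slot estimates Named list of parameter estimates on the natural scale.
#' @slot chi2 Goodness-of-fit statistic versus the saturated multinomial.
#' @slot df Degrees of freedom.
#' @slot pValue Upper-tail chi-square probability.
#' @slot aic chi2 - 2 df (Mx convention).
#' @slot deviance -2 log-likelihood at the estimates.
#' @slot expected 10 x 2 matrix of expected counts.
#' @slot converged Convergence flag (best restart).
#' @slot restarts Data frame logging every restart's final objective.
#' @export
setClass("TwinModelFit", representation(spec = "NKModelSpec", method = "character",
                                        estimates = "list", chi2 = "numeric",
                                        df = "integer", pValue = "numeric",
                                        aic = "numeric", deviance = "numeric",
                                        expected = "matrix", converged = "logical",
                                        restarts = "data.frame"))

setMethod("show", "TwinModelFit", function(object) {
  cat("TwinModelFit:", object@spec@model, "(", object@spec@label, ")\n")
  cat(sprintf("  chi2 = %.3f  df = %d  p = %.3g  AIC = %.3f  [%s]\n",
              object@chi2, object@df, object@pValue, object@aic, object@method))
  if (!object@converged) cat("  WARNING: best restart did not converge\n")
  est <- flattenParams(object@spec, object@estimates)
  cat("  estimates:\n")
  print(round(est, 3))
})

#' ModelComparison: joint fit of several comorbidity models
#'
#' @slot fits Named list of [TwinModelFit-class] objects.
#' @slot table Comparison data frame sorted by AIC.
#' @export
setClass("ModelComparison", representation(fits = "list", table = "data.frame"))

setMethod("show", "ModelComparison", function(object) {
  cat("ModelComparison of", length(object@fits), "models (sorted by AIC)\n")
  tb <- object@table
  tb$chi2 <- round(tb$chi2, 2)
  tb$p <- signif(tb$p, 3)
  tb$aic <- round(tb$aic, 2)
  tb$deltaAic <- round(tb$deltaAic, 2)
  print(tb, row.names = FALSE)
})
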