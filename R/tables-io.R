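## Table input/output.
##
## CSV schema: header `category,mz,dz`; one row per canonical category, the
## category written as its explicit label (e.g. `MDD0CUD0|MDD0CUD1`).
## JSON schema: object {"MZ": {label: count, ...}, "DZ": {...}}.

#' Read a ComorbidityTable from disk
#'
#' @param path File path.
#' @param format "csv" or "json" (see the package vignette for the schemas);
#'   guessed from the file extension by default.
#' @return A validated [ComorbidityTable-class]; pair totals are recomputed
#'   from the cells.
#' @export
readComorbidityTable <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  cats <- pairCategories()
  if (format == "csv") {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("category", "mz", "dz")
    if (!all(need %in% names(d)))
      stop("table file must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(d$category))
      stop("duplicate category row: ",
           paste(unique(d$category[duplicated(d$category)]), collapse = ", "))
    missing <- setdiff(cats$label, d$category)
    if (length(missing))
      stop("missing category row(s): ", paste(missing, collapse = ", "))
    extra <- setdiff(d$category, cats$label)
    if (length(extra))
      stop("unknown category row(s): ", paste(extra, collapse = ", "))
    mz <- stats::setNames(d$mz, d$category)
    dz <- stats::setNames(d$dz, d$category)
  } else {
    d <- jsonlite::fromJSON(path)
    if (!all(c("MZ", "DZ") %in% names(d)))
      stop("JSON table must have MZ and DZ objects")
    grab <- function(g) {
      v <- unlist(d[[g]])
      if (anyDuplicated(names(v))) stop("duplicate category in ", g)
      missing <- setdiff(cats$label, names(v))
      if (length(missing))
        stop("missing category in ", g, ": ", paste(missing, collapse = ", "))
      v
    }
    mz <- grab("MZ")
    dz <- grab("DZ")
  }
  if (any(mz != round(mz)) || any(dz != round(dz)))
    stop("counts must be integers")
  if (any(mz < 0) || any(dz < 0)) stop("counts must be non-negative")
  ComorbidityTable(mz = mz, dz = dz)
}

#' Write a ComorbidityTable to disk
#'
#' @param x A [ComorbidityTable-class].
#' @param path File path.
#' @param format "csv" or "json"; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
writeComorbidityTable <- function(x, path, format = c("auto", "csv", "json")) {
  stopifnot(is(x, "ComorbidityTable"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  cts <- tableCounts(x)
  if (format == "csv") {
    d <- data.frame(category = rownames(cts), mz = cts[, "MZ"], dz = cts[, "DZ"])
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  } else {
    obj <- list(MZ = as.list(stats::setNames(cts[, "MZ"], rownames(cts))),
                DZ = as.list(stats::setNames(cts[, "DZ"], rownames(cts))))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' The Australian twin MDD/CUD pair-count table
#'
#' The published 10-category by 2-zygosity input table of the Australian
#' Twin Registry cannabis-use-disorder / major-depressive-disorder study
#' (565 complete MZ and 640 complete DZ pairs, lifetime DSM-5-approximated
#' binary diagnoses).  The same counts ship as a CSV fixture in
#' `inst/extdata/aus_twin_mdd_cud.csv`.
#'
#' @return A [ComorbidityTable-class].
#' @examples
#' tab <- ausTwinTable()
#' pairTotals(tab)  # 565 MZ, 640 DZ
#' @export
ausTwinTable <- function() {
  ComorbidityTable(mz = c(298L, 28L, 114L, 17L, 16L, 6L, 16L, 47L, 12L, 11L),
                   dz = c(277L, 73L, 145L, 35L, 10L, 21L, 23L, 33L, 18L, 5L))
}
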