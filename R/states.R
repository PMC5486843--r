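## Person states and unordered pair categories.
##
## A person's joint lifetime phenotype is one of four states coded
## 2*MDD + CUD (0 = neither, 1 = CUD only, 2 = MDD only, 3 = both).  A twin
## pair is classified by the unordered multiset of its two person states,
## giving choose(4 + 1, 2) = 10 categories; twin order is disregarded to
## avoid sparse cells, so each off-diagonal category pools the two mirrored
## ordered combinations.

stateLabel <- function(code) {
  paste0("MDD", code %/% 2, "CUD", code %% 2)
}

#' The four person phenotype states
#'
#' @return A data frame with one row per joint phenotype state: integer
#'   `code` (2*mdd + cud), binary `mdd` and `cud` indicators, and the
#'   canonical `label`.
#' @examples
#' personStates()
#' @export
personStates <- function() {
  code <- 0:3
  data.frame(code = code, mdd = code %/% 2, cud = code %% 2,
             label = stateLabel(code), stringsAsFactors = FALSE)
}

#' The ten unordered twin-pair phenotype categories
#'
#' Categories are ordered by the canonical enumeration of state pairs
#' (lo, hi) with code(lo) <= code(hi), which matches the published input
#' table's row order.
#'
#' @return A data frame with columns `stateLo`, `stateHi` (person state
#'   codes), `label`, and `diagonal` (TRUE when both twins share a state).
#' @examples
#' pairCategories()
#' @export
pairCategories <- function() {
  g <- expand.grid(stateHi = 0:3, stateLo = 0:3)
  g <- g[g$stateLo <= g$stateHi, c("stateLo", "stateHi")]
  g <- g[order(g$stateLo, g$stateHi), ]
  rownames(g) <- NULL
  g$label <- paste0(stateLabel(g$stateLo), "|", stateLabel(g$stateHi))
  g$diagonal <- g$stateLo == g$stateHi
  g
}

## Collapse a 4x4 matrix over ordered person-state pairs (twin1, twin2)
## to the 10 unordered categories.  Works for probabilities and counts.
collapseOrdered <- function(P16) {
  cats <- pairCategories()
  vapply(seq_len(10), function(k) {
    i <- cats$stateLo[k] + 1
    j <- cats$stateHi[k] + 1
    if (i == j) P16[i, j] else P16[i, j] + P16[j, i]
  }, numeric(1))
}

#' Collapse ordered twin-pair counts to the ten unordered categories
#'
#' Takes counts over the 16 ordered combinations of twin1 and twin2 person
#' states (per zygosity) and pools mirrored combinations, discarding twin
#' order.  Diagonal cells pass through; totals are conserved.
#'
#' @param ordered A 4x4x2 array (twin1 state, twin2 state, zygosity MZ/DZ)
#'   of non-negative integer counts, or a 4x4 matrix for a single zygosity
#'   group together with `zygosity`.
#' @param zygosity When `ordered` is a matrix, the zygosity group it refers
#'   to ("MZ" or "DZ"); the other group is filled with zeros.
#' @return A [ComorbidityTable].
#' @examples
#' a <- array(1L, c(4, 4, 2))
#' collapsePairs(a)  # diagonal categories 1, off-diagonal 2, per zygosity
#' @export
collapsePairs <- function(ordered, zygosity = NULL) {
  if (is.matrix(ordered)) {
    if (is.null(zygosity)) stop("supply 'zygosity' with a single-group matrix")
    zygosity <- match.arg(zygosity, c("MZ", "DZ"))
    a <- array(0, c(4, 4, 2))
    a[, , if (zygosity == "MZ") 1 else 2] <- ordered
    ordered <- a
  }
  if (!identical(dim(ordered), c(4L, 4L, 2L)))
    stop("'ordered' must be a 4x4x2 array of counts")
  if (any(ordered < 0) || any(ordered != round(ordered)))
    stop("ordered counts must be non-negative integers")
  ComorbidityTable(mz = collapseOrdered(ordered[, , 1]),
                   dz = collapseOrdered(ordered[, , 2]))
}

#' Tabulate individual-level twin-pair records into a ComorbidityTable
#'
#' Accepts either wide records (one row per pair: `zygosity`, `mdd1`,
#' `cud1`, `mdd2`, `cud2`, as produced by [simulatePairs()]) or long
#' records (two rows per pair: `pairId`/`pair_id`, `zygosity`, `twin`,
#' `mdd`, `cud`).  Twin order within a pair is irrelevant.
#'
#' @param records A data frame of pair records.
#' @return A [ComorbidityTable] whose totals equal the record counts per
#'   zygosity group.
#' @export
recordsToTable <- function(records) {
  if (all(c("mdd1", "cud1", "mdd2", "cud2") %in% names(records))) {
    wide <- records
  } else if (all(c("zygosity", "twin", "mdd", "cud") %in% names(records))) {
    idcol <- intersect(c("pairId", "pair_id"), names(records))
    if (length(idcol) == 0) stop("long records need a 'pairId' or 'pair_id' column")
    o <- records[order(records[[idcol[1]]], records$twin), ]
    t1 <- o[o$twin == 1, ]
    t2 <- o[o$twin == 2, ]
    if (nrow(t1) != nrow(t2) || !all(t1[[idcol[1]]] == t2[[idcol[1]]]))
      stop("long records must contain twins 1 and 2 for every pair id")
    wide <- data.frame(zygosity = t1$zygosity,
                       mdd1 = t1$mdd, cud1 = t1$cud,
                       mdd2 = t2$mdd, cud2 = t2$cud)
  } else {
    stop("unrecognised record layout")
  }
  if (!all(wide$zygosity %in% c("MZ", "DZ")))
    stop("unknown zygosity label: ",
         paste(unique(setdiff(wide$zygosity, c("MZ", "DZ"))), collapse = ", "))
  bin <- c(wide$mdd1, wide$cud1, wide$mdd2, wide$cud2)
  if (!all(bin %in% c(0, 1))) stop("phenotypes must be binary 0/1")
  s1 <- 2 * wide$mdd1 + wide$cud1
  s2 <- 2 * wide$mdd2 + wide$cud2
  a <- array(0L, c(4, 4, 2))
  for (z in c("MZ", "DZ")) {
    sel <- wide$zygosity == z
    a[, , if (z == "MZ") 1 else 2] <-
      matrix(tabulate(4 * s1[sel] + s2[sel] + 1, nbins = 16), 4, 4, byrow = TRUE)
  }
  collapsePairs(a)
}
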