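## Logical co-expression pattern filter over treatment means.

#' Per-gene treatment means over replicates
#'
#' @param x a [TransplantExperiment-class] or a numeric matrix
#'   (genes x samples).
#' @param design design data.frame (ignored for a TransplantExperiment).
#' @return numeric matrix genes x 7 treatments, columns named
#'   `"origin->destination"`.
#' @export
treatmentMeans <- function(x, design = NULL) {
  if (is(x, "TransplantExperiment")) {
    design <- designTable(x)
    mat <- SummarizedExperiment::assay(x)
  } else {
    mat <- as.matrix(x)
    if (is.null(design)) .stopf("design is required for matrix input")
    design <- .validateDesign(design)
    mat <- mat[, design$sample_id, drop = FALSE]
  }
  .checkFullDesign(design)
  labels <- treatmentLabel(design$origin_pco2, design$destination_pco2)
  grp <- factor(labels, levels = unique(labels))
  t(rowsum(t(mat), grp) / as.vector(table(grp)))
}

## The 8 strict inequalities (each row: greater treatment, lesser
## treatment), built for the design's low/mid/high pCO2 levels. With
## lo = 400, mi = 900, hi = 1550 these read:
## 900->400 > 400->400,  400->400 > 1550->400,  400->900 > 900->900,
## 400->1550 > 1550->1550, 400->400 > 400->900, 400->1550 > 400->900,
## 400->900 > 1550->400, 400->900 > 1550->1550
#' @rdname matchesPattern
#' @export
patternRules <- function(levels = c(low = 400, mid = 900, high = 1550)) {
  lo <- levels[["low"]]; mi <- levels[["mid"]]; hi <- levels[["high"]]
  L <- function(o, d) treatmentLabel(o, d)
  cbind(greater = c(L(mi, lo), L(lo, lo), L(lo, mi), L(lo, hi),
                    L(lo, lo), L(lo, hi), L(lo, mi), L(lo, mi)),
        lesser  = c(L(lo, lo), L(hi, lo), L(mi, mi), L(hi, hi),
                    L(lo, mi), L(lo, mi), L(hi, lo), L(hi, hi)))
}

#' Match the 8-inequality co-expression pattern
#'
#' Tests whether treatment means follow the helicase-like down-regulation
#' pattern: expression highest in the mid-origin back-transplants, lowest
#' in the high-pCO2 natives and back-transplants, with the control lineage
#' in between — all eight inequalities strict, so exact ties never match.
#' The match depends only on the ordering of the means, hence is invariant
#' under any strictly increasing transform.
#'
#' @param m named numeric vector of the 7 treatment means, or a matrix as
#'   returned by [treatmentMeans()] (one row per gene).
#' @param levels named vector `c(low=, mid=, high=)` of pCO2 levels used
#'   to build the treatment labels.
#' @return logical (vector, for matrix input).
#' @examples
#' m <- c("400->400" = 1.0, "400->900" = 0.8, "900->900" = 0.7,
#'        "900->400" = 1.1, "400->1550" = 0.9, "1550->1550" = 0.6,
#'        "1550->400" = 0.5)
#' matchesPattern(m)  # TRUE
#' @export
matchesPattern <- function(m, levels = c(low = 400, mid = 900, high = 1550)) {
  rules <- patternRules(levels)
  if (is.matrix(m)) {
    miss <- setdiff(unique(as.vector(rules)), colnames(m))
    if (length(miss))
      .stopf("missing treatment mean(s): %s", paste(miss, collapse = ", "))
    ok <- rep(TRUE, nrow(m))
    for (r in seq_len(nrow(rules)))
      ok <- ok & (m[, rules[r, 1]] > m[, rules[r, 2]])
    return(unname(ok))
  }
  miss <- setdiff(unique(as.vector(rules)), names(m))
  if (length(miss))
    .stopf("missing treatment mean(s): %s", paste(miss, collapse = ", "))
  if (any(!is.finite(m))) .stopf("treatment means must be finite")
  all(m[rules[, 1]] > m[rules[, 2]])
}

#' Scan all genes for the co-expression pattern
#'
#' @inheritParams treatmentMeans
#' @param levels pCO2 levels, as in [matchesPattern()].
#' @return character vector of gene ids whose replicate-mean expression
#'   satisfies all 8 inequalities.
#' @export
scanPattern <- function(x, design = NULL, levels = NULL) {
  if (is.null(levels)) {
    d <- if (is(x, "TransplantExperiment")) designTable(x) else
      .validateDesign(design)
    levels <- .pco2Levels(d)
  }
  tm <- treatmentMeans(x, design)
  rownames(tm)[matchesPattern(tm, levels)]
}
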