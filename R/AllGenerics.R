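#' Accessors for transplantScan classes
#'
#' `designTable()` returns the sample design as a plain data.frame (with a
#' `sample_id` column); `treatments()` returns the per-sample treatment
#' label (`"origin->destination"`); `poolNames()` and `nSites()` access a
#' [SyncTable-class]; `syncCounts()` returns its `sites x pools x 6` count
#' array.
#'
#' @param x a [TransplantExperiment-class] or [SyncTable-class] object.
#' @return see the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("designTable", function(x) standardGeneric("designTable"))

#' @rdname accessors
#' @export
setGeneric("treatments", function(x) standardGeneric("treatments"))

#' @rdname accessors
#' @export
setGeneric("poolNames", function(x) standardGeneric("poolNames"))

#' @rdname accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname accessors
#' @export
setGeneric("syncCounts", function(x) standardGeneric("syncCounts"))

#' @rdname accessors
setMethod("designTable", "TransplantExperiment", function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  data.frame(sample_id = rownames(cd), cd, row.names = NULL,
             stringsAsFactors = FALSE)[, .designColumns]
})

#' @rdname accessors
setMethod("treatments", "TransplantExperiment", function(x) {
  d <- designTable(x)
  treatmentLabel(d$origin_pco2, d$destination_pco2)
})

#' @rdname accessors
setMethod("poolNames", "SyncTable", function(x) dimnames(x@counts)[[2]])

#' @rdname accessors
setMethod("nSites", "SyncTable", function(x) length(x@position))

#' @rdname accessors
setMethod("syncCounts", "SyncTable", function(x) x@counts)

#' @describeIn SyncTable-class subset sites
#' @param x,i,j,...,drop subsetting arguments; only site subsetting (`i`)
#'   is supported.
#' @export
setMethod("[", "SyncTable", function(x, i, j, ..., drop = FALSE) {
  SyncTable(x@contig[i], x@position[i], x@ref[i],
            x@counts[i, , , drop = FALSE])
})

setMethod("show", "TransplantExperiment", function(object) {
  callNextMethod()
  tr <- table(treatments(object))
  cat("treatments(", length(tr), "): ",
      paste(names(tr), tr, sep = " x ", collapse = ", "), "\n", sep = "")
})

setMethod("show", "SyncTable", function(object) {
  cat("SyncTable with", nSites(object), "sites x",
      length(poolNames(object)), "pools\n")
  if (nSites(object) > 0) {
    n <- min(3L, nSites(object))
    for (i in seq_len(n)) {
      cat(sprintf("  %s:%d ref=%s depth/pool=%.0f\n", object@contig[i],
                  object@position[i], object@ref[i],
                  sum(object@counts[i, , ]) / length(poolNames(object))))
    }
    if (nSites(object) > n) cat("  ...\n")
  }
})
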