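#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' TransplantExperiment: counts plus reciprocal-transplant sample design
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] whose
#' `colData` carries the reciprocal-transplant design: for every sequenced
#' pool the pCO2 the population was raised at for two generations
#' (`origin_pco2`), the pCO2 it was transplanted to (`destination_pco2`),
#' the replicate population (`replicate`) and the number of pooled
#' individuals (`pool_size`). The first assay holds the gene x sample count
#' (or normalized-count) matrix.
#'
#' @slot .. inherited from `SummarizedExperiment`.
#' @seealso [TransplantExperiment()] (constructor), [designTable()],
#'   [treatments()], [scanExpression()], [scanPattern()]
#' @exportClass TransplantExperiment
setClass("TransplantExperiment", contains = "SummarizedExperiment")

setValidity("TransplantExperiment", function(object) {
  cd <- as.data.frame(SummarizedExperiment::colData(object))
  cd$sample_id <- rownames(cd)
  msg <- tryCatch({
    .validateDesign(cd, context = "colData")
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(msg)) return(msg)
  vals <- SummarizedExperiment::assay(object)
  if (!is.numeric(vals)) return("assay must be numeric")
  if (any(!is.finite(vals))) return("assay contains non-finite values")
  if (any(vals < 0)) return("assay contains negative values")
  if (anyDuplicated(rownames(object))) return("duplicated gene ids")
  TRUE
})

#' Construct a TransplantExperiment
#'
#' @param counts numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param design data.frame with columns `sample_id`, `origin_pco2`,
#'   `destination_pco2`, `replicate`, `pool_size`. Every column of `counts`
#'   must appear in `design$sample_id`; columns are reordered to follow the
#'   design.
#' @param rowData optional `DataFrame` of per-gene annotation.
#' @param metadata optional list stored in the object metadata.
#' @return a [TransplantExperiment-class] object.
#' @examples
#' design <- generateDesign(2, c(30, 70), seed = 1)
#' counts <- matrix(rpois(10 * 14, 50), 10, 14,
#'                  dimnames = list(paste0("g", 1:10), design$sample_id))
#' te <- TransplantExperiment(counts, design)
#' treatments(te)
#' @export
TransplantExperiment <- function(counts, design, rowData = NULL,
                                 metadata = list()) {
  design <- .validateDesign(design)
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    .stopf("counts must have sample ids as colnames")
  if (is.null(rownames(counts)))
    .stopf("counts must have gene ids as rownames")
  missing <- setdiff(colnames(counts), design$sample_id)
  if (length(missing))
    .stopf("sample(s) in counts absent from design: %s",
           paste(missing, collapse = ", "))
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  cd <- S4Vectors::DataFrame(design[, setdiff(.designColumns, "sample_id")],
                             row.names = design$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd, metadata = metadata)
  if (!is.null(rowData)) SummarizedExperiment::rowData(se) <- rowData
  new("TransplantExperiment", se)
}

#' SyncTable: per-site pooled allele counts (PoPoolation2 sync layout)
#'
#' Holds one row per variant site and, for each sequenced pool, the six
#' read counts `A:T:C:G:N:del` produced by the PoPoolation2 pipeline.
#' Positions are 1-based everywhere.
#'
#' @slot contig character, contig id per site.
#' @slot position integer, 1-based position per site.
#' @slot ref character, reference base per site (A/C/G/T/N).
#' @slot counts 3-d numeric array `sites x pools x 6`, allele dimension
#'   named `A,T,C,G,N,del`; pool dimension named by sample id.
#' @seealso [readSync()], [writeSync()], [simulatePoolSnps()], [cmhScan()]
#' @exportClass SyncTable
setClass("SyncTable",
  representation(contig = "character", position = "integer",
                 ref = "character", counts = "array"))

.syncAlleles <- c("A", "T", "C", "G", "N", "del")

setValidity("SyncTable", function(object) {
  d <- dim(object@counts)
  if (length(d) != 3L || d[3] != 6L)
    return("counts must be a sites x pools x 6 array")
  if (length(object@contig) != d[1] || length(object@position) != d[1] ||
      length(object@ref) != d[1])
    return("contig/position/ref length must equal the number of sites")
  if (d[1] > 0 && any(object@position < 1L))
    return("positions must be 1-based (>= 1)")
  if (any(object@counts < 0) || any(!is.finite(object@counts)))
    return("allele counts must be finite and >= 0")
  if (!identical(dimnames(object@counts)[[3]], .syncAlleles))
    return("allele dimension must be named A,T,C,G,N,del")
  if (is.null(dimnames(object@counts)[[2]]))
    return("pool dimension must carry sample ids")
  TRUE
})

#' Construct a SyncTable
#'
#' @param contig character vector of contig ids.
#' @param position integer vector of 1-based positions.
#' @param ref character vector of reference bases.
#' @param counts numeric array `sites x pools x 6` (alleles A,T,C,G,N,del);
#'   the pool dimension must be named with sample ids.
#' @return a [SyncTable-class] object.
#' @export
SyncTable <- function(contig, position, ref, counts) {
  dimnames(counts)[[3]] <- .syncAlleles
  new("SyncTable", contig = as.character(contig),
      position = as.integer(position), ref = as.character(ref),
      counts = counts)
}
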