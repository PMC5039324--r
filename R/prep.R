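## Expression preparation: isoform collapsing, median-of-ratios size
## factors, scale normalization, and the dispersion/zero gene filters.

#' Collapse transcript isoforms into unigene counts
#'
#' Contigs sharing both an assembly component and an annotation string are
#' taken to be isoforms of one gene ("unigene") and their counts are
#' summed; contigs of the same component with different annotations stay
#' separate. The unigene id is the component id suffixed with a stable
#' 32-bit hash of the annotation string. Per-sample totals are conserved
#' exactly.
#'
#' @param counts contig-level count matrix (contig ids as rownames).
#' @param annot annotation data.frame with columns `contig_id`,
#'   `component_id`, `annotation` (see [readAnnotation()]); every contig in
#'   `counts` must be annotated.
#' @return unigene-level count matrix; attribute `"isoform_map"` holds a
#'   data.frame mapping `contig_id` to `unigene_id`.
#' @examples
#' counts <- matrix(c(5, 5, 3, 7), 2, 2, byrow = TRUE,
#'                  dimnames = list(c("c1_seq1", "c1_seq2"), c("s1", "s2")))
#' annot <- data.frame(contig_id = c("c1_seq1", "c1_seq2"),
#'                     component_id = "c1", annotation = "kinase")
#' collapseIsoforms(counts, annot)  # one unigene row (8, 12)
#' @export
collapseIsoforms <- function(counts, annot) {
  stopifnot(is.matrix(counts))
  idx <- match(rownames(counts), annot$contig_id)
  if (anyNA(idx))
    .stopf("contig(s) without annotation: %s",
           paste(head(rownames(counts)[is.na(idx)], 5), collapse = ", "))
  comp <- annot$component_id[idx]
  ann <- annot$annotation[idx]
  key <- paste(comp, ann, sep = "\r")
  uid <- paste0(comp, "_", .stringHash(ann))
  uid_of_key <- uid[!duplicated(key)]
  names(uid_of_key) <- key[!duplicated(key)]
  out <- rowsum(counts, group = key, reorder = FALSE)
  rownames(out) <- unname(uid_of_key[rownames(out)])
  if (anyDuplicated(rownames(out)))
    .stopf("unigene id collision; annotation hash is not injective here")
  attr(out, "isoform_map") <- data.frame(contig_id = rownames(counts),
                                         unigene_id = uid)
  out
}

#' Median-of-ratios size factors
#'
#' The scale-normalization estimator of Anders & Huber as used by DESeq:
#' the pseudo-reference is the per-gene geometric mean across samples
#' (computed in log space), restricted to genes with strictly positive
#' counts in every sample; the size factor of sample j is the median over
#' those genes of `count[g, j] / geomean[g]`.
#'
#' @param counts count matrix (genes x samples); needs at least one gene
#'   with all counts > 0.
#' @return named numeric vector of positive size factors, one per sample.
#' @seealso [normalizeCounts()]
#' @export
medianRatioSizeFactors <- function(counts) {
  stopifnot(is.matrix(counts))
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    .stopf("no gene with all counts > 0; cannot estimate size factors")
  lg <- log(counts[ref, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg - geo, 2, function(v) exp(median(v)))
  if (any(!is.finite(sf)) || any(sf <= 0))
    .stopf("size factor estimation failed (non-positive factor)")
  sf
}

#' Apply size factors
#'
#' Divides each column of the count matrix by its size factor, yielding
#' real-valued scale-normalized counts.
#'
#' @param counts count matrix (genes x samples).
#' @param factors positive size factors, one per sample (named vectors are
#'   matched by sample id).
#' @return normalized matrix of the same shape.
#' @export
normalizeCounts <- function(counts, factors) {
  stopifnot(is.matrix(counts))
  if (!is.null(names(factors)) && !is.null(colnames(counts))) {
    if (!all(colnames(counts) %in% names(factors)))
      .stopf("size factors missing for sample(s): %s",
             paste(setdiff(colnames(counts), names(factors)), collapse = ", "))
    factors <- factors[colnames(counts)]
  }
  if (length(factors) != ncol(counts))
    .stopf("%d size factors for %d samples", length(factors), ncol(counts))
  if (any(!is.finite(factors)) || any(factors <= 0))
    .stopf("size factors must be finite and > 0")
  sweep(counts, 2, factors, "/")
}

#' Filter genes on dispersion and zero counts
#'
#' A gene is excluded iff its sample standard deviation exceeds its mean
#' and/or at least one sample has a zero count. The SD uses the n-1
#' denominator (the usual sample SD; the rule's source does not specify).
#' `rule = "variance"` substitutes variance > mean, an alternative wording
#' of the same screen. The filter is idempotent.
#'
#' @param normalized normalized count matrix (genes x samples).
#' @param rule `"sd"` (default) or `"variance"`.
#' @return list with `kept` (the surviving submatrix) and `report`
#'   (data.frame: `gene_id`, `kept`, `reason` in
#'   `"", "zero", "sd>mean", "zero;sd>mean"`).
#' @export
filterGenes <- function(normalized, rule = c("sd", "variance")) {
  stopifnot(is.matrix(normalized))
  rule <- match.arg(rule)
  mu <- rowMeans(normalized)
  n <- ncol(normalized)
  v <- rowSums((normalized - mu)^2) / (n - 1L)
  disp <- if (rule == "sd") sqrt(v) else v
  rule_name <- if (rule == "sd") "sd>mean" else "var>mean"
  zero <- apply(normalized == 0, 1, any)
  over <- disp > mu
  reason <- rep("", nrow(normalized))
  reason[zero] <- "zero"
  reason[over] <- rule_name
  reason[zero & over] <- paste("zero", rule_name, sep = ";")
  drop <- zero | over
  list(kept = normalized[!drop, , drop = FALSE],
       report = data.frame(gene_id = rownames(normalized),
                           kept = !drop, reason = reason,
                           row.names = NULL))
}
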