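## Readers and writers for every file the pipeline touches. All readers
## validate and reject malformed input, naming file, line/row and the rule
## violated; nothing is silently coerced. TSV throughout, sync positions
## 1-based, never converted.

.checkFile <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  path
}

#' Read / write a gene x sample count matrix (TSV)
#'
#' First column = gene id, header row = sample ids. Values must be
#' finite, numeric and non-negative; gene and sample ids must be unique.
#' `writeCountMatrix` followed by `readCountMatrix` is the identity.
#'
#' @param path file path.
#' @return `readCountMatrix`: numeric matrix with gene ids as rownames.
#' @export
readCountMatrix <- function(path) {
  .checkFile(path)
  if (file.size(path) == 0)
    .stopf("%s: empty count matrix file", path)
  df <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
               colClasses = "character"),
    error = function(e) .stopf("%s: not a readable TSV (%s)", path,
                               conditionMessage(e)))
  if (nrow(df) == 0 || ncol(df) < 2)
    .stopf("%s: empty or header-only count matrix", path)
  gene_ids <- df[[1]]
  if (anyDuplicated(gene_ids))
    .stopf("%s: duplicated gene id '%s'", path,
           gene_ids[duplicated(gene_ids)][1])
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids))
    .stopf("%s: duplicated sample id '%s'", path,
           sample_ids[duplicated(sample_ids)][1])
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(gene_ids, sample_ids))
  bad <- which(is.na(vals) | !is.finite(vals) | vals < 0, arr.ind = TRUE)
  if (nrow(bad))
    .stopf("%s: non-numeric or negative count at gene '%s', sample '%s'",
           path, gene_ids[bad[1, 1]], sample_ids[bad[1, 2]])
  vals
}

#' @rdname readCountMatrix
#' @param mat numeric matrix with gene ids as rownames, sample ids as
#'   colnames.
#' @export
writeCountMatrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write pooled allele counts in PoPoolation2 sync format
#'
#' Tab-separated: contig, 1-based position, reference base, then one
#' colon-separated `A:T:C:G:N:del` sextuple per pool, e.g.
#' `2L  5  A  10:0:0:5:0:0`. Column counts and sextuples are validated per
#' line.
#'
#' @param path file path.
#' @param pool_names optional sample ids for the pool columns (in file
#'   order). If omitted, pools are named `pool1`, `pool2`, ...
#' @param n_pools optional expected number of pools; a mismatch is an
#'   error.
#' @return `readSync`: a [SyncTable-class].
#' @export
readSync <- function(path, pool_names = NULL, n_pools = NULL) {
  .checkFile(path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) .stopf("%s: empty sync file", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1]))
    .stopf("%s: line %d has %d columns, expected %d", path,
           which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1])
  np <- nf[1] - 3L
  if (np < 1L) .stopf("%s: no pool columns", path)
  if (!is.null(n_pools) && np != n_pools)
    .stopf("%s: %d pool columns, expected %d", path, np, n_pools)
  if (is.null(pool_names)) pool_names <- paste0("pool", seq_len(np))
  if (length(pool_names) != np)
    .stopf("%s: %d pool names for %d pool columns", path,
           length(pool_names), np)
  m <- matrix(unlist(fields), ncol = nf[1], byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos) || any(pos < 1L))
    .stopf("%s: line %d has invalid position '%s' (1-based integer required)",
           path, which(is.na(pos) | pos < 1L)[1],
           m[which(is.na(pos) | pos < 1L)[1], 2])
  counts <- array(NA_real_, c(length(lines), np, 6L),
                  dimnames = list(NULL, pool_names, .syncAlleles))
  for (j in seq_len(np)) {
    parts <- strsplit(m[, 3L + j], ":", fixed = TRUE)
    lp <- lengths(parts)
    if (any(lp != 6L))
      .stopf("%s: line %d pool %d: sextuple '%s' has %d fields, expected 6",
             path, which(lp != 6L)[1], j, m[which(lp != 6L)[1], 3L + j],
             lp[lp != 6L][1])
    v <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = 6L, byrow = TRUE)
    bad <- which(apply(v, 1, function(r) anyNA(r) || any(r < 0) ||
                         any(r != floor(r))))
    if (length(bad))
      .stopf("%s: line %d pool %d: sextuple '%s' has a non-count entry",
             path, bad[1], j, m[bad[1], 3L + j])
    counts[, j, ] <- v
  }
  SyncTable(m[, 1], pos, m[, 3], counts)
}

#' @rdname readSync
#' @param sync a [SyncTable-class].
#' @export
writeSync <- function(sync, path) {
  stopifnot(is(sync, "SyncTable"))
  n <- nSites(sync)
  np <- length(poolNames(sync))
  cols <- vapply(seq_len(np), function(j) {
    apply(format(sync@counts[, j, , drop = FALSE], trim = TRUE,
                 scientific = FALSE), 1, paste, collapse = ":")
  }, character(n))
  lines <- do.call(paste, c(list(sync@contig, sync@position, sync@ref),
                            as.data.frame(matrix(cols, nrow = n)),
                            sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write the sample design table (TSV)
#'
#' Columns: `sample_id`, `origin_pco2`, `destination_pco2`, `replicate`,
#' `pool_size`.
#'
#' @param path file path.
#' @return `readDesign`: validated design data.frame.
#' @export
readDesign <- function(path) {
  .checkFile(path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  .validateDesign(df, context = sprintf("design file %s", path))
}

#' @rdname readDesign
#' @param design design data.frame.
#' @export
writeDesign <- function(design, path) {
  design <- .validateDesign(design)
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a contig annotation table (TSV)
#'
#' Columns: `contig_id` (unique), `component_id` (assembly component the
#' contig belongs to), `annotation` (free-text), `go_terms`
#' (comma-separated GO ids, may be empty).
#'
#' @param path file path.
#' @return data.frame with those four columns (`go_terms` kept as the raw
#'   comma-separated string).
#' @export
readAnnotation <- function(path) {
  .checkFile(path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  need <- c("contig_id", "component_id", "annotation")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    .stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  if (anyDuplicated(df$contig_id))
    .stopf("%s: duplicated contig_id '%s'", path,
           df$contig_id[duplicated(df$contig_id)][1])
  if (!"go_terms" %in% colnames(df)) df$go_terms <- ""
  df[, c("contig_id", "component_id", "annotation", "go_terms")]
}

#' Read / write a flat gene-to-GO map (two-column TSV, one pair per line)
#'
#' Header `gene_id`, `term`; a gene annotated with k terms appears on k
#' lines. GO ids are treated as opaque strings; duplicate pairs collapse
#' to one.
#'
#' @param path file path.
#' @return `readGoMap`: data.frame with columns `gene_id`, `term`.
#' @export
readGoMap <- function(path) {
  .checkFile(path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (!all(c("gene_id", "term") %in% colnames(df)))
    .stopf("%s: GO map needs columns gene_id, term", path)
  unique(df[, c("gene_id", "term")])
}

#' @rdname readGoMap
#' @param go_map data.frame with columns `gene_id`, `term`.
#' @export
writeGoMap <- function(go_map, path) {
  stopifnot(all(c("gene_id", "term") %in% colnames(go_map)))
  write.table(go_map[, c("gene_id", "term")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
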