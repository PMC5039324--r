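## End-to-end orchestration on synthetic data: simulate -> prep -> three
## scans -> enrichment, with a manifest of every parameter and checksum.
## All intermediates are plain TSV so every stage can be inspected and
## re-run independently; given the same seed the run directory is
## byte-identical (no timestamps anywhere).

.logLine <- function(con, verbose, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(msg, con)
  if (verbose) message(msg)
}

#' Run the full synthetic-study pipeline
#'
#' Generates a reciprocal-transplant study (design, counts with planted
#' hypothesis/pattern genes, pooled SNPs with planted frequency shifts,
#' GO annotations with a planted term enriched among the H2 truth genes),
#' then runs preparation (size factors, normalization, gene filters), the
#' ANCOVA hypothesis scan, the co-expression pattern scan, the CMH SNP
#' scan, and GO enrichment of the recovered H2 list. Every stage writes a
#' TSV into `out_dir`; `manifest.yaml` records package version, seed, all
#' parameters and the MD5 checksum of every result file.
#'
#' @param out_dir output directory (created; must not already contain a
#'   manifest unless `overwrite = TRUE`).
#' @param seed master seed; stage seeds are derived from it, so reruns
#'   with the same seed are byte-identical.
#' @param n_genes,n_sites problem sizes.
#' @param frac_h1,frac_h2,frac_h3,frac_pattern planted gene-class
#'   fractions (see [simulateCounts()]).
#' @param delta_f,frac_selected planted SNP shift (see
#'   [simulatePoolSnps()]).
#' @param coverage reads per pool per site.
#' @param alpha significance level for both scans.
#' @param scale analysis scale for the expression scans.
#' @param fdr FDR method for enrichment.
#' @param min_minor_count,min_coverage CMH testability thresholds.
#' @param verbose also echo the log to the console.
#' @param overwrite allow writing into a directory holding a previous run.
#' @return (invisibly) list with the result objects and file paths.
#' @examples
#' \donttest{
#' run <- runPipeline(file.path(tempdir(), "demo"), seed = 1,
#'                    n_genes = 300, n_sites = 300)
#' }
#' @export
runPipeline <- function(out_dir, seed, n_genes = 2000, n_sites = 2000,
                        frac_h1 = 0.05, frac_h2 = 0.05, frac_h3 = 0.02,
                        frac_pattern = 0.02, delta_f = 0.3,
                        frac_selected = 0.1, coverage = 50,
                        alpha = 0.05, scale = c("log2p1", "raw"),
                        fdr = c("BY", "BH"), min_minor_count = 2,
                        min_coverage = 10, verbose = TRUE,
                        overwrite = FALSE) {
  scale <- match.arg(scale)
  fdr <- match.arg(fdr)
  seed <- .checkCount(seed, "seed", min = 0L)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.yaml")
  if (file.exists(manifest_path) && !overwrite)
    .stopf("%s already holds a run; set overwrite = TRUE", out_dir)
  log_path <- file.path(out_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  step <- function(name, expr) {
    .logLine(con, verbose, "[%s] start", name)
    res <- tryCatch(expr, error = function(e)
      .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    .logLine(con, verbose, "[%s] done", name)
    res
  }
  paths <- list()
  wr <- function(name, writer) { paths[[name]] <<- file.path(out_dir, name)
                                 writer(paths[[name]]); paths[[name]] }

  design <- step("design", generateDesign(seed = seed))
  wr("design.tsv", function(p) writeDesign(design, p))

  te <- step("simulate-counts", simulateCounts(
    design, n_genes = n_genes, frac_h1 = frac_h1, frac_h2 = frac_h2,
    frac_h3 = frac_h3, frac_pattern = frac_pattern, seed = seed + 1L))
  counts <- SummarizedExperiment::assay(te)
  truth_genes <- data.frame(gene_id = rownames(te),
    truth = as.character(SummarizedExperiment::rowData(te)$truth))
  wr("counts.tsv", function(p) writeCountMatrix(counts, p))
  wr("truth_genes.tsv", function(p) write.table(truth_genes, p, sep = "\t",
    quote = FALSE, row.names = FALSE))

  prep <- step("prep", {
    sf <- medianRatioSizeFactors(counts)
    normalized <- normalizeCounts(counts, sf)
    flt <- filterGenes(normalized)
    list(sf = sf, normalized = normalized, flt = flt)
  })
  wr("size_factors.tsv", function(p) write.table(
    data.frame(sample_id = names(prep$sf), size_factor = prep$sf),
    p, sep = "\t", quote = FALSE, row.names = FALSE))
  wr("normalized.tsv", function(p) writeCountMatrix(
    round(prep$flt$kept, 6), p))
  wr("filter_report.tsv", function(p) write.table(prep$flt$report, p,
    sep = "\t", quote = FALSE, row.names = FALSE))

  kept <- prep$flt$kept
  scan <- step("scan-ancova",
               scanExpression(kept, design, alpha = alpha, scale = scale))
  wr("ancova_results.tsv", function(p) write.table(
    data.frame(gene_id = rownames(scan),
               as.data.frame(scan)), p, sep = "\t", quote = FALSE,
    row.names = FALSE))

  pattern <- step("scan-pattern",
                  scanPattern(.analysisScale(kept, scale), design))
  wr("pattern_genes.txt", function(p) writeLines(pattern, p))

  snps <- step("simulate-snps", simulatePoolSnps(
    design, n_sites = n_sites, coverage = coverage, delta_f = delta_f,
    frac_selected = frac_selected, seed = seed + 2L))
  wr("snps.sync", function(p) writeSync(snps$sync, p))
  wr("truth_sites.tsv", function(p) write.table(
    data.frame(contig = snps$sync@contig, position = snps$sync@position,
               truth = snps$truth), p, sep = "\t", quote = FALSE,
    row.names = FALSE))

  cmh <- step("scan-cmh", cmhScan(snps$sync, design, alpha = alpha,
    min_minor_count = min_minor_count, min_coverage = min_coverage))
  wr("cmh_results.tsv", function(p) write.table(
    as.data.frame(cmh), p, sep = "\t", quote = FALSE, row.names = FALSE))

  enr <- step("enrich", {
    go_map <- simulateGoAnnotations(rownames(counts),
      planted_genes = truth_genes$gene_id[truth_genes$truth == "H2"],
      enrichment_factor = 10, seed = seed + 3L)
    wr("go_map.tsv", function(p) writeGoMap(go_map, p))
    h2 <- rownames(scan)[scan$class == "H2"]
    universe <- rownames(kept)
    if (length(intersect(h2, universe)))
      enrichTerms(intersect(h2, universe), universe, go_map, fdr = fdr)
    else S4Vectors::DataFrame()
  })
  wr("enrichment.tsv", function(p) write.table(as.data.frame(enr), p,
    sep = "\t", quote = FALSE, row.names = FALSE))

  step("manifest", {
    files <- sort(unlist(paths))
    sums <- tools::md5sum(files)
    names(sums) <- basename(files)
    manifest <- list(
      package = "transplantScan",
      version = as.character(utils::packageVersion("transplantScan")),
      seed = seed,
      parameters = list(n_genes = n_genes, n_sites = n_sites,
        frac_h1 = frac_h1, frac_h2 = frac_h2, frac_h3 = frac_h3,
        frac_pattern = frac_pattern, delta_f = delta_f,
        frac_selected = frac_selected, coverage = coverage, alpha = alpha,
        scale = scale, fdr = fdr, min_minor_count = min_minor_count,
        min_coverage = min_coverage),
      checksums = as.list(sums))
    yaml::write_yaml(manifest, manifest_path)
  })
  .logLine(con, verbose, "pipeline complete: %d result files",
           length(paths))
  invisible(list(design = design, experiment = te, prep = prep,
                 scan = scan, pattern = pattern, cmh = cmh,
                 enrichment = enr, paths = paths,
                 manifest = manifest_path))
}
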