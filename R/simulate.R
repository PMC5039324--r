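## Synthetic study generator: design, expression counts with planted
## reaction-norm structure, pooled SNP reads with planted frequency shifts,
## and GO annotations with a planted enriched term.

#' Generate a reciprocal-transplant sample design
#'
#' Emulates the 14-pool layout of a two-generation reciprocal-transplant
#' experiment at three pCO2 levels (400, 900, 1550 uatm): natives at each
#' level (400->400, 900->900, 1550->1550), the control population
#' transplanted up (400->900, 400->1550) and the acclimated populations
#' transplanted back to control (900->400, 1550->400), each with
#' `replicates_per_treatment` replicate pools.
#'
#' @param replicates_per_treatment number of replicate pools per treatment
#'   (2 in the emulated study, giving 14 samples).
#' @param pool_size_range integer `(min, max)`; pool sizes (individuals per
#'   pool) are drawn uniformly in this range. The emulated study spans
#'   28-76 individuals.
#' @param seed integer seed; pool-size draws are reproducible given it.
#' @return data.frame with columns `sample_id`, `origin_pco2`,
#'   `destination_pco2`, `replicate`, `pool_size`.
#' @examples
#' generateDesign(2, c(28, 76), seed = 1)
#' @export
generateDesign <- function(replicates_per_treatment = 2,
                           pool_size_range = c(28, 76), seed = NULL) {
  replicates_per_treatment <- .checkCount(replicates_per_treatment,
                                          "replicates_per_treatment")
  if (length(pool_size_range) != 2L || !is.numeric(pool_size_range) ||
      any(pool_size_range != as.integer(pool_size_range)) ||
      pool_size_range[1] < 1 || pool_size_range[1] > pool_size_range[2])
    .stopf("pool_size_range must be integers with 1 <= min <= max")
  if (replicates_per_treatment > length(LETTERS))
    .stopf("at most %d replicates are supported", length(LETTERS))
  tr <- .transplantTreatments(c(low = 400, mid = 900, high = 1550))
  .withSeed(seed, {
    rep_letters <- LETTERS[seq_len(replicates_per_treatment)]
    design <- data.frame(
      origin_pco2 = rep(tr$origin, each = replicates_per_treatment),
      destination_pco2 = rep(tr$destination, each = replicates_per_treatment),
      replicate = rep(rep_letters, times = nrow(tr))
    )
    design$sample_id <- paste0(treatmentLabel(design$origin_pco2,
                                              design$destination_pco2),
                               design$replicate)
    ## gsub: "400->900A" -> "400-900A", file/column friendly
    design$sample_id <- gsub("->", "-", design$sample_id, fixed = TRUE)
    sizes <- seq(pool_size_range[1], pool_size_range[2])
    design$pool_size <- sizes[sample.int(length(sizes), nrow(design),
                                         replace = TRUE)]
    .validateDesign(design)
  })
}

## Expected per-treatment log2 means for the planted gene classes. The
## 1550-origin line is the only perturbed one for H1/H2/H3, so the
## plasticity precondition (400-origin vs 900-origin lines equal) holds in
## expectation for those classes. H1 pivots the 1550-origin line around the
## destination midpoint (elevation preserved); H2 shifts the whole line
## (slope preserved); H3 does both.
.plantedMeans <- function(truth, base, e_h1, e_h2, tr_labels,
                          hi_home, hi_back) {
  n <- length(truth)
  mu <- matrix(base, n, length(tr_labels), dimnames = list(NULL, tr_labels))
  h1 <- truth == "H1" | truth == "H3"
  ## pivot: high-destination endpoint moves by e, low-destination by -e
  mu[h1, hi_home] <- mu[h1, hi_home] + e_h1[h1]
  mu[h1, hi_back] <- mu[h1, hi_back] - e_h1[h1]
  h2 <- truth == "H2" | truth == "H3"
  mu[h2, hi_home] <- mu[h2, hi_home] + e_h2[h2]
  mu[h2, hi_back] <- mu[h2, hi_back] + e_h2[h2]
  mu
}

## Offsets (in units of one pattern step) satisfying all 8 pattern
## inequalities strictly; see matchesPattern(). Labels built from the
## design's low/mid/high pCO2 levels.
.patternOffsets <- function(lev) {
  lo <- lev[["low"]]; mi <- lev[["mid"]]; hi <- lev[["high"]]
  setNames(c(1, 0, -1, -2, -3, -4, -5),
           treatmentLabel(c(mi, lo, lo, lo, mi, hi, hi),
                          c(lo, lo, hi, mi, mi, hi, lo)))
}

#' Simulate an expression count matrix with planted hypothesis structure
#'
#' Draws negative-binomial counts around treatment-specific means on a
#' log2 grid. Gene classes are planted deterministically (first a block of
#' H1 genes, then H2, H3, pattern, remainder null):
#' \describe{
#'   \item{null}{identical expected means in all 7 treatments.}
#'   \item{H1}{the 1550-origin reaction norm changes slope only, pivoting
#'     around the destination-pCO2 midpoint so its elevation is unchanged;
#'     the planted endpoint deviation is `effect_h1_log2fc` at the high
#'     destination (and its negative at the 400 destination).}
#'   \item{H2}{all 1550-origin samples (1550->1550 and 1550->400) shift by
#'     `effect_h2_log2fc` log2 units; no slope change.}
#'   \item{H3}{both perturbations.}
#'   \item{pattern}{expected means follow the 8-inequality co-expression
#'     pattern (see [matchesPattern()]) with spacing `pattern_step_log2`.}
#' }
#' Per-gene effect sizes are drawn `Normal(effect, effect_sd_log2)`; with
#' `effect_sd_log2 = 0` they are exact. Each sample receives a
#' multiplicative sequencing-depth factor drawn log-uniformly in
#' `depth_range`, so size-factor estimation downstream is non-trivial.
#'
#' @param design design data.frame (see [generateDesign()]).
#' @param n_genes number of genes.
#' @param baseline_log_mean,baseline_log_sd per-gene baseline log2 mean is
#'   drawn Normal(baseline_log_mean, baseline_log_sd).
#' @param nb_dispersion negative-binomial size parameter `k` shared by all
#'   genes (`variance = mu + mu^2/k`).
#' @param frac_h1,frac_h2,frac_h3,frac_pattern fractions of genes planted
#'   per class (remainder null); realized counts are `round(frac * n_genes)`.
#' @param effect_h1_log2fc planted H1 endpoint deviation (log2), default
#'   -0.42 mirroring the down-regulation magnitude the approach targets.
#' @param effect_h2_log2fc planted H2 elevation shift (log2 fold change),
#'   default -0.42.
#' @param effect_sd_log2 SD of per-gene effect sizes (default 0.2).
#' @param pattern_step_log2 spacing (log2) between consecutive treatment
#'   means of a planted pattern gene.
#' @param depth_range range of the log-uniform library-depth factors.
#' @param seed integer seed; same seed, same counts.
#' @return a [TransplantExperiment-class]; `rowData` carries `truth`
#'   (factor null/H1/H2/H3/pattern) and `mu_log2` (expected noise-free
#'   log2 mean per treatment); `colData` carries `depth_factor`.
#' @examples
#' design <- generateDesign(seed = 1)
#' te <- simulateCounts(design, n_genes = 100, frac_h2 = 0.1, seed = 2)
#' table(SummarizedExperiment::rowData(te)$truth)
#' @export
simulateCounts <- function(design, n_genes = 2000,
                           baseline_log_mean = 6, baseline_log_sd = 2,
                           nb_dispersion = 10,
                           frac_h1 = 0, frac_h2 = 0, frac_h3 = 0,
                           frac_pattern = 0,
                           effect_h1_log2fc = -0.42,
                           effect_h2_log2fc = -0.42,
                           effect_sd_log2 = 0.2,
                           pattern_step_log2 = 0.3,
                           depth_range = c(0.5, 2), seed = NULL) {
  design <- .validateDesign(design)
  lev <- .checkFullDesign(design)
  n_genes <- .checkCount(n_genes, "n_genes")
  if (nb_dispersion <= 0) .stopf("nb_dispersion must be > 0")
  fr <- c(frac_h1, frac_h2, frac_h3, frac_pattern)
  for (f in fr) .checkProb(f, "class fraction")
  if (sum(fr) > 1) .stopf("class fractions sum to %.3f > 1", sum(fr))

  .withSeed(seed, {
    n_cls <- round(fr * n_genes)
    truth <- rep(c("H1", "H2", "H3", "pattern", "null"),
                 c(n_cls, n_genes - sum(n_cls)))
    base <- rnorm(n_genes, baseline_log_mean, baseline_log_sd)
    e_h1 <- rnorm(n_genes, effect_h1_log2fc, effect_sd_log2)
    e_h2 <- rnorm(n_genes, effect_h2_log2fc, effect_sd_log2)

    tr_labels <- treatmentLabel(design$origin_pco2, design$destination_pco2)
    labels <- unique(tr_labels)
    mu <- .plantedMeans(truth, base, e_h1, e_h2, labels,
                        hi_home = treatmentLabel(lev[["high"]], lev[["high"]]),
                        hi_back = treatmentLabel(lev[["high"]], lev[["low"]]))
    pat <- truth == "pattern"
    if (any(pat)) {
      off <- .patternOffsets(lev)[labels]
      mu[pat, ] <- base[pat] +
        pattern_step_log2 * matrix(off, sum(pat), length(labels), byrow = TRUE)
    }

    depth <- exp(runif(nrow(design), log(depth_range[1]), log(depth_range[2])))
    mu_sample <- 2^mu[, match(tr_labels, labels), drop = FALSE]
    mu_sample <- sweep(mu_sample, 2, depth, "*")
    counts <- matrix(
      rnbinom(length(mu_sample), mu = mu_sample, size = nb_dispersion),
      n_genes, nrow(design),
      dimnames = list(sprintf("gene%05d", seq_len(n_genes)),
                      design$sample_id))
    rd <- S4Vectors::DataFrame(
      truth = factor(truth, levels = c("null", "H1", "H2", "H3", "pattern")))
    rd$mu_log2 <- mu
    te <- TransplantExperiment(counts, design, rowData = rd,
      metadata = list(params = list(
        n_genes = n_genes, baseline_log_mean = baseline_log_mean,
        baseline_log_sd = baseline_log_sd, nb_dispersion = nb_dispersion,
        frac_h1 = frac_h1, frac_h2 = frac_h2, frac_h3 = frac_h3,
        frac_pattern = frac_pattern, effect_h1_log2fc = effect_h1_log2fc,
        effect_h2_log2fc = effect_h2_log2fc, effect_sd_log2 = effect_sd_log2,
        pattern_step_log2 = pattern_step_log2, depth_range = depth_range,
        seed = seed)))
    SummarizedExperiment::colData(te)$depth_factor <- depth
    te
  })
}

#' Simulate pooled allele counts in sync layout with planted shifts
#'
#' Each origin lineage (origin x replicate: 400-A, 400-B, 900-A, 900-B,
#' 1550-A, 1550-B) carries one alternate-allele frequency per site;
#' transplanted pools inherit the frequency of their origin lineage (the
#' transplant is assumed too short for frequencies to change). "Selected"
#' sites differ by `delta_f` between the 400- and 1550-uatm lineages; all
#' other sites share one frequency across lineages. Read counts per pool
#' are `Binomial(coverage, pool frequency)` where the pool frequency is
#' either the lineage frequency itself (`"fixed_lineage_freq"`) or is first
#' resampled as `Binomial(2 * pool_size, lineage freq) / (2 * pool_size)`
#' (`"individuals_then_reads"`, the default: a pool of N diploids carries
#' only 2N chromosomes, adding variance `p(1-p)/(2N)` on top of the read
#' binomial). Sites are biallelic by construction: reference reads in the
#' A column, alternate reads in the T column.
#'
#' @param design design data.frame; pool sizes are taken from it.
#' @param n_sites number of variant sites.
#' @param coverage reads per site per pool (fixed).
#' @param delta_f planted frequency difference between the 400- and
#'   1550-uatm lineages at selected sites.
#' @param frac_selected fraction of sites carrying the shift (first block
#'   of sites, deterministically).
#' @param base_freq_range base alternate-allele frequencies are drawn
#'   uniformly in this range (selected sites: upper bound capped at
#'   `1 - delta_f` so the shifted frequency stays a probability).
#' @param pool_freq_model `"individuals_then_reads"` or
#'   `"fixed_lineage_freq"` (see above).
#' @param sites_per_contig sites are grouped into contigs of this many
#'   sites (positions 10, 20, ... within each contig).
#' @param seed integer seed.
#' @return list with `sync` (a [SyncTable-class]) and `truth` (character,
#'   "selected"/"null" per site).
#' @examples
#' design <- generateDesign(seed = 1)
#' sim <- simulatePoolSnps(design, n_sites = 50, delta_f = 0.3,
#'                         frac_selected = 0.2, seed = 3)
#' table(sim$truth)
#' @export
simulatePoolSnps <- function(design, n_sites = 1000, coverage = 50,
                             delta_f = 0, frac_selected = 0,
                             base_freq_range = c(0.1, 0.9),
                             pool_freq_model = c("individuals_then_reads",
                                                 "fixed_lineage_freq"),
                             sites_per_contig = 5, seed = NULL) {
  design <- .validateDesign(design)
  n_sites <- .checkCount(n_sites, "n_sites")
  coverage <- .checkCount(coverage, "coverage")
  .checkProb(delta_f, "delta_f")
  .checkProb(frac_selected, "frac_selected")
  pool_freq_model <- match.arg(pool_freq_model)
  lo <- base_freq_range[1]; hi <- base_freq_range[2]
  if (lo < 0 || hi > 1 || lo >= hi)
    .stopf("base_freq_range must satisfy 0 <= min < max <= 1")
  if (min(hi, 1 - delta_f) <= lo && frac_selected > 0)
    .stopf("delta_f = %.2f leaves no room in base_freq_range", delta_f)
  sites_per_contig <- .checkCount(sites_per_contig, "sites_per_contig")

  lev <- .pco2Levels(design)
  lineage <- paste(design$origin_pco2, design$replicate, sep = "-")
  lineages <- unique(lineage)
  is_high <- startsWith(lineages,
                        paste0(format(lev[["high"]], trim = TRUE), "-"))

  .withSeed(seed, {
    n_sel <- round(frac_selected * n_sites)
    truth <- rep(c("selected", "null"), c(n_sel, n_sites - n_sel))
    f0 <- runif(n_sites, lo, hi)
    if (n_sel > 0) f0[seq_len(n_sel)] <- runif(n_sel, lo, min(hi, 1 - delta_f))
    ## lineage frequencies: sites x lineages
    f_lin <- matrix(f0, n_sites, length(lineages),
                    dimnames = list(NULL, lineages))
    if (n_sel > 0)
      f_lin[seq_len(n_sel), is_high] <- f_lin[seq_len(n_sel), is_high] +
        delta_f

    counts <- array(0, dim = c(n_sites, nrow(design), 6L),
                    dimnames = list(NULL, design$sample_id, .syncAlleles))
    for (j in seq_len(nrow(design))) {
      f <- f_lin[, lineage[j]]
      if (pool_freq_model == "individuals_then_reads") {
        chrom <- 2L * design$pool_size[j]
        f <- rbinom(n_sites, chrom, f) / chrom
      }
      alt <- rbinom(n_sites, coverage, f)
      counts[, j, "T"] <- alt
      counts[, j, "A"] <- coverage - alt
    }
    contig <- sprintf("contig%05d", (seq_len(n_sites) - 1L) %/%
                        sites_per_contig + 1L)
    pos <- 10L * (((seq_len(n_sites) - 1L) %% sites_per_contig) + 1L)
    list(sync = SyncTable(contig, pos, rep("A", n_sites), counts),
         truth = truth)
  })
}

#' Simulate a flat gene-to-GO-term annotation map with one planted term
#'
#' Background terms annotate each gene independently with a per-term
#' frequency drawn uniformly in `background_freq_range`. The planted term
#' annotates genes in `planted_genes` with probability
#' `min(1, enrichment_factor * planted_background_freq)` and all other
#' genes at `planted_background_freq`.
#'
#' @param gene_ids character vector, the annotation universe.
#' @param n_terms number of background terms (`GO:B0001`, ...).
#' @param planted_genes subset of `gene_ids` over-annotated with the
#'   planted term `GO:PLANTED`.
#' @param enrichment_factor fold over-representation of the planted term in
#'   `planted_genes` (1 = no enrichment).
#' @param planted_background_freq planted-term frequency outside
#'   `planted_genes`.
#' @param background_freq_range range of background term frequencies.
#' @param seed integer seed.
#' @return data.frame with columns `gene_id`, `term` (one row per
#'   annotation pair).
#' @export
simulateGoAnnotations <- function(gene_ids, n_terms = 50,
                                  planted_genes = character(),
                                  enrichment_factor = 1,
                                  planted_background_freq = 0.05,
                                  background_freq_range = c(0.01, 0.1),
                                  seed = NULL) {
  if (!length(gene_ids)) .stopf("empty annotation universe")
  if (anyDuplicated(gene_ids)) .stopf("duplicated gene ids")
  if (length(setdiff(planted_genes, gene_ids)))
    .stopf("planted_genes must be a subset of gene_ids")
  n_terms <- .checkCount(n_terms, "n_terms", min = 0L)
  if (enrichment_factor < 0) .stopf("enrichment_factor must be >= 0")
  .withSeed(seed, {
    pairs <- list()
    for (t in seq_len(n_terms)) {
      p <- runif(1, background_freq_range[1], background_freq_range[2])
      hit <- gene_ids[runif(length(gene_ids)) < p]
      if (length(hit))
        pairs[[length(pairs) + 1L]] <-
          data.frame(gene_id = hit, term = sprintf("GO:B%04d", t))
    }
    p_in <- min(1, enrichment_factor * planted_background_freq)
    in_sub <- gene_ids %in% planted_genes
    p_gene <- ifelse(in_sub, p_in, planted_background_freq)
    hit <- gene_ids[runif(length(gene_ids)) < p_gene]
    if (length(hit))
      pairs[[length(pairs) + 1L]] <-
        data.frame(gene_id = hit, term = "GO:PLANTED")
    out <- do.call(rbind, pairs)
    if (is.null(out)) out <- data.frame(gene_id = character(),
                                        term = character())
    rownames(out) <- NULL
    out
  })
}
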