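## Replicate-stratified Cochran-Mantel-Haenszel screen for consistent
## allele-frequency differences between the control (400 uatm) and
## high-pCO2 (1550 uatm) lineages in pooled sequencing data.
##
## The statistic, for strata k with 2x2 cells [[a, b], [c, d]], row sums
## r1, r2, column sums c1, c2 and total n:
##
##   X^2 = ( |sum_k (a_k - E_k)| - cc )^2 / sum_k V_k,
##   E_k = r1_k c1_k / n_k,  V_k = r1_k r2_k c1_k c2_k / (n_k^2 (n_k - 1)),
##
## with cc = 1/2 under the continuity correction (off by default), referred
## to a chi-square with 1 df. Strata with any zero margin contribute
## nothing and are not counted. Implemented directly (and vectorised in
## the site scan); stats::mantelhaen.test is the independent oracle in the
## tests.

#' Default replicate pairing for the CMH screen
#'
#' Pools are paired so each stratum opposes a 400-lineage pool to a
#' 1550-lineage pool of the same replicate: the natives (400->400 vs
#' 1550->1550, per replicate), and the transplants — 400->1550 pools are
#' treated as additional replicates of the 400 lineage and 1550->400 pools
#' of the 1550 lineage, since allele frequencies are assumed unchanged
#' over the transplant itself. With two replicate populations this yields
#' four strata. The 900-uatm pools take no part.
#'
#' @param design design data.frame.
#' @return data.frame with columns `pool_400`, `pool_1550` (sample ids),
#'   one row per stratum.
#' @export
cmhPairing <- function(design) {
  design <- .validateDesign(design)
  lev <- .pco2Levels(design)
  lo <- lev[["low"]]; hi <- lev[["high"]]
  sid <- function(o, d, r) {
    i <- which(design$origin_pco2 == o & design$destination_pco2 == d &
                 design$replicate == r)
    if (length(i) != 1L)
      .stopf("no unique sample for treatment %s replicate %s",
             treatmentLabel(o, d), r)
    design$sample_id[i]
  }
  reps <- sort(unique(design$replicate))
  rows <- lapply(reps, function(r)
    data.frame(pool_400 = c(sid(lo, lo, r), sid(lo, hi, r)),
               pool_1550 = c(sid(hi, hi, r), sid(hi, lo, r))))
  do.call(rbind, rows)
}

#' Reduce a sync site to two alleles and testability
#'
#' For each site, the two nucleotides with the highest summed read counts
#' across the used pools are retained (N and deletion columns never count
#' as alleles; ties break on sync column order A, T, C, G). The site is
#' testable iff every used pool has coverage at those two alleles of at
#' least `min_coverage` and the total minor-allele count across pools is
#' at least `min_minor_count`.
#'
#' @param sync a [SyncTable-class].
#' @param pools character vector of pool (sample) ids to use.
#' @param min_minor_count minimum global minor-allele read count.
#' @param min_coverage minimum per-pool coverage at the two alleles.
#' @return list with `allele1`, `allele2` (character per site), `counts1`,
#'   `counts2` (sites x pools read-count matrices) and `testable`
#'   (logical per site).
#' @export
callBiallelic <- function(sync, pools, min_minor_count = 2,
                          min_coverage = 10) {
  stopifnot(is(sync, "SyncTable"))
  miss <- setdiff(pools, poolNames(sync))
  if (length(miss))
    .stopf("pool(s) not in sync table: %s", paste(miss, collapse = ", "))
  nuc <- c("A", "T", "C", "G")
  cnt <- sync@counts[, pools, nuc, drop = FALSE]
  tot <- apply(cnt, c(1, 3), sum)                      # sites x 4
  if (nSites(sync) == 1L) tot <- matrix(tot, 1, dimnames = list(NULL, nuc))
  i1 <- max.col(tot, ties.method = "first")
  tot2 <- tot
  tot2[cbind(seq_len(nrow(tot)), i1)] <- -1
  i2 <- max.col(tot2, ties.method = "first")
  n <- nSites(sync)
  counts1 <- counts2 <- matrix(0, n, length(pools),
                               dimnames = list(NULL, pools))
  for (j in seq_along(pools)) {
    cj <- cnt[, j, , drop = FALSE]
    dim(cj) <- c(n, 4L)
    counts1[, j] <- cj[cbind(seq_len(n), i1)]
    counts2[, j] <- cj[cbind(seq_len(n), i2)]
  }
  minor <- pmin(tot[cbind(seq_len(n), i1)], tot[cbind(seq_len(n), i2)])
  cov_ok <- rowSums(counts1 + counts2 >= min_coverage) == length(pools)
  list(allele1 = nuc[i1], allele2 = nuc[i2],
       counts1 = counts1, counts2 = counts2,
       testable = cov_ok & minor >= min_minor_count)
}

## Vectorised CMH over sites: a1/a2 = allele1/allele2 counts, each a
## sites x (2K) matrix with the 400-lineage pool of stratum k in column
## 2k-1 and the 1550-lineage pool in column 2k.
.cmhVec <- function(a1, a2, continuity_correction = FALSE) {
  K <- ncol(a1) / 2L
  i400 <- 2L * seq_len(K) - 1L
  i1550 <- 2L * seq_len(K)
  a <- a1[, i400, drop = FALSE]
  b <- a1[, i1550, drop = FALSE]
  c_ <- a2[, i400, drop = FALSE]
  d <- a2[, i1550, drop = FALSE]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  n <- r1 + r2
  ok <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
  delta <- ifelse(ok, a - r1 * c1 / n, 0)
  V <- ifelse(ok, r1 * r2 * c1 * c2 / (n^2 * (n - 1)), 0)
  sumD <- rowSums(delta)
  sumV <- rowSums(V)
  ## Yates-style: the half-unit correction only applies when the absolute
  ## deviation exceeds it (as in the standard reference implementation)
  cc <- ifelse(continuity_correction & abs(sumD) >= 0.5, 0.5, 0)
  num <- (abs(sumD) - cc)^2
  stat <- ifelse(sumV > 0, num / sumV, NA_real_)
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE),
       strata_used = rowSums(ok),
       freq_diff = a / pmax(c1, 1) - b / pmax(c2, 1))
}

#' Cochran-Mantel-Haenszel test over 2x2 strata
#'
#' @param strata list of 2x2 matrices (rows: allele 1 / allele 2;
#'   columns: 400-lineage pool / 1550-lineage pool), one per replicate
#'   stratum.
#' @param continuity_correction subtract 1/2 from the absolute deviation
#'   before squaring (off by default: the classical statistic).
#' @return list of class `"cmhResult"`: `statistic`, `p` (upper tail of
#'   chi-square, 1 df), `strata_used` (strata with all margins positive),
#'   `freq_diff` (per-stratum allele-1 frequency difference, 400 minus
#'   1550 column) and `untestable` (TRUE when all strata are degenerate,
#'   in which case statistic and p are NA).
#' @examples
#' cmhTest(list(matrix(c(10, 0, 0, 10), 2)))$statistic  # 19
#' @export
cmhTest <- function(strata, continuity_correction = FALSE) {
  if (!is.list(strata) || !length(strata))
    .stopf("strata must be a non-empty list of 2x2 tables")
  for (s in strata)
    if (!is.matrix(s) || !identical(dim(s), c(2L, 2L)) || any(s < 0))
      .stopf("each stratum must be a non-negative 2x2 matrix")
  a1 <- matrix(unlist(lapply(strata, function(s) s[1, ])), 1)
  a2 <- matrix(unlist(lapply(strata, function(s) s[2, ])), 1)
  v <- .cmhVec(a1, a2, continuity_correction)
  structure(list(statistic = v$statistic, p = v$p,
                 strata_used = v$strata_used,
                 freq_diff = drop(v$freq_diff),
                 untestable = is.na(v$statistic)),
            class = "cmhResult")
}

#' @export
print.cmhResult <- function(x, ...) {
  if (x$untestable) {
    cat("CMH test: untestable (all strata have a zero margin)\n")
  } else {
    cat(sprintf("CMH chi-square = %.4g on 1 df, p = %.4g (%d strata)\n",
                x$statistic, x$p, x$strata_used))
  }
  invisible(x)
}

#' Scan a sync table for consistent allele-frequency changes
#'
#' Calls the top two alleles per site ([callBiallelic()]), runs the CMH
#' test across the replicate strata of `pairing`, and applies Bonferroni
#' correction with denominator equal to the number of testable sites in
#' this run.
#'
#' @param sync a [SyncTable-class].
#' @param design design data.frame.
#' @param pairing stratum pairing as from [cmhPairing()] (the default).
#' @param alpha family-wise error target (default 0.05).
#' @param min_minor_count,min_coverage testability thresholds, see
#'   [callBiallelic()].
#' @param continuity_correction see [cmhTest()].
#' @return `DataFrame`, one row per site: `contig`, `position`, `allele1`,
#'   `allele2`, `testable`, `statistic`, `p`, `strata_used`,
#'   `significant` (Bonferroni-corrected at `alpha`), and `freq_400` /
#'   `freq_1550` (mean allele-1 frequency over the lineage's pools).
#'   `metadata()` records `n_testable`, the Bonferroni `threshold`,
#'   `significant_contigs` (distinct contigs with at least one significant
#'   site) and the thresholds used.
#' @examples
#' design <- generateDesign(seed = 1)
#' sim <- simulatePoolSnps(design, n_sites = 100, coverage = 60,
#'                         delta_f = 0.5, frac_selected = 0.1, seed = 2)
#' res <- cmhScan(sim$sync, design)
#' S4Vectors::metadata(res)$n_testable
#' @export
cmhScan <- function(sync, design, pairing = cmhPairing(design),
                    alpha = 0.05, min_minor_count = 2, min_coverage = 10,
                    continuity_correction = FALSE) {
  stopifnot(is(sync, "SyncTable"))
  design <- .validateDesign(design)
  .checkProb(alpha, "alpha")
  if (!all(c("pool_400", "pool_1550") %in% colnames(pairing)))
    .stopf("pairing needs columns pool_400, pool_1550")
  used <- c(rbind(pairing$pool_400, pairing$pool_1550))
  if (anyDuplicated(used))
    .stopf("each pool may be used in at most one stratum")
  miss <- setdiff(used, design$sample_id)
  if (length(miss))
    .stopf("pairing sample(s) absent from design: %s",
           paste(miss, collapse = ", "))
  call <- callBiallelic(sync, used, min_minor_count, min_coverage)
  v <- .cmhVec(call$counts1, call$counts2, continuity_correction)
  testable <- call$testable & !is.na(v$statistic)
  m <- sum(testable)
  if (m == 0) warning("no testable site in this run")
  threshold <- if (m > 0) alpha / m else NA_real_
  sig <- testable & !is.na(v$p) & v$p <= threshold
  K <- nrow(pairing)
  f400 <- rowMeans(call$counts1[, 2 * seq_len(K) - 1, drop = FALSE] /
    pmax(call$counts1[, 2 * seq_len(K) - 1, drop = FALSE] +
         call$counts2[, 2 * seq_len(K) - 1, drop = FALSE], 1))
  f1550 <- rowMeans(call$counts1[, 2 * seq_len(K), drop = FALSE] /
    pmax(call$counts1[, 2 * seq_len(K), drop = FALSE] +
         call$counts2[, 2 * seq_len(K), drop = FALSE], 1))
  out <- S4Vectors::DataFrame(
    contig = sync@contig, position = sync@position,
    allele1 = call$allele1, allele2 = call$allele2,
    testable = testable,
    statistic = ifelse(testable, v$statistic, NA_real_),
    p = ifelse(testable, v$p, NA_real_),
    strata_used = v$strata_used,
    significant = sig,
    freq_400 = f400, freq_1550 = f1550)
  S4Vectors::metadata(out) <- list(
    n_testable = m, alpha = alpha, threshold = threshold,
    significant_contigs = unique(sync@contig[sig]),
    min_minor_count = min_minor_count, min_coverage = min_coverage,
    continuity_correction = continuity_correction,
    pairing = pairing)
  out
}
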