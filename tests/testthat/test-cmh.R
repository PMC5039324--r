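randomStratum <- function(max_n = 60) {
  matrix(rpois(4, sample(3:max_n, 1)) + 1, 2, 2)
}

test_that("CMH closed-form fixtures hold exactly", {
  r <- cmhTest(list(matrix(c(10, 0, 0, 10), 2)))
  expect_equal(r$statistic, 19)  # (n-1)/n * Pearson = 19/20 * 20
  r0 <- cmhTest(list(matrix(c(5, 5, 5, 5), 2)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
})

test_that("single-stratum CMH equals (n-1)/n times Pearson chi-square", {
  set.seed(61)
  for (i in 1:300) {
    m <- randomStratum()
    n <- sum(m)
    expect_equal(cmhTest(list(m))$statistic,
                 (n - 1) / n * pearsonChisq2x2(m), tolerance = 1e-12)
  }
})

test_that("CMH agrees with the stats::mantelhaen.test oracle across strata", {
  set.seed(62)
  for (i in 1:50) {
    strata <- replicate(4, randomStratum(), simplify = FALSE)
    arr <- array(unlist(strata), c(2, 2, 4))
    ours <- cmhTest(strata)
    ref <- mantelhaen.test(arr, correct = FALSE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    refc <- mantelhaen.test(arr, correct = TRUE)
    expect_equal(cmhTest(strata, continuity_correction = TRUE)$statistic,
                 unname(refc$statistic), tolerance = 1e-10)
  }
})

test_that("CMH is invariant to label swaps and strata order, and doubles on duplication", {
  set.seed(63)
  strata <- replicate(3, randomStratum(), simplify = FALSE)
  s0 <- cmhTest(strata)$statistic
  swap_rows <- lapply(strata, function(m) m[2:1, ])
  swap_cols <- lapply(strata, function(m) m[, 2:1])
  expect_equal(cmhTest(swap_rows)$statistic, s0, tolerance = 1e-12)
  expect_equal(cmhTest(swap_cols)$statistic, s0, tolerance = 1e-12)
  expect_equal(cmhTest(rev(strata))$statistic, s0, tolerance = 1e-12)
  expect_equal(cmhTest(c(strata, strata))$statistic, 2 * s0,
               tolerance = 1e-12)
  # deeper sequencing increases the statistic
  for (m in c(2, 5, 10))
    expect_gt(cmhTest(lapply(strata, function(s) s * m))$statistic, s0)
})

test_that("zero-margin strata are excluded and degenerate input flagged", {
  good <- matrix(c(12, 3, 4, 11), 2)
  empty_row <- matrix(c(0, 5, 0, 7), 2, byrow = TRUE)  # row1 = 0, 0
  r <- cmhTest(list(good, empty_row))
  expect_equal(r$statistic, cmhTest(list(good))$statistic)
  expect_equal(r$strata_used, 1L)
  all_bad <- cmhTest(list(empty_row))
  expect_true(all_bad$untestable)
  expect_true(is.na(all_bad$p))
  expect_error(cmhTest(list()), "non-empty")
  expect_error(cmhTest(list(matrix(1:6, 2))), "2x2")
})

test_that("biallelic calling keeps the top two nucleotides and flags testability", {
  d <- smallDesign()
  pools <- d$sample_id[1:4]
  mk <- function(per_pool) {
    counts <- array(0, c(1, 4, 6),
                    dimnames = list(NULL, pools,
                                    c("A", "T", "C", "G", "N", "del")))
    for (j in 1:4) counts[1, j, ] <- per_pool
    SyncTable("c1", 1L, "A", counts)
  }
  # monomorphic: minor count 0 < 2 -> untestable
  mono <- callBiallelic(mk(c(10, 0, 0, 0, 0, 0)), pools)
  expect_false(mono$testable)
  # A=7, T=3, coverage 10: thresholds met exactly
  bi <- callBiallelic(mk(c(7, 3, 0, 0, 0, 0)), pools)
  expect_true(bi$testable)
  expect_equal(bi$allele1, "A"); expect_equal(bi$allele2, "T")
  expect_equal(unname(bi$counts1[1, ]), rep(7, 4))
  # three alleles: C reads are discarded by the top-two rule
  tri <- callBiallelic(mk(c(50, 49, 1, 0, 0, 0)), pools)
  expect_equal(sort(c(tri$allele1, tri$allele2)), c("A", "T"))
  # N and del columns never become alleles
  nn <- callBiallelic(mk(c(7, 3, 0, 0, 99, 99)), pools)
  expect_setequal(c(nn$allele1, nn$allele2), c("A", "T"))
  # per-pool coverage below threshold -> untestable
  low <- callBiallelic(mk(c(5, 3, 0, 0, 0, 0)), pools)
  expect_false(low$testable)
})

test_that("default pairing builds the four 400-vs-1550 replicate strata", {
  d <- smallDesign()
  pr <- cmhPairing(d)
  expect_equal(nrow(pr), 4L)
  expect_setequal(pr$pool_400, c("400-400A", "400-1550A",
                                 "400-400B", "400-1550B"))
  expect_setequal(pr$pool_1550, c("1550-1550A", "1550-400A",
                                  "1550-1550B", "1550-400B"))
  # 900-uatm pools take no part
  expect_false(any(grepl("900", unlist(pr[, c("pool_400", "pool_1550")]))))
})

test_that("cmhScan applies Bonferroni over testable sites and rolls up contigs", {
  d <- smallDesign()
  # strongly shifted single site: significant with m = 1
  counts <- array(0, c(1, 14, 6),
                  dimnames = list(NULL, d$sample_id,
                                  c("A", "T", "C", "G", "N", "del")))
  f <- c(rep(0.1, 1), rep(0.9, 1))
  pr <- cmhPairing(d)
  for (j in seq_len(14)) {
    hi <- d$sample_id[j] %in% pr$pool_1550
    alt <- round(ifelse(hi, 0.9, 0.1) * 50)
    counts[1, j, "T"] <- alt
    counts[1, j, "A"] <- 50 - alt
  }
  sync <- SyncTable("ctgX", 7L, "A", counts)
  res <- cmhScan(sync, d)
  expect_true(res$testable[1])
  expect_true(res$significant[1])
  expect_equal(S4Vectors::metadata(res)$n_testable, 1L)
  expect_equal(S4Vectors::metadata(res)$threshold, 0.05)
  expect_equal(S4Vectors::metadata(res)$significant_contigs, "ctgX")
  # reusing a pool across strata is rejected
  bad <- pr; bad$pool_1550[2] <- bad$pool_1550[1]
  expect_error(cmhScan(sync, d, pairing = bad), "at most one stratum")
  # zero testable sites warns
  counts0 <- counts; counts0[1, , ] <- 0; counts0[1, , "A"] <- 50
  expect_warning(cmhScan(SyncTable("c1", 1L, "A", counts0), d),
                 "no testable")
})

test_that("planted frequency shifts are detected and nulls are not", {
  d <- smallDesign()
  sim <- simulatePoolSnps(d, n_sites = 400, coverage = 80, delta_f = 0.5,
                          frac_selected = 0.1,
                          pool_freq_model = "fixed_lineage_freq", seed = 64)
  res <- cmhScan(sim$sync, d)
  sel <- sim$truth == "selected"
  expect_gt(mean(res$significant[sel]), 0.8)
  expect_lt(mean(res$significant[!sel]), 0.01)
})
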