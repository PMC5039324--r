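test_that("generateDesign emulates the 14-pool reciprocal-transplant layout", {
  d <- generateDesign(2, c(28, 76), seed = 1)
  expect_equal(nrow(d), 14L)
  tr <- table(treatmentLabel(d$origin_pco2, d$destination_pco2))
  expect_length(tr, 7L)
  expect_true(all(tr == 2L))
  expect_true(all(d$pool_size >= 28 & d$pool_size <= 76))
  expect_false(anyDuplicated(d$sample_id) > 0)

  d1 <- generateDesign(1, c(10, 10), seed = 99)
  expect_equal(nrow(d1), 7L)
  expect_true(all(d1$pool_size == 10L))
  expect_equal(nrow(generateDesign(3, c(5, 5), seed = 2)), 21L)
})

test_that("generateDesign rejects invalid parameters", {
  expect_error(generateDesign(0, c(10, 20)), "replicates_per_treatment")
  expect_error(generateDesign(2, c(20, 10)), "pool_size_range")
  expect_error(generateDesign(2, c(0, 10)), "pool_size_range")
})

test_that("simulation is reproducible under a seed and varies across seeds", {
  d <- smallDesign()
  t1 <- simulateCounts(d, n_genes = 40, frac_h2 = 0.2, seed = 5)
  t2 <- simulateCounts(d, n_genes = 40, frac_h2 = 0.2, seed = 5)
  t3 <- simulateCounts(d, n_genes = 40, frac_h2 = 0.2, seed = 6)
  expect_identical(SummarizedExperiment::assay(t1),
                   SummarizedExperiment::assay(t2))
  expect_false(identical(SummarizedExperiment::assay(t1),
                         SummarizedExperiment::assay(t3)))
  s1 <- simulatePoolSnps(d, n_sites = 30, seed = 5)
  s2 <- simulatePoolSnps(d, n_sites = 30, seed = 5)
  s3 <- simulatePoolSnps(d, n_sites = 30, seed = 6)
  expect_identical(syncCounts(s1$sync), syncCounts(s2$sync))
  expect_false(identical(syncCounts(s1$sync), syncCounts(s3$sync)))
})

test_that("gene class fractions are realized deterministically", {
  d <- smallDesign()
  te <- simulateCounts(d, n_genes = 100, frac_h1 = 0.13, frac_h2 = 0.07,
                       frac_h3 = 0.031, frac_pattern = 0.02, seed = 1)
  truth <- SummarizedExperiment::rowData(te)$truth
  expect_equal(as.vector(table(truth)[c("H1", "H2", "H3", "pattern")]),
               c(13L, 7L, 3L, 2L))
  expect_error(simulateCounts(d, n_genes = 10, frac_h1 = 0.6, frac_h2 = 0.6),
               "sum")
  te0 <- simulateCounts(d, n_genes = 30, seed = 2)
  expect_true(all(SummarizedExperiment::rowData(te0)$truth == "null"))
})

test_that("planted H2 genes shift all 1550-origin means by the stated log2 fc", {
  d <- smallDesign()
  te <- simulateCounts(d, n_genes = 50, frac_h2 = 0.5,
                       effect_h2_log2fc = -0.42, effect_sd_log2 = 0,
                       seed = 3)
  rd <- SummarizedExperiment::rowData(te)
  mu <- rd$mu_log2
  h2 <- rd$truth == "H2"
  # expected 1550-origin / 400-origin mean ratio = 2^(-0.42), no slope change
  expect_equal(unname(mu[h2, "1550->1550"] - mu[h2, "400->400"]),
               rep(-0.42, sum(h2)))
  expect_equal(unname(mu[h2, "1550->400"] - mu[h2, "400->400"]),
               rep(-0.42, sum(h2)))
  # H1 genes pivot: elevation (midpoint mean) preserved
  te1 <- simulateCounts(d, n_genes = 50, frac_h1 = 0.5, effect_sd_log2 = 0,
                        seed = 4)
  rd1 <- SummarizedExperiment::rowData(te1)
  mu1 <- rd1$mu_log2
  h1 <- rd1$truth == "H1"
  expect_equal(
    unname((mu1[h1, "1550->1550"] + mu1[h1, "1550->400"]) / 2),
    unname((mu1[h1, "400->400"] + mu1[h1, "400->1550"]) / 2))
  expect_false(any(mu1[h1, "1550->1550"] == mu1[h1, "1550->400"]))
  # 400- and 900-origin lines are untouched for planted H-class genes
  for (lab in c("400->400", "400->900", "400->1550", "900->900", "900->400"))
    expect_equal(unname(mu1[h1, lab]),
                 unname(mu1[h1, "400->400"]) + c(0))
})

test_that("planted pattern genes satisfy all 8 inequalities on noise-free means", {
  d <- smallDesign()
  te <- simulateCounts(d, n_genes = 60, frac_pattern = 0.3, seed = 7)
  rd <- SummarizedExperiment::rowData(te)
  mu <- rd$mu_log2
  pat <- rd$truth == "pattern"
  expect_true(all(matchesPattern(mu[pat, , drop = FALSE])))
  expect_false(any(matchesPattern(mu[!pat, , drop = FALSE])))
})

test_that("null counts follow negative-binomial moments", {
  # one shared mean across genes and samples, no depth heterogeneity:
  # every count is an iid NB(mu, k) draw; var ~= mu + mu^2/k
  d <- smallDesign()
  k <- 5
  te <- simulateCounts(d, n_genes = 1000, baseline_log_mean = 7,
                       baseline_log_sd = 0, nb_dispersion = k,
                       depth_range = c(1, 1), seed = 8)
  x <- as.vector(SummarizedExperiment::assay(te))  # 14000 draws
  mu <- 2^7
  expect_equal(mean(x), mu, tolerance = 0.02)
  expect_equal(var(x), mu + mu^2 / k, tolerance = 0.1)
})

test_that("pool read-frequency variance follows the two-stage law of total variance", {
  # Var(f_hat) = p(1-p) (1/(2N) + (1 - 1/(2N))/C) under individuals-then-reads
  d <- generateDesign(2, c(20, 20), seed = 1)   # all pools N = 20
  p <- 0.3; C <- 50
  sim <- simulatePoolSnps(d, n_sites = 40000, coverage = C,
                          base_freq_range = c(p - 1e-9, p + 1e-9),
                          pool_freq_model = "individuals_then_reads",
                          seed = 9)
  f <- syncCounts(sim$sync)[, 1, "T"] / C
  N <- 20
  v_theory <- p * (1 - p) * (1 / (2 * N) + (1 - 1 / (2 * N)) / C)
  expect_equal(var(f), v_theory, tolerance = 0.05)
  # fixed-frequency model: plain binomial variance p(1-p)/C
  sim2 <- simulatePoolSnps(d, n_sites = 40000, coverage = C,
                           base_freq_range = c(p - 1e-9, p + 1e-9),
                           pool_freq_model = "fixed_lineage_freq", seed = 10)
  f2 <- syncCounts(sim2$sync)[, 1, "T"] / C
  expect_equal(var(f2), p * (1 - p) / C, tolerance = 0.05)
})

test_that("planted SNP shifts and boundary frequencies behave as constructed", {
  d <- smallDesign()
  s0 <- simulatePoolSnps(d, n_sites = 50, delta_f = 0, seed = 1)
  expect_true(all(s0$truth == "null"))
  # frequency ~0 everywhere: all reads are the reference allele
  s1 <- simulatePoolSnps(d, n_sites = 50, base_freq_range = c(0, 1e-12),
                         pool_freq_model = "fixed_lineage_freq", seed = 2)
  expect_true(all(syncCounts(s1$sync)[, , "T"] == 0))
  expect_true(all(syncCounts(s1$sync)[, , "A"] == 50))
  # selected sites: 1550-lineage pools carry the shifted frequency
  s2 <- simulatePoolSnps(d, n_sites = 4000, coverage = 200, delta_f = 0.4,
                         frac_selected = 0.5, base_freq_range = c(0.2, 0.5),
                         pool_freq_model = "fixed_lineage_freq", seed = 3)
  sel <- s2$truth == "selected"
  f <- syncCounts(s2$sync)[, , "T"] / 200
  d400 <- rowMeans(f[, c("400-400A", "400-1550A")])
  d1550 <- rowMeans(f[, c("1550-1550A", "1550-400A")])
  expect_equal(mean(d1550[sel] - d400[sel]), 0.4, tolerance = 0.02)
  expect_equal(mean(d1550[!sel] - d400[!sel]), 0, tolerance = 0.02)
})

test_that("simulated GO annotations plant the requested enrichment", {
  genes <- sprintf("g%04d", 1:4000)
  sub <- genes[1:400]
  # factor 1: subset frequency matches background
  m1 <- simulateGoAnnotations(genes, n_terms = 0, planted_genes = sub,
                              enrichment_factor = 1,
                              planted_background_freq = 0.2, seed = 1)
  f_in <- mean(sub %in% m1$gene_id)
  f_out <- mean(setdiff(genes, sub) %in% m1$gene_id)
  expect_lt(abs(f_in - f_out), 0.08)
  # factor 20 with background 5%: subset fully annotated
  m2 <- simulateGoAnnotations(genes, n_terms = 0, planted_genes = sub,
                              enrichment_factor = 20,
                              planted_background_freq = 0.05, seed = 2)
  expect_true(all(sub %in% m2$gene_id[m2$term == "GO:PLANTED"]))
  expect_error(simulateGoAnnotations(character()), "empty")
  expect_error(simulateGoAnnotations(genes, planted_genes = "nope"),
               "subset")
})
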