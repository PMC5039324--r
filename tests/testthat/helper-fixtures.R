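# Shared fixtures and independent oracles used across test files.

smallDesign <- function(replicates = 2, pool = c(30, 70), seed = 11) {
  generateDesign(replicates, pool, seed = seed)
}

# The seven treatment labels in canonical order.
trLabels <- c("400->400", "900->900", "1550->1550", "400->900",
              "400->1550", "900->400", "1550->400")

# Treatment-mean fixture satisfying all 8 pattern inequalities.
patternTrueMeans <- function() {
  c("400->400" = 1.0, "400->900" = 0.8, "900->900" = 0.7,
    "900->400" = 1.1, "400->1550" = 0.9, "1550->1550" = 0.6,
    "1550->400" = 0.5)
}

# Build an expression matrix from per-treatment means + iid normal noise.
exprFromMeans <- function(means, design, n_genes = 1, sd = 0) {
  labs <- treatmentLabel(design$origin_pco2, design$destination_pco2)
  mu <- matrix(means[labs], n_genes, nrow(design), byrow = TRUE)
  mat <- mu + matrix(rnorm(length(mu), 0, sd), nrow(mu))
  dimnames(mat) <- list(sprintf("g%03d", seq_len(n_genes)), design$sample_id)
  mat
}

# Pearson chi-square of a 2x2 table, written independently of the package.
pearsonChisq2x2 <- function(m) {
  n <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / n
  sum((m - e)^2 / e)
}

# All permutations of 1..n (recursive prefix construction); independent
# oracle for the pattern null match rate.
allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Exact probability that 7 exchangeable (tie-free) treatment means satisfy
# the 8-inequality pattern: fraction of the 5040 rank orders consistent
# with the partial order.
patternNullRate <- function() {
  perms <- allPerms(7)
  labs <- c("400->400", "400->900", "900->900", "900->400", "400->1550",
            "1550->1550", "1550->400")
  hits <- apply(perms, 1, function(p) {
    m <- setNames(p, labs)
    matchesPattern(m)
  })
  mean(hits)
}

# One CMH null/shifted pool-seq experiment scanned end to end.
cmhExperiment <- function(design, n_sites, delta_f, frac_selected, seed,
                          coverage = 50) {
  sim <- simulatePoolSnps(design, n_sites = n_sites, coverage = coverage,
                          delta_f = delta_f, frac_selected = frac_selected,
                          pool_freq_model = "fixed_lineage_freq",
                          seed = seed)
  list(truth = sim$truth, scan = cmhScan(sim$sync, design))
}
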