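---
title: "Methods: reciprocal-transplant expression scans and pool-seq CMH screening"
author: "transplantScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reciprocal-transplant expression scans and pool-seq CMH screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transplantScan)
```

# The experimental design this package analyses

A two-generation reciprocal-transplant experiment: copepod populations are
raised for two generations at three pCO2 levels (400, 900 and 1550 uatm,
two replicate populations each), after which adults are transplanted —
control animals up to 900 and 1550 uatm, acclimated animals back to
400 uatm — and each of the seven resulting treatments is sequenced as
pooled RNA (two replicate pools per treatment, 14 pools in all, 28–76
individuals per pool). Two questions drive the downstream analysis:

1. **Expression**: which genes changed their *reaction norm* (expression as
   a function of destination pCO2) after two generations at high pCO2 —
   a change in slope (plasticity), in level (phenotype), or both?
2. **Allele frequencies**: at which variant sites did the high-pCO2
   lineages shift allele frequency *consistently across replicates*,
   suggesting selection on standing variation rather than drift?

`TransplantExperiment` (a `SummarizedExperiment` whose `colData` holds the
origin/destination/replicate/pool-size design) carries the expression
side; `SyncTable` carries per-site, per-pool `A:T:C:G:N:del` read counts
in the PoPoolation2 sync layout (1-based positions throughout).

# Expression preparation

Isoforms sharing an assembly component *and* an annotation string are
summed into one "unigene" (`collapseIsoforms()`; per-sample totals are
conserved exactly). Counts are scale-normalized with median-of-ratios
size factors (`medianRatioSizeFactors()`): the pseudo-reference is the
per-gene geometric mean over samples computed in log space, restricted to
genes positive in every sample, and sample j's factor is the median ratio
to that reference. Genes are then filtered (`filterGenes()`): a gene is
dropped iff its sample standard deviation exceeds its mean or any sample
is zero. Two wordings of this screen circulate ("standard deviation
greater than mean" vs "variance greater than mean"); the SD form is the
default and the variance form is available as `rule = "variance"`. The SD
uses the n−1 denominator — a convention choice, stated here because the
rule's source does not specify it. The filter is applied after
normalization and is idempotent.

# The ANCOVA hypothesis scan

For one gene, expression of an origin population observed at two
destination pCO2 levels defines a regression line. Two lines are compared
with the centered full-interaction model

$$ y = b_0 + b_1\,(x - \bar x) + b_2\,g + b_3\,g\,(x - \bar x), \qquad
   g = \mp\tfrac12, $$

where $\bar x$ is the midpoint of the two destinations. With this coding
$b_2$ is exactly the between-line difference at the midpoint (the
*elevation* difference) and $b_3$ the difference in slopes; both get
two-sided t-tests on $n-4$ residual df (8 points and 4 df with two
replicate pools). The elevation is deliberately tested at the covariate
midpoint rather than at $x=0$: with an intercept-coded model the
"elevation" test would depend on the arbitrary origin of the pCO2 axis.
A classical sequential ANCOVA (common-slope model first) was considered
and not used, because the slope-difference test is the primary contrast
here and the full-interaction model keeps both contrasts orthogonal in
the balanced design.

`classifyGene()` then applies the screen:

* **Precondition** (plasticity between control and mid): the 400-origin
  line over destinations {400, 900} and the 900-origin line over the same
  destinations differ in *neither* slope nor elevation (both p > alpha).
* On the high pair — 400-origin over {400, 1550} vs 1550-origin:
  different slopes only → **H1** (transgenerational change of
  plasticity); different elevation only → **H2** (transgenerational
  change of phenotype); both → **H3**; otherwise **none**.

Decisions worth stating plainly:

* Analysis scale defaults to `log2(normalized + 1)`; the linear model and
  normality check presuppose roughly symmetric noise, which raw counts do
  not give. `scale = "raw"` is available.
* Ties at exactly p = alpha count as significant (`<=`).
* The Shapiro–Wilk statistic on pooled residuals is reported as a
  diagnostic only; genes are never excluded on it.
* H1 and H2 require the *other* contrast to be non-significant — the
  classes are mutually exclusive by construction.
* **No multiple-testing correction is applied across genes.** The scan is
  a per-gene classification at a fixed alpha, exactly as the screen is
  defined; class counts on ~16 000 genes at alpha = 0.05 contain false
  positives by design and must be read as a screen, not a discovery list.
* Per-sample values enter the regressions (n = 8 points for two replicate
  pools), not replicate means.
* Degenerate genes (zero residual variance) report p = 0 for nonzero
  contrasts, p = 1 for zero contrasts, and are flagged.

# The co-expression pattern filter

`matchesPattern()` encodes the eight strict inequalities over the seven
replicate-mean treatments (with lo/mid/hi = 400/900/1550):

```
900->400 > 400->400    400->400 > 1550->400
400->900 > 900->900    400->1550 > 1550->1550
400->400 > 400->900    400->1550 > 400->900
400->900 > 1550->400   400->900 > 1550->1550
```

All eight must hold strictly; exact ties never match, and the test
depends only on the ordering of the means, so it is invariant under any
strictly increasing transform (the analysis scale is irrelevant). Two of
the eight inequalities are transitively implied by the others
(400->400 > 1550->400 follows from rows 5 and 7; 400->1550 > 1550->1550
from rows 6 and 8 via 400->1550 > 400->900), so a fixture can never
violate either of those two *alone* — the partial order has six covering
relations. Under an exchangeable tie-free null, exactly 18 of the
7! = 5040 rank orders satisfy the pattern, a match probability of
0.00357; the test suite checks the Monte-Carlo rate against this
enumeration.

# The pool-seq CMH screen

Each variant site contributes one 2×2 table per replicate stratum
(allele 1/allele 2 × 400-lineage pool/1550-lineage pool). Transplanted
pools are treated as extra replicates of their *origin* lineage — the
transplant phase is assumed too short for allele-frequency change (no
mortality) — giving four strata from two replicate populations; 900-uatm
pools take no part. The Cochran–Mantel–Haenszel statistic

$$ X^2 = \frac{\bigl(\lvert\sum_k (a_k - E_k)\rvert - c\bigr)^2}
               {\sum_k V_k} $$

pools evidence for a *consistent* association across strata
(1 df chi-square; continuity correction off by default, and when enabled
it follows the Yates convention of applying only when the absolute
deviation exceeds one half). Strata with any zero margin contribute
nothing. Sites enter the test only if, after reducing to the top two
nucleotides (N and deletions never count), every used pool has coverage
of at least `min_coverage = 10` and the global minor-allele count is at
least `min_minor_count = 2`; both thresholds are arguments and are
recorded in the scan metadata. Bonferroni's denominator is the number of
*testable sites in this run* — the run's own decisions are reproducible,
rather than inheriting a count from any particular dataset. A corrected
result is significant iff p ≤ alpha/m.

## Calibration and the two pool-sampling models

The synthetic generator offers two read-sampling models.
`individuals_then_reads` (the default, and the realistic one) first
resamples the pool's allele frequency as
$\mathrm{Bin}(2N, f)/2N$ for a pool of $N$ diploids, then draws reads
$\mathrm{Bin}(C, \hat f)$; the read-frequency variance is
$p(1-p)\bigl(\tfrac1{2N} + (1-\tfrac1{2N})\tfrac1C\bigr)$ (checked by
Monte-Carlo against this closed form). `fixed_lineage_freq` draws reads
directly at the lineage frequency. The CMH statistic models read counts
as the only noise; under the two-stage model the statistic is
overdispersed by roughly $1 + (C-1)/2N$ (≈1.5 at C = N = 50) and the
Bonferroni screen is anticonservative — with deep coverage on a finite
pool, read counts overstate the information about the lineage frequency.
The error-control validation therefore runs under `fixed_lineage_freq`,
which is the regime the test's guarantees address; on real pool-seq data
the practical mitigations are larger pools, coverage capping, or
effective-sample-size corrections, none of which the screen applies
silently. Measured behaviour at study scale (200 null experiments ×
10 000 sites, 4 strata, coverage 50): family-wise error ≈ 0.04–0.07,
inside the binomial 99% band around 0.05; recovery of a planted
delta-f = 0.3 shift ≈ 0.96 of 1000 planted sites.

# GO enrichment

One hypergeometric upper-tail test per term with at least one hit in the
gene list (`hypergeomUpper()`, exact via `phyper`), adjusted by
Benjamini–Yekutieli — valid under arbitrary dependency between terms,
which overlapping GO annotations guarantee; Benjamini–Hochberg is the
lighter option. Annotation is a flat gene→term map: DAG ancestor
propagation is out of scope, but an ancestor-expanded map can be supplied
and everything downstream is unchanged. Unannotated universe genes count
in N. The reported ratio is (% of list with term)/(% of universe with
term). Sensible universes: all genes surviving the expression filter for
expression-derived lists; all contigs containing at least one tested SNP
for CMH-derived lists.

# The synthetic study generator

`generateDesign()`, `simulateCounts()`, `simulatePoolSnps()` and
`simulateGoAnnotations()` produce a complete synthetic study with ground
truth, under one seed per call (same seed → bit-identical output).

Counts are negative-binomial around treatment means built on a log2 grid:
H2 shifts all 1550-origin samples by `effect_h2_log2fc` (default −0.42,
the down-regulation magnitude this kind of screen targets; per-gene
effects get SD `effect_sd_log2 = 0.2`); H1 pivots the 1550-origin line
around the destination midpoint so elevation is preserved exactly; H3
does both; pattern genes follow a 7-level ladder that satisfies all eight
inequalities. Class fractions are realized deterministically
(`round(frac × n_genes)`, block allocation). Library-depth factors are
log-uniform in [0.5, 2], so size-factor estimation is genuinely
exercised. Defaults — baseline log2 mean 6 (≈64 counts, matching a
transcriptome where most filtered genes sit between 20 and a few hundred
counts), dispersion k = 10 (count CV² ≈ 0.1 + 1/μ, typical of pooled bulk
RNA-seq) — are fixed once as study-realistic values; within-treatment
biological variance beyond NB noise is deliberately *not* added and would
be the first thing to vary when stress-testing.

What the generator does **not** emulate: per-gene dispersion trends,
correlated gene modules, batch structure, mapping artefacts, multiallelic
sites, or linkage between SNPs. Passing recovery tests on this generator
therefore validates the *inference machinery*, not robustness to those
real-data features.

# Validation at study scale, and one honest negative

The test suite validates each stage against an independent oracle
(`stats::lm` for the ANCOVA fit, `stats::mantelhaen.test` for CMH,
`DESeq2::estimateSizeFactorsForMatrix` for size factors, brute-force
enumeration for the hypergeometric tail and the pattern null rate), plus
calibration and recovery runs at the sizes quoted above; the ANCOVA
p-values pass a Kolmogorov–Smirnov uniformity check on a 5000-gene
Gaussian global null.

One validation target is *not* met, by arithmetic rather than defect:
with effects planted at exactly 3× the analysis-scale residual SD and two
replicate pools per treatment, per-class recovery of H1/H2/H3 measures
0.66–0.75 against a 0.8 target. The per-contrast noncentral-t power at
that effect size is 0.88 on 4 residual df, and the classification rule
further multiplies in the probability that the plasticity precondition
passes (≈0.90) and that the other contrast stays non-significant (≈0.95;
squared power for H3) — an upper bound near 0.75 for H1/H2 and 0.70 for
H3. The measured component rates (precondition ≈0.90, per-contrast power
0.82–0.86, null type-I ≈0.055) match that decomposition. Raising
replication or effect size would clear the bar; at the stated study
conditions the honest answer is that the screen's per-class sensitivity
is about 0.7, and the suite reports it as such.

A related practical caveat surfaced while building the recovery harness:
planting a large fraction of shifted genes (tens of percent) biases
median-of-ratios size factors — part of the planted shift is absorbed
into normalization, miscalibrating the scan. The harness plants 15% of
genes across the three classes, close to the share of genes such screens
flag in practice; the same compositional-bias caveat applies to real
datasets with massive asymmetric regulation.

# Problem sizes used by the validation runs

Simulations are sized to be information-rich yet quick: 10 000 sites ×
200 experiments for error control, 10 000 sites for recovery, 5000 genes
for calibration, 6000 genes (300 per planted class) for class recovery,
10^5 draws against a 5040-permutation enumeration for the pattern null.
These sizes are the package's validation choices and are stated in the
test files themselves.

# Session info

```{r}
sessionInfo()
```
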