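## Slope/elevation ANCOVA on reciprocal-transplant reaction norms.
##
## Each "line" is a regression of expression on destination pCO2 for one
## origin population, observed at exactly two destinations. Two lines are
## compared with the centered full-interaction model
##
##   y = b0 + b1 (x - mid) + b2 g + b3 g (x - mid),   g = -1/2 / +1/2
##
## so b2 is directly the between-line difference at the covariate midpoint
## ("elevation") and b3 the difference in slopes. Both are tested with
## two-sided t-tests on n - 4 residual df. The fit is written out via the
## normal equations and vectorised across genes, which keeps the
## 5000-gene calibration scans fast; stats::lm on the same design matrix
## is the independent oracle in the test suite.

.ancovaFitMatrix <- function(Y, x, g) {
  dimnames(Y) <- NULL
  m <- length(x)
  ux <- sort(unique(x))
  mid <- mean(ux)
  xc <- x - mid
  X <- unname(cbind(1, xc, g, g * xc))
  XtXinv <- solve(crossprod(X))
  B <- Y %*% X %*% XtXinv                      # genes x 4
  res <- Y - B %*% t(X)
  rss <- rowSums(res^2)
  df <- m - 4L
  sigma2 <- rss / df
  se <- sqrt(sigma2 %o% diag(XtXinv))
  tval <- B / se
  p <- 2 * pt(-abs(tval), df)
  ## zero residual variance: report p = 0 for a nonzero contrast, 1 for a
  ## zero contrast, and flag the gene
  scale2 <- rowSums(Y^2) + 1
  degenerate <- rss < 1e-20 * scale2
  if (any(degenerate)) {
    tol_b <- 1e-10 * sqrt(scale2)
    for (j in 1:4)
      p[degenerate, j] <- ifelse(abs(B[degenerate, j]) > tol_b[degenerate],
                                 0, 1)
  }
  list(coef = B, slope_diff = B[, 4], elevation_diff = B[, 3],
       slope_p = p[, 4], elevation_p = p[, 3],
       residuals = res, residual_df = df, midpoint = mid,
       degenerate = degenerate)
}

.asLine <- function(line, name) {
  if (is.list(line) && !is.data.frame(line)) line <- as.data.frame(line)
  if (!is.data.frame(line) || !all(c("x", "y") %in% colnames(line)))
    .stopf("%s must have components 'x' and 'y'", name)
  if (length(unique(line$x)) != 2L)
    .stopf("%s must be observed at exactly two distinct x values", name)
  line
}

#' Slope/elevation ANCOVA between two transplant regression lines
#'
#' @param lineA,lineB data.frames (or lists) with components `x`
#'   (destination pCO2, exactly two distinct values shared by both lines)
#'   and `y` (expression on the analysis scale), one row per sample.
#' @return an object of class `"ancovaPair"`: list with `slope_diff`
#'   (expression per uatm, lineB minus lineA), `elevation_diff`
#'   (expression difference at the covariate midpoint), `slope_p`,
#'   `elevation_p` (two-sided t-tests on `residual_df` df),
#'   `residual_df`, `normality_p` (Shapiro-Wilk on pooled residuals),
#'   `midpoint` and `degenerate` (TRUE when the residual variance is zero,
#'   in which case p is 0 for nonzero contrasts and 1 for zero ones).
#' @examples
#' a <- data.frame(x = c(400, 400, 1550, 1550), y = c(5.1, 4.9, 5.0, 5.2))
#' b <- data.frame(x = c(400, 400, 1550, 1550), y = c(6.0, 6.2, 4.1, 3.9))
#' ancovaPairTest(a, b)$elevation_p
#' @export
ancovaPairTest <- function(lineA, lineB) {
  lineA <- .asLine(lineA, "lineA")
  lineB <- .asLine(lineB, "lineB")
  if (!setequal(unique(lineA$x), unique(lineB$x)))
    .stopf("lineA and lineB must share the same two x values")
  x <- c(lineA$x, lineB$x)
  y <- c(lineA$y, lineB$y)
  g <- rep(c(-0.5, 0.5), c(nrow(lineA), nrow(lineB)))
  if (length(x) - 4L < 1L)
    .stopf("insufficient replication: %d points leave no residual df",
           length(x))
  fit <- .ancovaFitMatrix(matrix(y, 1), x, g)
  res <- drop(fit$residuals)
  norm_p <- tryCatch(shapiro.test(res)$p.value, error = function(e) NA_real_)
  structure(list(slope_diff = fit$slope_diff, elevation_diff =
                   fit$elevation_diff, slope_p = fit$slope_p,
                 elevation_p = fit$elevation_p,
                 residual_df = fit$residual_df, normality_p = norm_p,
                 midpoint = fit$midpoint, degenerate = fit$degenerate,
                 residuals = res),
            class = "ancovaPair")
}

#' @export
print.ancovaPair <- function(x, ...) {
  cat(sprintf(paste0("ANCOVA pair test (df = %d)\n",
                     "  slope diff:     %+.4g  (p = %.4g)\n",
                     "  elevation diff: %+.4g  (p = %.4g)  at x = %g\n"),
              x$residual_df, x$slope_diff, x$slope_p, x$elevation_diff,
              x$elevation_p, x$midpoint))
  if (x$degenerate) cat("  [degenerate: zero residual variance]\n")
  invisible(x)
}

## Sample index sets for the plasticity pair (400-origin vs 900-origin,
## destinations {400, 900}) and the high pair (400-origin vs 1550-origin,
## destinations {400, 1550}).
.pairLayout <- function(design) {
  lev <- .checkFullDesign(design)
  lo <- lev[["low"]]; mi <- lev[["mid"]]; hi <- lev[["high"]]
  pair <- function(oB, dB2) {
    iA <- c(.treatmentSamples(design, lo, lo), .treatmentSamples(design, lo, dB2))
    iB <- c(.treatmentSamples(design, oB, oB), .treatmentSamples(design, oB, lo))
    list(idx = c(iA, iB),
         x = design$destination_pco2[c(iA, iB)],
         g = rep(c(-0.5, 0.5), c(length(iA), length(iB))))
  }
  list(plasticity = pair(mi, mi), high = pair(hi, hi))
}

.analysisScale <- function(mat, scale) {
  switch(scale, log2p1 = log2(mat + 1), raw = mat,
         .stopf("unknown scale '%s'", scale))
}

.scanCore <- function(mat, design, alpha, scale) {
  layout <- .pairLayout(design)
  vals <- .analysisScale(mat, scale)
  fitP <- with(layout$plasticity,
               .ancovaFitMatrix(vals[, idx, drop = FALSE], x, g))
  fitH <- with(layout$high,
               .ancovaFitMatrix(vals[, idx, drop = FALSE], x, g))
  pre <- fitP$slope_p > alpha & fitP$elevation_p > alpha
  s <- fitH$slope_p <= alpha
  e <- fitH$elevation_p <= alpha
  cls <- rep("none", nrow(mat))
  cls[pre & s & !e] <- "H1"
  cls[pre & !s & e] <- "H2"
  cls[pre & s & e] <- "H3"
  norm_p <- vapply(seq_len(nrow(mat)), function(i) {
    tryCatch(shapiro.test(c(fitP$residuals[i, ], fitH$residuals[i, ]))$p.value,
             error = function(err) NA_real_)
  }, numeric(1))
  list(class = cls, fitP = fitP, fitH = fitH, normality_p = norm_p)
}

#' Classify one gene's expression into the transplant hypotheses
#'
#' Implements the reaction-norm hypothesis screen. Precondition
#' (phenotypic plasticity between the control and mid treatments): the
#' 400-origin and 900-origin regression lines over destinations
#' \{400, 900\} differ in neither slope nor elevation (both p > alpha).
#' Then, on the 400-origin vs 1550-origin lines over destinations
#' \{400, 1550\}: different slopes only is H1 (transgenerational change of
#' plasticity), different elevation only is H2 (transgenerational change
#' of phenotype), both is H3, anything else none. Ties at exactly
#' p = alpha count as significant.
#'
#' @param expr numeric vector of one gene's expression, named by sample id
#'   (or in design order).
#' @param design design data.frame with all 7 transplant treatments.
#' @param alpha significance level of every test (default 0.05).
#' @param scale `"log2p1"` (analyse `log2(x + 1)`, default) or `"raw"`.
#' @return list with `class` (`"none"/"H1"/"H2"/"H3"`), `plasticity` and
#'   `high` (the two [ancovaPairTest()] results) and `normality_p`
#'   (Shapiro-Wilk on the pooled residuals of both fits).
#' @export
classifyGene <- function(expr, design, alpha = 0.05,
                         scale = c("log2p1", "raw")) {
  scale <- match.arg(scale)
  design <- .validateDesign(design)
  if (!is.null(names(expr))) {
    miss <- setdiff(design$sample_id, names(expr))
    if (length(miss))
      .stopf("expr is missing sample(s): %s", paste(miss, collapse = ", "))
    expr <- expr[design$sample_id]
  } else if (length(expr) != nrow(design)) {
    .stopf("expr has %d values for %d samples", length(expr), nrow(design))
  }
  mat <- matrix(expr, 1, dimnames = list("gene", design$sample_id))
  core <- .scanCore(mat, design, alpha, scale)
  layout <- .pairLayout(design)
  vals <- drop(.analysisScale(mat, scale))
  pairOf <- function(p) {
    nA <- sum(p$g < 0)
    ancovaPairTest(data.frame(x = p$x[seq_len(nA)], y = vals[p$idx[seq_len(nA)]]),
                   data.frame(x = p$x[-seq_len(nA)], y = vals[p$idx[-seq_len(nA)]]))
  }
  list(class = core$class, plasticity = pairOf(layout$plasticity),
       high = pairOf(layout$high), normality_p = core$normality_p)
}

#' Scan an expression matrix for transplant-hypothesis genes
#'
#' Applies [classifyGene()]'s screen to every gene of a (filtered,
#' normalized) matrix, vectorised. No multiple-testing correction is
#' applied across genes: the screen is a per-gene hypothesis
#' classification at the stated alpha, not a FDR-controlled discovery
#' list; treat the class counts accordingly.
#'
#' @param x a [TransplantExperiment-class] (first assay is scanned) or a
#'   numeric matrix.
#' @param design design data.frame; ignored (taken from the object) when
#'   `x` is a TransplantExperiment.
#' @param alpha per-test significance level.
#' @param scale `"log2p1"` or `"raw"`.
#' @return `DataFrame` with one row per gene: `class`, slope/elevation
#'   differences and p-values for both line pairs, `normality_p`,
#'   `degenerate`. `metadata()$class_counts` tabulates the classes.
#' @examples
#' te <- simulateCounts(generateDesign(seed = 1), n_genes = 50, seed = 2)
#' res <- scanExpression(te)
#' S4Vectors::metadata(res)$class_counts
#' @export
scanExpression <- function(x, design = NULL, alpha = 0.05,
                           scale = c("log2p1", "raw")) {
  scale <- match.arg(scale)
  if (is(x, "TransplantExperiment")) {
    design <- designTable(x)
    mat <- SummarizedExperiment::assay(x)
  } else {
    mat <- as.matrix(x)
    if (is.null(design)) .stopf("design is required for matrix input")
    design <- .validateDesign(design)
    mat <- mat[, design$sample_id, drop = FALSE]
  }
  .checkProb(alpha, "alpha")
  if (nrow(mat) == 0) {
    out <- S4Vectors::DataFrame(class = character(0))
    S4Vectors::metadata(out)$class_counts <- table(factor(character(0),
      levels = c("none", "H1", "H2", "H3")))
    return(out)
  }
  core <- .scanCore(mat, design, alpha, scale)
  out <- S4Vectors::DataFrame(
    class = core$class,
    plast_slope_diff = core$fitP$slope_diff,
    plast_slope_p = core$fitP$slope_p,
    plast_elevation_diff = core$fitP$elevation_diff,
    plast_elevation_p = core$fitP$elevation_p,
    high_slope_diff = core$fitH$slope_diff,
    high_slope_p = core$fitH$slope_p,
    high_elevation_diff = core$fitH$elevation_diff,
    high_elevation_p = core$fitH$elevation_p,
    normality_p = core$normality_p,
    degenerate = core$fitP$degenerate | core$fitH$degenerate,
    row.names = rownames(mat))
  S4Vectors::metadata(out)$class_counts <-
    table(factor(core$class, levels = c("none", "H1", "H2", "H3")))
  S4Vectors::metadata(out)$alpha <- alpha
  S4Vectors::metadata(out)$scale <- scale
  out
}
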