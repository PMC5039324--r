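test_that("identical lines give zero effects and p = 1", {
  set.seed(41)
  a <- data.frame(x = c(400, 400, 1550, 1550), y = 5 + rnorm(4, 0, 0.3))
  res <- ancovaPairTest(a, a)
  expect_equal(res$slope_diff, 0)
  expect_equal(res$elevation_diff, 0)
  expect_equal(res$slope_p, 1)
  expect_equal(res$elevation_p, 1)
  expect_equal(res$residual_df, 4L)
})

test_that("swapping the two lines negates effects and keeps p-values", {
  set.seed(42)
  a <- data.frame(x = rep(c(400, 1550), each = 2), y = rnorm(4, 5))
  b <- data.frame(x = rep(c(400, 1550), each = 2), y = rnorm(4, 6))
  r1 <- ancovaPairTest(a, b)
  r2 <- ancovaPairTest(b, a)
  expect_equal(r2$slope_diff, -r1$slope_diff)
  expect_equal(r2$elevation_diff, -r1$elevation_diff)
  expect_equal(r2$slope_p, r1$slope_p)
  expect_equal(r2$elevation_p, r1$elevation_p)
})

test_that("the 8-point fixture matches a general-linear-model oracle", {
  a <- data.frame(x = c(400, 400, 1550, 1550), y = c(5.2, 4.8, 6.1, 5.9))
  b <- data.frame(x = c(400, 400, 1550, 1550), y = c(6.6, 6.2, 4.3, 4.9))
  res <- ancovaPairTest(a, b)
  # independent oracle: stats::lm (QR) on the same centered design
  x <- c(a$x, b$x); y <- c(a$y, b$y)
  g <- rep(c(-0.5, 0.5), each = 4)
  xc <- x - mean(c(400, 1550))
  fit <- lm(y ~ xc + g + I(g * xc))
  sm <- summary(fit)$coefficients
  expect_equal(res$elevation_diff, unname(sm["g", "Estimate"]),
               tolerance = 1e-10)
  expect_equal(res$slope_diff, unname(sm["I(g * xc)", "Estimate"]),
               tolerance = 1e-10)
  expect_equal(res$elevation_p, unname(sm["g", "Pr(>|t|)"]),
               tolerance = 1e-10)
  expect_equal(res$slope_p, unname(sm["I(g * xc)", "Pr(>|t|)"]),
               tolerance = 1e-10)
})

test_that("affine covariate and scale changes behave as expected", {
  set.seed(43)
  a <- data.frame(x = rep(c(400, 1550), each = 3), y = rnorm(6, 5))
  b <- data.frame(x = rep(c(400, 1550), each = 3), y = rnorm(6, 6))
  r1 <- ancovaPairTest(a, b)
  # covariate in centered kilo-units: p unchanged, slope rescaled
  s <- 1000
  a2 <- transform(a, x = (x - 975) / s)
  b2 <- transform(b, x = (x - 975) / s)
  r2 <- ancovaPairTest(a2, b2)
  expect_equal(r2$slope_p, r1$slope_p, tolerance = 1e-10)
  expect_equal(r2$elevation_p, r1$elevation_p, tolerance = 1e-10)
  expect_equal(r2$slope_diff, r1$slope_diff * s, tolerance = 1e-10)
  # multiplying expression by a positive constant keeps p-values
  r3 <- ancovaPairTest(transform(a, y = 7 * y), transform(b, y = 7 * y))
  expect_equal(r3$slope_p, r1$slope_p, tolerance = 1e-10)
  expect_equal(r3$elevation_p, r1$elevation_p, tolerance = 1e-10)
})

test_that("degenerate and under-replicated inputs are handled explicitly", {
  a <- data.frame(x = c(400, 400, 1550, 1550), y = rep(1, 4))
  b <- data.frame(x = c(400, 400, 1550, 1550), y = rep(3, 4))
  res <- ancovaPairTest(a, b)
  expect_true(res$degenerate)
  expect_equal(res$elevation_p, 0)  # nonzero contrast, zero residual var
  expect_equal(res$slope_p, 1)      # zero contrast
  expect_error(
    ancovaPairTest(data.frame(x = c(400, 1550), y = 1:2),
                   data.frame(x = c(400, 1550), y = 1:2)),
    "insufficient replication")
  expect_error(
    ancovaPairTest(a, data.frame(x = c(400, 400, 900, 900), y = 1:4)),
    "same two x values")
})

test_that("classifyGene recovers clean planted reaction-norm classes", {
  d <- smallDesign()
  base <- c("400->400" = 8, "400->900" = 8, "900->900" = 8, "900->400" = 8,
            "400->1550" = 8, "1550->1550" = 8, "1550->400" = 8)
  h2 <- base; h2[c("1550->1550", "1550->400")] <- 7        # elevation only
  h1 <- base; h1["1550->1550"] <- 7; h1["1550->400"] <- 9  # slope only
  h3 <- base; h3["1550->1550"] <- 6.4; h3["1550->400"] <- 7.6
  set.seed(44)
  noise <- 0.08
  cls <- function(means) {
    expr <- drop(exprFromMeans(means, d, sd = noise))
    classifyGene(expr, d, scale = "raw")
  }
  expect_equal(cls(base)$class, "none")
  expect_equal(cls(h2)$class, "H2")
  expect_equal(cls(h1)$class, "H1")
  r3 <- cls(h3)
  expect_equal(r3$class, "H3")
  expect_s3_class(r3$high, "ancovaPair")
  expect_lt(r3$high$elevation_p, 0.05)
  # missing treatment is a design error
  expect_error(classifyGene(rnorm(12), d[d$destination_pco2 != 1550 |
                                           d$origin_pco2 != 1550, ]),
               "no sample")
})

test_that("scanExpression agrees with classifyGene and handles edge shapes", {
  d <- smallDesign()
  set.seed(45)
  te <- simulateCounts(d, n_genes = 60, frac_h2 = 0.3, effect_h2_log2fc = -2,
                       effect_sd_log2 = 0, baseline_log_sd = 0.5, seed = 46)
  scan <- scanExpression(te)
  mat <- SummarizedExperiment::assay(te)
  for (g in c(1, 10, 25, 60)) {
    one <- classifyGene(mat[g, ], d)
    expect_equal(scan$class[g], one$class)
    expect_equal(scan$high_elevation_p[g], one$high$elevation_p,
                 tolerance = 1e-12)
  }
  expect_equal(nrow(scanExpression(mat[0, , drop = FALSE], d)), 0L)
  expect_equal(nrow(scanExpression(mat[1, , drop = FALSE], d)), 1L)
  counts <- S4Vectors::metadata(scan)$class_counts
  expect_equal(sum(counts), 60L)
})
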