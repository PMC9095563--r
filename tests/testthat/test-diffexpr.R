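test_that("size factors follow the median-of-ratios convention", {
  m <- cbind(a = c(2, 4, 6), b = c(4, 8, 12))
  expect_equal(unname(computeSizeFactors(m)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-6)
  ident <- cbind(s1 = c(5, 9, 2), s2 = c(5, 9, 2), s3 = c(5, 9, 2))
  expect_equal(unname(computeSizeFactors(ident)), rep(1, 3))
  expect_equal(unname(computeSizeFactors(matrix(1:3, ncol = 1,
                                                dimnames = list(NULL, "s")))),
               1)
})

test_that("scaling one column scales its size factor and leaves lfc alone", {
  set.seed(5)
  k <- matrix(rnbinom(200 * 6, mu = 300, size = 20), 200,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:6)))
  cd <- data.frame(condition = rep(c("control", "treated"), each = 3),
                   batch = "b1")
  sf1 <- computeSizeFactors(k)
  k2 <- k
  k2[, 1] <- k2[, 1] * 4L
  sf2 <- computeSizeFactors(k2)
  # size factors are defined up to a common constant: the scaled sample's
  # factor grows by exactly 4 relative to every other sample
  expect_equal(unname((sf2[1] / sf2[-1]) / (sf1[1] / sf1[-1])), rep(4, 5),
               tolerance = 1e-9)
  # fold-changes are essentially invariant: the offset shift is absorbed
  # by the intercept; the NB weights mu/(1+alpha*mu) are not perfectly
  # scale-equivariant, so invariance is numerical rather than bit-exact
  cells <- factor(cd$condition)
  disp <- estimateNBDispersions(k, sf1, cells)
  r1 <- nbWaldTest(k, cd, ~condition, c("condition", "treated", "control"),
                   sizeFactors = sf1, dispersions = disp)
  r2 <- nbWaldTest(k2, cd, ~condition, c("condition", "treated", "control"),
                   sizeFactors = sf2, dispersions = disp)
  expect_lt(max(abs(r1$log2FoldChange - r2$log2FoldChange), na.rm = TRUE),
            0.02)
})

test_that("gene-wise dispersion behaves like the moments estimator", {
  set.seed(31)
  cells <- factor(rep("a", 20))
  # Poisson data: dispersion collapses to the floor
  kP <- matrix(rpois(2000 * 20, lambda = 400), 2000)
  dP <- estimateNBDispersions(kP, rep(1, 20), cells)
  expect_lt(mean(dP$alpha_gw), 0.01)
  # genuine NB at alpha = 0.2, mean 500, 50 replicates
  kN <- matrix(rnbinom(500 * 50, mu = 500, size = 5), 500)
  dN <- estimateNBDispersions(kN, rep(1, 50), factor(rep("a", 50)))
  expect_gt(median(dN$alpha_gw), 0.1)
  expect_lt(median(dN$alpha_gw), 0.3)
  # constant counts within groups: floored
  kC <- matrix(rep(c(10L, 20L), each = 3), nrow = 1)
  dC <- estimateNBDispersions(kC, rep(1, 6),
                              factor(rep(c("a", "b"), each = 3)))
  expect_equal(dC$alpha_gw, 1e-8)
  # final estimate lies between the gene-wise and trend values
  fin <- dN$alpha_final
  expect_true(all(fin >= pmin(dN$alpha_gw, dN$alpha_trend) - 1e-12))
  expect_true(all(fin <= pmax(dN$alpha_gw, dN$alpha_trend) + 1e-12))
})

test_that("all-zero genes are excluded from testing and reported NA", {
  set.seed(8)
  k <- rbind(zero = 0L,
             matrix(rnbinom(50 * 6, mu = 200, size = 10), 50,
                    dimnames = list(sprintf("g%02d", 1:50), NULL)))
  colnames(k) <- paste0("s", 1:6)
  cd <- data.frame(condition = rep(c("control", "treated"), each = 3))
  r <- nbWaldTest(k, cd, ~condition, c("condition", "treated", "control"))
  expect_true(is.na(r["zero", "pvalue"]))
  expect_true(is.na(r["zero", "padj"]))
  sig <- significantFeatures(r, baseMeanMin = 0)
  expect_false("zero" %in% c(sig$up, sig$down))
})

test_that("a planted fold-change is recovered with a tiny p-value", {
  set.seed(77)
  ng <- 40
  mu <- matrix(1000, ng, 6)
  mu[1, 4:6] <- 1000 * 2^2                 # planted log2fc = 2 in gene 1
  k <- matrix(rnbinom(ng * 6, mu = mu, size = 1 / 0.01), ng,
              dimnames = list(sprintf("g%02d", 1:ng), paste0("s", 1:6)))
  cd <- data.frame(condition = rep(c("control", "treated"), each = 3))
  r <- nbWaldTest(k, cd, ~condition, c("condition", "treated", "control"))
  expect_lt(r$pvalue[1], 1e-4)
  expect_lt(abs(r$log2FoldChange[1] - 2), 0.3)
})

test_that("the NB Wald estimates agree with a reference GLM fit", {
  skip_if_not_installed("MASS")
  set.seed(19)
  cd <- data.frame(condition = rep(c("control", "treated"), each = 3),
                   batch = rep_len(c("b1", "b2"), 6))
  X <- stats::model.matrix(~ batch + condition,
                           transform(cd, condition = relevel(
                             factor(condition), "control")))
  for (i in 1:20) {
    y <- rnbinom(6, mu = exp(runif(1, log(50), log(2000))), size = 20)
    if (all(y == 0)) next
    alpha <- runif(1, 0.01, 0.3)
    ours <- ptrOmics:::.nbFitOne(y, X, alpha, rep(0, 6), 3L)
    ref <- suppressWarnings(stats::glm.fit(
      X, y, family = MASS::negative.binomial(theta = 1 / alpha)))
    refSe <- sqrt(diag(solve(crossprod(X * ref$weights, X))))[3]
    expect_equal(unname(ours[1]), unname(ref$coefficients[3]),
                 tolerance = 1e-3)
    expect_equal(unname(ours[2]), unname(refSe), tolerance = 1e-3)
  }
})

test_that("contrasting a level with itself gives exactly zero fold-change", {
  set.seed(3)
  k <- matrix(rnbinom(30 * 4, mu = 100, size = 10), 30,
              dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:4)))
  cd <- data.frame(condition = rep("control", 4))
  r <- nbWaldTest(k, cd, ~1, c("condition", "control", "control"))
  expect_true(all(r$log2FoldChange == 0, na.rm = TRUE))
})

test_that("null Wald p-values are approximately uniform", {
  set.seed(55)
  ng <- 10000
  mu <- exp(runif(ng, log(100), log(2000)))
  k <- matrix(rnbinom(ng * 6, mu = rep(mu, each = 6), size = 1 / 0.05),
              nrow = ng, byrow = TRUE,
              dimnames = list(sprintf("g%05d", 1:ng), paste0("s", 1:6)))
  cd <- data.frame(condition = rep(c("control", "treated"), each = 3))
  r <- nbWaldTest(k, cd, ~condition, c("condition", "treated", "control"))
  p <- r$pvalue[!is.na(r$pvalue)]
  ks <- max(abs(sort(p) - seq_along(p) / length(p)))
  expect_lt(ks, 0.03)
  # parameter recovery: the unshrunken estimator tracks its information
  # bound (per-gene lfc sd at alpha 0.05, mean 500, n 3+3 is ~0.27 log2
  # units, i.e. an expected absolute error of ~0.215; no lfc shrinkage is
  # applied by design)
  # symmetric planting keeps the median-of-ratios median anchored on nulls
  set.seed(56)
  lfc <- c(rep(1, 50), rep(-1, 50), rep(0, 900))
  mu2 <- matrix(500, 1000, 6)
  mu2[, 4:6] <- 500 * 2^lfc
  k2 <- matrix(rnbinom(6000, mu = mu2, size = 20), 1000,
               dimnames = list(sprintf("h%04d", 1:1000), paste0("s", 1:6)))
  r2 <- nbWaldTest(k2, cd, ~condition, c("condition", "treated", "control"))
  expect_lt(mean(abs(r2$log2FoldChange - lfc), na.rm = TRUE), 0.25)
  expect_lt(abs(mean(r2$log2FoldChange - lfc, na.rm = TRUE)), 0.05)
})

test_that("BH adjustment matches the hand example and validates input", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(66)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    p[sample(length(p), size = min(2, length(p)))] <- NA
    expect_equal(bhAdjust(p), oracleBH(p))
  }
  # monotone non-decreasing in p-rank and padj >= p
  p <- runif(100)
  a <- bhAdjust(p)
  expect_true(all(a >= p))
  expect_true(all(diff(a[order(p)]) >= -1e-12))
})

test_that("significance thresholds are strict as printed", {
  res <- S4Vectors::DataFrame(
    baseMean = c(501, 600, 500, 600),
    log2FoldChange = c(0.6, 0.5, 0.9, -0.6),
    padj = c(0.04, 0.04, 0.04, 0.05),
    row.names = c("up_ok", "lfc_at_limit", "bm_at_limit", "padj_at_limit"))
  sig <- significantFeatures(res)
  expect_identical(sig$up, "up_ok")
  expect_identical(sig$down, character(0))
})

test_that("QC transform gives reproducible PCA and honest correlations", {
  set.seed(12)
  k <- matrix(rnbinom(300 * 4, mu = 200, size = 10), 300,
              dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:4)))
  k <- cbind(k, s5 = k[, 4])               # duplicated sample
  qc <- qcTransformPca(k, rep(1, 5))
  expect_equal(qc$coordinates["s4", ], qc$coordinates["s5", ],
               tolerance = 1e-9)
  expect_equal(unname(diag(qc$correlations)), rep(1, 5))
  # a constant per-gene batch offset disappears under batch removal
  off <- rnorm(300, sd = 2)
  k2 <- matrix(rnbinom(300 * 6, mu = 300, size = 1 / 0.02), 300)
  colnames(k2) <- paste0("s", 1:6)
  batch <- rep(c("x", "y"), each = 3)
  k2[, 4:6] <- matrix(rnbinom(300 * 3, mu = 300 * 2^off, size = 1 / 0.02),
                      300)
  qcRaw <- qcTransformPca(k2, rep(1, 6))
  qcAdj <- qcTransformPca(k2, rep(1, 6), batch = batch)
  sep <- function(co) abs(mean(co[1:3, 1]) - mean(co[4:6, 1]))
  expect_lt(sep(qcAdj$coordinates), sep(qcRaw$coordinates) / 5)
})

test_that("fold-changes and calls agree with an independent NB implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(71)
  ng <- 300
  lfc <- c(rep(1.5, 20), rep(-1.5, 20), rep(0, 260))
  mu <- exp(runif(ng, log(100), log(2000)))
  m <- matrix(mu, ng, 6)
  m[, 4:6] <- mu * 2^lfc
  k <- matrix(rnbinom(ng * 6, mu = m, size = 1 / 0.05), ng,
              dimnames = list(sprintf("g%03d", 1:ng), paste0("s", 1:6)))
  cd <- data.frame(condition = factor(rep(c("control", "treated"),
                                          each = 3)))
  ours <- nbWaldTest(k, cd, ~condition,
                     c("condition", "treated", "control"))
  dds <- DESeq2::DESeqDataSetFromMatrix(k, cd, ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds, contrast = c("condition", "treated",
                                           "control"))
  ok <- !is.na(ours$log2FoldChange) & !is.na(ref$log2FoldChange)
  expect_gt(cor(ours$log2FoldChange[ok], ref$log2FoldChange[ok]), 0.98)
  expect_lt(mean(abs(ours$baseMean - ref$baseMean) /
                   pmax(ref$baseMean, 1)), 0.01)
  # the planted genes are called by both at padj < 0.05
  planted <- 1:40
  expect_gt(mean(ours$padj[planted] < 0.05, na.rm = TRUE), 0.9)
  expect_gt(mean(ref$padj[planted] < 0.05, na.rm = TRUE), 0.9)
})
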