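simPair <- function(lfcRna, lfcChro, nGenes = length(lfcRna), mu = 500,
                    alpha = 0.02, n = 3, seed = 1) {
  set.seed(seed)
  mk <- function(lfc, assay) {
    m <- matrix(mu, nGenes, 2 * n)
    m[, (n + 1):(2 * n)] <- mu * 2^lfc
    k <- matrix(rnbinom(nGenes * 2 * n, mu = m, size = 1 / alpha), nGenes,
                dimnames = list(sprintf("g%04d", seq_len(nGenes)),
                                paste0(assay, "_s", seq_len(2 * n))))
    cd <- data.frame(sample = colnames(k),
                     condition = rep(c("control", "treated"), each = n),
                     batch = "b1", assay = assay)
    makeOE(k, cd)
  }
  list(rna = mk(lfcRna, "rna"), chro = mk(lfcChro, "chro"))
}

test_that("the interaction recovers an RNA-only effect and ignores shared ones", {
  # low dispersion and high depth so the per-gene interaction SE
  # (~sqrt(4*(1+alpha*mu)/(n*mu)) nats) is well below the 0.3 band
  lfcRna <- c(rep(-1, 10), rep(1.2, 10), rep(0, 60))
  lfcChro <- c(rep(0, 10), rep(1.2, 10), rep(0, 60))
  p <- simPair(lfcRna, lfcChro, mu = 3000, alpha = 0.002, seed = 41)
  tf <- twoFactorTest(p$rna, p$chro)
  # planted RNA-only genes: interaction close to the RNA lfc
  expect_true(all(abs(tf$interactionLfc[1:10] - (-1)) < 0.3))
  # genes with the same effect in both assays: interaction near zero,
  # not significant (BH padj can dip by chance for a rare null gene)
  expect_true(all(abs(tf$interactionLfc[11:20]) < 0.3))
  expect_gte(sum(tf$padj[11:20] > 0.2), 9)
})

test_that("genes absent or all-zero in one assay are untestable", {
  p <- simPair(rep(0, 20), rep(0, 20), seed = 42)
  kC <- SummarizedExperiment::assay(p$chro, "counts")
  kC["g0001", ] <- 0L
  cdC <- as.data.frame(SummarizedExperiment::colData(p$chro))
  cdC$sample <- rownames(cdC)
  chro0 <- makeOE(kC, cdC)
  tf <- twoFactorTest(p$rna, chro0)
  expect_true(is.na(tf["g0001", "pvalue"]))
  calls <- classifyPtr(tf,
                       nbWaldTest(kC, cdC, ~condition,
                                  c("condition", "treated", "control")),
                       runDE(p$rna, c("treated", "control")))
  expect_identical(as.character(calls["g0001", "category"]), "untestable")
})

test_that("GPS/LPS classification applies the printed thresholds strictly", {
  mk <- function(...) S4Vectors::DataFrame(..., row.names = "g")
  int <- mk(padj = 0.1)
  chro <- mk(padj = 0.5, log2FoldChange = 0.1, baseMean = 150)
  rnaDown <- mk(padj = 0.1, log2FoldChange = -0.8, baseMean = 200)
  expect_identical(
    as.character(classifyPtr(int, chro, rnaDown)$category), "GPS")
  rnaUp <- mk(padj = 0.1, log2FoldChange = 0.8, baseMean = 200)
  expect_identical(
    as.character(classifyPtr(int, chro, rnaUp)$category), "LPS")
  # chro padj 0.15 is not > 0.2: the gene is not "transcriptionally
  # unchanged", so it cannot be GPS
  chro15 <- mk(padj = 0.15, log2FoldChange = 0.1, baseMean = 150)
  expect_false(as.character(
    classifyPtr(int, chro15, rnaDown)$category) == "GPS")
})

test_that("categories are mutually exclusive and exhaustive", {
  lfcRna <- c(rep(-1.5, 15), rep(1.5, 15), rep(1.5, 20), rep(0, 100))
  lfcChro <- c(rep(0, 15), rep(0, 15), rep(1.5, 20), rep(0, 100))
  p <- simPair(lfcRna, lfcChro, seed = 43)
  tf <- twoFactorTest(p$rna, p$chro)
  rnaRes <- runDE(p$rna, c("treated", "control"))
  chroRes <- runDE(p$chro, c("treated", "control"))
  calls <- classifyPtr(tf, chroRes, rnaRes)
  expect_identical(nrow(calls), 150L)
  expect_false(anyNA(calls$category))
  expect_identical(sum(table(calls$category)), 150L)
})

test_that("flipping the RNA effect sign swaps GPS and LPS exactly", {
  set.seed(44)
  n <- 200
  ids <- sprintf("g%04d", 1:n)
  int <- S4Vectors::DataFrame(padj = runif(n), row.names = ids)
  chro <- S4Vectors::DataFrame(padj = runif(n),
                               log2FoldChange = rnorm(n, 0, 0.5),
                               baseMean = runif(n, 50, 1000),
                               row.names = ids)
  rna <- S4Vectors::DataFrame(padj = runif(n),
                              log2FoldChange = rnorm(n, 0, 1),
                              baseMean = runif(n, 50, 1000),
                              row.names = ids)
  rnaFlip <- rna
  rnaFlip$log2FoldChange <- -rna$log2FoldChange
  a <- table(classifyPtr(int, chro, rna)$category)
  b <- table(classifyPtr(int, chro, rnaFlip)$category)
  expect_identical(a[["GPS"]], b[["LPS"]])
  expect_identical(a[["LPS"]], b[["GPS"]])
  expect_identical(a[["transcriptional"]], b[["transcriptional"]])
})

test_that("planted post-transcriptional genes are recovered end to end", {
  nGps <- 30
  lfcRna <- c(rep(-1.5, nGps), rep(1.5, 30), rep(0, 540))
  lfcChro <- c(rep(0, nGps), rep(1.5, 30), rep(0, 540))
  p <- simPair(lfcRna, lfcChro, alpha = 0.05, seed = 45)
  tf <- twoFactorTest(p$rna, p$chro)
  rnaRes <- runDE(p$rna, c("treated", "control"))
  chroRes <- runDE(p$chro, c("treated", "control"))
  calls <- classifyPtr(tf, chroRes, rnaRes)
  gpsCalled <- rownames(calls)[calls$category == "GPS"]
  sens <- mean(sprintf("g%04d", 1:nGps) %in% gpsCalled)
  expect_gte(sens, 0.7)
  # planted transcriptional genes rarely leak into GPS
  falseGps <- mean(sprintf("g%04d", 31:60) %in% gpsCalled)
  expect_lte(falseGps, 0.1)
})

test_that("concordance reporting follows the baseMean filter", {
  ids <- sprintf("g%03d", 1:1000)
  mk <- function(lfc, bm) S4Vectors::DataFrame(
    log2FoldChange = lfc, baseMean = bm, row.names = ids)
  set.seed(46)
  lfc <- rnorm(1000)
  same <- concordanceReport(mk(lfc, 1000), mk(lfc, 1000))
  expect_equal(same$r, 1.0)
  indep <- concordanceReport(mk(rnorm(1000), 1000), mk(rnorm(1000), 1000))
  expect_lt(abs(indep$r), 0.1)
  few <- mk(rnorm(1000), c(600, 600, rep(10, 998)))
  expect_warning(res <- concordanceReport(few, mk(lfc, 1000)), "fewer")
  expect_true(is.na(res$r))
  expect_identical(res$n, 2L)
})
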