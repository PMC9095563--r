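test_that("seed patterns and worked site examples are exact", {
  pats <- seedPatterns("AGCACCA")
  expect_identical(unname(pats["8mer"]), "TGGTGCTA")
  expect_identical(unname(pats["7mer-m8"]), "TGGTGCT")
  expect_identical(unname(pats["7mer-A1"]), "GGTGCTA")

  s <- findSeedSites(c(geneA = "AAATGGTGCTAAA"),
                     data.frame(mirna_id = "m", seed = "AGCACCA"))
  expect_identical(nrow(s), 1L)
  expect_identical(s$site_type, "8mer")
  expect_identical(s$utr_pos, 3L)

  s2 <- findSeedSites(c(geneA = "AATGGTGCTCAA"),
                      data.frame(mirna_id = "m", seed = "AGCACCA"))
  expect_identical(s2$site_type, "7mer-m8")
  expect_identical(s2$utr_pos, 2L)

  expect_identical(nrow(findSeedSites(c(geneA = "ACGTACGTACGT"),
                                      data.frame(mirna_id = "m",
                                                 seed = "AGCACCA"))), 0L)
  # N bases never match
  expect_identical(nrow(findSeedSites(c(geneA = "AAATGGTGCTNAA"),
                                      data.frame(mirna_id = "m",
                                                 seed = "AGCACCA"))), 1L)
  expect_identical(nrow(findSeedSites(c(geneA = "AAATGGTNCTAAA"),
                                      data.frame(mirna_id = "m",
                                                 seed = "AGCACCA"))), 0L)
})

test_that("site detection equals the exhaustive scan oracle", {
  set.seed(91)
  mirnas <- data.frame(mirna_id = sprintf("m%02d", 1:5),
                       seed = replicate(5, randomDna(7)))
  seqs <- setNames(replicate(30, randomDna(1500)), sprintf("u%02d", 1:30))
  got <- findSeedSites(seqs, mirnas)
  for (g in names(seqs)) {
    for (m in seq_len(nrow(mirnas))) {
      want <- oracleSeedSites(seqs[[g]], mirnas$seed[m])
      sub <- got[got$gene_id == g & got$mirna_id == mirnas$mirna_id[m],
                 c("site_type", "utr_pos")]
      sub <- sub[order(sub$utr_pos, sub$site_type), ]
      expect_identical(unname(as.matrix(sub)), unname(as.matrix(want)),
                       label = paste(g, mirnas$mirna_id[m]))
    }
  }
})

test_that("conservation requires support from two other species", {
  rat <- data.frame(gene_id = c("gA", "gB", "gC"), mirna_id = "m",
                    site_type = "8mer", utr_pos = 0L)
  one <- function(genes) data.frame(gene_id = genes,
                                    mirna_id = rep("m", length(genes)),
                                    site_type = rep("7mer-m8",
                                                    length(genes)),
                                    utr_pos = rep(5L, length(genes)))
  sites <- conservedSites(list(rat = rat, human = one(c("gA", "gB")),
                               mouse = one("gA"), dog = one(character(0))))
  expect_identical(sites$conserved, c(TRUE, FALSE, FALSE))
  expect_identical(sites$species_support[1], "rat,human,mouse")
  # gene missing from every other species cannot be conserved
  expect_false(sites$conserved[sites$gene_id == "gC"])
})

test_that("the density score counts conserved sites per list gene", {
  sites <- data.frame(gene_id = c("g1", "g1", "g3", "g4", "g9"),
                      mirna_id = "m", site_type = "8mer",
                      utr_pos = c(0L, 10L, 0L, 0L, 0L),
                      conserved = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(scoreGeneList(c("g1", "g2", "g3", "g4"), "m", sites), 1.0)
  expect_equal(scoreGeneList(c("g5", "g6"), "m", sites), 0.0)
  expect_error(scoreGeneList(character(0), "m", sites), "empty")
})

test_that("empirical p uses the plus-one rule with ties counted as extreme", {
  set.seed(17)
  background <- sprintf("b%03d", 1:100)
  sites <- data.frame(gene_id = c("b001", "b002"), mirna_id = "m",
                      site_type = "8mer", utr_pos = 0L, conserved = TRUE)
  res <- mirnaEnrichment(c("b001", "b002"), "m", sites, background,
                         nPerm = 500, seed = 99)
  tb <- enrichmentTable(res)
  nulls <- nullScores(res)[[1]]
  expect_equal(tb$p_emp, (sum(nulls >= tb$observed_score) + 1) / 501)
  expect_equal(tb$observed_score, 1.0)
  # observed above every null score gives the floor 1/(nPerm+1)
  expect_equal(tb$p_emp, 1 / 501)
  # a miRNA with no sites anywhere ties with every null: p = 1
  res0 <- mirnaEnrichment(c("b001", "b002"), "none", sites, background,
                          nPerm = 200, seed = 7)
  expect_equal(enrichmentTable(res0)$p_emp, 1.0)
})

test_that("the null draw is deterministic given the seed and monotone in sites", {
  set.seed(29)
  background <- sprintf("b%03d", 1:200)
  siteGenes <- sample(background, 40)
  sites <- data.frame(gene_id = siteGenes, mirna_id = "m",
                      site_type = "8mer", utr_pos = 0L, conserved = TRUE)
  lst <- sample(background, 25)
  a <- mirnaEnrichment(lst, "m", sites, background, nPerm = 300, seed = 5)
  b <- mirnaEnrichment(lst, "m", sites, background, nPerm = 300, seed = 5)
  expect_identical(enrichmentTable(a)$p_emp, enrichmentTable(b)$p_emp)
  expect_identical(nullScores(a), nullScores(b))
  # adding a conserved site to a list gene never increases p_emp
  sites2 <- rbind(sites, data.frame(gene_id = lst[1], mirna_id = "m",
                                    site_type = "8mer", utr_pos = 32L,
                                    conserved = TRUE))
  c_ <- mirnaEnrichment(lst, "m", sites2, background, nPerm = 300, seed = 5)
  expect_lte(enrichmentTable(c_)$p_emp, enrichmentTable(a)$p_emp)
})

test_that("p_emp is approximately uniform for background-drawn lists", {
  set.seed(37)
  background <- sprintf("b%04d", 1:500)
  # several sites per targeted gene so that list scores are not heavily
  # tied (ties are counted as extreme, which would bias p upward)
  tg <- sample(background, 150)
  siteTab <- do.call(rbind, lapply(seq_along(tg), function(i)
    data.frame(gene_id = tg[i], mirna_id = "m", site_type = "8mer",
               utr_pos = seq_len(1 + (i %% 3)) * 10L, conserved = TRUE)))
  ps <- vapply(1:200, function(i) {
    lst <- sample(background, 40)
    enrichmentTable(mirnaEnrichment(lst, "m", siteTab, background,
                                    nPerm = 499, seed = i))$p_emp
  }, numeric(1))
  expect_gt(mean(ps), 0.45)
  expect_lt(mean(ps), 0.55)
})

test_that("a planted master miRNA is ranked first among candidates", {
  set.seed(53)
  background <- sprintf("b%03d", 1:300)
  gps <- sprintf("p%02d", 1:20)
  background <- c(background, gps)
  mk <- function(genes, mir) if (length(genes))
    data.frame(gene_id = genes, mirna_id = mir, site_type = "8mer",
               utr_pos = 0L, conserved = TRUE) else NULL
  sites <- rbind(mk(gps, "master"), mk(sample(background, 15), "master"),
                 mk(sample(background, 15), "decoy1"),
                 mk(sample(background, 15), "decoy2"))
  res <- enrichGps(gps, c("decoy1", "master", "decoy2"), sites, background,
                   nPerm = 500, seed = 2)
  tb <- enrichmentTable(res)
  o <- order(tb$p_emp, -tb$observed_score)
  expect_identical(tb$mirna_id[o][1], "master")
  expect_equal(min(tb$p_emp), 1 / 501)
  expect_equal(tb$frac_targeted[tb$mirna_id == "master"], 1.0)
  # one targeted gene out of four gives frac_targeted 0.25
  res2 <- mirnaEnrichment(c("p01", "b001", "b002", "b003"), "decoy1",
                          mk("p01", "decoy1"), background, nPerm = 100,
                          seed = 3)
  expect_equal(enrichmentTable(res2)$frac_targeted, 0.25)
})

test_that("degenerate enrichment inputs are handled explicitly", {
  sites <- data.frame(gene_id = "g1", mirna_id = "m", site_type = "8mer",
                      utr_pos = 0L, conserved = TRUE)
  expect_warning(r <- enrichGps(character(0), "m", sites, c("g1", "g2")),
                 "empty GPS")
  expect_identical(nrow(enrichmentTable(r)), 0L)
  expect_warning(enrichGps("g1", character(0), sites, c("g1", "g2")),
                 "no upregulated")
  expect_error(mirnaEnrichment(c("g1", "g2"), "m", sites, c("g1", "g2")),
               "larger than")
  expect_error(mirnaEnrichment("gX", "m", sites, c("g1", "g2")), "subset")
})
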