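#' Configuration for a synthetic integrative study
#'
#' Builds the parameter set for [simulateStudy()]. The defaults describe a
#' two-condition beta-cell-like experiment at desk scale: 2000 genes, 20
#' miRNAs, 3 replicates per group in two batches, NB dispersion 0.05,
#' planted |log2FC| of 1.5, 10% transcriptionally regulated genes, 5% GPS
#' and 5% LPS genes, and one master miRNA whose conserved target sites are
#' planted in 80% of GPS genes against a 5% background targeting rate.
#'
#' @param nGenes,nMirnas numbers of genes and miRNAs.
#' @param nPerGroup replicates per condition (per assay).
#' @param conditions two condition labels, reference first.
#' @param batches batch labels cycled over replicates within condition.
#' @param meanLogRange range (natural-log scale) of baseline gene means;
#'   baselines are drawn log-uniformly.
#' @param mirnaMeanLogRange same for miRNA baselines.
#' @param alpha NB dispersion (0 gives Poisson counts).
#' @param fracTranscriptional,fracPtrGps,fracPtrLps planted fractions
#'   (must sum to at most 1).
#' @param effectLfc planted |log2 fold-change| (0 simulates a null study).
#' @param masterMirnaId id given to the master miRNA.
#' @param nUpMirnas,nDownMirnas how many miRNAs are planted up- (including
#'   the master) and down-regulated.
#' @param gpsTargetRate fraction of GPS genes receiving a conserved master
#'   site.
#' @param backgroundTargetRate per-miRNA fraction of all genes receiving a
#'   conserved site.
#' @param utrLen 3'UTR length (bases).
#' @param geneLengthRange range of annotated gene lengths (bases).
#' @param depthSd,batchSd lognormal sigmas for per-sample depth and
#'   per-batch-per-gene effects.
#' @param rngSeed seed controlling every random choice of the generator.
#' @return a validated `SimConfig` list.
#' @export
simStudyConfig <- function(nGenes = 2000, nMirnas = 20, nPerGroup = 3,
                           conditions = c("control", "treated"),
                           batches = c("b1", "b2"),
                           meanLogRange = log(c(200, 2000)),
                           mirnaMeanLogRange = log(c(600, 6000)),
                           alpha = 0.05,
                           fracTranscriptional = 0.10,
                           fracPtrGps = 0.05, fracPtrLps = 0.05,
                           effectLfc = 1.5,
                           masterMirnaId = "miR-29a",
                           nUpMirnas = 3, nDownMirnas = 2,
                           gpsTargetRate = 0.8,
                           backgroundTargetRate = 0.05,
                           utrLen = 600,
                           geneLengthRange = c(2500, 4000),
                           depthSd = 0.15, batchSd = 0.1,
                           rngSeed = 1) {
    cfg <- list(nGenes = as.integer(nGenes), nMirnas = as.integer(nMirnas),
                nPerGroup = as.integer(nPerGroup), conditions = conditions,
                batches = batches, meanLogRange = meanLogRange,
                mirnaMeanLogRange = mirnaMeanLogRange, alpha = alpha,
                fracTranscriptional = fracTranscriptional,
                fracPtrGps = fracPtrGps, fracPtrLps = fracPtrLps,
                effectLfc = effectLfc, masterMirnaId = masterMirnaId,
                nUpMirnas = as.integer(nUpMirnas),
                nDownMirnas = as.integer(nDownMirnas),
                gpsTargetRate = gpsTargetRate,
                backgroundTargetRate = backgroundTargetRate,
                utrLen = as.integer(utrLen),
                geneLengthRange = as.integer(geneLengthRange),
                depthSd = depthSd, batchSd = batchSd,
                rngSeed = as.integer(rngSeed))
    fr <- cfg$fracTranscriptional + cfg$fracPtrGps + cfg$fracPtrLps
    if (fr > 1)
        stop("planted fractions sum to ", fr, " > 1")
    rates <- c(cfg$gpsTargetRate, cfg$backgroundTargetRate)
    if (any(rates < 0 | rates > 1))
        stop("targeting rates must lie in [0, 1]")
    if (cfg$effectLfc < 0)
        stop("effectLfc must be non-negative")
    if (length(cfg$conditions) != 2)
        stop("exactly two conditions (reference first) are supported")
    if (cfg$nUpMirnas < 1 || cfg$nUpMirnas + cfg$nDownMirnas > cfg$nMirnas)
        stop("invalid numbers of regulated miRNAs")
    class(cfg) <- "SimConfig"
    cfg
}

.SIM_SPECIES <- c("rat", "human", "mouse", "dog")

# draw an NB count matrix; mu matrix, alpha scalar (0 => Poisson)
.rcounts <- function(mu, alpha) {
    k <- if (alpha > 0) stats::rnbinom(length(mu), mu = mu, size = 1 / alpha)
         else stats::rpois(length(mu), lambda = mu)
    matrix(as.integer(k), nrow = nrow(mu), dimnames = dimnames(mu))
}

# remove every canonical match for any miRNA from random UTR backbones so
# that planted site counts are fully controlled
.scrubUtrs <- function(seqs, pd, maxRounds = 40L) {
    spacer <- strrep("N", 8)
    for (round in seq_len(maxRounds)) {
        lens <- nchar(seqs)
        offs <- cumsum(c(0L, utils::head(lens + 8L, -1L)))
        concat <- Biostrings::DNAString(paste(seqs, collapse = spacer))
        m <- Biostrings::matchPDict(pd, concat)
        st <- unlist(Biostrings::startIndex(m), use.names = FALSE)
        if (!length(st))
            return(seqs)
        st <- unique(st)
        si <- findInterval(st - 1L, offs)
        loc <- st - offs[si]                 # 1-based within sequence
        for (h in seq_along(st)) {
            i <- si[h]
            substr(seqs[i], loc[h], loc[h] + 6L) <-
                paste(sample(c("A", "C", "G", "T"), 7, replace = TRUE),
                      collapse = "")
        }
    }
    stop("could not scrub UTR backbones of accidental seed matches")
}

#' Simulate a complete synthetic integrative study
#'
#' Generates annotation, single-base nascent-transcription signal, count
#' matrices for three assays (RNA-seq, ChRO-seq gene bodies, small RNA-seq),
#' 3'UTR sequences for four species with planted conserved target sites, a
#' mature miRNA set, sample metadata, and the ground truth needed to score
#' recovery. Transcriptionally regulated genes shift in both ChRO and RNA
#' counts; GPS genes shift (down) in RNA only; LPS genes shift (up) in RNA
#' only. The master miRNA is planted upregulated and its conserved sites are
#' enriched among GPS genes. ChRO-seq signal is emitted as single-base BED
#' records placed uniformly within the truncated gene bodies so that
#' [countSignal()] reproduces the intended count matrix exactly.
#'
#' @param cfg a `SimConfig` from [simStudyConfig()].
#' @param dir optional output directory; when given, all study files (GTF,
#'   per-sample signal BEDs, counts TSVs, UTR and miRNA FASTAs, metadata
#'   TSV, truth tables) are written there.
#' @return a list with elements `config`, `bodies` (truncated
#'   [GeneBodies]), `counts` (list of matrices: rna, chro, mirna),
#'   `colData` (list of data.frames per assay), `utrs` (named list of
#'   character vectors per species), `mirnas` (`DataFrame`), `truth`
#'   (list: `genes` data.frame with planted classes and fold-changes,
#'   `sites` data.frame of planted sites, `masterMirnaId`), and `files`
#'   (named paths, when `dir` was given).
#' @export
simulateStudy <- function(cfg = simStudyConfig(), dir = NULL) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$rngSeed)
    nG <- cfg$nGenes; nM <- cfg$nMirnas
    geneIds <- sprintf("g%04d", seq_len(nG))

    ## ---- annotation ----
    lens <- sample(seq(cfg$geneLengthRange[1], cfg$geneLengthRange[2]), nG,
                   replace = TRUE)
    gaps <- 1000L
    starts0 <- cumsum(c(0L, utils::head(lens + gaps, -1L))) + 10000L
    strands <- sample(c("+", "-"), nG, replace = TRUE)
    bodies <- GeneBodies(geneIds, "chr1", starts0, starts0 + lens, strands)
    bodies <- truncateGeneBodies(bodies)

    ## ---- planted gene classes ----
    nT <- round(cfg$fracTranscriptional * nG)
    nGps <- round(cfg$fracPtrGps * nG)
    nLps <- round(cfg$fracPtrLps * nG)
    cls <- rep("null", nG)
    cls[seq_len(nT)] <- rep(c("transcriptional_up", "transcriptional_down"),
                            length.out = nT)
    cls[nT + seq_len(nGps)] <- "GPS"
    cls[nT + nGps + seq_len(nLps)] <- "LPS"
    lfcRna <- numeric(nG); lfcChro <- numeric(nG)
    e <- cfg$effectLfc
    lfcRna[cls == "transcriptional_up"] <- e
    lfcRna[cls == "transcriptional_down"] <- -e
    lfcChro[cls == "transcriptional_up"] <- e
    lfcChro[cls == "transcriptional_down"] <- -e
    lfcRna[cls == "GPS"] <- -e
    lfcRna[cls == "LPS"] <- e

    ## ---- samples ----
    mkColData <- function(assay) {
        cond <- rep(cfg$conditions, each = cfg$nPerGroup)
        batch <- rep(rep_len(cfg$batches, cfg$nPerGroup), 2)
        data.frame(sample = paste(assay, cond,
                                  rep(seq_len(cfg$nPerGroup), 2), sep = "_"),
                   condition = cond, batch = batch, assay = assay,
                   stringsAsFactors = FALSE)
    }
    cd <- list(rna = mkColData("rna"), chro = mkColData("chro"),
               mirna = mkColData("mirna"))

    ## ---- counts ----
    qGene <- exp(stats::runif(nG, cfg$meanLogRange[1], cfg$meanLogRange[2]))
    drawAssay <- function(baseline, lfc, colData, ids) {
        nS <- nrow(colData)
        nF <- length(baseline)
        depth <- exp(stats::rnorm(nS, 0, cfg$depthSd))
        bEff <- matrix(exp(stats::rnorm(nF * length(cfg$batches), 0,
                                        cfg$batchSd)),
                       nF, dimnames = list(ids, cfg$batches))
        treated <- as.integer(colData$condition == cfg$conditions[2])
        mu <- matrix(0, nF, nS, dimnames = list(ids, colData$sample))
        for (j in seq_len(nS))
            mu[, j] <- baseline * 2^(treated[j] * lfc) *
                bEff[, colData$batch[j]] * depth[j]
        .rcounts(mu, cfg$alpha)
    }
    kRna <- drawAssay(qGene, lfcRna, cd$rna, geneIds)
    kChro <- drawAssay(qGene, lfcChro, cd$chro, geneIds)

    mirnaIds <- c(cfg$masterMirnaId,
                  sprintf("sim-miR-%02d", seq_len(nM - 1)))
    qMir <- exp(stats::runif(nM, cfg$mirnaMeanLogRange[1],
                             cfg$mirnaMeanLogRange[2]))
    lfcMir <- numeric(nM)
    lfcMir[seq_len(cfg$nUpMirnas)] <- e          # master is index 1
    lfcMir[cfg$nUpMirnas + seq_len(cfg$nDownMirnas)] <- -e
    kMir <- drawAssay(qMir, lfcMir, cd$mirna, mirnaIds)

    ## ---- miRNA sequences with unique seeds ----
    repeat {
        mature <- vapply(seq_len(nM), function(i)
            paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
                  collapse = ""), character(1))
        seeds <- substr(mature, 2, 8)
        if (!anyDuplicated(seeds)) break
    }
    mirnas <- DataFrame(mirna_id = mirnaIds, mature = mature, seed = seeds)

    ## ---- UTR backbones, scrub, plant ----
    allPats <- unique(unlist(lapply(seeds, function(s) {
        p <- seedPatterns(s)
        c(p[["7mer-m8"]], p[["7mer-A1"]])     # width-7 cores cover all types
    })))
    utrs <- list()
    L <- cfg$utrLen
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(allPats))
    for (sp in .SIM_SPECIES) {
        big <- paste(sample(c("A", "C", "G", "T"), nG * L, replace = TRUE),
                     collapse = "")
        raw <- substring(big, seq(1L, nG * L, L), seq(L, nG * L, L))
        names(raw) <- geneIds
        utrs[[sp]] <- .scrubUtrs(raw, pd)
    }
    ## plan all plantings first (non-overlapping slots: block starts every
    ## 8 bases), then execute per species in a single pass
    nBlocks <- L %/% 8L
    others <- setdiff(.SIM_SPECIES, "rat")
    planM <- integer(0); planG <- integer(0); planSp <- character(0)
    planB <- integer(0)
    usedBlocks <- new.env(parent = emptyenv())
    for (m in seq_len(nM)) {
        isMaster <- mirnaIds[m] == cfg$masterMirnaId
        targeted <- stats::runif(nG) < cfg$backgroundTargetRate
        if (isMaster)
            targeted[cls == "GPS"] <- stats::runif(nGps) < cfg$gpsTargetRate
        for (g in which(targeted)) {
            spHere <- c("rat", others[sample.int(3L, 2L)])
            for (sp in spHere) {
                key <- paste0(sp, "|", g)
                taken <- usedBlocks[[key]]
                free <- if (is.null(taken)) seq_len(nBlocks)
                        else setdiff(seq_len(nBlocks), taken)
                if (!length(free)) next
                b <- if (length(free) == 1L) free else free[sample.int(
                    length(free), 1L)]
                usedBlocks[[key]] <- c(taken, b)
                planM <- c(planM, m); planG <- c(planG, g)
                planSp <- c(planSp, sp); planB <- c(planB, b)
            }
        }
    }
    pats8 <- vapply(seeds, function(s) seedPatterns(s)[["8mer"]],
                    character(1))
    for (sp in .SIM_SPECIES) {
        idx <- which(planSp == sp)
        if (!length(idx)) next
        sv <- utrs[[sp]]
        for (i in idx) {
            p <- (planB[i] - 1L) * 8L + 1L
            substr(sv[planG[i]], p, p + 7L) <- pats8[planM[i]]
        }
        utrs[[sp]] <- sv
    }
    truthSites <- data.frame(gene_id = geneIds[planG],
                             mirna_id = mirnaIds[planM],
                             species = planSp,
                             utr_pos = (planB - 1L) * 8L,
                             stringsAsFactors = FALSE)

    truthGenes <- data.frame(gene_id = geneIds, class = cls,
                             lfc_rna = lfcRna, lfc_chro = lfcChro,
                             baseline = qGene, stringsAsFactors = FALSE)
    truth <- list(genes = truthGenes, sites = truthSites,
                  mirnaLfc = data.frame(mirna_id = mirnaIds,
                                        lfc = lfcMir,
                                        stringsAsFactors = FALSE),
                  masterMirnaId = cfg$masterMirnaId)

    out <- list(config = cfg, bodies = bodies,
                counts = list(rna = kRna, chro = kChro, mirna = kMir),
                colData = cd, utrs = utrs, mirnas = mirnas, truth = truth,
                files = NULL)

    ## ---- emit files ----
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        files <- list()
        # GTF (1-based closed)
        gtf <- file.path(dir, "annotation.gtf")
        writeLines(paste("chr1", "sim", "gene", starts0 + 1L, starts0 + lens,
                         ".", strands, ".",
                         sprintf('gene_id "%s";', geneIds), sep = "\t"), gtf)
        files$gtf <- gtf
        # ChRO signal BEDs: uniform positions within truncated bodies
        bs <- bodyStarts(bodies); be <- bodyEnds(bodies)
        for (j in seq_len(nrow(cd$chro))) {
            smp <- cd$chro$sample[j]
            reps <- kChro[, j]
            gidx <- rep(seq_len(nG), reps)
            width <- (be - bs)[gidx]
            pos <- bs[gidx] + floor(stats::runif(length(gidx)) * width)
            dt <- data.table::data.table(chrom = "chr1", pos = as.integer(pos),
                                         strand = strands[gidx])
            dt <- dt[, list(score = .N), by = c("chrom", "pos", "strand")]
            data.table::setorderv(dt, c("chrom", "pos", "strand"))
            bed <- data.table::data.table(chrom = dt$chrom, start = dt$pos,
                                          end = dt$pos + 1L, name = ".",
                                          score = dt$score,
                                          strand = dt$strand)
            f <- file.path(dir, paste0("signal_", smp, ".bed"))
            data.table::fwrite(bed, f, sep = "\t", col.names = FALSE)
            files$signal[[smp]] <- f
        }
        # counts + metadata
        files$rnaCounts <- writeCountsTsv(kRna, file.path(dir, "counts_rna.tsv"))
        files$chroCounts <- writeCountsTsv(kChro,
                                           file.path(dir, "counts_chro.tsv"))
        files$mirnaCounts <- writeCountsTsv(kMir,
                                            file.path(dir,
                                                      "counts_mirna.tsv"))
        md <- rbind(cd$rna, cd$chro, cd$mirna)
        # signal paths are recorded relative to the metadata file so the
        # study directory can be moved (and reruns are byte-identical)
        md$path <- ""
        md$path[md$assay == "chro"] <- basename(unlist(files$signal[
            md$sample[md$assay == "chro"]]))
        files$metadata <- file.path(dir, "metadata.tsv")
        data.table::fwrite(md, files$metadata, sep = "\t")
        # FASTAs (miRNAs written in the RNA alphabet)
        for (sp in .SIM_SPECIES) {
            f <- file.path(dir, paste0("utr_", sp, ".fa"))
            writeLines(paste0(">", geneIds, "\n", utrs[[sp]]), f)
            files$utrs[[sp]] <- f
        }
        files$mirnas <- file.path(dir, "mirnas.fa")
        writeLines(paste0(">", mirnaIds, "\n", chartr("T", "U", mature)),
                   files$mirnas)
        # truth
        files$truthGenes <- file.path(dir, "truth_genes.tsv")
        data.table::fwrite(truthGenes, files$truthGenes, sep = "\t")
        files$truthSites <- file.path(dir, "truth_sites.tsv")
        data.table::fwrite(truthSites, files$truthSites, sep = "\t")
        files$truthJson <- file.path(dir, "truth.json")
        jsonlite::write_json(list(masterMirnaId = cfg$masterMirnaId,
                                  classCounts = as.list(table(cls))),
                             files$truthJson, auto_unbox = TRUE)
        out$files <- files
    }
    out
}

#' Score pipeline recovery against the planted truth
#'
#' @param ptrCalls `DataFrame` from [classifyPtr()].
#' @param enrichment a [MirEnrichment] from the GPS enrichment stage (may be
#'   empty).
#' @param truth the `truth` element of a [simulateStudy()] result.
#' @return list with `perClass` (data.frame: class, n_true, n_called,
#'   sensitivity, fdr), `masterRank` (rank of the master miRNA by empirical
#'   p, ties broken by observed density; `NA` when untested) and
#'   `masterPemp`.
#' @export
evaluateRecovery <- function(ptrCalls, enrichment, truth) {
    tg <- truth$genes
    if (!all(tg$gene_id %in% rownames(ptrCalls)))
        stop("gene universe mismatch between truth and calls")
    called <- as.character(ptrCalls[tg$gene_id, "category"])
    trueCls <- ifelse(grepl("^transcriptional", tg$class), "transcriptional",
                      tg$class)
    classes <- c("GPS", "LPS", "transcriptional")
    perClass <- do.call(rbind, lapply(classes, function(cl) {
        nTrue <- sum(trueCls == cl)
        nCalled <- sum(called == cl)
        tp <- sum(called == cl & trueCls == cl)
        data.frame(class = cl, n_true = nTrue, n_called = nCalled,
                   sensitivity = if (nTrue) tp / nTrue else NA_real_,
                   fdr = if (nCalled) (nCalled - tp) / nCalled else 0,
                   stringsAsFactors = FALSE)
    }))
    tb <- enrichmentTable(enrichment)
    if (nrow(tb) && truth$masterMirnaId %in% tb$mirna_id) {
        o <- order(tb$p_emp, -tb$observed_score)
        masterRank <- match(truth$masterMirnaId, tb$mirna_id[o])
        masterPemp <- tb$p_emp[tb$mirna_id == truth$masterMirnaId]
    } else {
        masterRank <- NA_integer_
        masterPemp <- NA_real_
    }
    list(perClass = perClass, masterRank = masterRank,
         masterPemp = masterPemp)
}
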