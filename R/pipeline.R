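.DEFAULT_THRESHOLDS <- list(
    de = list(padjMax = 0.05, absLfcMin = 0.5, baseMeanMin = 500),
    dt = list(padjMax = 0.05, absLfcMin = 0.5),      # ChRO-seq calls
    ptr = list(padjMax = 0.2, baseMeanMin = 100, lfcMin = 0.5),
    enrichment = list(nPerm = 1000, requiredOtherSpecies = 2,
                      backgroundBaseMeanMin = 100))

.KNOWN_KEYS <- list(
    top = c("inputs", "contrasts", "thresholds", "conditions", "tssExclusion",
            "minGeneLength", "lengthFilterOn", "rngSeed", "outDir"),
    inputs = c("gtf", "metadata", "rnaCounts", "mirnaCounts", "chroCounts",
               "utrs", "mirnas"),
    thresholds = names(.DEFAULT_THRESHOLDS),
    de = c("padjMax", "absLfcMin", "baseMeanMin"),
    dt = c("padjMax", "absLfcMin"),
    ptr = c("padjMax", "baseMeanMin", "lfcMin"),
    enrichment = c("nPerm", "requiredOtherSpecies", "backgroundBaseMeanMin"))

# deterministic per-stage seed fan-out from the global seed
.stageSeed <- function(seed, stage) {
    stages <- c("simulate", "de", "integrate", "enrich")
    i <- match(stage, stages)
    if (is.na(i)) stop("unknown stage '", stage, "'")
    as.integer((as.numeric(seed) * 48271 + i * 1000003) %% 2147483587L) + 1L
}

.checkKeys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown))
        stop("unknown configuration key(s) in ", where, ": ",
             paste(unknown, collapse = ", "))
}

#' Validate and complete a pipeline configuration
#'
#' Reads a YAML file (or takes a list), rejects unknown keys by name, fills
#' defaults (1000 permutations; the published significance thresholds:
#' adjusted p < 0.05, |log2FC| > 0.5, baseMean > 500 for DE calls; adjusted
#' p < 0.2 and baseMean > 100 for the post-transcriptional definition), and
#' checks ranges and referenced paths.
#'
#' @param config path to a YAML file, or a list.
#' @param checkPaths verify that referenced input files exist (default TRUE
#'   when any inputs are given).
#' @return the completed configuration list (class `PipelineConfig`).
#' @export
validatePipelineConfig <- function(config, checkPaths = TRUE) {
    if (is.character(config) && length(config) == 1L) {
        if (!file.exists(config))
            stop("config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    stopifnot(is.list(config))
    .checkKeys(config, .KNOWN_KEYS$top, "top level")
    if (!is.null(config$inputs))
        .checkKeys(config$inputs, .KNOWN_KEYS$inputs, "inputs")
    th <- config$thresholds
    if (!is.null(th)) {
        .checkKeys(th, .KNOWN_KEYS$thresholds, "thresholds")
        for (blk in names(th))
            .checkKeys(th[[blk]], .KNOWN_KEYS[[blk]],
                       paste0("thresholds$", blk))
    }
    merged <- .DEFAULT_THRESHOLDS
    for (blk in names(th))
        merged[[blk]] <- utils::modifyList(merged[[blk]], th[[blk]])
    config$thresholds <- merged
    for (blk in c("de", "dt", "ptr")) {
        p <- merged[[blk]]$padjMax
        if (p <= 0 || p > 1)
            stop("thresholds$", blk, "$padjMax must lie in (0, 1], got ", p)
    }
    if (merged$enrichment$nPerm < 1)
        stop("thresholds$enrichment$nPerm must be >= 1")
    if (is.null(config$conditions))
        config$conditions <- c("control", "iAs", "MAs", "treated")
    if (is.null(config$contrasts))
        stop("at least one contrast (e.g. list(c('treated', 'control'))) ",
             "is required")
    config$contrasts <- lapply(config$contrasts, function(ct) {
        ct <- unlist(ct)
        if (length(ct) != 2)
            stop("each contrast must be c(levelA, levelB)")
        bad <- setdiff(ct, config$conditions)
        if (length(bad))
            stop("contrast references unknown condition(s): ",
                 paste(bad, collapse = ", "))
        ct
    })
    if (is.null(config$rngSeed)) config$rngSeed <- 1L
    if (is.null(config$tssExclusion)) config$tssExclusion <- 500L
    if (is.null(config$minGeneLength)) config$minGeneLength <- 1000L
    if (is.null(config$lengthFilterOn)) config$lengthFilterOn <- "span"
    if (checkPaths && !is.null(config$inputs)) {
        paths <- unlist(config$inputs)
        missing <- paths[!file.exists(paths)]
        if (length(missing))
            stop("input path(s) do not exist: ",
                 paste(missing, collapse = ", "))
    }
    class(config) <- c("PipelineConfig", "list")
    config
}

#' Differential expression for one contrast of one assay
#'
#' Subsets the samples to the two contrast levels, chooses the design
#' (`~ batch + condition` when more than one batch is present among the
#' selected samples, `~ condition` otherwise), and runs the NB Wald test.
#'
#' @param exp an [OmicsExperiment] (single assay type).
#' @param contrast `c(levelA, levelB)` condition levels.
#' @return `DataFrame` from [nbWaldTest()].
#' @export
runDE <- function(exp, contrast) {
    cd <- as.data.frame(SummarizedExperiment::colData(exp))
    sel <- cd$condition %in% contrast
    if (!any(cd$condition == contrast[1]) || !any(cd$condition == contrast[2]))
        stop("contrast levels not found: ", paste(contrast, collapse = " vs "))
    k <- SummarizedExperiment::assay(exp, "counts")[, sel, drop = FALSE]
    cdSel <- droplevels(cd[sel, , drop = FALSE])
    design <- if (length(unique(cdSel$batch)) > 1) ~ batch + condition
              else ~ condition
    nbWaldTest(k, cdSel, design = design,
               contrast = c("condition", contrast[1], contrast[2]))
}

#' Run the integrative analysis in memory
#'
#' The computational core behind [runPipeline()]: per contrast it runs
#' differential expression on all three assays, the two-factor interaction
#' test, GPS/LPS classification, fold-change concordance, and the
#' Monte-Carlo target enrichment of GPS genes against the miRNAs
#' upregulated in the same contrast.
#'
#' @param rna,chro,mirna [OmicsExperiment] objects.
#' @param utrs named list of UTR sequence sets (see [readUtrSequences()]).
#' @param mirnas miRNA table (see [readMirnas()]).
#' @param contrasts list of `c(levelA, levelB)` condition pairs.
#' @param thresholds nested threshold list as in the pipeline config
#'   (defaults used when `NULL`).
#' @param seed global seed; per-stage seeds are derived deterministically.
#' @return list with `sites` (conserved site table) and one entry per
#'   contrast carrying the stage results.
#' @export
runIntegrativeAnalysis <- function(rna, chro, mirna, utrs, mirnas,
                                   contrasts = list(c("treated", "control")),
                                   thresholds = NULL, seed = 1) {
    if (is.null(thresholds)) thresholds <- .DEFAULT_THRESHOLDS
    thDe <- thresholds$de; thDt <- thresholds$dt; thPtr <- thresholds$ptr
    thEn <- thresholds$enrichment
    ## conserved target sites (contrast-independent)
    sitesBySpecies <- lapply(utrs, findSeedSites, mirnas = mirnas)
    sites <- conservedSites(sitesBySpecies,
                            requiredOtherSpecies = thEn$requiredOtherSpecies)
    ratUtrGenes <- names(utrs$rat)
    out <- list(sites = sites, contrasts = list())
    for (ct in contrasts) {
        label <- paste0(ct[1], "_vs_", ct[2])
        rnaRes <- runDE(rna, ct)
        chroRes <- runDE(chro, ct)
        mirRes <- runDE(mirna, ct)
        sigMir <- significantFeatures(mirRes, thDe$padjMax, thDe$absLfcMin,
                                      thDe$baseMeanMin)
        sigGenes <- significantFeatures(rnaRes, thDe$padjMax, thDe$absLfcMin,
                                        thDe$baseMeanMin)
        dtGenes <- significantFeatures(chroRes, thDt$padjMax, thDt$absLfcMin,
                                       baseMeanMin = 0)
        twoF <- twoFactorTest(rna, chro, contrast = c("condition", ct[1],
                                                      ct[2]))
        calls <- classifyPtr(twoF, chroRes, rnaRes,
                             ptrPadjMax = thPtr$padjMax,
                             baseMeanMin = thPtr$baseMeanMin,
                             lfcMin = thPtr$lfcMin,
                             dtPadjMax = thDt$padjMax,
                             dtLfcMin = thDt$absLfcMin)
        gps <- rownames(calls)[calls$category == "GPS"]
        lps <- rownames(calls)[calls$category == "LPS"]
        background <- intersect(
            rownames(rnaRes)[!is.na(rnaRes$baseMean) &
                             rnaRes$baseMean > thEn$backgroundBaseMeanMin],
            ratUtrGenes)
        enr <- withCallingHandlers(
            enrichGps(gps, sigMir$up, sites, background,
                      nPerm = thEn$nPerm, seed = .stageSeed(seed, "enrich")),
            warning = function(w) {
                message("enrichment [", label, "]: ", conditionMessage(w))
                invokeRestart("muffleWarning")
            })
        conc <- tryCatch(concordanceReport(rnaRes, chroRes,
                                           baseMeanMin = thDe$baseMeanMin),
                         warning = function(w) list(r = NA_real_, n = 0L))
        out$contrasts[[label]] <- list(
            contrast = ct, rnaRes = rnaRes, chroRes = chroRes,
            mirnaRes = mirRes, sigMirnas = sigMir, sigGenes = sigGenes,
            dtGenes = dtGenes, twoFactor = twoF, ptrCalls = calls,
            gps = gps, lps = lps, background = background,
            enrichment = enr, concordance = conc)
    }
    out
}

.writeResultTsv <- function(df, path) {
    dt <- data.table::data.table(feature_id = rownames(df))
    for (cn in colnames(df)) dt[[cn]] <- as.vector(df[[cn]])
    data.table::fwrite(dt, path, sep = "\t", na = "NA")
    invisible(path)
}

#' Run the full pipeline from a configuration
#'
#' Executes: gene-model truncation, ChRO-seq gene-body counting (from
#' per-sample signal BEDs, or a precomputed counts TSV), per-contrast
#' differential expression on the three assays, the two-factor integration
#' and GPS/LPS classification, and the GPS target-site enrichment. Writes
#' per-stage TSVs, a machine-readable `summary.json` (stable content: no
#' timestamps, so reruns with the same seed are byte-identical) and
#' `pipeline.log` with versions, seeds and the parameter echo.
#'
#' @param config a `PipelineConfig` (see [validatePipelineConfig()]) or a
#'   path to a YAML file.
#' @return (invisibly) the [runIntegrativeAnalysis()] result list, with an
#'   added `summary` element.
#' @export
runPipeline <- function(config) {
    cfg <- if (inherits(config, "PipelineConfig")) config
           else validatePipelineConfig(config)
    outDir <- cfg$outDir
    if (is.null(outDir))
        stop("config$outDir is required")
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    logFile <- file.path(outDir, "pipeline.log")
    logCon <- file(logFile, open = "wt")
    on.exit(close(logCon), add = TRUE)
    logf <- function(...) {
        line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
        writeLines(line, logCon)
        message(line)
    }
    stage <- function(name, expr) {
        logf("stage ", name, " started")
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 " (partial outputs in ", outDir, ")", call. = FALSE))
    }
    logf("ptrOmics ", as.character(utils::packageVersion("ptrOmics")),
         " | ", R.version.string)
    logf("rngSeed=", cfg$rngSeed,
         " thresholds=", jsonlite::toJSON(cfg$thresholds, auto_unbox = TRUE))

    inp <- cfg$inputs
    md <- stage("metadata", readSampleMetadata(inp$metadata))
    bodies <- stage("annotation", {
        b <- readGeneModels(inp$gtf)
        truncateGeneBodies(b, cfg$tssExclusion, cfg$minGeneLength,
                           cfg$lengthFilterOn)
    })
    logf(sum(isEligible(bodies)), " of ", length(bodies),
         " genes eligible after truncation")

    mdChro <- md[md$assay == "chro", , drop = FALSE]
    chroCounts <- stage("chro-count", {
        if (!is.null(inp$chroCounts)) {
            readCountsTsv(inp$chroCounts)
        } else {
            if (!"path" %in% colnames(mdChro) || any(mdChro$path == ""))
                stop("metadata must provide a signal BED path per chro sample")
            # relative paths resolve against the metadata file's directory
            paths <- ifelse(file.exists(mdChro$path), mdChro$path,
                            file.path(dirname(inp$metadata), mdChro$path))
            cl <- lapply(paths, function(p)
                countSignal(readSignalBed(p), bodies))
            names(cl) <- mdChro$sample
            m <- do.call(cbind, cl)
            colnames(m) <- mdChro$sample
            m
        }
    })
    rnaCounts <- stage("rna-counts", readCountsTsv(inp$rnaCounts))
    mirCounts <- stage("mirna-counts", readCountsTsv(inp$mirnaCounts))
    asOE <- function(counts, assayName) {
        m <- md[md$assay == assayName, , drop = FALSE]
        cl <- lapply(m$sample, function(s) counts[, s])
        names(cl) <- m$sample
        assembleCountMatrix(cl, m, conditions = cfg$conditions)
    }
    rna <- stage("assemble", asOE(rnaCounts, "rna"))
    chro <- asOE(chroCounts, "chro")
    mirna <- asOE(mirCounts, "mirna")
    utrs <- stage("utrs", readUtrSequences(inp$utrs))
    mirnas <- stage("mirnas", readMirnas(inp$mirnas))

    res <- stage("analysis", runIntegrativeAnalysis(
        rna, chro, mirna, utrs, mirnas, contrasts = cfg$contrasts,
        thresholds = cfg$thresholds, seed = cfg$rngSeed))

    res$summary <- stage("report", {
        utils::write.table(res$sites, file.path(outDir, "target_sites.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        summary <- list(rngSeed = cfg$rngSeed, contrasts = list())
        for (label in names(res$contrasts)) {
            cres <- res$contrasts[[label]]
            .writeResultTsv(cres$rnaRes,
                            file.path(outDir, paste0("de_rna_", label, ".tsv")))
            .writeResultTsv(cres$chroRes,
                            file.path(outDir, paste0("de_chro_", label,
                                                     ".tsv")))
            .writeResultTsv(cres$mirnaRes,
                            file.path(outDir, paste0("de_mirna_", label,
                                                     ".tsv")))
            .writeResultTsv(cres$twoFactor,
                            file.path(outDir, paste0("two_factor_", label,
                                                     ".tsv")))
            .writeResultTsv(cres$ptrCalls,
                            file.path(outDir, paste0("ptr_calls_", label,
                                                     ".tsv")))
            etb <- as.data.frame(enrichmentTable(cres$enrichment))
            utils::write.table(etb, file.path(outDir, paste0("enrichment_",
                                                             label, ".tsv")),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            top <- if (nrow(etb)) {
                o <- order(etb$p_emp, -etb$observed_score)
                list(mirna_id = etb$mirna_id[o[1]],
                     p_emp = etb$p_emp[o[1]], padj = etb$padj[o[1]],
                     frac_targeted = etb$frac_targeted[o[1]])
            } else NULL
            summary$contrasts[[label]] <- list(
                n_sig_mirnas_up = length(cres$sigMirnas$up),
                n_sig_mirnas_down = length(cres$sigMirnas$down),
                n_sig_genes_up = length(cres$sigGenes$up),
                n_sig_genes_down = length(cres$sigGenes$down),
                n_dt_genes = length(cres$dtGenes$up) +
                    length(cres$dtGenes$down),
                n_gps = length(cres$gps), n_lps = length(cres$lps),
                concordance_r = cres$concordance$r,
                concordance_n = cres$concordance$n,
                top_mirna = top)
        }
        jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA,
                             null = "null")
        summary
    })
    logf("pipeline finished")
    invisible(res)
}
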