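#' Two-factor (assay x condition) interaction test
#'
#' Tests, per gene, whether the condition effect differs between steady-state
#' RNA-seq and nascent transcription (ChRO-seq). Counts from the two assays
#' are concatenated and a joint NB GLM is fitted with design
#' `~ assay + condition + assay:condition` (plus `batch` when present in
#' both assays); the Wald test is on the interaction coefficient, which
#' estimates the RNA-specific part of the condition effect (positive when
#' the RNA fold-change exceeds the transcriptional fold-change). Size
#' factors are computed within assay, since sequencing depth is not
#' comparable across assays. Genes absent or all-zero in either assay are
#' untestable (`NA`).
#'
#' @param rna,chro [OmicsExperiment] objects (assay types "rna" and "chro")
#'   or plain count matrices with matching `rnaColData`/`chroColData`.
#' @param contrast `c("condition", levelA, levelB)`; samples are subset to
#'   the two levels.
#' @param rnaColData,chroColData data.frames when matrices are supplied.
#' @return `DataFrame` with columns `interactionLfc` (log2), `lfcSE`, `stat`,
#'   `pvalue`, `padj`, plus per-assay `baseMean`s, indexed by the shared
#'   gene universe.
#' @export
twoFactorTest <- function(rna, chro,
                          contrast = c("condition", "treated", "control"),
                          rnaColData = NULL, chroColData = NULL) {
    ext <- function(x, cd, what) {
        if (is(x, "OmicsExperiment"))
            list(k = SummarizedExperiment::assay(x, "counts"),
                 cd = as.data.frame(SummarizedExperiment::colData(x)))
        else {
            if (is.null(cd)) stop("colData required for ", what, " matrix")
            list(k = as.matrix(x), cd = as.data.frame(cd))
        }
    }
    R <- ext(rna, rnaColData, "rna")
    C <- ext(chro, chroColData, "chro")
    fac <- contrast[1]; levA <- contrast[2]; levB <- contrast[3]
    selR <- R$cd[[fac]] %in% c(levA, levB)
    selC <- C$cd[[fac]] %in% c(levA, levB)
    if (!any(selR) || !any(selC))
        stop("contrast levels not found in both assays")
    kR <- R$k[, selR, drop = FALSE]; cdR <- R$cd[selR, , drop = FALSE]
    kC <- C$k[, selC, drop = FALSE]; cdC <- C$cd[selC, , drop = FALSE]
    genes <- union(rownames(R$k), rownames(C$k))
    shared <- intersect(rownames(kR), rownames(kC))
    kR <- kR[shared, , drop = FALSE]
    kC <- kC[shared, , drop = FALSE]
    sfR <- computeSizeFactors(kR)
    sfC <- computeSizeFactors(kC)
    baseMeanRna <- rowMeans(sweep(kR, 2, sfR, "/"))
    baseMeanChro <- rowMeans(sweep(kC, 2, sfC, "/"))
    counts <- cbind(kC, kR)                      # chro is the reference assay
    sf <- c(sfC, sfR)
    cd <- data.frame(
        assay = factor(rep(c("chro", "rna"), c(ncol(kC), ncol(kR))),
                       levels = c("chro", "rna")),
        condition = stats::relevel(factor(c(as.character(cdC[[fac]]),
                                            as.character(cdR[[fac]]))),
                                   ref = levB))
    useBatch <- "batch" %in% colnames(cdR) && "batch" %in% colnames(cdC) &&
        setequal(unique(cdR$batch), unique(cdC$batch)) &&
        length(unique(c(cdR$batch, cdC$batch))) > 1
    if (useBatch) {
        cd$batch <- factor(c(as.character(cdC$batch),
                             as.character(cdR$batch)))
        design <- ~ batch + assay + condition + assay:condition
    } else {
        design <- ~ assay + condition + assay:condition
    }
    X <- stats::model.matrix(design, cd)
    coefIdx <- grep(":", colnames(X))
    if (length(coefIdx) != 1)
        stop("unexpected design matrix; cannot locate interaction coefficient")
    testable <- rowSums(kR) > 0 & rowSums(kC) > 0
    cells <- interaction(cd[setdiff(all.vars(design), "")], drop = TRUE)
    disp <- estimateNBDispersions(counts, sf, cells)
    off <- log(sf)
    res <- matrix(NA_real_, length(shared), 3)
    alpha <- disp$alpha_final
    for (i in seq_along(shared)) {
        if (!testable[i] || is.na(alpha[i])) next
        res[i, ] <- .nbFitOne(counts[i, ], X, alpha[i], off, coefIdx)
    }
    stat <- res[, 1] / res[, 2]
    p <- 2 * stats::pnorm(-abs(stat))
    out <- DataFrame(interactionLfc = res[, 1] / log(2),
                     lfcSE = res[, 2] / log(2),
                     stat = stat, pvalue = p, padj = bhAdjust(p),
                     baseMeanRna = baseMeanRna, baseMeanChro = baseMeanChro,
                     row.names = shared)
    # genes present in only one assay are reported untestable
    missing <- setdiff(genes, shared)
    if (length(missing)) {
        pad <- DataFrame(interactionLfc = NA_real_, lfcSE = NA_real_,
                         stat = NA_real_, pvalue = NA_real_, padj = NA_real_,
                         baseMeanRna = NA_real_, baseMeanChro = NA_real_,
                         row.names = missing)
        out <- rbind(out, pad)
    }
    out[order(rownames(out)), ]
}

#' Classify genes as transcriptionally vs post-transcriptionally regulated
#'
#' Applies the two-stage definition of post-transcriptional regulation:
#' a gene is a candidate when the assay x condition interaction is
#' significant (adjusted p below `ptrPadjMax`), is *unchanged* at the
#' transcriptional level (ChRO-seq baseMean above `baseMeanMin` and adjusted
#' p above `ptrPadjMax`), and *changed* at steady state (RNA-seq baseMean
#' above `baseMeanMin`, |log2 fold-change| above `lfcMin`, adjusted p below
#' `ptrPadjMax`). Candidates with negative RNA fold-change gain
#' post-transcriptional suppression (GPS); positive ones lose it (LPS).
#' Genes significantly changed in nascent transcription (adjusted p below
#' `dtPadjMax` and |log2FC| above `dtLfcMin`) are "transcriptional"; the
#' rest are "unchanged"; genes with any missing component are "untestable".
#'
#' @param interaction `DataFrame` from [twoFactorTest()].
#' @param chroResults,rnaResults `DataFrame`s from [nbWaldTest()] on the
#'   ChRO-seq and RNA-seq counts for the same contrast.
#' @param ptrPadjMax adjusted-p threshold for the PTR definition
#'   (default 0.2).
#' @param baseMeanMin expression floor for both assays (default 100).
#' @param lfcMin |log2FC| threshold for the steady-state change
#'   (default 0.5).
#' @param dtPadjMax,dtLfcMin thresholds declaring a transcriptional change
#'   (defaults 0.05 and 0.5).
#' @return `DataFrame`: `category` in
#'   \{GPS, LPS, transcriptional, unchanged, untestable\} plus the component
#'   statistics used.
#' @export
classifyPtr <- function(interaction, chroResults, rnaResults,
                        ptrPadjMax = 0.2, baseMeanMin = 100, lfcMin = 0.5,
                        dtPadjMax = 0.05, dtLfcMin = 0.5) {
    genes <- sort(unique(c(rownames(interaction), rownames(chroResults),
                           rownames(rnaResults))))
    pick <- function(tab, col) {
        v <- rep(NA_real_, length(genes))
        i <- match(rownames(tab), genes)
        v[i] <- tab[[col]]
        v
    }
    int_padj <- pick(interaction, "padj")
    chro_padj <- pick(chroResults, "padj")
    chro_lfc <- pick(chroResults, "log2FoldChange")
    chro_bm <- pick(chroResults, "baseMean")
    rna_padj <- pick(rnaResults, "padj")
    rna_lfc <- pick(rnaResults, "log2FoldChange")
    rna_bm <- pick(rnaResults, "baseMean")
    comp <- cbind(int_padj, chro_padj, chro_lfc, chro_bm, rna_padj, rna_lfc,
                  rna_bm)
    untestable <- apply(is.na(comp), 1, any)
    ptrCore <- !untestable & int_padj < ptrPadjMax &
        chro_bm > baseMeanMin & chro_padj > ptrPadjMax &
        rna_bm > baseMeanMin & rna_padj < ptrPadjMax
    gps <- ptrCore & rna_lfc < -lfcMin
    lps <- ptrCore & rna_lfc > lfcMin
    transcr <- !untestable & !gps & !lps &
        chro_padj < dtPadjMax & abs(chro_lfc) > dtLfcMin
    category <- rep("unchanged", length(genes))
    category[transcr] <- "transcriptional"
    category[gps] <- "GPS"
    category[lps] <- "LPS"
    category[untestable] <- "untestable"
    DataFrame(category = factor(category,
                                levels = c("GPS", "LPS", "transcriptional",
                                           "unchanged", "untestable")),
              interaction_padj = int_padj,
              chro_padj = chro_padj, chro_lfc = chro_lfc,
              chro_baseMean = chro_bm,
              rna_padj = rna_padj, rna_lfc = rna_lfc, rna_baseMean = rna_bm,
              row.names = genes)
}

#' Concordance between nascent and steady-state fold-changes
#'
#' Pearson correlation of per-gene log2 fold-changes between ChRO-seq and
#' RNA-seq for one contrast, over genes with RNA-seq baseMean above
#' `baseMeanMin`.
#'
#' @param rnaResults,chroResults `DataFrame`s from [nbWaldTest()].
#' @param baseMeanMin RNA-seq expression floor (default 500).
#' @return list with `r` (Pearson), `n` (genes used). Fewer than 3 usable
#'   genes yields `r = NA` with a warning.
#' @export
concordanceReport <- function(rnaResults, chroResults, baseMeanMin = 500) {
    shared <- intersect(rownames(rnaResults), rownames(chroResults))
    r <- rnaResults[shared, ]; c_ <- chroResults[shared, ]
    ok <- !is.na(r$log2FoldChange) & !is.na(c_$log2FoldChange) &
        !is.na(r$baseMean) & r$baseMean > baseMeanMin
    if (sum(ok) < 3) {
        warning("fewer than 3 genes pass the concordance filter")
        return(list(r = NA_real_, n = sum(ok)))
    }
    list(r = stats::cor(r$log2FoldChange[ok], c_$log2FoldChange[ok]),
         n = sum(ok))
}
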