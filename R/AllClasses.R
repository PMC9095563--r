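#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames strand start end
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom data.table data.table fread fwrite setnames rbindlist setorderv .N .SD
NULL

#' Gene models with truncated counting windows
#'
#' `GeneBodies` extends [GenomicRanges::GRanges] with per-gene metadata
#' describing the gene-body counting window used for nascent-transcription
#' (ChRO-seq/PRO-seq) quantification. The underlying range is the full
#' annotated gene span (1-based, as in a GRanges); the counting window is kept
#' in 0-based half-open coordinates in the `body_start`/`body_end` metadata
#' columns so that single-base polymerase positions (BED convention) can be
#' assigned with `body_start <= pos < body_end`.
#'
#' Required metadata columns:
#' \describe{
#'   \item{gene_id}{unique gene identifier}
#'   \item{body_start, body_end}{0-based half-open counting window}
#'   \item{eligible}{passes the minimum gene-length filter (`NA` before
#'     truncation)}
#'   \item{truncated}{whether the promoter pause-region exclusion has been
#'     applied}
#' }
#'
#' @seealso [truncateGeneBodies()], [readGeneModels()], [countSignal()]
#' @export
setClass("GeneBodies", contains = "GRanges")

setValidity("GeneBodies", function(object) {
    mc <- mcols(object)
    need <- c("gene_id", "body_start", "body_end", "eligible", "truncated")
    miss <- setdiff(need, colnames(mc))
    if (length(miss))
        return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
    if (anyDuplicated(mc$gene_id))
        return("duplicated gene_id")
    if (length(object)) {
        if (any(strand(object) == "*"))
            return("strand must be '+' or '-'")
        s0 <- start(object) - 1L
        e0 <- end(object)
        bad <- mc$body_start < s0 | mc$body_end > e0
        # empty windows (body_start >= body_end) are allowed for ineligible genes
        if (any(bad & mc$body_start < mc$body_end))
            return("body window not contained in gene span")
    }
    TRUE
})

#' Construct a GeneBodies object
#'
#' Coordinates are given in the 0-based half-open convention (as in BED);
#' they are stored internally on the usual 1-based GRanges scale.
#'
#' @param geneId character vector of unique gene identifiers.
#' @param chrom chromosome names.
#' @param start,end 0-based half-open gene span.
#' @param strand "+" or "-".
#' @return A [GeneBodies] object with untruncated counting windows
#'   (`body == span`, `truncated = FALSE`, `eligible = NA`).
#' @examples
#' gb <- GeneBodies("geneA", "chr1", 1000, 4000, "+")
#' geneStarts(gb)  # 1000
#' @export
GeneBodies <- function(geneId, chrom, start, end, strand) {
    if (any(start >= end))
        stop("gene span must satisfy start < end")
    gr <- GRanges(chrom, IRanges(as.integer(start) + 1L, as.integer(end)),
                  strand = strand)
    mcols(gr) <- DataFrame(
        gene_id = as.character(geneId),
        body_start = as.integer(start),
        body_end = as.integer(end),
        eligible = rep(NA, length(gr)),
        truncated = rep(FALSE, length(gr)))
    new("GeneBodies", gr)
}

#' @describeIn GeneBodies-accessors gene identifiers
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @describeIn GeneBodies-accessors 0-based gene span starts
#' @export
setGeneric("geneStarts", function(x) standardGeneric("geneStarts"))
#' @describeIn GeneBodies-accessors 0-based half-open gene span ends
#' @export
setGeneric("geneEnds", function(x) standardGeneric("geneEnds"))
#' @describeIn GeneBodies-accessors 0-based counting-window starts
#' @export
setGeneric("bodyStarts", function(x) standardGeneric("bodyStarts"))
#' @describeIn GeneBodies-accessors 0-based half-open counting-window ends
#' @export
setGeneric("bodyEnds", function(x) standardGeneric("bodyEnds"))
#' @describeIn GeneBodies-accessors logical; passes the length filter
#' @export
setGeneric("isEligible", function(x) standardGeneric("isEligible"))

#' Accessors for GeneBodies
#'
#' All coordinate accessors return the 0-based half-open convention used
#' throughout the counting code.
#'
#' @param x a [GeneBodies] object.
#' @name GeneBodies-accessors
NULL

#' @rdname GeneBodies-accessors
setMethod("geneIds", "GeneBodies", function(x) mcols(x)$gene_id)
#' @rdname GeneBodies-accessors
setMethod("geneStarts", "GeneBodies", function(x) start(x) - 1L)
#' @rdname GeneBodies-accessors
setMethod("geneEnds", "GeneBodies", function(x) end(x))
#' @rdname GeneBodies-accessors
setMethod("bodyStarts", "GeneBodies", function(x) mcols(x)$body_start)
#' @rdname GeneBodies-accessors
setMethod("bodyEnds", "GeneBodies", function(x) mcols(x)$body_end)
#' @rdname GeneBodies-accessors
setMethod("isEligible", "GeneBodies", function(x) mcols(x)$eligible)

setMethod("show", "GeneBodies", function(object) {
    cat("GeneBodies with", length(object), "genes\n")
    if (length(object)) {
        tr <- all(mcols(object)$truncated)
        cat("  truncated:", tr, "\n")
        if (tr)
            cat("  eligible :", sum(mcols(object)$eligible), "of",
                length(object), "\n")
    }
    invisible(object)
})

#' Multi-assay count container
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] holding one raw count
#' matrix (assay `"counts"`) with the sample annotation columns the pipeline
#' requires: `condition`, `batch` and `assay` (one of `"rna"`, `"chro"`,
#' `"mirna"`).
#'
#' @seealso [assembleCountMatrix()]
#' @export
setClass("OmicsExperiment", contains = "SummarizedExperiment")

setValidity("OmicsExperiment", function(object) {
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    k <- SummarizedExperiment::assay(object, "counts")
    if (any(is.na(k)) || any(k < 0))
        return("counts must be non-negative and non-missing")
    cd <- SummarizedExperiment::colData(object)
    need <- c("condition", "batch", "assay")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        return(paste("missing colData column(s):", paste(miss, collapse = ", ")))
    if (anyDuplicated(colnames(object)))
        return("sample names must be unique")
    if (!all(cd$assay %in% c("rna", "chro", "mirna")))
        return("assay must be one of 'rna', 'chro', 'mirna'")
    TRUE
})

setMethod("show", "OmicsExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat("OmicsExperiment:", nrow(object), "features x", ncol(object),
        "samples\n")
    cat("  assay(s)   :", paste(unique(cd$assay), collapse = ", "), "\n")
    cat("  condition  :", paste(levels(factor(cd$condition)), collapse = ", "),
        "\n")
    cat("  batch      :", paste(levels(factor(cd$batch)), collapse = ", "),
        "\n")
    invisible(object)
})

#' Monte-Carlo miRNA target-site enrichment result
#'
#' Holds, per tested miRNA, the observed conserved target-site density of a
#' gene list, the permutation null (same-size random lists drawn from the
#' background universe), the empirical p-value with the plus-one correction,
#' the fraction of list genes carrying at least one conserved site, and
#' BH-adjusted p-values across the tested miRNAs.
#'
#' @slot table a `DataFrame` with columns `mirna_id`, `list_size`,
#'   `observed_score`, `p_emp`, `padj`, `frac_targeted`.
#' @slot nullScores list of numeric vectors (one per miRNA, length `nPerm`).
#' @slot nPerm number of permutations.
#' @slot seed RNG seed used for the null draws.
#' @seealso [mirnaEnrichment()], [enrichGps()]
#' @export
setClass("MirEnrichment",
         representation(table = "DataFrame", nullScores = "list",
                        nPerm = "integer", seed = "integer"))

setValidity("MirEnrichment", function(object) {
    tb <- object@table
    need <- c("mirna_id", "list_size", "observed_score", "p_emp", "padj",
              "frac_targeted")
    miss <- setdiff(need, colnames(tb))
    if (length(miss))
        return(paste("missing column(s):", paste(miss, collapse = ", ")))
    if (nrow(tb) != length(object@nullScores))
        return("one null-score vector per tested miRNA required")
    if (nrow(tb)) {
        lo <- 1 / (object@nPerm + 1)
        if (any(tb$p_emp < lo - 1e-12 | tb$p_emp > 1))
            return("p_emp out of [1/(nPerm+1), 1]")
        if (any(tb$frac_targeted < 0 | tb$frac_targeted > 1))
            return("frac_targeted out of [0, 1]")
    }
    TRUE
})

#' @describeIn MirEnrichment-class extract the per-miRNA result table
#' @param x a `MirEnrichment` object.
#' @export
enrichmentTable <- function(x) {
    stopifnot(is(x, "MirEnrichment"))
    x@table
}

#' @describeIn MirEnrichment-class extract the permutation null scores
#' @export
nullScores <- function(x) {
    stopifnot(is(x, "MirEnrichment"))
    x@nullScores
}

setMethod("show", "MirEnrichment", function(object) {
    tb <- object@table
    cat("MirEnrichment:", nrow(tb), "miRNA(s),", object@nPerm,
        "permutations (seed", object@seed, ")\n")
    if (nrow(tb)) {
        o <- order(tb$p_emp, -tb$observed_score)
        top <- tb[o[1], ]
        cat(sprintf("  top: %s  density=%.4g  p_emp=%.4g  padj=%.4g\n",
                    top$mirna_id, top$observed_score, top$p_emp, top$padj))
    }
    invisible(object)
})
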