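#' Read single-base polymerase-position signal from BED6
#'
#' ChRO-seq/PRO-seq signal is represented as stranded single-base intervals:
#' each record marks the 3' end of a nascent RNA (the position of the active
#' polymerase). The BED score column carries the collapsed read count
#' (weight); scores of 0 or NA are taken as weight 1.
#'
#' @param path BED6 file.
#' @return [GenomicRanges::GRanges] of width-1 ranges with a `weight`
#'   metadata column.
#' @details Intervals with width other than 1 are an error citing the first
#'   offending record.
#' @export
readSignalBed <- function(path) {
    if (!file.exists(path))
        stop("signal BED not readable: ", path)
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    if (ncol(dt) < 6)
        stop("signal BED must have 6 columns (strand in column 6): ", path)
    data.table::setnames(dt, 1:6, c("chrom", "start", "end", "name", "score",
                                    "strand"))
    bad <- which(dt$end - dt$start != 1L)
    if (length(bad))
        stop("signal record is not a single base at line ", bad[1], " of ",
             path, " (", dt$chrom[bad[1]], ":", dt$start[bad[1]], "-",
             dt$end[bad[1]], ")")
    w <- suppressWarnings(as.integer(dt$score))
    w[is.na(w) | w < 1L] <- 1L
    gr <- GRanges(dt$chrom, IRanges(dt$start + 1L, width = 1L),
                  strand = dt$strand)
    mcols(gr)$weight <- w
    gr
}

#' Count stranded single-base signal in truncated gene bodies
#'
#' A record contributes to gene `g` when the chromosome matches, the strand
#' matches, and the 0-based position satisfies
#' `body_start <= pos < body_end`. Weights are summed; a record overlapping
#' several eligible genes counts once per overlapped gene. Only genes passing
#' the length filter are counted.
#'
#' @param signal a `GRanges` of width-1 records with a `weight` column (see
#'   [readSignalBed()]), or a data.frame with columns `chrom`, `pos`
#'   (0-based), `strand`, and optionally `weight`.
#' @param genes a truncated [GeneBodies] object.
#' @return named integer vector of per-gene counts over the eligible genes.
#' @export
countSignal <- function(signal, genes) {
    stopifnot(is(genes, "GeneBodies"))
    if (!all(mcols(genes)$truncated))
        stop("gene bodies must be truncated before counting",
             " (see truncateGeneBodies)")
    if (is.data.frame(signal)) {
        w <- if ("weight" %in% colnames(signal)) as.integer(signal$weight)
             else rep(1L, nrow(signal))
        signal <- GRanges(signal$chrom,
                          IRanges(as.integer(signal$pos) + 1L, width = 1L),
                          strand = signal$strand, weight = w)
    }
    if (length(signal) && any(GenomicRanges::width(signal) != 1L))
        stop("signal must consist of single-base records")
    mc <- mcols(genes)
    elig <- which(mc$eligible)
    out <- integer(length(elig))
    names(out) <- mc$gene_id[elig]
    if (!length(elig) || !length(signal))
        return(out)
    bodies <- GRanges(seqnames(genes)[elig],
                      IRanges(mc$body_start[elig] + 1L, mc$body_end[elig]),
                      strand = strand(genes)[elig])
    hits <- GenomicRanges::findOverlaps(signal, bodies, ignore.strand = FALSE)
    if (length(hits)) {
        agg <- tapply(mcols(signal)$weight[S4Vectors::queryHits(hits)],
                      S4Vectors::subjectHits(hits), sum)
        out[as.integer(names(agg))] <- as.integer(agg)
    }
    out
}

#' Read the sample metadata table
#'
#' @param path TSV with columns `sample`, `condition`, `batch`, `assay` and
#'   optionally `path` (per-sample signal or counts file).
#' @return data.frame.
#' @export
readSampleMetadata <- function(path) {
    md <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
    need <- c("sample", "condition", "batch", "assay")
    miss <- setdiff(need, colnames(md))
    if (length(miss))
        stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
    md
}

#' Assemble per-sample counts into an OmicsExperiment
#'
#' Column order follows the metadata row order; condition and assay labels
#' are validated.
#'
#' @param countsList named list of per-sample named count vectors (identical
#'   gene universe), names are sample ids.
#' @param metadata data.frame with columns `sample`, `condition`, `batch`,
#'   `assay`.
#' @param conditions allowed condition labels; the first is the reference.
#' @return an [OmicsExperiment].
#' @export
assembleCountMatrix <- function(countsList, metadata,
                                conditions = c("control", "iAs", "MAs",
                                               "treated")) {
    if (anyDuplicated(metadata$sample))
        stop("duplicated sample id(s) in metadata: ",
             paste(unique(metadata$sample[duplicated(metadata$sample)]),
                   collapse = ", "))
    bad <- setdiff(unique(metadata$condition), conditions)
    if (length(bad))
        stop("unknown condition label(s): ", paste(bad, collapse = ", "),
             " (allowed: ", paste(conditions, collapse = ", "), ")")
    miss <- setdiff(metadata$sample, names(countsList))
    if (length(miss))
        stop("no counts for sample(s): ", paste(miss, collapse = ", "))
    universe <- names(countsList[[1]])
    for (s in metadata$sample) {
        if (!identical(names(countsList[[s]]), universe))
            stop("gene universe differs for sample '", s, "'")
    }
    m <- vapply(metadata$sample, function(s) as.integer(countsList[[s]]),
                integer(length(universe)))
    if (length(universe) == 1L) m <- matrix(m, nrow = 1L,
                                            dimnames = list(universe,
                                                            metadata$sample))
    rownames(m) <- universe
    colnames(m) <- metadata$sample
    cd <- DataFrame(condition = factor(metadata$condition,
                                       levels = intersect(conditions,
                                                          metadata$condition)),
                    batch = as.character(metadata$batch),
                    assay = as.character(metadata$assay),
                    row.names = metadata$sample)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = m), colData = cd)
    new("OmicsExperiment", se)
}

#' Write / read a counts matrix as TSV
#'
#' The first column is `gene_id`, one column per sample.
#' @param counts integer matrix with row and column names.
#' @param path output file.
#' @export
writeCountsTsv <- function(counts, path) {
    dt <- data.table::data.table(gene_id = rownames(counts))
    for (j in colnames(counts)) dt[[j]] <- counts[, j]
    data.table::fwrite(dt, path, sep = "\t")
    invisible(path)
}

#' @rdname writeCountsTsv
#' @return `readCountsTsv`: integer matrix with gene ids as row names.
#' @export
readCountsTsv <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE)
    m <- as.matrix(dt[, -1])
    storage.mode(m) <- "integer"
    rownames(m) <- dt[[1]]
    m
}
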