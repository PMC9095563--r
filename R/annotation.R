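#' Read gene models from a GTF file
#'
#' Imports gene annotation and returns one untruncated [GeneBodies] entry per
#' gene. When gene-level records are present they are used directly; otherwise
#' transcript (or exon) records sharing a `gene_id` are collapsed to the union
#' of their spans, which is appropriate for gene-body-wide nascent
#' transcription signal. GTF 1-based closed coordinates are converted to the
#' 0-based half-open convention used internally.
#'
#' @param path path to a GTF file.
#' @return A [GeneBodies] object (untruncated).
#' @details Duplicate `gene_id`s with conflicting coordinates (different
#'   chromosome or strand) are an error. An empty file yields an empty object
#'   with a warning.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "src", "gene", 1001, 4000, ".", "+", ".",
#'                  'gene_id "geneA";', sep = "\t"), gtf)
#' gb <- readGeneModels(gtf)
#' geneStarts(gb)  # 1000
#' @export
readGeneModels <- function(path) {
    if (!file.exists(path))
        stop("annotation file not found: ", path)
    if (file.size(path) == 0 ||
        !length(grep("^[^#]", readLines(path, warn = FALSE)))) {
        warning("empty annotation file: ", path)
        return(GeneBodies(character(), character(), integer(), integer(),
                          character())[0])
    }
    gr <- tryCatch(
        rtracklayer::import(path, format = "gtf"),
        error = function(e) stop("malformed GTF '", path, "': ",
                                 conditionMessage(e)))
    if (is.null(gr$gene_id) || anyNA(gr$gene_id))
        stop("GTF records without gene_id in ", path)
    if ("gene" %in% as.character(gr$type))
        gr <- gr[gr$type == "gene"]
    dt <- data.table::data.table(
        gene_id = as.character(gr$gene_id),
        chrom = as.character(seqnames(gr)),
        start1 = start(gr), end1 = end(gr),
        strand = as.character(strand(gr)))
    agg <- dt[, {
        if (length(unique(chrom)) > 1L || length(unique(strand)) > 1L)
            stop("duplicate gene_id '", gene_id[1],
                 "' with conflicting coordinates")
        list(chrom = chrom[1], start1 = min(start1), end1 = max(end1),
             strand = strand[1])
    }, by = "gene_id"]
    GeneBodies(agg$gene_id, agg$chrom, agg$start1 - 1L, agg$end1, agg$strand)
}

#' Apply pause-region exclusion and gene-length filter
#'
#' Truncates each gene-body counting window by removing `tssExclusion` bases
#' downstream of the transcription start site (the promoter-proximal
#' polymerase pause peak), and flags genes shorter than `minGeneLength` as
#' ineligible for counting. On the plus strand the window becomes
#' `[start + tssExclusion, end)`; on the minus strand
#' `[start, end - tssExclusion)`.
#'
#' @param x a [GeneBodies] object.
#' @param tssExclusion bases removed downstream of the TSS (default 500).
#' @param minGeneLength minimum length in bases (default 1000); genes below
#'   it are excluded (strictly: length < `minGeneLength` fails).
#' @param lengthFilterOn `"span"` (default) applies the filter to the full
#'   annotated gene span; `"body"` applies it to the truncated window.
#' @return The truncated [GeneBodies]; idempotent (re-truncating changes
#'   nothing).
#' @export
truncateGeneBodies <- function(x, tssExclusion = 500L, minGeneLength = 1000L,
                               lengthFilterOn = c("span", "body")) {
    stopifnot(is(x, "GeneBodies"))
    lengthFilterOn <- match.arg(lengthFilterOn)
    mc <- mcols(x)
    if (length(x) && all(mc$truncated))
        return(x)
    s0 <- start(x) - 1L
    e0 <- end(x)
    plus <- as.character(strand(x)) == "+"
    bs <- ifelse(plus, s0 + as.integer(tssExclusion), s0)
    be <- ifelse(plus, e0, e0 - as.integer(tssExclusion))
    span_len <- e0 - s0
    body_len <- pmax(be - bs, 0L)
    elig <- if (lengthFilterOn == "span") span_len >= minGeneLength
            else body_len >= minGeneLength
    elig <- elig & body_len > 0L
    mc$body_start <- as.integer(bs)
    mc$body_end <- as.integer(be)
    mc$eligible <- elig
    mc$truncated <- TRUE
    mcols(x) <- mc
    metadata(x)$tssExclusion <- as.integer(tssExclusion)
    metadata(x)$minGeneLength <- as.integer(minGeneLength)
    metadata(x)$lengthFilterOn <- lengthFilterOn
    validObject(x)
    x
}

#' Export truncated gene bodies as BED6
#'
#' Writes one BED line per gene: the truncated counting window in 0-based
#' half-open coordinates, `name` = gene id, `score` = 0, strand in column 6.
#' Ineligible genes are written too (their windows may be empty of signal by
#' construction); [importBodiesBed()] restores the windows bit-exactly.
#'
#' @param x a truncated [GeneBodies] object.
#' @param path output file.
#' @param eligibleOnly write only genes passing the length filter.
#' @export
exportBodiesBed <- function(x, path, eligibleOnly = FALSE) {
    stopifnot(is(x, "GeneBodies"), all(mcols(x)$truncated))
    mc <- mcols(x)
    keep <- if (eligibleOnly) which(mc$eligible) else seq_along(x)
    dt <- data.table::data.table(
        chrom = as.character(seqnames(x))[keep],
        start = mc$body_start[keep],
        end = mc$body_end[keep],
        name = mc$gene_id[keep],
        score = 0L,
        strand = as.character(strand(x))[keep])
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
    invisible(path)
}

#' Read gene-body windows back from BED6
#'
#' @param path BED6 file written by [exportBodiesBed()].
#' @return data.frame with columns `gene_id`, `chrom`, `body_start`,
#'   `body_end`, `strand` (0-based half-open).
#' @export
importBodiesBed <- function(path) {
    bed <- rtracklayer::import(path, format = "bed")
    data.frame(gene_id = bed$name,
               chrom = as.character(seqnames(bed)),
               body_start = start(bed) - 1L,
               body_end = end(bed),
               strand = as.character(strand(bed)),
               stringsAsFactors = FALSE)
}

#' Load 3'UTR sequences for several species
#'
#' Reads one FASTA per species. Headers are keyed by gene id (first
#' whitespace-delimited token). Sequences are uppercased and U is normalized
#' to T so that downstream seed matching is exact-string over \{A,C,G,T,N\}.
#' Within a species, duplicate gene ids keep the longest sequence (with a
#' warning).
#'
#' @param paths named character vector or list, `species -> FASTA path`.
#' @param requiredSpecies species that must be present; an absent file is an
#'   error naming the species.
#' @return named list of [Biostrings::DNAStringSet], one per species, names
#'   are gene ids.
#' @export
readUtrSequences <- function(paths,
                             requiredSpecies = c("rat", "human", "mouse",
                                                 "dog")) {
    paths <- unlist(paths)
    miss <- setdiff(requiredSpecies, names(paths))
    if (length(miss))
        stop("missing UTR file(s) for species: ", paste(miss, collapse = ", "),
             " (required: ", paste(requiredSpecies, collapse = ", "), ")")
    out <- list()
    for (sp in names(paths)) {
        if (!file.exists(paths[[sp]]))
            stop("UTR FASTA for species '", sp, "' not readable: ",
                 paths[[sp]])
        seqs <- Biostrings::readBStringSet(paths[[sp]])
        ids <- sub("\\s.*$", "", names(seqs))
        chr <- chartr("uU", "tT", as.character(seqs))
        chr <- toupper(chr)
        if (any(nchar(chr) == 0))
            stop("empty UTR sequence in species '", sp, "'")
        if (anyDuplicated(ids)) {
            warning("species '", sp, "': duplicate gene id(s) ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "),
                    "; keeping the longest sequence")
            o <- order(-nchar(chr))
            keep <- !duplicated(ids[o])
            idx <- o[keep]
            idx <- sort(idx[order(ids[idx])])  # stable, id-sorted selection
            chr <- chr[idx]; ids <- ids[idx]
        }
        ss <- Biostrings::DNAStringSet(chr)
        names(ss) <- ids
        out[[sp]] <- ss
    }
    out
}

#' Load mature miRNA sequences
#'
#' Reads a FASTA of mature miRNA sequences (RNA or DNA alphabet) and extracts
#' the seed: positions 2-8 of the mature sequence. Records shorter than 8 nt
#' are rejected with a warning.
#'
#' @param path FASTA file.
#' @return `DataFrame` with columns `mirna_id`, `mature` (normalized to the
#'   DNA alphabet), `seed` (7-mer, DNA alphabet).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">miR-x", "UAGCACCAUCUGAAAUCGGUUA"), fa)
#' readMirnas(fa)$seed  # "AGCACCA"
#' @export
readMirnas <- function(path) {
    if (!file.exists(path))
        stop("miRNA FASTA not readable: ", path)
    seqs <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(seqs))
    chr <- toupper(chartr("uU", "tT", as.character(seqs)))
    short <- nchar(chr) < 8
    if (any(short)) {
        warning("rejecting ", sum(short), " miRNA record(s) shorter than 8 nt: ",
                paste(ids[short], collapse = ", "))
        chr <- chr[!short]; ids <- ids[!short]
    }
    if (anyDuplicated(ids))
        stop("duplicate miRNA id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    DataFrame(mirna_id = unname(ids), mature = unname(chr),
              seed = unname(substr(chr, 2L, 8L)))
}
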