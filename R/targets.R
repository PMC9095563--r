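#' Canonical seed-match patterns for a miRNA seed
#'
#' The seed is positions 2-8 of the mature miRNA. The 7-mer site core
#' (`match7`) is the reverse complement of the seed in DNA alphabet; the
#' canonical site classes on the mRNA sense strand are `8mer` =
#' `match7 + "A"`, `7mer-m8` = `match7`, and `7mer-A1` = `match7[2:7] + "A"`.
#'
#' @param seed 7-nt seed (RNA or DNA alphabet).
#' @return named character vector with elements `8mer`, `7mer-m8`, `7mer-A1`.
#' @export
seedPatterns <- function(seed) {
    seed <- toupper(chartr("uU", "tT", seed))
    if (nchar(seed) != 7)
        stop("seed must be 7 nt")
    match7 <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(seed)))
    c("8mer" = paste0(match7, "A"),
      "7mer-m8" = match7,
      "7mer-A1" = paste0(substr(match7, 2, 7), "A"))
}

# priority order used when overlapping candidate sites compete
.SITE_PRIORITY <- c("8mer" = 3L, "7mer-m8" = 2L, "7mer-A1" = 1L)

# Suppress candidates overlapping an accepted candidate of strictly higher
# priority within the same (gene, miRNA). Accepted 8mers suppress
# overlapping 7mer-m8/7mer-A1 candidates; accepted 7mer-m8s suppress
# overlapping 7mer-A1s. Same-priority overlaps are all kept. `cand` is a
# data.table with gene_id, mirna_id, utr_pos (0-based), width, prio.
.suppressLowerPriority <- function(cand) {
    byCols <- c("gene_id", "mirna_id")
    asIv <- function(dt) {
        dt <- data.table::copy(dt)
        dt$.s <- dt$utr_pos
        dt$.e <- dt$utr_pos + dt$width - 1L   # closed for foverlaps
        data.table::setkeyv(dt, c(byCols, ".s", ".e"))
        dt
    }
    dropOverlapping <- function(x, y) {
        if (!nrow(x) || !nrow(y))
            return(x)
        hit <- data.table::foverlaps(x, y, by.x = c(byCols, ".s", ".e"),
                                     which = TRUE, nomatch = NULL)
        if (nrow(hit)) x[-unique(hit$xid), ] else x
    }
    c8 <- asIv(cand[cand$prio == 3L, ])
    c7 <- asIv(cand[cand$prio == 2L, ])
    c1 <- asIv(cand[cand$prio == 1L, ])
    c7 <- dropOverlapping(c7, c8)
    c1 <- dropOverlapping(dropOverlapping(c1, c8), c7)
    out <- data.table::rbindlist(list(c8, c7, c1))
    out$.s <- NULL; out$.e <- NULL
    out
}

#' Find canonical miRNA seed-match sites in 3'UTR sequences
#'
#' Scans each UTR (mRNA sense strand, DNA alphabet) left to right for the
#' three canonical site classes of each miRNA. At overlapping loci only the
#' highest-priority class is reported (8mer > 7mer-m8 > 7mer-A1): a 7mer-m8
#' or 7mer-A1 match subsumed by a reported 8mer is suppressed. `N` bases
#' never match.
#'
#' @param utrs a named [Biostrings::DNAStringSet] (names are gene ids), a
#'   single character string, or a named character vector.
#' @param mirnas a `DataFrame`/data.frame with columns `mirna_id` and `seed`
#'   (see [readMirnas()]), or a single 7-nt seed string.
#' @return data.frame with columns `gene_id`, `mirna_id`, `site_type`,
#'   `utr_pos` (0-based start in the UTR), ordered by gene, miRNA, position.
#' @examples
#' findSeedSites(c(geneA = "AAATGGTGCTAAA"),
#'               data.frame(mirna_id = "m", seed = "AGCACCA"))
#' @export
findSeedSites <- function(utrs, mirnas) {
    if (is.character(utrs)) {
        if (is.null(names(utrs)))
            names(utrs) <- paste0("seq", seq_along(utrs))
        utrs <- Biostrings::DNAStringSet(utrs)
    }
    if (is.character(mirnas) && length(mirnas) == 1L)
        mirnas <- data.frame(mirna_id = "mirna", seed = mirnas)
    mirnas <- as.data.frame(mirnas)
    empty <- data.frame(gene_id = character(), mirna_id = character(),
                        site_type = character(), utr_pos = integer(),
                        stringsAsFactors = FALSE)
    if (!length(utrs) || !nrow(mirnas))
        return(empty)
    ## all patterns, scanned with one PDict per pattern width over the
    ## concatenated UTR set (N spacers cannot match any pattern)
    patTab <- do.call(rbind, lapply(seq_len(nrow(mirnas)), function(m) {
        pats <- seedPatterns(mirnas$seed[m])
        data.frame(mirna_id = mirnas$mirna_id[m], site_type = names(pats),
                   pattern = unname(pats), width = nchar(unname(pats)),
                   prio = .SITE_PRIORITY[names(pats)],
                   stringsAsFactors = FALSE)
    }))
    seqChr <- as.character(utrs)
    lens <- nchar(seqChr)
    offs <- cumsum(c(0L, utils::head(lens + 8L, -1L)))
    subject <- Biostrings::DNAString(paste(seqChr, collapse = strrep("N", 8)))
    res <- list(); k <- 0L
    for (wdt in unique(patTab$width)) {
        sel <- which(patTab$width == wdt)
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(patTab$pattern[sel]))
        hits <- Biostrings::matchPDict(pd, subject)
        st <- Biostrings::startIndex(hits)
        nh <- lengths(st)
        if (!sum(nh)) next
        starts <- unlist(st, use.names = FALSE)
        si <- findInterval(starts - 1L, offs)
        k <- k + 1L
        res[[k]] <- data.table::data.table(
            gene_id = names(utrs)[si],
            mirna_id = rep(patTab$mirna_id[sel], nh),
            site_type = rep(patTab$site_type[sel], nh),
            utr_pos = starts - offs[si] - 1L,
            width = wdt,
            prio = rep(patTab$prio[sel], nh))
    }
    if (!k)
        return(empty)
    cand <- data.table::rbindlist(res)
    out <- .suppressLowerPriority(cand)
    out <- out[order(out$gene_id, out$mirna_id, out$utr_pos), ]
    data.frame(gene_id = out$gene_id, mirna_id = out$mirna_id,
               site_type = out$site_type, utr_pos = out$utr_pos,
               stringsAsFactors = FALSE)
}

#' Cross-species conservation of reference-species sites
#'
#' A site in the reference species (rat) is conserved when, for the same
#' (gene, miRNA) pair, at least `requiredOtherSpecies` of the non-reference
#' species carry at least one canonical site of any class in their UTR of
#' that gene. Conservation is presence-based (no positional alignment);
#' species lacking a UTR for the gene simply do not support it.
#'
#' @param sitesBySpecies named list of site tables from [findSeedSites()],
#'   one per species; must include `refSpecies`.
#' @param requiredOtherSpecies minimum number of supporting non-reference
#'   species (default 2).
#' @param refSpecies reference species name (default "rat").
#' @return the reference-species site table with added columns
#'   `species_support` (comma-separated, reference first) and `conserved`.
#' @export
conservedSites <- function(sitesBySpecies, requiredOtherSpecies = 2,
                           refSpecies = "rat") {
    if (!refSpecies %in% names(sitesBySpecies))
        stop("no site table for reference species '", refSpecies, "'")
    ref <- sitesBySpecies[[refSpecies]]
    others <- setdiff(names(sitesBySpecies), refSpecies)
    key <- function(tab) paste(tab$gene_id, tab$mirna_id, sep = "\r")
    refKey <- key(ref)
    supp <- matrix(FALSE, nrow(ref), length(others),
                   dimnames = list(NULL, others))
    for (sp in others)
        supp[, sp] <- refKey %in% unique(key(sitesBySpecies[[sp]]))
    nSupp <- rowSums(supp)
    support <- vapply(seq_len(nrow(ref)), function(i)
        paste(c(refSpecies, others[supp[i, ]]), collapse = ","),
        character(1))
    ref$species_support <- if (nrow(ref)) support else character(0)
    ref$conserved <- nSupp >= requiredOtherSpecies
    ref
}

#' Conserved target-site density of a gene list
#'
#' The miRhub-style list statistic: total number of conserved
#' reference-species sites for the miRNA across the list genes, divided by
#' the list size. Genes without a UTR (hence without sites) contribute zero
#' sites but count in the denominator.
#'
#' @param geneList character vector of gene ids (non-empty).
#' @param mirnaId miRNA to score.
#' @param sites a conserved site table from [conservedSites()] (rows with
#'   `conserved == TRUE` are used).
#' @return the density score (sites per gene).
#' @export
scoreGeneList <- function(geneList, mirnaId, sites) {
    if (!length(geneList))
        stop("gene list is empty")
    cs <- sites[sites$conserved & sites$mirna_id == mirnaId, , drop = FALSE]
    sum(cs$gene_id %in% geneList) / length(geneList)
}

#' Monte-Carlo target-site enrichment over a gene list
#'
#' For each tested miRNA the observed conserved-site density of the list is
#' compared with densities of `nPerm` random gene lists of the same size
#' drawn uniformly without replacement from the background universe (the
#' same draws are reused across miRNAs). The empirical p-value uses the
#' plus-one correction with ties counted as extreme:
#' `p = (#\{null >= observed\} + 1) / (nPerm + 1)`. BH adjustment is applied
#' across the tested miRNAs.
#'
#' @param geneList character vector of gene ids, a subset of `background`.
#' @param mirnaIds miRNAs to test.
#' @param sites conserved site table from [conservedSites()].
#' @param background character vector, the expressed-gene universe;
#'   must be larger than the list.
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed for the null draws.
#' @return a [MirEnrichment] object.
#' @export
mirnaEnrichment <- function(geneList, mirnaIds, sites, background,
                            nPerm = 1000, seed = 1) {
    geneList <- unique(geneList)
    background <- unique(background)
    if (!length(geneList))
        stop("gene list is empty")
    if (length(background) <= length(geneList))
        stop("background (", length(background),
             ") must be larger than the gene list (", length(geneList), ")")
    extra <- setdiff(geneList, background)
    if (length(extra))
        stop("gene list must be a subset of the background; offending: ",
             paste(utils::head(extra, 5), collapse = ", "))
    nPerm <- as.integer(nPerm)
    cs <- sites[sites$conserved, , drop = FALSE]
    # per-gene site counts per miRNA over the background
    countOf <- function(mir) {
        tab <- cs[cs$mirna_id == mir, , drop = FALSE]
        cnt <- integer(length(background))
        names(cnt) <- background
        if (nrow(tab)) {
            t2 <- table(tab$gene_id[tab$gene_id %in% background])
            cnt[names(t2)] <- as.integer(t2)
        }
        cnt
    }
    set.seed(seed)
    idx <- replicate(nPerm, sample.int(length(background),
                                       length(geneList)))
    listIdx <- match(geneList, background)
    rows <- vector("list", length(mirnaIds))
    nulls <- vector("list", length(mirnaIds))
    for (j in seq_along(mirnaIds)) {
        cnt <- countOf(mirnaIds[j])
        obs <- sum(cnt[listIdx]) / length(geneList)
        nullScores <- colSums(matrix(cnt[idx], nrow = length(geneList))) /
            length(geneList)
        p <- (sum(nullScores >= obs) + 1) / (nPerm + 1)
        rows[[j]] <- data.frame(
            mirna_id = mirnaIds[j], list_size = length(geneList),
            observed_score = obs, p_emp = p,
            frac_targeted = mean(cnt[listIdx] > 0),
            stringsAsFactors = FALSE)
        nulls[[j]] <- nullScores
    }
    tb <- do.call(rbind, rows)
    tb$padj <- bhAdjust(tb$p_emp)
    tb <- tb[, c("mirna_id", "list_size", "observed_score", "p_emp", "padj",
                 "frac_targeted")]
    new("MirEnrichment", table = DataFrame(tb), nullScores = nulls,
        nPerm = nPerm, seed = as.integer(seed))
}

#' Enrichment of upregulated-miRNA targets among GPS genes
#'
#' Convenience wrapper for the master-regulator question: scores the GPS
#' (gain of post-transcriptional suppression) gene list against each
#' upregulated miRNA. List genes absent from the background (e.g. lacking a
#' UTR) are dropped with a message.
#'
#' @param gpsGenes character vector of GPS gene ids.
#' @param upMirnas character vector of upregulated miRNA ids.
#' @param sites conserved site table from [conservedSites()].
#' @param background expressed-gene universe.
#' @param nPerm,seed see [mirnaEnrichment()].
#' @return a [MirEnrichment]; empty (with a warning) when the GPS list or
#'   the miRNA list is empty.
#' @export
enrichGps <- function(gpsGenes, upMirnas, sites, background, nPerm = 1000,
                      seed = 1) {
    emptyRes <- function() new("MirEnrichment",
                               table = DataFrame(mirna_id = character(),
                                                 list_size = integer(),
                                                 observed_score = numeric(),
                                                 p_emp = numeric(),
                                                 padj = numeric(),
                                                 frac_targeted = numeric()),
                               nullScores = list(), nPerm = as.integer(nPerm),
                               seed = as.integer(seed))
    if (!length(gpsGenes)) {
        warning("empty GPS gene list; nothing to test")
        return(emptyRes())
    }
    if (!length(upMirnas)) {
        warning("no upregulated miRNAs; nothing to test")
        return(emptyRes())
    }
    keep <- intersect(gpsGenes, background)
    if (length(keep) < length(unique(gpsGenes)))
        message(length(unique(gpsGenes)) - length(keep),
                " GPS gene(s) outside the background universe were dropped")
    if (!length(keep)) {
        warning("no GPS gene lies in the background universe")
        return(emptyRes())
    }
    mirnaEnrichment(keep, upMirnas, sites, background, nPerm = nPerm,
                    seed = seed)
}
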