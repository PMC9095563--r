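# Independent reference implementations used to cross-check the package.
# These deliberately avoid the code paths of the implementation (no
# GenomicRanges overlap machinery, no Biostrings matching, no p.adjust).

# brute-force per-record scan: counts signal records into gene bodies
oracleCountSignal <- function(records, genes) {
  # records: data.frame chrom, pos (0-based), strand, weight
  # genes: data.frame gene_id, chrom, strand, body_start, body_end, eligible
  genes <- genes[genes$eligible, , drop = FALSE]
  out <- integer(nrow(genes))
  names(out) <- genes$gene_id
  if (!nrow(records)) return(out)
  for (i in seq_len(nrow(records))) {
    hit <- genes$chrom == records$chrom[i] &
      genes$strand == records$strand[i] &
      genes$body_start <= records$pos[i] & records$pos[i] < genes$body_end
    out[hit] <- out[hit] + records$weight[i]
  }
  out
}

# step-up BH by sorting, scaling and cumulative minimum
oracleBH <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pv <- p[ok]
  m <- length(pv)
  o <- order(pv)
  adjSorted <- pmin(1, rev(cummin(rev(pv[o] * m / seq_len(m)))))
  out[ok[o]] <- adjSorted
  out
}

# reverse complement without Biostrings
oracleRevComp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# exhaustive k-mer scan for canonical seed sites in one sequence, with an
# independently coded suppression loop (higher-priority overlapping sites
# win; within a priority everything is kept)
oracleSeedSites <- function(seq, seed) {
  m7 <- oracleRevComp(chartr("U", "T", toupper(seed)))
  pats <- list(`8mer` = paste0(m7, "A"),
               `7mer-m8` = m7,
               `7mer-A1` = paste0(substr(m7, 2, 7), "A"))
  prio <- c(`8mer` = 3L, `7mer-m8` = 2L, `7mer-A1` = 1L)
  cand <- NULL
  for (ty in names(pats)) {
    # zero-width lookahead so overlapping occurrences are all reported
    hits <- gregexpr(paste0("(?=", pats[[ty]], ")"), seq, perl = TRUE)[[1]]
    if (hits[1] == -1) next
    cand <- rbind(cand, data.frame(site_type = ty, utr_pos = hits - 1L,
                                   width = nchar(pats[[ty]]),
                                   prio = prio[[ty]]))
  }
  if (is.null(cand))
    return(data.frame(site_type = character(), utr_pos = integer()))
  cand <- cand[order(-cand$prio, cand$utr_pos), ]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand$utr_pos[i]; e <- s + cand$width[i]
    higher <- which(keep & cand$prio > cand$prio[i])
    ov <- length(higher) && any(cand$utr_pos[higher] < e &
                                cand$utr_pos[higher] +
                                  cand$width[higher] > s)
    keep[i] <- !ov
  }
  res <- cand[keep, c("site_type", "utr_pos")]
  res[order(res$utr_pos, res$site_type), , drop = FALSE]
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a small truncated GeneBodies fixture from a plain data.frame
makeBodies <- function(df) {
  gb <- GeneBodies(df$gene_id, df$chrom, df$start, df$end, df$strand)
  truncateGeneBodies(gb)
}

# OmicsExperiment from a matrix and a colData-style data.frame
makeOE <- function(counts, colData,
                   conditions = c("control", "iAs", "MAs", "treated")) {
  cl <- lapply(seq_len(ncol(counts)), function(j) counts[, j])
  names(cl) <- colData$sample
  assembleCountMatrix(cl, colData, conditions = conditions)
}

oeFromSim <- function(k, cd) makeOE(k, cd)
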