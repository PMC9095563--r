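#' Median-of-ratios size factors
#'
#' The standard count-normalization convention for NB differential
#' expression: per sample, the median over genes of the ratio of the count to
#' the gene's geometric mean across samples, using only genes with positive
#' counts in every sample.
#'
#' @param counts integer matrix, genes x samples (or an [OmicsExperiment]).
#' @param fallback if no gene is positive in all samples, `"error"` (default)
#'   stops with advice; `"pseudo-reference"` uses the mean-of-logs
#'   pseudo-reference over genes positive in at least one sample.
#' @return positive numeric vector, one per sample. A single sample gets
#'   factor 1.
#' @examples
#' computeSizeFactors(cbind(a = c(2, 4, 6), b = c(4, 8, 12)))
#' @export
computeSizeFactors <- function(counts, fallback = c("error",
                                                    "pseudo-reference")) {
    fallback <- match.arg(fallback)
    if (is(counts, "OmicsExperiment"))
        counts <- SummarizedExperiment::assay(counts, "counts")
    counts <- as.matrix(counts)
    if (ncol(counts) == 1L) {
        sf <- 1
        names(sf) <- colnames(counts)
        return(sf)
    }
    logc <- log(counts)
    logmeans <- rowMeans(logc)                  # -Inf when any count is 0
    usable <- is.finite(logmeans)
    if (!any(usable)) {
        if (fallback == "error")
            stop("no gene has positive counts in all samples; ",
                 "rerun with fallback = 'pseudo-reference'")
        logmeans <- apply(logc, 1, function(v) mean(v[is.finite(v)]))
        usable <- rowSums(is.finite(logc)) > 0
        if (!any(usable))
            stop("all counts are zero; size factors undefined")
    }
    sf <- apply(logc[usable, , drop = FALSE], 2, function(v) {
        ok <- is.finite(v)
        exp(stats::median((v - logmeans[usable])[ok]))
    })
    if (any(!is.finite(sf) | sf <= 0))
        stop("non-positive size factor; check the count matrix")
    sf
}

.ALPHA_FLOOR <- 1e-8

#' Estimate negative-binomial dispersions
#'
#' Gene-wise dispersions by the method of moments on normalized counts
#' within design cells, a mean-dispersion trend `a0 + a1/mean` fitted by
#' least squares over genes with mean > 1, and a final estimate that averages
#' gene-wise and trend values in log space. Because the gene-wise estimator
#' carries very few residual degrees of freedom at typical replicate numbers,
#' it is clamped to a window around the trend before averaging (tight from
#' below, where deviations are essentially sampling noise that would make
#' Wald tests anticonservative; loose from above, where genuinely
#' overdispersed genes live).
#'
#' @param counts integer matrix, genes x samples.
#' @param sizeFactors per-sample positive scalars.
#' @param cells factor of design cells (samples sharing all design
#'   covariates), e.g. `interaction(batch, condition)`.
#' @param shrinkWeight weight on the gene-wise estimate in log space
#'   (default 0.5).
#' @param clampLower,clampUpper the gene-wise estimate is clamped to
#'   `[trend/clampLower, trend*clampUpper]` before averaging.
#' @return `DataFrame` with columns `alpha_gw`, `alpha_trend`, `alpha_final`
#'   (all floored at 1e-8; `NA` for all-zero genes, which cannot be tested).
#' @export
estimateNBDispersions <- function(counts, sizeFactors, cells,
                                  shrinkWeight = 0.5, clampLower = 1.5,
                                  clampUpper = 8) {
    counts <- as.matrix(counts)
    cells <- droplevels(as.factor(cells))
    stopifnot(ncol(counts) == length(sizeFactors),
              ncol(counts) == length(cells))
    nz <- rowSums(counts) > 0
    y <- sweep(counts, 2, sizeFactors, "/")
    n <- ncol(y)
    k <- nlevels(cells)
    if (n - k < 1L)
        stop("dispersion estimation needs at least one replicated design cell")
    cellIdx <- as.integer(cells)
    # per-gene within-cell residual variance (df = n - k)
    cellMeans <- vapply(seq_len(k), function(j)
        rowMeans(y[, cellIdx == j, drop = FALSE]), numeric(nrow(y)))
    if (nrow(y) == 1L) cellMeans <- matrix(cellMeans, nrow = 1L)
    fitted <- cellMeans[, cellIdx, drop = FALSE]
    s2 <- rowSums((y - fitted)^2) / (n - k)
    mbar <- rowMeans(y)
    # Var(K/s) = mu/s + alpha*mu^2, so subtract the Poisson part scaled by
    # the average reciprocal size factor
    poisPart <- mbar * mean(1 / sizeFactors)
    agw <- pmax((s2 - poisPart) / mbar^2, .ALPHA_FLOOR)
    agw[!nz] <- NA_real_
    ok <- nz & mbar > 1
    if (sum(ok) >= 3) {
        tf <- stats::lm.fit(cbind(1, 1 / mbar[ok]), agw[ok])
        atr <- pmax(tf$coefficients[1] + tf$coefficients[2] / mbar,
                    .ALPHA_FLOOR)
    } else {
        atr <- agw  # too few genes for a trend
    }
    atr[!nz] <- NA_real_
    agwC <- pmin(pmax(agw, atr / clampLower), atr * clampUpper)
    afin <- pmax(exp(shrinkWeight * log(agwC) +
                     (1 - shrinkWeight) * log(atr)), .ALPHA_FLOOR)
    DataFrame(alpha_gw = unname(agw), alpha_trend = unname(atr),
              alpha_final = unname(afin), row.names = rownames(counts))
}

# Minimal IRLS for an NB log-link GLM with fixed dispersion alpha.
# Working weights w = mu/(1 + alpha*mu) (expected information); working
# response z = eta + (y - mu)/mu. Returns list(coef, cov, converged).
.nbIrls <- function(y, X, alpha, offset, maxit = 100L, tol = 1e-8) {
    fail <- list(coef = NULL, cov = NULL, converged = FALSE)
    tryCatch({
        etaTot <- log(y + 0.5) # any positive start works; IRLS is contractive
        beta <- numeric(ncol(X))
        conv <- FALSE
        for (it in seq_len(maxit)) {
            mu <- exp(etaTot)
            mu[mu > 1e12] <- 1e12
            mu[mu < 1e-10] <- 1e-10
            w <- mu / (1 + alpha * mu)
            z <- (etaTot - offset) + (y - mu) / mu
            Xw <- X * w
            newBeta <- drop(solve(crossprod(Xw, X), crossprod(Xw, z)))
            if (anyNA(newBeta) || any(!is.finite(newBeta)))
                return(fail)
            delta <- max(abs(newBeta - beta))
            beta <- newBeta
            etaTot <- drop(X %*% beta) + offset
            if (it > 1L && delta < tol * (1 + max(abs(beta)))) {
                conv <- TRUE
                break
            }
        }
        mu <- exp(etaTot)
        mu[mu > 1e12] <- 1e12
        mu[mu < 1e-10] <- 1e-10
        w <- mu / (1 + alpha * mu)
        cov <- solve(crossprod(X * w, X))
        list(coef = beta, cov = cov, converged = conv)
    }, error = function(e) fail)
}

# Fit one gene; on non-convergence or separation (e.g. all zeros in one
# group) refit once with a +0.5 pseudocount and flag. Returns coef,
# expected-information SE for column `coefIdx`, refit flag (NA row when
# even the refit fails).
.nbFitOne <- function(y, X, alpha, offset, coefIdx, maxit = 100L) {
    f <- .nbIrls(y, X, alpha, offset, maxit = maxit)
    refit <- !f$converged
    if (refit)
        f <- .nbIrls(y + 0.5, X, alpha, offset, maxit = maxit)
    if (!f$converged)
        return(c(NA_real_, NA_real_, 1))
    c(f$coef[coefIdx], sqrt(f$cov[coefIdx, coefIdx]), as.numeric(refit))
}

#' Negative-binomial Wald differential-expression test
#'
#' Per-gene NB log-link GLM fit by iteratively reweighted least squares with
#' the dispersion fixed at its final shrunken estimate; the Wald statistic is
#' the contrast coefficient over its expected-information standard error,
#' with a two-sided normal-tail p-value and BH adjustment across genes.
#'
#' @param counts integer matrix, genes x samples.
#' @param colData data.frame of sample covariates (rows match columns of
#'   `counts`).
#' @param design a formula over columns of `colData`, e.g.
#'   `~ batch + condition`.
#' @param contrast `c(factor, levelA, levelB)`: the reported log2 fold-change
#'   is levelA vs levelB.
#' @param sizeFactors optional; computed by [computeSizeFactors()] when
#'   missing.
#' @param dispersions optional `DataFrame` from [estimateNBDispersions()];
#'   estimated when missing using the design cells of `design`.
#' @return `DataFrame` with columns `baseMean`, `log2FoldChange`, `lfcSE`,
#'   `stat`, `pvalue`, `padj`, `flagged` (pseudocount refit used). All-zero
#'   genes are `NA` throughout and never reach significance lists.
#' @export
nbWaldTest <- function(counts, colData, design = ~condition,
                       contrast = c("condition", "treated", "control"),
                       sizeFactors = NULL, dispersions = NULL) {
    counts <- as.matrix(counts)
    colData <- as.data.frame(colData)
    stopifnot(nrow(colData) == ncol(counts), length(contrast) == 3)
    fac <- contrast[1]; levA <- contrast[2]; levB <- contrast[3]
    if (!fac %in% colnames(colData))
        stop("contrast factor '", fac, "' not in colData")
    if (is.null(sizeFactors))
        sizeFactors <- computeSizeFactors(counts)
    baseMean <- rowMeans(sweep(counts, 2, sizeFactors, "/"))
    if (levA == levB) {
        # a level contrasted with itself is identically zero
        return(DataFrame(baseMean = baseMean,
                         log2FoldChange = ifelse(rowSums(counts) > 0, 0,
                                                 NA_real_),
                         lfcSE = NA_real_, stat = NA_real_,
                         pvalue = ifelse(rowSums(counts) > 0, 1, NA_real_),
                         padj = ifelse(rowSums(counts) > 0, 1, NA_real_),
                         flagged = FALSE, row.names = rownames(counts)))
    }
    colData[[fac]] <- stats::relevel(factor(colData[[fac]]), ref = levB)
    vars <- all.vars(design)
    miss <- setdiff(vars, colnames(colData))
    if (length(miss))
        stop("design variable(s) not in colData: ", paste(miss, collapse = ", "))
    for (v in vars) colData[[v]] <- droplevels(factor(colData[[v]]))
    X <- stats::model.matrix(design, colData)
    if (qr(X)$rank < ncol(X))
        stop("design matrix is not full rank")
    coefName <- paste0(fac, levA)
    coefIdx <- match(coefName, colnames(X))
    if (is.na(coefIdx)) {
        ia <- grep(paste0("^", fac, levA, "($|:)"), colnames(X))
        if (length(ia) != 1)
            stop("cannot locate contrast coefficient '", coefName,
                 "' in design matrix")
        coefIdx <- ia
    }
    if (is.null(dispersions)) {
        cells <- interaction(colData[vars], drop = TRUE)
        dispersions <- estimateNBDispersions(counts, sizeFactors, cells)
    }
    off <- log(sizeFactors)
    ng <- nrow(counts)
    res <- matrix(NA_real_, ng, 3)
    alpha <- dispersions$alpha_final
    for (i in seq_len(ng)) {
        if (is.na(alpha[i]) || baseMean[i] == 0) next
        res[i, ] <- .nbFitOne(counts[i, ], X, alpha[i], off, coefIdx)
    }
    log2fc <- res[, 1] / log(2)
    se <- res[, 2] / log(2)
    stat <- res[, 1] / res[, 2]
    p <- 2 * stats::pnorm(-abs(stat))
    DataFrame(baseMean = baseMean, log2FoldChange = log2fc, lfcSE = se,
              stat = stat, pvalue = p, padj = bhAdjust(p),
              flagged = !is.na(res[, 3]) & res[, 3] > 0,
              row.names = rownames(counts))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with cumulative-minimum enforcement, capped at 1. `NA` entries
#' are excluded from the number of tests and propagate as `NA`.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values in the original order.
#' @export
bhAdjust <- function(p) {
    if (!is.numeric(p))
        stop("p must be numeric")
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Select significant features by the standard volcano thresholds
#'
#' Strict inequalities: adjusted p below `padjMax`, |log2 fold-change| above
#' `absLfcMin` (up: `lfc > absLfcMin`; down: `lfc < -absLfcMin`), baseMean
#' above `baseMeanMin`.
#'
#' @param results `DataFrame` from [nbWaldTest()] (rownames are feature ids).
#' @param padjMax,absLfcMin,baseMeanMin thresholds (defaults 0.05, 0.5, 500).
#' @return list with character vectors `up` and `down`.
#' @export
significantFeatures <- function(results, padjMax = 0.05, absLfcMin = 0.5,
                                baseMeanMin = 500) {
    ok <- !is.na(results$padj) & !is.na(results$log2FoldChange) &
        !is.na(results$baseMean) &
        results$padj < padjMax & results$baseMean > baseMeanMin
    list(up = rownames(results)[ok & results$log2FoldChange > absLfcMin],
         down = rownames(results)[ok & results$log2FoldChange < -absLfcMin])
}

#' QC transform, PCA and sample correlations
#'
#' Normalized counts are transformed as `log2(count/sizeFactor + 1)`;
#' optionally per-gene batch means are removed (centered, so the grand mean
#' per gene is preserved). PCA is computed on the gene-centered matrix with a
#' deterministic sign convention: within each component the gene loading of
#' largest magnitude is made positive.
#'
#' @param counts integer matrix, genes x samples (>= 3 samples).
#' @param sizeFactors per-sample scalars; computed when missing.
#' @param batch optional factor; enables batch-mean removal.
#' @param nPcs number of principal components requested (default 3; fewer
#'   are returned when there are fewer samples).
#' @return list with `coordinates` (samples x PCs), `varianceExplained`, and
#'   `correlations` (Pearson r between samples on the transformed matrix).
#' @export
qcTransformPca <- function(counts, sizeFactors = NULL, batch = NULL,
                           nPcs = 3) {
    counts <- as.matrix(counts)
    if (ncol(counts) < 3)
        stop("PCA QC needs at least 3 samples")
    if (is.null(sizeFactors))
        sizeFactors <- computeSizeFactors(counts)
    y <- log2(sweep(counts, 2, sizeFactors, "/") + 1)
    if (!is.null(batch)) {
        batch <- as.factor(batch)
        if (nlevels(batch) > 1) {
            gm <- rowMeans(y)
            for (b in levels(batch)) {
                j <- which(batch == b)
                y[, j] <- y[, j] - (rowMeans(y[, j, drop = FALSE]) - gm)
            }
        }
    }
    yc <- y - rowMeans(y)
    npc <- min(nPcs, ncol(y) - 1L)
    sv <- svd(t(yc), nu = npc, nv = npc)
    coords <- sv$u %*% diag(sv$d[seq_len(npc)], npc, npc)
    for (j in seq_len(npc)) {
        i <- which.max(abs(sv$v[, j]))
        if (sv$v[i, j] < 0) {
            sv$v[, j] <- -sv$v[, j]
            coords[, j] <- -coords[, j]
        }
    }
    rownames(coords) <- colnames(counts)
    colnames(coords) <- paste0("PC", seq_len(npc))
    ve <- sv$d^2 / sum(sv$d^2)
    list(coordinates = coords, varianceExplained = ve[seq_len(npc)],
         correlations = stats::cor(y))
}
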