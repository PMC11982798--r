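#' Quality-control cell filter
#'
#' Retains cells detecting at least \code{minGenes} genes and carrying at
#' least \code{minUmis} UMIs; cells strictly below either threshold are
#' removed (the thresholds themselves are retained). Defaults match the
#' single-cell QC convention of 1000 genes and 1250 UMIs.
#'
#' @param cells a \code{SingleCellExperiment} with a \code{counts} assay.
#' @param minGenes,minUmis inclusive lower bounds.
#' @return the filtered \code{SingleCellExperiment}.
#' @export
qcFilterCells <- function(cells, minGenes = 1000L, minUmis = 1250L) {
    if (ncol(cells) == 0L) stop("empty cell table")
    cts <- .counts(cells)
    genesDetected <- Matrix::colSums(cts > 0)
    umis <- Matrix::colSums(cts)
    keep <- genesDetected >= minGenes & umis >= minUmis
    if (!any(keep))
        stop("QC removed all ", ncol(cells), " cells (minGenes = ",
             minGenes, ", minUmis = ", minUmis, ")")
    cells[, keep]
}

#' Low-abundance gene filter
#'
#' Drops genes detected in fewer than \code{minCells} cells. With
#' \code{perSample = TRUE} (the default, matching per-sample filtering
#' before merging) a gene is kept when it passes the threshold in at least
#' one sample.
#'
#' @param cells a \code{SingleCellExperiment}.
#' @param minCells detection threshold (default 5; genes in < 5 cells go).
#' @param perSample evaluate the threshold within each sample.
#' @param sample name of the sample column in \code{colData}.
#' @return the filtered \code{SingleCellExperiment}.
#' @export
filterGenes <- function(cells, minCells = 5L, perSample = TRUE,
                        sample = "sample") {
    cts <- .counts(cells)
    det <- cts > 0
    if (perSample && sample %in%
        colnames(SummarizedExperiment::colData(cells))) {
        sm <- SummarizedExperiment::colData(cells)[[sample]]
        keep <- Reduce(`|`, lapply(unique(sm), function(s)
            Matrix::rowSums(det[, sm == s, drop = FALSE]) >= minCells))
    } else {
        keep <- Matrix::rowSums(det) >= minCells
    }
    cells[keep, ]
}

#' Library-size log-normalization
#'
#' Scales each cell to \code{scale} total counts and applies
#' \code{log1p}; the result is stored as (or returned as) the
#' \code{logcounts} assay. \code{sum(expm1(x))} per cell equals
#' \code{scale} exactly (up to floating point).
#'
#' @param cells a \code{SingleCellExperiment} (post-QC).
#' @param scale target library size (default 10000).
#' @return \code{cells} with a \code{logcounts} assay added.
#' @export
logNormalizeCells <- function(cells, scale = 10000) {
    cts <- .counts(cells)
    libs <- Matrix::colSums(cts)
    if (any(libs == 0))
        stop(sum(libs == 0), " zero-count cell(s); run qcFilterCells() first")
    norm <- cts %*% Matrix::Diagonal(x = scale / libs)
    dimnames(norm) <- dimnames(cts)
    SummarizedExperiment::assay(cells, "logcounts") <- log1p(norm)
    cells
}

#' Per-cell module score with expression-matched binned controls
#'
#' Genes are binned into \code{nBins} by average expression across cells;
#' for each signature gene, \code{nControls} control genes are drawn
#' without replacement from its bin (signature genes themselves are never
#' controls; if a bin holds fewer candidates than requested they are drawn
#' with replacement, with a warning). The score of a cell is the mean
#' expression of the signature genes minus the mean expression of the
#' pooled control draw.
#'
#' @param expr normalized expression matrix (genes x cells), or a
#'   \code{SingleCellExperiment} carrying \code{logcounts}.
#' @param genes signature gene ids (a character vector or a
#'   \linkS4class{SignatureSet}).
#' @param nBins number of average-expression bins (default 25).
#' @param nControls control genes per signature gene (default 50).
#' @param seed RNG seed for the control draw (local stream; the caller's
#'   RNG state is untouched).
#' @return named numeric vector, one score per cell.
#' @export
moduleScore <- function(expr, genes, nBins = 25L, nControls = 50L,
                        seed = 0L) {
    m <- .logcounts(expr)
    if (is(genes, "SignatureSet")) genes <- signatureGenes(genes)
    genes <- intersect(genes, rownames(m))
    if (!length(genes))
        stop("none of the signature genes are present in the matrix")
    avg <- Matrix::rowMeans(m)
    # genes never detected carry no matching information: they are excluded
    # from the bins and the control universe, so padding the matrix with
    # all-zero genes cannot perturb the score
    expressed <- names(avg)[avg > 0]
    nBins <- max(1L, min(nBins, length(expressed)))
    bins <- if (nBins == 1L) rep(1L, length(expressed))
        else cut(rank(avg[expressed], ties.method = "average"),
                 breaks = nBins, labels = FALSE)
    names(bins) <- expressed
    genes <- intersect(genes, expressed)
    if (!length(genes))
        stop("no signature gene is expressed in the matrix")
    # sorted pool: the control draw is invariant to gene row order
    pool <- sort(setdiff(expressed, genes))
    controls <- withSeed(seed, {
        unlist(lapply(genes, function(g) {
            cand <- pool[bins[pool] == bins[g]]
            if (length(cand) >= nControls) {
                sample(cand, nControls)
            } else if (length(cand)) {
                warning("bin ", bins[g], " has only ", length(cand),
                        " control candidates; sampling with replacement")
                sample(cand, nControls, replace = TRUE)
            } else {
                warning("bin ", bins[g], " has no control candidates; ",
                        "gene ", g, " contributes no controls")
                character(0)
            }
        }), use.names = FALSE)
    })
    sigMean <- Matrix::colMeans(m[genes, , drop = FALSE])
    ctlMean <- Matrix::colMeans(m[controls, , drop = FALSE])
    stats::setNames(as.numeric(sigMean - ctlMean), colnames(m))
}

# Two-component Gaussian mixture threshold: the equal-posterior point
# between the component means. Returns +Inf (degenerate) when BIC prefers
# a single component.
#' @importFrom mclust Mclust mclustBIC predict.Mclust
.mixtureThreshold <- function(score) {
    fit <- try(suppressWarnings(
        Mclust(score, G = 1:2, modelNames = c("E", "V"),
               verbose = FALSE)), silent = TRUE)
    if (inherits(fit, "try-error") || is.null(fit) || fit$G < 2L)
        return(list(threshold = Inf, degenerate = TRUE))
    mu <- fit$parameters$mean
    lo <- min(mu); hi <- max(mu)
    if (hi - lo < sqrt(.Machine$double.eps))
        return(list(threshold = Inf, degenerate = TRUE))
    post <- function(x) {
        z <- predict.Mclust(fit, newdata = x)$z
        z[, which.max(mu)] - z[, which.min(mu)]
    }
    thr <- try(stats::uniroot(post, lower = lo, upper = hi)$root,
               silent = TRUE)
    if (inherits(thr, "try-error")) thr <- (lo + hi) / 2
    list(threshold = thr, degenerate = FALSE)
}

#' Digestion-response score and escape-cell flagging
#'
#' Computes the per-cell module score against the digestion signature and
#' derives an escape threshold from a two-component Gaussian mixture fitted
#' to the scores (cut at the equal-posterior point between components).
#' When model selection prefers a single component the distribution is
#' treated as unimodal: the threshold is \code{+Inf} and nothing is
#' flagged. A fixed-quantile alternative is available.
#'
#' @param cells a \code{SingleCellExperiment} with \code{logcounts}.
#' @param signature a \linkS4class{SignatureSet} (or gene vector).
#' @param nBins,nControls,seed passed to [moduleScore()].
#' @param method \code{"mixture"} (default) or \code{"quantile"}.
#' @param quantile cut quantile for \code{method = "quantile"}.
#' @return an \linkS4class{EscapeScores}.
#' @export
digestionScore <- function(cells, signature, nBins = 25L, nControls = 50L,
                           seed = 0L, method = c("mixture", "quantile"),
                           quantile = 0.9) {
    method <- match.arg(method)
    score <- moduleScore(cells, signature, nBins = nBins,
                         nControls = nControls, seed = seed)
    if (method == "quantile") {
        thr <- stats::quantile(score, quantile, names = FALSE)
        degen <- FALSE
    } else {
        mix <- .mixtureThreshold(score)
        thr <- mix$threshold
        degen <- mix$degenerate
        if (degen)
            warning("score distribution is unimodal; no cells flagged")
    }
    new("EscapeScores", score = score, threshold = thr,
        flagged = score >= thr, controlBins = as.integer(nBins),
        controlsPerGene = as.integer(nControls), seed = as.integer(seed),
        degenerate = degen)
}

#' Atlas curation bookkeeping
#'
#' Removes flagged cells and reports the counts; \code{nAfter + nFlagged =
#' nBefore} always, with the flagged percentage rounded half-away-from-zero
#' to an integer.
#'
#' @param cells a \code{SingleCellExperiment}.
#' @param flags an \linkS4class{EscapeScores} aligned to \code{cells}.
#' @return list with \code{cells} (curated object) and \code{report}
#'   (\code{nBefore}, \code{nFlagged}, \code{nAfter}, \code{pctFlagged}).
#' @export
curateCells <- function(cells, flags) {
    fl <- escapeFlags(flags)
    if (length(fl) != ncol(cells) ||
        !identical(names(fl), colnames(cells)))
        stop("flags are not aligned to the cell table")
    nBefore <- ncol(cells)
    nFlagged <- sum(fl)
    list(cells = cells[, !fl],
         report = list(nBefore = nBefore, nFlagged = nFlagged,
                       nAfter = nBefore - nFlagged,
                       pctFlagged = pctOf(nFlagged, nBefore)))
}

#' Cluster composition by condition
#'
#' Within each condition, the fraction of cells per cluster; fractions sum
#' to 1 within each condition.
#'
#' @param cells a \code{SingleCellExperiment}.
#' @param cluster,condition \code{colData} column names.
#' @return matrix of fractions, clusters x conditions.
#' @export
compositionTable <- function(cells, cluster = "cluster",
                             condition = "condition") {
    cd <- SummarizedExperiment::colData(cells)
    if (!cluster %in% colnames(cd))
        stop("missing cluster labels ('", cluster, "')")
    if (!condition %in% colnames(cd))
        stop("missing condition labels ('", condition, "')")
    tab <- table(cd[[cluster]], cd[[condition]])
    sweep(unclass(tab), 2, colSums(tab), "/")
}
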