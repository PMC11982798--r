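#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes with
#' a positive geometric mean, of the ratio count / geometric-mean(gene).
#' Factors are re-centred so their geometric mean is exactly 1.
#'
#' @param object counts matrix (genes x samples) or a
#'   \code{SummarizedExperiment} with a \code{counts} assay.
#' @return named numeric vector of positive per-sample factors.
#' @examples
#' m <- cbind(s1 = c(2, 4), s2 = c(4, 8))
#' medianRatioSizeFactors(m)  # ~ c(0.7071, 1.4142)
#' @export
medianRatioSizeFactors <- function(object) {
    counts <- .counts(object)
    logGeo <- rowMeans(log(counts))
    use <- is.finite(logGeo)
    if (!any(use))
        stop("size-factor estimation failed: no gene has positive counts ",
             "in every sample")
    geo <- exp(logGeo[use])
    sf <- apply(counts[use, , drop = FALSE], 2, function(col)
        stats::median(col / geo))
    sf / exp(mean(log(sf)))
}

# Method-of-moments NB dispersion from normalized counts, pooled within
# groups. Each gene's estimate is floored at `floor` and at the cross-gene
# median, which keeps the Wald test calibrated at small n.
.momDispersion <- function(norm, groups, floor = 1e-8) {
    gl <- split(seq_along(groups), groups)
    m <- matrix(sapply(gl, function(i) rowMeans(norm[, i, drop = FALSE])),
                nrow = nrow(norm))
    v <- matrix(sapply(gl, function(i)
        apply(norm[, i, drop = FALSE], 1, stats::var)), nrow = nrow(norm))
    pm <- rowMeans(m)
    pv <- rowMeans(v)
    d <- pmax(floor, (pv - pm) / pmax(pm, 1e-8)^2)
    d[!is.finite(d)] <- floor
    pmax(d, stats::median(d, na.rm = TRUE))
}

.deFrame <- function(genes, baseMean, log2FC, se, stat, pvalue) {
    S4Vectors::DataFrame(baseMean = baseMean, log2FC = log2FC, se = se,
                         stat = stat, pvalue = pvalue,
                         padj = bhAdjust(pvalue), row.names = genes)
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' Fits per-gene group means on size-factor-normalized counts, estimates a
#' method-of-moments dispersion (floored gene-wise and at the cross-gene
#' median), and tests \code{log2FC = log2(mean_b / mean_a)} against zero
#' with a delta-method standard error and a two-sided normal p-value.
#' A pseudocount of 0.5 enters the fold change only when a group mean is
#' zero. All-zero genes are reported with \code{log2FC = 0, pvalue = 1},
#' not dropped. P-values are BH-adjusted into \code{padj}.
#'
#' @param object counts matrix or \code{SummarizedExperiment}.
#' @param variable name of the design column holding the grouping factor
#'   (for a plain matrix, pass the factor itself).
#' @param ref,alt reference and alternative levels; the reported fold change
#'   is \code{alt} over \code{ref}.
#' @param within optional named list used to subset samples first, e.g.
#'   \code{list(digestion = "U")} tests the drought contrast within the
#'   undigested arm.
#' @param sizeFactors optional precomputed factors; defaults to
#'   [medianRatioSizeFactors()] on the subsetted matrix.
#' @param dispersionFloor lower bound for the per-gene dispersion.
#' @return \code{DataFrame} with columns \code{baseMean}, \code{log2FC},
#'   \code{se}, \code{stat}, \code{pvalue}, \code{padj}; rownames are genes.
#' @export
nbWaldTest <- function(object, variable, ref, alt, within = NULL,
                       sizeFactors = NULL, dispersionFloor = 1e-8) {
    counts <- .counts(object)
    grp <- if (is.character(variable) && length(variable) == 1L) {
        if (!is(object, "SummarizedExperiment"))
            stop("pass a grouping factor directly for matrix input")
        as.character(SummarizedExperiment::colData(object)[[variable]])
    } else as.character(variable)
    keep <- rep(TRUE, ncol(counts))
    if (!is.null(within)) {
        cd <- SummarizedExperiment::colData(object)
        for (nm in names(within)) keep <- keep & cd[[nm]] %in% within[[nm]]
    }
    counts <- counts[, keep, drop = FALSE]
    grp <- grp[keep]
    ia <- which(grp == ref); ib <- which(grp == alt)
    if (length(ia) < 2L || length(ib) < 2L)
        stop("both contrast groups need >= 2 replicates (got ",
             length(ia), " and ", length(ib), ")")
    sub <- counts[, c(ia, ib), drop = FALSE]
    if (is.null(sizeFactors)) sizeFactors <- medianRatioSizeFactors(sub)
    norm <- sweep(sub, 2, sizeFactors, "/")
    g2 <- rep(c("a", "b"), c(length(ia), length(ib)))
    disp <- .momDispersion(norm, g2, floor = dispersionFloor)
    na <- length(ia); nb <- length(ib)
    mA <- rowMeans(norm[, g2 == "a", drop = FALSE])
    mB <- rowMeans(norm[, g2 == "b", drop = FALSE])
    pc <- ifelse(mA == 0 | mB == 0, 0.5, 0)
    lfc <- log2((mB + pc) / (mA + pc))
    se <- sqrt((1 / na) * (1 / pmax(mA, 0.5) + disp) +
               (1 / nb) * (1 / pmax(mB, 0.5) + disp)) / log(2)
    stat <- lfc / se
    p <- 2 * stats::pnorm(-abs(stat))
    zero <- mA == 0 & mB == 0
    lfc[zero] <- 0; stat[zero] <- 0; p[zero] <- 1
    .deFrame(rownames(counts), (mA + mB) / 2, lfc, se, stat, p)
}

#' Likelihood-ratio test for the digestion-by-drought interaction
#'
#' Per gene, fits negative-binomial GLMs with a fixed method-of-moments
#' dispersion: the full model \code{~ digestion * condition} versus the
#' reduced \code{~ digestion + condition}, both with \code{log(sizeFactor)}
#' offsets. The statistic is twice the log-likelihood difference (clamped
#' at zero) with a chi-square null on the difference in parameter count.
#' The conventional interacting set for this screen is
#' \code{pvalue < 0.05}.
#'
#' @inheritParams nbWaldTest
#' @param digestion,condition design column names (default \code{"digestion"},
#'   \code{"condition"}).
#' @return \code{DataFrame} as in [nbWaldTest()]; \code{log2FC} reports the
#'   largest absolute interaction contrast
#'   (MD-vs-WW fold change in each digested arm minus that in U).
#' @export
nbInteractionLRT <- function(object, digestion = "digestion",
                             condition = "condition", sizeFactors = NULL,
                             dispersionFloor = 1e-8) {
    counts <- .counts(object)
    cd <- SummarizedExperiment::colData(object)
    dig <- factor(cd[[digestion]])
    con <- factor(cd[[condition]])
    if (nlevels(dig) < 2L || nlevels(con) < 2L)
        stop("full factorial design required for the interaction LRT")
    if (is.null(sizeFactors)) sizeFactors <- medianRatioSizeFactors(counts)
    norm <- sweep(counts, 2, sizeFactors, "/")
    groups <- interaction(dig, con, drop = TRUE)
    disp <- .momDispersion(norm, groups, floor = dispersionFloor)
    off <- log(sizeFactors)
    dfDiff <- (nlevels(dig) - 1L) * (nlevels(con) - 1L)
    n <- nrow(counts)
    stat <- numeric(n); ok <- logical(n)
    for (i in seq_len(n)) {
        y <- counts[i, ]
        if (all(y == 0)) { stat[i] <- 0; ok[i] <- TRUE; next }
        theta <- 1 / disp[i]
        fam <- MASS::negative.binomial(theta = theta)
        fit <- try({
            full <- stats::glm(y ~ dig * con + offset(off), family = fam)
            red <- stats::glm(y ~ dig + con + offset(off), family = fam)
            llFull <- .nbLogLik(y, stats::fitted(full), theta)
            llRed <- .nbLogLik(y, stats::fitted(red), theta)
            max(0, 2 * (llFull - llRed))
        }, silent = TRUE)
        if (inherits(fit, "try-error")) { stat[i] <- 0 } else stat[i] <- fit
        ok[i] <- TRUE
    }
    p <- stats::pchisq(stat, df = dfDiff, lower.tail = FALSE)
    p[stat == 0] <- 1
    # interaction effect size: strongest departure of a digested arm's
    # drought response from the undigested drought response
    gm <- sapply(split(seq_along(groups), groups),
                 function(j) rowMeans(norm[, j, drop = FALSE]))
    lfcArm <- function(arm) {
        a <- gm[, paste(arm, "MD", sep = ".")] + 0.5
        b <- gm[, paste(arm, "WW", sep = ".")] + 0.5
        log2(a / b)
    }
    arms <- setdiff(levels(dig), "U")
    delta <- sapply(arms, function(a) lfcArm(a) - lfcArm("U"))
    ix <- max.col(abs(delta), ties.method = "first")
    lfc <- delta[cbind(seq_len(n), ix)]
    .deFrame(rownames(counts), rowMeans(norm), lfc,
             rep(NA_real_, n), stat, p)
}

.nbLogLik <- function(y, mu, theta)
    sum(stats::dnbinom(y, size = theta, mu = pmax(mu, 1e-10), log = TRUE))

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, order-preserving with the input.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(p) {
    if (!length(p)) return(numeric(0))
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stop("p-values must be finite and in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Z-score a vector
#'
#' \code{(x - mean(x)) / sd(x)} with the sample (n-1) standard deviation,
#' matching \code{scale()} semantics.
#'
#' @param x numeric vector of length >= 2 with positive spread.
#' @return standardized vector with mean 0 and sample SD 1.
#' @export
zScore <- function(x) {
    if (length(x) < 2L) stop("need at least 2 values")
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("cannot Z-score a constant vector")
    (x - mean(x)) / s
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall concordance coefficient between two equal-length
#' vectors.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return tau-b in [-1, 1].
#' @export
kendallTau <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 2L) stop("need at least 2 observations")
    stats::cor(x, y, method = "kendall")
}

#' Cluster response profiles on Kendall correlation distance
#'
#' Genes are represented by their per-group mean normalized expression over
#' the six design groups, in the fixed order (U,WW), (U,MD), (D,WW), (D,MD),
#' (FD,WW), (FD,MD). Partitioning-around-medoids is run on the distance
#' \code{1 - kendallTau} between profiles (original scale, per the
#' clustering convention used for response profiles), and k is chosen from
#' \code{kRange} by maximal mean silhouette width. Centroids are reported as
#' Z-scored group means for visualization.
#'
#' @param genes character vector of (typically differentially expressed)
#'   genes to cluster.
#' @param object counts \code{SummarizedExperiment} with \code{digestion}
#'   and \code{condition} design columns.
#' @param kRange candidate cluster counts (default 2:8).
#' @param sizeFactors optional; defaults to median-of-ratios on all samples.
#' @return a \linkS4class{ProfileClustering}.
#' @export
clusterProfiles <- function(genes, object, kRange = 2:8,
                            sizeFactors = NULL) {
    counts <- .counts(object)
    if (length(genes) < max(kRange) + 1L)
        stop("need more genes than max(kRange) to cluster")
    cd <- SummarizedExperiment::colData(object)
    if (is.null(sizeFactors)) sizeFactors <- medianRatioSizeFactors(counts)
    norm <- sweep(counts[genes, , drop = FALSE], 2, sizeFactors, "/")
    grpOrder <- c("U.WW", "U.MD", "D.WW", "D.MD", "FD.WW", "FD.MD")
    grp <- paste(cd$digestion, cd$condition, sep = ".")
    grpOrder <- grpOrder[grpOrder %in% grp]
    prof <- sapply(grpOrder, function(g)
        rowMeans(norm[, grp == g, drop = FALSE]))
    spread <- apply(prof, 1, function(r) diff(range(r)))
    if (all(spread < 1e-12) ||
        max(stats::dist(prof)) < 1e-12) {
        warning("all profiles identical; returning a single cluster")
        cent <- matrix(0, 1, ncol(prof),
                       dimnames = list("1", colnames(prof)))
        return(new("ProfileClustering",
                   assignments = stats::setNames(rep(1L, length(genes)), genes),
                   centroids = cent, k = 1L, silhouette = NA_real_,
                   degenerate = TRUE))
    }
    tau <- stats::cor(t(prof), method = "kendall")
    d <- stats::as.dist(1 - tau)
    fits <- lapply(kRange, function(k)
        cluster::pam(d, k = k, diss = TRUE))
    sil <- vapply(fits, function(f) f$silinfo$avg.width, numeric(1))
    best <- which.max(sil)
    fit <- fits[[best]]
    assign <- stats::setNames(as.integer(fit$clustering), genes)
    z <- t(apply(prof, 1, function(r) {
        s <- stats::sd(r)
        if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
    }))
    cent <- do.call(rbind, lapply(seq_len(kRange[best]), function(cl)
        colMeans(z[assign == cl, , drop = FALSE])))
    dimnames(cent) <- list(seq_len(kRange[best]), colnames(prof))
    new("ProfileClustering", assignments = assign, centroids = cent,
        k = as.integer(kRange[best]), silhouette = sil[best],
        degenerate = FALSE)
}
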