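#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test: exact enumeration when both groups have at most
#' 20 observations and the pooled data are tie-free, otherwise the
#' tie-corrected normal approximation (without continuity correction, so
#' the two branches agree closely at moderate n).
#'
#' @param a,b numeric vectors (each non-empty).
#' @return list with \code{statistic} (the Mann-Whitney U of the first
#'   group) and \code{p} (two-sided).
#' @export
wilcoxonRankSum <- function(a, b) {
    if (!length(a) || !length(b)) stop("both groups must be non-empty")
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- !ties && length(a) <= 20 && length(b) <= 20
    wt <- suppressWarnings(
        stats::wilcox.test(a, b, exact = exact, correct = FALSE))
    list(statistic = unname(wt$statistic), p = wt$p.value)
}

# vectorized fold change used across the single-cell tests: means on the
# de-logged scale with a +1 stabilizer
.scLog2FC <- function(exprA, exprB) {
    mA <- Matrix::rowMeans(expm1(exprA))
    mB <- Matrix::rowMeans(expm1(exprB))
    log2((mB + 1) / (mA + 1))
}

#' Tissue-specific drought response
#'
#' Per tissue, tests MD versus WW for every gene on log-normalized
#' expression with the Wilcoxon rank-sum test, and reports genes passing
#' all of: \code{p < pCut}, \code{|log2FC| > lfcCut} (strict), and detected
#' in at least \code{pctCut} of the cells of the condition where the gene
#' is higher (the "population where it is induced"). Tissues with fewer
#' than \code{minCells} cells in either condition are skipped with a
#' warning. Also returns the shared/unique decomposition of the up- and
#' down-regulated sets across tissues.
#'
#' @param cells a curated \code{SingleCellExperiment} with
#'   \code{logcounts}, a condition column (\code{"WW"}/\code{"MD"}) and
#'   tissue labels.
#' @param tissue,condition \code{colData} column names.
#' @param pCut,lfcCut,pctCut thresholds (defaults 0.05, 0.75, 0.05).
#' @param minCells minimum cells per condition per tissue (default 10).
#' @return list with \code{perTissue} (named list of data.frames: gene,
#'   log2FC, pvalue, pctExpressed, direction), \code{upIntersections},
#'   \code{downIntersections}, and \code{thresholds}.
#' @export
tissueDroughtResponse <- function(cells, tissue = "tissue",
                                  condition = "condition",
                                  pCut = 0.05, lfcCut = 0.75,
                                  pctCut = 0.05, minCells = 10L) {
    cd <- SummarizedExperiment::colData(cells)
    expr <- .logcounts(cells)
    tis <- as.character(cd[[tissue]])
    con <- as.character(cd[[condition]])
    out <- list()
    for (t in sort(unique(tis))) {
        iWW <- which(tis == t & con == "WW")
        iMD <- which(tis == t & con == "MD")
        if (length(iWW) < minCells || length(iMD) < minCells) {
            warning("tissue '", t, "' has fewer than ", minCells,
                    " cells in a condition; skipped")
            next
        }
        eWW <- expr[, iWW, drop = FALSE]
        eMD <- expr[, iMD, drop = FALSE]
        lfc <- .scLog2FC(eWW, eMD)
        pctWW <- Matrix::rowMeans(eWW > 0)
        pctMD <- Matrix::rowMeans(eMD > 0)
        pctInduced <- ifelse(lfc >= 0, pctMD, pctWW)
        cand <- which(abs(lfc) > lfcCut & pctInduced >= pctCut)
        rows <- lapply(cand, function(g) {
            p <- wilcoxonRankSum(as.numeric(eMD[g, ]),
                                 as.numeric(eWW[g, ]))$p
            if (p < pCut)
                data.frame(gene = rownames(expr)[g], log2FC = lfc[g],
                           pvalue = p, pctExpressed = pctInduced[g],
                           direction = if (lfc[g] > 0) "up" else "down",
                           stringsAsFactors = FALSE)
        })
        rows <- do.call(rbind, rows)
        if (is.null(rows))
            rows <- data.frame(gene = character(), log2FC = numeric(),
                               pvalue = numeric(), pctExpressed = numeric(),
                               direction = character(),
                               stringsAsFactors = FALSE)
        out[[t]] <- rows[order(rows$pvalue), , drop = FALSE]
    }
    upSets <- lapply(out, function(d) d$gene[d$direction == "up"])
    downSets <- lapply(out, function(d) d$gene[d$direction == "down"])
    keep <- function(sets) sets[vapply(sets, length, 1L) > 0]
    list(perTissue = out,
         upIntersections = if (length(keep(upSets)))
             setIntersections(keep(upSets)) else NULL,
         downIntersections = if (length(keep(downSets)))
             setIntersections(keep(downSets)) else NULL,
         thresholds = list(pCut = pCut, lfcCut = lfcCut, pctCut = pctCut))
}

#' Pseudobulk aggregation
#'
#' Averages expression per (cluster, sample) group. Empty groups are
#' dropped with a warning.
#'
#' @param cells a \code{SingleCellExperiment}.
#' @param by character vector of \code{colData} columns defining groups
#'   (default \code{c("cluster", "sample")}).
#' @param assay assay to average (default \code{"logcounts"}).
#' @return genes x groups matrix; group metadata in
#'   \code{attr(, "groups")}.
#' @export
pseudobulkAggregate <- function(cells, by = c("cluster", "sample"),
                                assay = "logcounts") {
    cd <- SummarizedExperiment::colData(cells)
    missing <- setdiff(by, colnames(cd))
    if (length(missing))
        stop("missing grouping column(s): ", paste(missing, collapse = ", "))
    expr <- SummarizedExperiment::assay(cells, assay)
    key <- do.call(paste, c(lapply(by, function(b) cd[[b]]), sep = "."))
    groups <- sort(unique(key))
    prof <- sapply(groups, function(g)
        Matrix::rowMeans(expr[, key == g, drop = FALSE]))
    meta <- unique(data.frame(lapply(by, function(b) cd[[b]]),
                              key = key, stringsAsFactors = FALSE))
    colnames(meta) <- c(by, "key")
    meta <- meta[match(groups, meta$key), , drop = FALSE]
    rownames(meta) <- NULL
    attr(prof, "groups") <- meta
    prof
}

#' Pseudobulk differential expression
#'
#' Converts averaged log-normalized profiles back to pseudo-counts
#' (\code{round(expm1(x) * scale)}) and runs the negative-binomial Wald
#' test across pseudobulk replicates, reporting the significant set at
#' \code{pvalue < pCut} and \code{|log2FC| > lfcCut} (both strict).
#'
#' @param profiles genes x groups matrix from [pseudobulkAggregate()].
#' @param groupLabels character/factor assigning each profile column to a
#'   contrast side.
#' @param ref,alt labels contrasted (fold change is alt over ref).
#' @param pCut,lfcCut thresholds (defaults 0.05 and 0.5).
#' @param scale pseudo-count scale (default 100).
#' @return list with \code{de} (full \code{DataFrame}) and
#'   \code{significant} (character vector of genes).
#' @export
pseudobulkDE <- function(profiles, groupLabels, ref, alt, pCut = 0.05,
                         lfcCut = 0.5, scale = 100) {
    groupLabels <- as.character(groupLabels)
    if (sum(groupLabels == ref) < 2L || sum(groupLabels == alt) < 2L)
        stop("need >= 2 pseudobulk replicates per contrast side")
    counts <- round(expm1(profiles) * scale)
    de <- nbWaldTest(counts, groupLabels, ref = ref, alt = alt)
    sig <- rownames(de)[de$pvalue < pCut & abs(de$log2FC) > lfcCut]
    list(de = de, significant = sig)
}

#' Dual drought-program detection in the mesophyll
#'
#' Scores every cell against the canonical (ABA-associated) and
#' iron-starvation program gene lists with [moduleScore()], derives one
#' mixture threshold per program (same rule as [digestionScore()]), and
#' labels each cell \code{canonical}, \code{iron}, \code{shared} (both
#' above threshold) or \code{none}.
#'
#' @param cells a \code{SingleCellExperiment} (typically the MD mesophyll
#'   subset) with \code{logcounts}.
#' @param canonicalGenes,ironGenes program gene id vectors.
#' @param nBins,nControls,seed passed to [moduleScore()].
#' @return \code{DataFrame} per cell: \code{scoreCanonical},
#'   \code{scoreIron}, \code{label}.
#' @export
dualProgramDetection <- function(cells, canonicalGenes, ironGenes,
                                 nBins = 25L, nControls = 50L, seed = 0L) {
    if (!length(canonicalGenes) || !length(ironGenes))
        stop("both program gene lists must be non-empty")
    expr <- .logcounts(cells)
    if (!any(canonicalGenes %in% rownames(expr)) ||
        !any(ironGenes %in% rownames(expr)))
        stop("a program is absent from the expression matrix")
    sCan <- moduleScore(expr, canonicalGenes, nBins, nControls, seed)
    sIron <- moduleScore(expr, ironGenes, nBins, nControls, seed + 1L)
    tCan <- .mixtureThreshold(sCan)$threshold
    tIron <- .mixtureThreshold(sIron)$threshold
    isCan <- sCan >= tCan
    isIron <- sIron >= tIron
    label <- ifelse(isCan & isIron, "shared",
             ifelse(isCan, "canonical",
             ifelse(isIron, "iron", "none")))
    S4Vectors::DataFrame(scoreCanonical = sCan, scoreIron = sIron,
                         label = label, row.names = colnames(expr))
}

#' Detection-set coexpression fraction
#'
#' Jaccard fraction of cells expressing both genes (above
#' \code{detectCut}) among cells expressing either.
#'
#' @param expr expression matrix or \code{SingleCellExperiment} with
#'   \code{logcounts}.
#' @param geneA,geneB gene ids.
#' @param detectCut detection threshold (default 0: any expression).
#' @return numeric in [0, 1]; 0 with a warning when neither gene is
#'   detected anywhere.
#' @export
coexpressionFraction <- function(expr, geneA, geneB, detectCut = 0) {
    m <- .logcounts(expr)
    if (!geneA %in% rownames(m) || !geneB %in% rownames(m))
        stop("gene not present in the matrix")
    a <- as.numeric(m[geneA, ]) > detectCut
    b <- as.numeric(m[geneB, ]) > detectCut
    either <- sum(a | b)
    if (either == 0) {
        warning("neither gene detected in any cell")
        return(0)
    }
    sum(a & b) / either
}

#' Marker filter for regulon-inference input
#'
#' Keeps marker rows expressed in more than \code{pctCut} of cells, with
#' log2 fold change above \code{lfcCut} and adjusted p-value below
#' \code{padjCut} (all strict), formatted as regulon-inference input.
#'
#' @param markers data.frame/DataFrame with columns \code{gene} (or
#'   rownames), \code{pct}, \code{log2FC}, \code{padj}, and optionally
#'   \code{cluster}.
#' @param pctCut,lfcCut,padjCut thresholds (defaults 0.10, 0.1, 0.05).
#' @return filtered data.frame with columns \code{cluster} (if present),
#'   \code{gene}, \code{log2FC}, \code{padj}, \code{pct}.
#' @export
markerFilterForRegulons <- function(markers, pctCut = 0.10, lfcCut = 0.1,
                                    padjCut = 0.05) {
    markers <- as.data.frame(markers)
    need <- c("pct", "log2FC", "padj")
    missing <- setdiff(need, colnames(markers))
    if (length(missing))
        stop("missing column(s): ", paste(missing, collapse = ", "))
    if (!"gene" %in% colnames(markers))
        markers$gene <- rownames(markers)
    keep <- markers$pct > pctCut & markers$log2FC > lfcCut &
        markers$padj < padjCut
    cols <- intersect(c("cluster", "gene", "log2FC", "padj", "pct"),
                      colnames(markers))
    out <- markers[keep, cols, drop = FALSE]
    rownames(out) <- NULL
    out
}
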