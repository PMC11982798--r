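#' Derive the digestion-response signature
#'
#' Takes the members of one response-profile cluster (by convention the
#' digestion-induced cluster), removes an exclusion set (drought-responsive
#' and digestion-by-drought interacting genes), ranks the survivors by
#' ascending FDR (ties: descending |log2 FC|, then gene id) and truncates to
#' \code{size}. Deterministic and idempotent.
#'
#' @param clustering a \linkS4class{ProfileClustering}.
#' @param ranking a DE \code{DataFrame} (from [nbWaldTest()]) supplying
#'   \code{padj} and \code{log2FC} for the ranking.
#' @param cluster id of the source cluster within \code{clustering}.
#' @param exclude character vector of genes to remove before truncation.
#' @param size requested signature size (default 250).
#' @return a \linkS4class{SignatureSet}.
#' @export
deriveSignature <- function(clustering, ranking, cluster,
                            exclude = character(), size = 250L) {
    if (size <= 0) stop("size must be positive")
    members <- names(clusterAssignments(clustering))[
        clusterAssignments(clustering) == as.integer(cluster)]
    if (!length(members)) stop("source cluster is empty")
    members <- setdiff(members, exclude)
    if (!all(members %in% rownames(ranking)))
        stop("ranking table lacks some cluster members")
    fdr <- ranking[members, "padj"]
    lfc <- abs(ranking[members, "log2FC"])
    ord <- order(fdr, -lfc, members)
    ranked <- members[ord]
    truncated <- length(ranked) >= size
    if (!truncated)
        warning("only ", length(ranked), " genes survive exclusion; ",
                "requested ", size)
    new("SignatureSet", genes = utils::head(ranked, size),
        sourceCluster = as.character(cluster),
        excluded = as.character(exclude),
        requestedSize = as.integer(size), truncated = truncated)
}

#' Count significant genes by direction
#'
#' @param de DE \code{DataFrame} with \code{padj} and \code{log2FC}.
#' @param fdrCut FDR threshold (default 0.05).
#' @return list with \code{nUp}, \code{nDown}, \code{nTotal}
#'   (= nUp + nDown) and \code{nZero} (significant genes with log2FC
#'   exactly 0, counted in neither direction).
#' @export
directionalCounts <- function(de, fdrCut = 0.05) {
    sig <- !is.na(de$padj) & de$padj < fdrCut
    nUp <- sum(sig & de$log2FC > 0)
    nDown <- sum(sig & de$log2FC < 0)
    list(nUp = nUp, nDown = nDown, nTotal = nUp + nDown,
         nZero = sum(sig & de$log2FC == 0))
}

#' Audit fold-change directions against a reference contrast
#'
#' For every gene significant in the reference DE table (FDR below
#' \code{fdrCut}), classifies its fold change in the target table as same
#' direction, opposite direction, or missing (absent from the target).
#' Percentages are rounded half-away-from-zero to integers, matching the
#' convention of printed percentages.
#'
#' @param reference,target DE \code{DataFrame}s with \code{log2FC} and
#'   (reference only) \code{padj}.
#' @param fdrCut reference significance threshold.
#' @return list with \code{nReference}, \code{nSame}, \code{nOpposite},
#'   \code{nMissing}, \code{pctOpposite}, \code{pctSame}.
#' @export
oppositeDirectionAudit <- function(reference, target, fdrCut = 0.05) {
    sig <- rownames(reference)[!is.na(reference$padj) &
                               reference$padj < fdrCut]
    if (!length(sig)) stop("reference significant set is empty")
    refSign <- sign(reference[sig, "log2FC"])
    present <- sig %in% rownames(target)
    tgtSign <- rep(NA_real_, length(sig))
    tgtSign[present] <- sign(target[sig[present], "log2FC"])
    nSame <- sum(present & refSign == tgtSign)
    nOpp <- sum(present & refSign == -tgtSign & tgtSign != 0)
    nMissing <- length(sig) - nSame - nOpp
    list(nReference = length(sig), nSame = nSame, nOpposite = nOpp,
         nMissing = nMissing,
         pctOpposite = pctOf(nOpp, length(sig)),
         pctSame = pctOf(nSame, length(sig)))
}

#' Overlap enrichment between two gene sets
#'
#' Fold enrichment of the observed intersection over the expectation
#' \code{|A| * |B| / universe}, with a continuity-corrected chi-square
#' p-value on the 2x2 membership table.
#'
#' @param setA,setB character vectors of gene ids.
#' @param universe size of the gene universe both sets were drawn from.
#' @return list with \code{fold}, \code{chisqP}, \code{nOverlap},
#'   \code{expected}.
#' @export
overlapEnrichment <- function(setA, setB, universe) {
    if (universe <= 0) stop("universe must be positive")
    if (!length(setA) || !length(setB)) stop("empty gene set")
    if (length(setA) > universe || length(setB) > universe)
        stop("set larger than universe")
    nA <- length(unique(setA)); nB <- length(unique(setB))
    nAB <- length(intersect(setA, setB))
    expected <- nA * nB / universe
    tab <- matrix(c(nAB, nA - nAB, nB - nAB,
                    universe - nA - nB + nAB), 2, 2)
    p <- suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
    list(fold = nAB / expected, chisqP = p, nOverlap = nAB,
         expected = expected)
}

#' Exclusive set intersections (UpSet decomposition)
#'
#' Every element of the union is counted in exactly one combination: the
#' signature of the sets it belongs to. Sizes therefore sum to the union
#' cardinality.
#'
#' @param sets named list of character vectors.
#' @return data.frame with columns \code{combination} (set names joined by
#'   \code{"&"}) and \code{size}, non-empty combinations only.
#' @export
setIntersections <- function(sets) {
    if (!length(sets) || is.null(names(sets)))
        stop("need a named list of at least one set")
    universe <- unique(unlist(sets))
    if (!length(universe))
        return(data.frame(combination = character(), size = integer()))
    member <- vapply(sets, function(s) universe %in% s,
                     logical(length(universe)))
    if (is.null(dim(member))) member <- matrix(member, nrow = 1)
    sig <- apply(member, 1, function(r)
        paste(names(sets)[r], collapse = "&"))
    tab <- table(sig)
    data.frame(combination = names(tab), size = as.integer(tab),
               row.names = NULL, stringsAsFactors = FALSE)
}
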