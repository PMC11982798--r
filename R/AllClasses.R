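#' @import methods
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Simulation configuration
#'
#' Parameterizes the synthetic bulk and single-cell generators. The defaults
#' (see [simConfig()]) reproduce the factorial study design: three digestion
#' treatments (undigested \code{U}, digested \code{D}, fixed-and-digested
#' \code{FD}) crossed with two watering regimes (well-watered \code{WW},
#' mild-drought \code{MD}), with planted digestion-responsive,
#' drought-responsive and interacting gene programs plus a single-cell layer
#' carrying escape cells and two mutually exclusive mesophyll drought
#' programs on a latent gradient.
#'
#' @slot nGenes number of genes simulated.
#' @slot nBulkReplicates replicates per (digestion, condition) design cell.
#' @slot baselineMeanLog,baselineSdLog log2-scale mean and SD of per-gene
#'   baseline expression.
#' @slot dispersion negative-binomial dispersion (1/size), shared by genes.
#' @slot digestionProgram list(nUp, nDown, effectLfc, fixationAttenuation).
#' @slot amplifiedProgram list(nGenes, effectLfc): genes whose digestion
#'   response is larger under fixation.
#' @slot droughtProgram list(nUp, nDown, effectLfc).
#' @slot interactionProgram list(nGenes, flip): drought response reverses
#'   sign under digestion.
#' @slot scParams single-cell layer parameters; see [simConfig()].
#' @slot seed integer seed; all randomness derives from it.
#' @exportClass SimConfig
setClass("SimConfig", representation(
    nGenes = "integer",
    nBulkReplicates = "integer",
    baselineMeanLog = "numeric",
    baselineSdLog = "numeric",
    dispersion = "numeric",
    digestionProgram = "list",
    amplifiedProgram = "list",
    droughtProgram = "list",
    interactionProgram = "list",
    scParams = "list",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    chkCount <- function(x, nm) {
        if (length(x) != 1L || is.na(x) || x < 1L)
            msg <<- c(msg, sprintf("%s must be a single positive integer", nm))
    }
    chkCount(object@nGenes, "nGenes")
    chkCount(object@nBulkReplicates, "nBulkReplicates")
    if (!is.finite(object@dispersion) || object@dispersion <= 0)
        msg <- c(msg, "dispersion must be a positive finite real")
    effs <- c(object@digestionProgram$effectLfc,
              object@amplifiedProgram$effectLfc,
              object@droughtProgram$effectLfc)
    if (!all(is.finite(effs)))
        msg <- c(msg, "all effect LFCs must be finite")
    att <- object@digestionProgram$fixationAttenuation
    if (!is.numeric(att) || att < 0 || att > 1)
        msg <- c(msg, "fixationAttenuation must lie in [0, 1]")
    sc <- object@scParams
    if (sc$escapeFraction < 0 || sc$escapeFraction > 1)
        msg <- c(msg, "escapeFraction must lie in [0, 1]")
    tp <- sc$tissueProportions
    if (abs(sum(tp) - 1) > 1e-9)
        msg <- c(msg, "tissueProportions must sum to 1")
    if (any(tp < 0) || is.null(names(tp)))
        msg <- c(msg, "tissueProportions must be a named non-negative vector")
    gtf <- sc$gradientTipFraction
    if (gtf <= 0 || gtf >= 1)
        msg <- c(msg, "gradientTipFraction must lie in (0, 1)")
    nPlanted <- with(object@digestionProgram, nUp + nDown) +
        object@amplifiedProgram$nGenes +
        with(object@droughtProgram, nUp + nDown) +
        object@interactionProgram$nGenes +
        length(tp) * sc$nMarkerGenesPerTissue +
        sc$canonicalProgramGenes + sc$ironProgramGenes
    if (nPlanted > object@nGenes)
        msg <- c(msg, "planted programs exceed nGenes; programs must be disjoint")
    if (length(msg)) msg else TRUE
})

#' Digestion-response gene signature
#'
#' An ordered gene list derived from the digestion-induced profile cluster,
#' with the exclusion list that was applied and the requested size. Order is
#' the selection ranking (ascending FDR, then descending |log2 FC|, then
#' gene id).
#'
#' @slot genes ordered character vector of signature members.
#' @slot sourceCluster id of the profile cluster the genes came from.
#' @slot excluded genes removed before truncation (drought-responsive or
#'   interacting genes).
#' @slot requestedSize the size asked for (default 250).
#' @slot truncated FALSE when fewer survivors than requested were available.
#' @exportClass SignatureSet
setClass("SignatureSet", representation(
    genes = "character",
    sourceCluster = "character",
    excluded = "character",
    requestedSize = "integer",
    truncated = "logical"
))

setValidity("SignatureSet", function(object) {
    msg <- character()
    if (length(intersect(object@genes, object@excluded)))
        msg <- c(msg, "signature genes and exclusion set must be disjoint")
    if (length(object@genes) > object@requestedSize)
        msg <- c(msg, "more genes than requestedSize")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "duplicate signature genes")
    if (length(msg)) msg else TRUE
})

#' Per-cell digestion scores and escape flags
#'
#' Holds the per-cell module score against the digestion signature, the
#' threshold used to call escape cells, and the resulting flags.
#'
#' @slot score named numeric, one module score per cell.
#' @slot threshold score cut-off; cells at or above it are flagged.
#'   \code{+Inf} when the score distribution was unimodal (nothing flagged).
#' @slot flagged named logical, \code{score >= threshold}.
#' @slot controlBins,controlsPerGene binned-control parameters used.
#' @slot seed RNG seed used for control-gene sampling.
#' @slot degenerate TRUE when the two-component mixture was rejected.
#' @exportClass EscapeScores
setClass("EscapeScores", representation(
    score = "numeric",
    threshold = "numeric",
    flagged = "logical",
    controlBins = "integer",
    controlsPerGene = "integer",
    seed = "integer",
    degenerate = "logical"
))

setValidity("EscapeScores", function(object) {
    msg <- character()
    if (length(object@score) != length(object@flagged))
        msg <- c(msg, "score and flagged lengths differ")
    if (!all(is.finite(object@score)))
        msg <- c(msg, "scores must be finite")
    if (!identical(unname(object@flagged),
                   unname(object@score >= object@threshold)))
        msg <- c(msg, "flagged must equal score >= threshold")
    if (length(msg)) msg else TRUE
})

#' Response-profile clustering
#'
#' Gene clusters computed on 1 - Kendall tau distance between per-group mean
#' expression profiles, with Z-scored centroids for visualization.
#'
#' @slot assignments named integer, gene to cluster id.
#' @slot centroids k x groups matrix of mean Z-scored profiles.
#' @slot k number of clusters.
#' @slot silhouette mean silhouette width at the chosen k.
#' @slot degenerate TRUE when all profiles were identical (single cluster).
#' @exportClass ProfileClustering
setClass("ProfileClustering", representation(
    assignments = "integer",
    centroids = "matrix",
    k = "integer",
    silhouette = "numeric",
    degenerate = "logical"
))

setValidity("ProfileClustering", function(object) {
    msg <- character()
    if (is.null(names(object@assignments)))
        msg <- c(msg, "assignments must be named by gene")
    if (nrow(object@centroids) != object@k)
        msg <- c(msg, "one centroid row per cluster required")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
    sc <- object@scParams
    cat("SimConfig:", object@nGenes, "genes,",
        object@nBulkReplicates, "bulk replicates per design cell\n")
    cat("  digestion program:", object@digestionProgram$nUp, "up /",
        object@digestionProgram$nDown, "down, LFC",
        object@digestionProgram$effectLfc, ", fixation attenuation",
        object@digestionProgram$fixationAttenuation, "\n")
    cat("  drought program:", object@droughtProgram$nUp, "up /",
        object@droughtProgram$nDown, "down; interaction genes:",
        object@interactionProgram$nGenes, "\n")
    cat("  single-cell:", sc$nCellsPerSample, "cells/sample, escape fraction",
        sc$escapeFraction, ", seed", object@seed, "\n")
})

setMethod("show", "SignatureSet", function(object) {
    cat("SignatureSet of", length(object@genes), "genes (requested",
        object@requestedSize, ") from cluster", object@sourceCluster, "\n")
    cat("  excluded:", length(object@excluded), "genes;",
        if (object@truncated) "truncated to size\n" else
            "fewer survivors than requested\n")
    cat("  head:", paste(utils::head(object@genes, 5), collapse = ", "), "\n")
})

setMethod("show", "EscapeScores", function(object) {
    cat("EscapeScores for", length(object@score), "cells\n")
    cat(sprintf("  threshold %.4g; %d flagged (%.1f%%)%s\n",
        object@threshold, sum(object@flagged),
        100 * mean(object@flagged),
        if (object@degenerate) " [unimodal: nothing flagged]" else ""))
})

setMethod("show", "ProfileClustering", function(object) {
    cat("ProfileClustering:", length(object@assignments), "genes in",
        object@k, "clusters (mean silhouette",
        sprintf("%.3f", object@silhouette), ")\n")
    print(table(cluster = object@assignments))
})

#' Accessors
#'
#' @param x a \linkS4class{SignatureSet}, \linkS4class{EscapeScores} or
#'   \linkS4class{ProfileClustering} object.
#' @return \code{signatureGenes}: character vector of signature members in
#'   ranking order. \code{cellScores}: named numeric of per-cell scores.
#'   \code{escapeFlags}: named logical. \code{scoreThreshold}: the numeric
#'   cut-off. \code{clusterAssignments}: named integer gene-to-cluster map.
#'   \code{clusterCentroids}: k x groups matrix of Z-scored centroids.
#' @name accessors
#' @aliases signatureGenes cellScores escapeFlags scoreThreshold
#'   clusterAssignments clusterCentroids
#' @export
signatureGenes <- function(x) x@genes

#' @rdname accessors
#' @export
cellScores <- function(x) x@score

#' @rdname accessors
#' @export
escapeFlags <- function(x) x@flagged

#' @rdname accessors
#' @export
scoreThreshold <- function(x) x@threshold

#' @rdname accessors
#' @export
clusterAssignments <- function(x) x@assignments

#' @rdname accessors
#' @export
clusterCentroids <- function(x) x@centroids
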