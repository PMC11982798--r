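#' Run the full fixation-aware curation pipeline
#'
#' End-to-end driver on synthetic data: simulate the bulk factorial design
#' and the single-cell samples, perform the digestion and drought contrasts
#' and the interaction LRT, cluster digestion response profiles, derive the
#' digestion signature (interaction and drought-responsive genes excluded),
#' score and curate the fixed-digested (FD) cells, and profile
#' tissue-specific and dual mesophyll drought responses on the curated
#' atlas. Everything is deterministic given the config seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param outdir optional directory; when given, the run report
#'   (\code{report.json}), the signature (\code{signature.txt}) and the DE
#'   tables are written there.
#' @param fdrCut bulk DEG threshold (default 0.05).
#' @param interactionPCut interaction-gene threshold on the LRT p-value
#'   (default 0.05).
#' @param signatureSize requested signature size (default 250).
#' @param qcMinGenes,qcMinUmis single-cell QC cuts. The defaults (200
#'   genes, 1500 UMIs) are scaled to the synthetic gene count; for
#'   real-scale data use [qcFilterCells()]'s defaults of 1000 and 1250.
#' @param tissueP,tissueLfc,tissuePct tissue drought-response thresholds
#'   (defaults 0.05, 0.75, 0.05).
#' @return a run-report list: per-stage counts, thresholds applied,
#'   rounded percentages, config echo and seed. Percentages are always
#'   recomputable from the stored counts.
#' @export
runPipeline <- function(config = simConfig(), outdir = NULL,
                        fdrCut = 0.05, interactionPCut = 0.05,
                        signatureSize = 250L,
                        qcMinGenes = 200L, qcMinUmis = 1500L,
                        tissueP = 0.05, tissueLfc = 0.75,
                        tissuePct = 0.05) {
    validObject(config)

    ## ---- bulk arm -------------------------------------------------------
    bulk <- simulateBulk(config)
    sf <- medianRatioSizeFactors(bulk)
    deDigestion <- nbWaldTest(bulk, "digestion", ref = "U", alt = "D",
                              within = list(condition = "WW"))
    digDegs <- rownames(deDigestion)[!is.na(deDigestion$padj) &
                                     deDigestion$padj < fdrCut]
    clustering <- clusterProfiles(digDegs, bulk, sizeFactors = sf)
    cent <- clusterCentroids(clustering)
    induced <- rownames(cent)[which.max(cent[, "D.WW"] - cent[, "U.WW"])]

    lrt <- nbInteractionLRT(bulk, sizeFactors = sf)
    interacting <- rownames(lrt)[lrt$pvalue < interactionPCut]

    droughtU <- nbWaldTest(bulk, "condition", ref = "WW", alt = "MD",
                           within = list(digestion = "U"))
    droughtD <- nbWaldTest(bulk, "condition", ref = "WW", alt = "MD",
                           within = list(digestion = "D"))
    droughtFD <- nbWaldTest(bulk, "condition", ref = "WW", alt = "MD",
                            within = list(digestion = "FD"))
    droughtDegsD <- rownames(droughtD)[!is.na(droughtD$padj) &
                                       droughtD$padj < fdrCut]
    exclusions <- union(interacting, droughtDegsD)
    signature <- withCallingHandlers(
        deriveSignature(clustering, deDigestion, induced,
                        exclude = exclusions, size = signatureSize),
        warning = function(w) invokeRestart("muffleWarning"))

    cntU <- directionalCounts(droughtU, fdrCut)
    cntD <- directionalCounts(droughtD, fdrCut)
    cntFD <- directionalCounts(droughtFD, fdrCut)
    auditD <- oppositeDirectionAudit(droughtU, droughtD, fdrCut)
    auditFD <- oppositeDirectionAudit(droughtU, droughtFD, fdrCut)
    degsU <- rownames(droughtU)[!is.na(droughtU$padj) &
                                droughtU$padj < fdrCut]
    degsFD <- rownames(droughtFD)[!is.na(droughtFD$padj) &
                                  droughtFD$padj < fdrCut]
    enrichFD <- if (length(degsU) && length(degsFD))
        overlapEnrichment(degsFD, degsU, universe = nrow(bulk)) else NULL

    ## ---- single-cell arm ------------------------------------------------
    cellsRaw <- simulateCells(config)
    nRaw <- ncol(cellsRaw)
    cells <- qcFilterCells(cellsRaw, minGenes = qcMinGenes,
                           minUmis = qcMinUmis)
    nQc <- ncol(cells)
    cells <- filterGenes(cells, minCells = 5L)
    cells <- logNormalizeCells(cells)

    fd <- cells[, cells$fixation == "FD"]
    scores <- digestionScore(fd, signature, seed = config@seed + 44L)
    cur <- curateCells(fd, scores)
    atlas <- cur$cells

    tissueResp <- withCallingHandlers(
        tissueDroughtResponse(atlas, pCut = tissueP, lfcCut = tissueLfc,
                              pctCut = tissuePct),
        warning = function(w) invokeRestart("muffleWarning"))

    rd <- SummarizedExperiment::rowData(atlas)
    canonicalGenes <- rownames(atlas)[rd$truth_canonical_drought]
    ironGenes <- rownames(atlas)[rd$truth_iron_starvation]
    meso <- atlas[, atlas$tissue == "mesophyll" & atlas$condition == "MD"]
    dual <- dualProgramDetection(meso, canonicalGenes, ironGenes,
                                 seed = config@seed + 55L)
    dualCounts <- as.list(table(factor(dual$label,
        levels = c("canonical", "iron", "shared", "none"))))

    coexCross <- coexpressionFraction(meso, canonicalGenes[1], ironGenes[1])
    coexWithin <- coexpressionFraction(meso, canonicalGenes[1],
                                       canonicalGenes[2])

    report <- list(
        tool = "fixcurate",
        version = as.character(utils::packageVersion("fixcurate")),
        seed = config@seed,
        config = list(nGenes = config@nGenes,
                      nBulkReplicates = config@nBulkReplicates,
                      dispersion = config@dispersion,
                      nCellsPerSample = config@scParams$nCellsPerSample,
                      escapeFraction = config@scParams$escapeFraction),
        thresholds = list(fdrCut = fdrCut,
                          interactionPCut = interactionPCut,
                          signatureSize = signatureSize,
                          qcMinGenes = qcMinGenes, qcMinUmis = qcMinUmis,
                          tissueP = tissueP, tissueLfc = tissueLfc,
                          tissuePct = tissuePct),
        bulk = list(
            nDigestionDegs = length(digDegs),
            nProfileClusters = clustering@k,
            inducedCluster = induced,
            nInteracting = length(interacting),
            droughtDegs = list(U = cntU, D = cntD, FD = cntFD),
            oppositeAudit = list(D = auditD, FD = auditFD),
            overlapEnrichmentFD = enrichFD,
            signatureSize = length(signatureGenes(signature)),
            nExcluded = length(exclusions)),
        cells = list(
            nSimulated = nRaw,
            nAfterQc = nQc,
            nRemovedQc = nRaw - nQc,
            nGenesKept = nrow(cells),
            fd = cur$report,
            tissueDegCounts = lapply(tissueResp$perTissue, nrow),
            dualProgram = dualCounts,
            coexpressionCrossProgram = coexCross,
            coexpressionWithinProgram = coexWithin))

    if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        writeRunReport(report, file.path(outdir, "report.json"))
        writeSignature(signature, file.path(outdir, "signature.txt"))
        .writeTsv(cbind(gene = rownames(droughtU),
                        as.data.frame(droughtU)),
                  file.path(outdir, "drought_U.tsv"))
        .writeTsv(cbind(gene = rownames(deDigestion),
                        as.data.frame(deDigestion)),
                  file.path(outdir, "digestion_D_vs_U.tsv"))
    }
    report
}
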