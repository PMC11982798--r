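# Shared fixtures, built once per test run and memoized.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
    if (!exists(name, envir = .fixtureCache))
        assign(name, builder(), envir = .fixtureCache)
    get(name, envir = .fixtureCache)
}

# a small config whose planted programs all fit in few genes
tinyConfig <- function(seed = 1L, scParams = list(), ...) {
    sc <- list(nCellsPerSample = 60L, nMarkerGenesPerTissue = 4L,
               canonicalProgramGenes = 4L, ironProgramGenes = 4L)
    sc[names(scParams)] <- scParams
    simConfig(nGenes = 60L, nBulkReplicates = 3L,
              digestionProgram = list(nUp = 5L, nDown = 5L),
              amplifiedProgram = list(nGenes = 3L),
              droughtProgram = list(nUp = 4L, nDown = 4L),
              interactionProgram = list(nGenes = 4L),
              scParams = sc, seed = seed, ...)
}

# default-condition single-cell dataset, QC'd and normalized
normalizedCells <- function() fixture("normCells", function() {
    sce <- simulateCells(simConfig(seed = 42L))
    sce <- qcFilterCells(sce, minGenes = 200, minUmis = 1500)
    sce <- filterGenes(sce, minCells = 5)
    logNormalizeCells(sce)
})

fdScored <- function() fixture("fdScored", function() {
    cells <- normalizedCells()
    fd <- cells[, cells$fixation == "FD"]
    rd <- SummarizedExperiment::rowData(fd)
    sig <- new("SignatureSet",
               genes = rownames(fd)[rd$truth_digestion_up],
               sourceCluster = "truth", excluded = character(),
               requestedSize = 250L, truncated = FALSE)
    list(fd = fd, scores = digestionScore(fd, sig, seed = 7L))
})

# counts SummarizedExperiment built directly from a matrix + design
makeBulkSE <- function(counts, digestion, condition) {
    samples <- paste(digestion, condition, seq_along(digestion), sep = "_")
    colnames(counts) <- samples
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(
            sample = samples, digestion = digestion,
            condition = condition,
            replicate = seq_along(digestion), row.names = samples))
}

# DE-result DataFrame for audit/bookkeeping tests
makeDE <- function(genes, log2FC, padj, pvalue = padj) {
    S4Vectors::DataFrame(baseMean = rep(1, length(genes)),
                         log2FC = log2FC, se = rep(1, length(genes)),
                         stat = log2FC, pvalue = pvalue, padj = padj,
                         row.names = genes)
}
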