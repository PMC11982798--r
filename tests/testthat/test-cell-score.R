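makeSCE <- function(counts, sample = rep("s1", ncol(counts)),
                    condition = rep("WW", ncol(counts))) {
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("g%04d", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("c%04d", seq_len(ncol(counts)))
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = methods::as(Matrix::Matrix(counts,
            sparse = TRUE), "CsparseMatrix")),
        colData = S4Vectors::DataFrame(sample = sample,
                                       condition = condition,
                                       row.names = colnames(counts)))
}

test_that("QC keeps cells at the thresholds and removes those below", {
    counts <- matrix(0, 1200, 3)
    counts[1:999, 1] <- 5          # 999 genes, 4995 UMIs
    counts[1:1000, 2] <- 1
    counts[1, 2] <- 251            # 1000 genes, 1250 UMIs
    counts[1:1100, 3] <- 1         # 1100 genes, 1100 UMIs
    sce <- makeSCE(counts)
    kept <- qcFilterCells(sce, minGenes = 1000, minUmis = 1250)
    expect_identical(colnames(kept), "c0002")
    expect_error(qcFilterCells(sce[, 1], minGenes = 1000, minUmis = 1250),
                 "removed all")
    expect_error(qcFilterCells(sce[, 0]), "empty")
    # QC is idempotent
    expect_identical(colnames(qcFilterCells(kept, 1000, 1250)),
                     colnames(kept))
})

test_that("gene filtering drops low-detection genes per the threshold", {
    det <- c(0, 1, 4, 5, 6, 100)
    counts <- matrix(0, 6, 100)
    for (i in seq_along(det)) if (det[i] > 0) counts[i, seq_len(det[i])] <- 1
    sce <- makeSCE(counts)
    kept <- filterGenes(sce, minCells = 5, perSample = FALSE)
    expect_equal(nrow(kept), 3)
    expect_identical(rownames(kept), c("g0004", "g0005", "g0006"))
    # idempotent
    expect_identical(rownames(filterGenes(kept, 5, perSample = FALSE)),
                     rownames(kept))
    # per-sample: a gene passing in one sample is retained after merging
    sce2 <- makeSCE(counts, sample = rep(c("s1", "s2"), each = 50))
    kept2 <- filterGenes(sce2, minCells = 5)
    expect_true("g0005" %in% rownames(kept2))  # 5 cells, all in s1
})

test_that("log-normalization round-trips the library scale", {
    set.seed(3)
    counts <- matrix(rpois(600, 2), 30, 20)
    counts[, 1] <- 0; counts[1, 1] <- 7  # uneven depth
    sce <- logNormalizeCells(makeSCE(counts), scale = 1e4)
    lc <- SummarizedExperiment::assay(sce, "logcounts")
    sums <- Matrix::colSums(expm1(lc))
    expect_equal(unname(sums), rep(1e4, 20), tolerance = 1e-6)
    # all-equal counts stay all-equal
    eq <- logNormalizeCells(makeSCE(matrix(4, 5, 3)), scale = 10)
    lce <- as.matrix(SummarizedExperiment::assay(eq, "logcounts"))
    expect_true(all(abs(lce - lce[1, 1]) < 1e-12))
    zero <- makeSCE(cbind(c(1, 0), c(0, 0)))
    expect_error(logNormalizeCells(zero), "zero-count")
})

test_that("module scores equal signature minus matched control means", {
    # one bin, controls = all non-signature genes, exact arithmetic
    expr <- rbind(matrix(2.0, 4, 10), matrix(0.5, 16, 10))
    rownames(expr) <- paste0("g", 1:20)
    colnames(expr) <- paste0("c", 1:10)
    s <- moduleScore(expr, paste0("g", 1:4), nBins = 1, nControls = 16,
                     seed = 1)
    expect_equal(unname(s), rep(1.5, 10))
    # all genes identical: score is exactly zero
    flat <- matrix(1, 20, 10,
                   dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
    s0 <- moduleScore(flat, paste0("g", 1:3), nBins = 1, nControls = 5,
                      seed = 1)
    expect_equal(unname(s0), rep(0, 10))
    expect_error(moduleScore(expr, c("nope1", "nope2")), "signature gene")
})

test_that("module scores are reproducible and stable across seeds", {
    cells <- normalizedCells()
    rd <- SummarizedExperiment::rowData(cells)
    sig <- rownames(cells)[rd$truth_digestion_up]
    s1 <- moduleScore(cells, sig, seed = 5)
    s2 <- moduleScore(cells, sig, seed = 5)
    expect_identical(s1, s2)
    s3 <- moduleScore(cells, sig, seed = 6)
    expect_gt(cor(s1, s3), 0.9)
})

test_that("module scores ignore gene order and all-zero padding", {
    cells <- normalizedCells()
    sub <- cells[1:400, 1:300]
    rd <- SummarizedExperiment::rowData(sub)
    sig <- head(rownames(sub)[rd$truth_digestion_up], 20)
    expr <- as.matrix(SummarizedExperiment::assay(sub, "logcounts"))
    base <- moduleScore(expr, sig, seed = 3)
    perm <- expr[sample(nrow(expr)), ]
    expect_equal(moduleScore(perm, sig, seed = 3), base)
    padded <- rbind(expr, matrix(0, 30, ncol(expr),
        dimnames = list(paste0("zz", 1:30), colnames(expr))))
    expect_equal(moduleScore(padded, sig, seed = 3), base)
})

test_that("the mixture threshold separates a constructed bimodal score", {
    set.seed(8)
    scores <- c(rnorm(100, 0, 0.05), rnorm(100, 1, 0.05))
    mix <- fixcurate:::.mixtureThreshold(scores)
    expect_false(mix$degenerate)
    expect_gt(mix$threshold, 0.2)
    expect_lt(mix$threshold, 0.8)
    flagged <- scores >= mix$threshold
    expect_identical(unname(flagged), rep(c(FALSE, TRUE), each = 100))
    # a unimodal score distribution yields no threshold
    uni <- fixcurate:::.mixtureThreshold(rnorm(300))
    expect_true(uni$degenerate)
    expect_identical(uni$threshold, Inf)
})

test_that("escape flagging recovers planted escape cells", {
    fx <- fdScored()
    flags <- escapeFlags(fx$scores)
    truth <- fx$fd$truth_escape
    recall <- sum(flags & truth) / sum(truth)
    precision <- sum(flags & truth) / sum(flags)
    expect_gte(recall, 0.9)
    expect_gte(precision, 0.8)
    # flag definition is threshold-consistent
    expect_identical(unname(flags),
                     unname(cellScores(fx$scores) >=
                            scoreThreshold(fx$scores)))
})

test_that("no-escape data leave essentially nothing flagged", {
    cfg <- simConfig(seed = 19L,
                     scParams = list(nCellsPerSample = 250L,
                                     escapeFraction = 0))
    cells <- logNormalizeCells(filterGenes(
        qcFilterCells(simulateCells(cfg), 200, 1500), 5))
    fd <- cells[, cells$fixation == "FD"]
    rd <- SummarizedExperiment::rowData(fd)
    sig <- new("SignatureSet",
               genes = rownames(fd)[rd$truth_digestion_up],
               sourceCluster = "truth", excluded = character(),
               requestedSize = 250L, truncated = FALSE)
    sc <- suppressWarnings(digestionScore(fd, sig, seed = 2L))
    expect_lt(mean(escapeFlags(sc)), 0.05)
})

test_that("curation bookkeeping conserves cells", {
    fx <- fdScored()
    cur <- curateCells(fx$fd, fx$scores)
    rep <- cur$report
    expect_equal(rep$nAfter + rep$nFlagged, rep$nBefore)
    expect_equal(rep$nAfter, ncol(cur$cells))
    expect_equal(rep$pctFlagged,
                 floor(100 * rep$nFlagged / rep$nBefore + 0.5))
    # misaligned flags are rejected
    expect_error(curateCells(fx$fd[, -1], fx$scores), "aligned")
})

test_that("composition fractions sum to one within each condition", {
    cells <- normalizedCells()
    SummarizedExperiment::colData(cells)$cluster <- cells$tissue
    tab <- compositionTable(cells)
    expect_equal(unname(colSums(tab)), rep(1, ncol(tab)), tolerance = 1e-9)
    one <- cells[, cells$tissue == "mesophyll"]
    SummarizedExperiment::colData(one)$cluster <- "m"
    tab1 <- compositionTable(one)
    expect_true(all(tab1 == 1))
    noLab <- cells
    expect_error(compositionTable(noLab, cluster = "absent"), "cluster")
})
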