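test_that("median-of-ratios size factors match hand computation", {
    m <- cbind(s1 = c(2, 4), s2 = c(4, 8))
    expect_equal(medianRatioSizeFactors(m),
                 c(s1 = 1 / sqrt(2), s2 = sqrt(2)), tolerance = 1e-9)
    # identical columns
    m2 <- cbind(a = c(5, 9, 2), b = c(5, 9, 2))
    expect_equal(unname(medianRatioSizeFactors(m2)), c(1, 1))
    # geometric mean of factors is 1, and the estimator agrees with a
    # direct recomputation, including after scaling one column
    set.seed(1)
    for (i in 1:5) {
        m3 <- matrix(rpois(60, 20) + 1, 10, 6)
        colnames(m3) <- paste0("s", 1:6)
        m3[, 3] <- m3[, 3] * 3
        sf <- medianRatioSizeFactors(m3)
        expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-9)
        expect_equal(unname(sf), unname(bruteForceSizeFactors(m3)),
                     tolerance = 1e-9)
    }
    expect_error(medianRatioSizeFactors(cbind(c(0, 1), c(1, 0))),
                 "no gene")
})

test_that("the NB Wald test recovers forced fold changes", {
    m <- cbind(matrix(10, 1, 3), matrix(20, 1, 3))
    rownames(m) <- "g"
    grp <- rep(c("a", "b"), each = 3)
    de <- nbWaldTest(m, grp, ref = "a", alt = "b",
                     sizeFactors = rep(1, 6))
    expect_equal(unname(de["g", "log2FC"]), 1.0)
    # identical groups: no effect, p = 1
    m2 <- matrix(c(7, 7, 7, 7, 7, 7), 1)
    rownames(m2) <- "g"
    de2 <- nbWaldTest(m2, grp, ref = "a", alt = "b",
                      sizeFactors = rep(1, 6))
    expect_equal(unname(de2["g", "log2FC"]), 0)
    expect_equal(unname(de2["g", "pvalue"]), 1)
    # all-zero genes are reported, not dropped
    m3 <- rbind(g0 = rep(0, 6), g1 = c(5, 6, 7, 50, 60, 70))
    de3 <- nbWaldTest(m3, grp, ref = "a", alt = "b",
                      sizeFactors = rep(1, 6))
    expect_equal(unname(de3["g0", "log2FC"]), 0)
    expect_equal(unname(de3["g0", "pvalue"]), 1)
    expect_error(nbWaldTest(m3, c("a", "a", "a", "a", "a", "b"),
                            ref = "a", alt = "b"), "replicates")
})

test_that("the Wald test agrees with an established NB implementation", {
    skip_if_not_installed("DESeq2")
    cfg <- simConfig(nGenes = 300L, seed = 21L,
                     digestionProgram = list(nUp = 20L, nDown = 20L),
                     amplifiedProgram = list(nGenes = 5L),
                     droughtProgram = list(nUp = 10L, nDown = 10L),
                     interactionProgram = list(nGenes = 5L),
                     scParams = list(nMarkerGenesPerTissue = 5L,
                                     canonicalProgramGenes = 5L,
                                     ironProgramGenes = 5L))
    se <- simulateBulk(cfg)
    keep <- se$condition == "WW" & se$digestion %in% c("U", "D")
    sub <- se[, keep]
    de <- nbWaldTest(sub, "digestion", ref = "U", alt = "D")
    dds <- DESeq2::DESeqDataSetFromMatrix(
        SummarizedExperiment::assay(sub),
        data.frame(digestion = factor(sub$digestion, c("U", "D"))),
        ~digestion)
    res <- DESeq2::results(suppressMessages(DESeq2::DESeq(dds, quiet = TRUE)))
    ok <- !is.na(res$padj) & de$baseMean > 5
    # fold-change agreement on well-measured genes
    expect_gt(cor(de$log2FC[ok], res$log2FoldChange[ok]), 0.95)
    # significance calls agree on the planted structure
    both <- table(ours = de$padj[ok] < 0.05, deseq = res$padj[ok] < 0.05)
    agree <- sum(diag(both)) / sum(both)
    expect_gt(agree, 0.9)
})

test_that("the interaction LRT has power on sign-flip genes and a valid null", {
    cfg <- simConfig(nGenes = 200L, seed = 31L,
                     digestionProgram = list(nUp = 0L, nDown = 0L),
                     amplifiedProgram = list(nGenes = 0L),
                     droughtProgram = list(nUp = 0L, nDown = 0L,
                                           effectLfc = 2),
                     interactionProgram = list(nGenes = 10L, flip = TRUE),
                     scParams = list(nMarkerGenesPerTissue = 0L,
                                     canonicalProgramGenes = 0L,
                                     ironProgramGenes = 0L))
    se <- simulateBulk(cfg)
    lrt <- nbInteractionLRT(se)
    expect_true(all(lrt$stat >= 0))
    rd <- SummarizedExperiment::rowData(se)
    flips <- which(rd$truth_interacting)
    expect_true(all(lrt$pvalue[flips] < 1e-4))
    nulls <- which(!rd$truth_interacting)
    expect_lt(mean(lrt$pvalue[nulls] < 0.05), 0.12)
})

test_that("BH adjustment matches hand-derived examples and validates input", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.3), 0.3)
    expect_equal(bhAdjust(c(0.005, 0.011, 0.02, 0.04)),
                 c(0.02, 0.022, 0.02666667, 0.04), tolerance = 1e-6)
    expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
    expect_error(bhAdjust(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("z-scoring is exact, affine-invariant, and rejects constants", {
    expect_equal(zScore(c(2, 4, 6)), c(-1, 0, 1))
    set.seed(2)
    x <- rnorm(50)
    z <- zScore(x)
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(sd(z), 1, tolerance = 1e-9)
    expect_equal(zScore(3.2 * x + 17), z, tolerance = 1e-9)
    expect_error(zScore(rep(4, 10)), "constant")
})

test_that("Kendall tau matches enumeration", {
    expect_equal(kendallTau(1:3, 1:3), 1)
    expect_equal(kendallTau(1:3, 3:1), -1)
    expect_equal(kendallTau(c(1, 2, 3, 4), c(1, 3, 2, 4)), 2 / 3,
                 tolerance = 1e-9)
    expect_error(kendallTau(1:3, 1:4), "equal length")
})

test_that("profile clustering separates planted response families", {
    # two noise-free families: monotone up and monotone down across the
    # six design groups (duplicated per replicate)
    up <- c(10, 10, 40, 40, 80, 80)
    down <- rev(up)
    counts <- rbind(
        t(replicate(25, rep(up, each = 2))),
        t(replicate(25, rep(down, each = 2))))
    rownames(counts) <- paste0("g", 1:50)
    se <- makeBulkSE(counts,
                     digestion = rep(c("U", "U", "D", "D", "FD", "FD"),
                                     each = 2),
                     condition = rep(c("WW", "MD"), 6))
    cl <- clusterProfiles(rownames(counts), se,
                          sizeFactors = rep(1, 12))
    expect_equal(cl@k, 2L)
    a <- clusterAssignments(cl)
    expect_equal(length(unique(a[1:25])), 1L)
    expect_equal(length(unique(a[26:50])), 1L)
    expect_false(a[1] == a[26])
    # with multiplicative noise the planted partition is still recovered
    set.seed(9)
    noisy <- round(counts * matrix(exp(rnorm(length(counts), 0, 0.1)),
                                   nrow(counts)))
    se2 <- makeBulkSE(noisy,
                      digestion = rep(c("U", "U", "D", "D", "FD", "FD"),
                                      each = 2),
                      condition = rep(c("WW", "MD"), 6))
    cl2 <- clusterProfiles(rownames(noisy), se2,
                           sizeFactors = rep(1, 12))
    truth <- rep(1:2, each = 25)
    expect_gte(mclust::adjustedRandIndex(clusterAssignments(cl2), truth),
               0.9)
})

test_that("identical profiles collapse to a single flagged cluster", {
    counts <- t(replicate(20, rep(c(5, 10, 20, 20, 40, 40), each = 2)))
    rownames(counts) <- paste0("g", 1:20)
    se <- makeBulkSE(counts,
                     digestion = rep(c("U", "U", "D", "D", "FD", "FD"),
                                     each = 2),
                     condition = rep(c("WW", "MD"), 6))
    expect_warning(cl <- clusterProfiles(rownames(counts), se,
                                         sizeFactors = rep(1, 12)),
                   "identical")
    expect_equal(cl@k, 1L)
    expect_true(cl@degenerate)
})
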