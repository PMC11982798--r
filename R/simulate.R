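#' Build a simulation configuration
#'
#' Constructs a validated \linkS4class{SimConfig}. The defaults emulate the
#' study design downstream modules assume: bulk RNA-seq of undigested (U),
#' digested (D) and fixed-and-digested (FD) leaf samples under well-watered
#' (WW) and mild-drought (MD) regimes, and single-cell samples from the two
#' digestion arms. Planted gene programs are pairwise disjoint:
#' \itemize{
#'   \item digestion program: induced/repressed by cell-wall digestion in D,
#'     attenuated by the factor \code{fixationAttenuation} in FD;
#'   \item amplified program: digestion response \emph{larger} under
#'     fixation (effect \code{effectLfc/2} in D, \code{effectLfc} in FD);
#'   \item drought program: responds to MD in every digestion arm;
#'   \item interaction program: drought response \code{+effectLfc} in U,
#'     sign-flipped in D, and flip attenuated back toward the undigested
#'     response in FD (\code{effectLfc * (2*attenuation - 1)});
#'   \item single-cell layer: tissue marker genes, escape cells in FD
#'     samples retaining the digestion program, and two mutually exclusive
#'     mesophyll drought programs (canonical/ABA at the tip of a latent
#'     drought gradient, iron-starvation in the mid/high band but not the
#'     tip).
#' }
#'
#' @param nGenes total genes simulated.
#' @param nBulkReplicates replicates per (digestion, condition) design cell.
#' @param baselineMeanLog,baselineSdLog log2-scale mean/SD of gene baselines.
#' @param dispersion shared NB dispersion (variance = mu + dispersion*mu^2).
#' @param digestionProgram,amplifiedProgram,droughtProgram,interactionProgram
#'   named lists overriding individual program fields (see Details).
#' @param scParams named list overriding single-cell fields:
#'   \code{nCellsPerSample}, \code{tissueProportions} (named, sums to 1),
#'   \code{nMarkerGenesPerTissue}, \code{markerLfc},
#'   \code{escapeFraction} (FD samples only), \code{canonicalProgramGenes},
#'   \code{ironProgramGenes}, \code{gradientTipFraction},
#'   \code{ironBandLow}, \code{depthMean}, \code{librarySdLog},
#'   \code{fixationArms}.
#' @param seed integer seed from which every RNG stream is derived.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(nGenes = 2000L,
                      nBulkReplicates = 3L,
                      baselineMeanLog = 6,
                      baselineSdLog = 2,
                      dispersion = 0.05,
                      digestionProgram = list(),
                      amplifiedProgram = list(),
                      droughtProgram = list(),
                      interactionProgram = list(),
                      scParams = list(),
                      seed = 1L) {
    merge <- function(defaults, user) {
        bad <- setdiff(names(user), names(defaults))
        if (length(bad))
            stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
        defaults[names(user)] <- user
        defaults
    }
    dig <- merge(list(nUp = 100L, nDown = 100L, effectLfc = 2,
                      fixationAttenuation = 0.8), digestionProgram)
    amp <- merge(list(nGenes = 50L, effectLfc = 2), amplifiedProgram)
    dro <- merge(list(nUp = 60L, nDown = 60L, effectLfc = 2), droughtProgram)
    int <- merge(list(nGenes = 60L, flip = TRUE), interactionProgram)
    sc <- merge(list(
        nCellsPerSample = 500L,
        tissueProportions = c(mesophyll = 0.5, epidermis = 0.3,
                              vasculature = 0.2),
        nMarkerGenesPerTissue = 30L,
        markerLfc = 2,
        escapeFraction = 0.24,
        canonicalProgramGenes = 40L,
        ironProgramGenes = 40L,
        programBaselineLog = 1,
        programLfc = 8,
        gradientTipFraction = 0.2,
        ironBandLow = 0.5,
        depthMean = 3000L,
        librarySdLog = 0.3,
        fixationArms = c("D", "FD")), scParams)
    new("SimConfig",
        nGenes = as.integer(nGenes),
        nBulkReplicates = as.integer(nBulkReplicates),
        baselineMeanLog = baselineMeanLog,
        baselineSdLog = baselineSdLog,
        dispersion = dispersion,
        digestionProgram = dig, amplifiedProgram = amp,
        droughtProgram = dro, interactionProgram = int,
        scParams = sc, seed = as.integer(seed))
}

# Deterministic gene annotation: disjoint program blocks at the head of the
# gene vector, plus baselines drawn from the config's own seed so that
# simulateBulk() and simulateCells() share identical gene-level structure.
.geneAnnotation <- function(config) {
    n <- config@nGenes
    ids <- sprintf("G%05d", seq_len(n))
    sc <- config@scParams
    tissues <- names(sc$tissueProportions)
    take <- local({
        ptr <- 0L
        function(k) {
            out <- seq.int(ptr + 1L, length.out = k)
            ptr <<- ptr + k
            out
        }
    })
    blocks <- list(
        digestion_up = take(config@digestionProgram$nUp),
        digestion_down = take(config@digestionProgram$nDown),
        digestion_amplified = take(config@amplifiedProgram$nGenes),
        drought_up = take(config@droughtProgram$nUp),
        drought_down = take(config@droughtProgram$nDown),
        interacting = take(config@interactionProgram$nGenes),
        canonical_drought = take(sc$canonicalProgramGenes),
        iron_starvation = take(sc$ironProgramGenes))
    markers <- lapply(tissues, function(t) take(sc$nMarkerGenesPerTissue))
    names(markers) <- tissues
    baseline <- withSeed(config@seed,
        stats::rnorm(n, config@baselineMeanLog, config@baselineSdLog))
    # drought-program genes behave like stress markers: near-silent at
    # baseline, strongly induced when their program is active
    baseline[c(blocks$canonical_drought, blocks$iron_starvation)] <-
        sc$programBaselineLog
    list(ids = ids, blocks = blocks, markers = markers, baseline = baseline)
}

.geneTruthFrame <- function(ann, n) {
    rd <- S4Vectors::DataFrame(row.names = ann$ids)
    for (tag in names(ann$blocks)) {
        col <- logical(n)
        col[ann$blocks[[tag]]] <- TRUE
        rd[[paste0("truth_", tag)]] <- col
    }
    marker <- rep(NA_character_, n)
    for (t in names(ann$markers)) marker[ann$markers[[t]]] <- t
    rd$truth_marker <- marker
    rd
}

# Digestion-arm log2 effects for a gene block layout.
# Columns: effect under U, D, FD.
.digestionEffects <- function(config, ann) {
    n <- config@nGenes
    L <- config@digestionProgram$effectLfc
    att <- config@digestionProgram$fixationAttenuation
    La <- config@amplifiedProgram$effectLfc
    eff <- matrix(0, n, 3, dimnames = list(ann$ids, c("U", "D", "FD")))
    b <- ann$blocks
    eff[b$digestion_up, "D"] <- L
    eff[b$digestion_up, "FD"] <- L * (1 - att)
    eff[b$digestion_down, "D"] <- -L
    eff[b$digestion_down, "FD"] <- -L * (1 - att)
    eff[b$digestion_amplified, "D"] <- La / 2
    eff[b$digestion_amplified, "FD"] <- La
    eff
}

# Drought (MD vs WW) log2 effects per digestion arm.
.droughtEffects <- function(config, ann) {
    n <- config@nGenes
    L <- config@droughtProgram$effectLfc
    att <- config@digestionProgram$fixationAttenuation
    eff <- matrix(0, n, 3, dimnames = list(ann$ids, c("U", "D", "FD")))
    b <- ann$blocks
    eff[b$drought_up, ] <- L
    eff[b$drought_down, ] <- -L
    eff[b$interacting, "U"] <- L
    if (config@interactionProgram$flip) {
        eff[b$interacting, "D"] <- -L
        eff[b$interacting, "FD"] <- L * (2 * att - 1)
    } else {
        eff[b$interacting, "D"] <- 0
        eff[b$interacting, "FD"] <- L * att
    }
    eff
}

#' Simulate the bulk factorial RNA-seq experiment
#'
#' Draws negative-binomial counts for a genes x samples design of three
#' digestion treatments (U, D, FD) crossed with two watering regimes
#' (WW, MD), with the planted programs described in [simConfig()]. Identical
#' configurations (including seed) give byte-identical output.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \code{SummarizedExperiment} with a \code{counts} assay, the
#'   sample design in \code{colData} (columns \code{sample},
#'   \code{digestion}, \code{condition}, \code{replicate}) and ground-truth
#'   gene tags in \code{rowData} (columns prefixed \code{truth_}).
#' @examples
#' se <- simulateBulk(simConfig(nGenes = 200, seed = 7))
#' table(se$digestion, se$condition)
#' @export
simulateBulk <- function(config) {
    validObject(config)
    ann <- .geneAnnotation(config)
    n <- config@nGenes
    reps <- config@nBulkReplicates
    design <- expand.grid(replicate = seq_len(reps),
                          condition = c("WW", "MD"),
                          digestion = c("U", "D", "FD"),
                          stringsAsFactors = FALSE)[, 3:1]
    design$sample <- with(design,
        paste(digestion, condition, replicate, sep = "_"))
    digEff <- .digestionEffects(config, ann)
    droEff <- .droughtEffects(config, ann)
    logMu <- vapply(seq_len(nrow(design)), function(j) {
        arm <- design$digestion[j]
        ann$baseline + digEff[, arm] +
            (design$condition[j] == "MD") * droEff[, arm]
    }, numeric(n))
    mu <- 2^logMu
    counts <- withSeed(config@seed + 11L, {
        matrix(stats::rnbinom(length(mu), mu = mu,
                              size = 1 / config@dispersion),
               nrow = n)
    })
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(ann$ids, design$sample)
    cd <- S4Vectors::DataFrame(design, row.names = design$sample)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = cd[, c("sample", "digestion", "condition", "replicate")],
        rowData = .geneTruthFrame(ann, n))
    S4Vectors::metadata(se)$simConfig <- config
    se
}

#' Simulate the single-cell experiment
#'
#' Draws a sparse genes x cells count matrix for one sample per
#' (fixation arm, condition) combination. Cells are assigned tissues by
#' \code{tissueProportions}; each tissue's marker genes are boosted in its
#' cells. Cells from unfixed digested (D) samples all express the digestion
#' program; in fixed (FD) samples only an \code{escapeFraction} of cells do
#' (these carry \code{truth_escape = TRUE}). Mesophyll cells carry a latent
#' drought gradient (Uniform(0,1) under MD, compressed to [0, 0.3] under
#' WW); the canonical/ABA program is active strictly above
#' \code{1 - gradientTipFraction} and the iron-starvation program in
#' \code{(ironBandLow, 1 - gradientTipFraction]}, so the two programs are
#' mutually exclusive by construction. Library sizes are log-normal around
#' \code{depthMean}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \code{SingleCellExperiment} with a sparse \code{counts} assay,
#'   per-cell metadata (\code{sample}, \code{condition}, \code{fixation},
#'   \code{tissue}) plus ground-truth columns \code{truth_escape},
#'   \code{truth_polarity}, \code{truth_gradient},
#'   \code{truth_subpopulation}, and gene tags in \code{rowData}.
#' @examples
#' sce <- simulateCells(simConfig(nGenes = 300,
#'     scParams = list(nCellsPerSample = 50), seed = 3))
#' table(sce$fixation, sce$condition)
#' @export
simulateCells <- function(config) {
    validObject(config)
    sc <- config@scParams
    if (sc$escapeFraction > 0 && !"FD" %in% sc$fixationArms)
        stop("escapeFraction > 0 requires a FixedDigested (FD) sample ",
             "in the design")
    ann <- .geneAnnotation(config)
    n <- config@nGenes
    tissues <- names(sc$tissueProportions)
    samples <- expand.grid(condition = c("WW", "MD"),
                           fixation = sc$fixationArms,
                           stringsAsFactors = FALSE)[, 2:1]
    samples$sample <- paste(samples$fixation, samples$condition, sep = "_")
    nc <- nrow(samples) * sc$nCellsPerSample

    meta <- withSeed(config@seed + 22L, {
        m <- data.frame(
            sample = rep(samples$sample, each = sc$nCellsPerSample),
            fixation = rep(samples$fixation, each = sc$nCellsPerSample),
            condition = rep(samples$condition, each = sc$nCellsPerSample),
            stringsAsFactors = FALSE)
        m$tissue <- sample(tissues, nc, replace = TRUE,
                           prob = sc$tissueProportions)
        m$truth_escape <- m$fixation == "FD" &
            stats::rbinom(nc, 1, sc$escapeFraction) == 1
        m$truth_polarity <- stats::runif(nc)
        g <- numeric(nc)
        meso <- m$tissue == "mesophyll"
        g[meso & m$condition == "MD"] <- stats::runif(sum(meso & m$condition == "MD"))
        g[meso & m$condition == "WW"] <- stats::runif(sum(meso & m$condition == "WW"), 0, 0.3)
        m$truth_gradient <- g
        m$depth <- stats::rlnorm(nc, log(sc$depthMean), sc$librarySdLog)
        m
    })
    tipLow <- 1 - sc$gradientTipFraction
    canonical <- meta$tissue == "mesophyll" & meta$truth_gradient > tipLow
    iron <- meta$tissue == "mesophyll" &
        meta$truth_gradient > sc$ironBandLow & meta$truth_gradient <= tipLow
    sub <- rep("none", nc)
    sub[canonical] <- "canonical"
    sub[iron] <- "iron"
    sub[!(meta$tissue == "mesophyll" & meta$condition == "MD")] <- "none"
    meta$truth_subpopulation <- sub
    digestionActive <- meta$fixation == "D" | meta$truth_escape

    b <- ann$blocks
    L <- config@digestionProgram$effectLfc
    La <- config@amplifiedProgram$effectLfc
    Ld <- config@droughtProgram$effectLfc
    # per-cell log2 effects composed from a small set of additive programs
    progEffects <- list(
        marker = NULL,  # handled per tissue below
        digestion = {
            e <- numeric(n)
            e[b$digestion_up] <- L; e[b$digestion_down] <- -L
            e[b$digestion_amplified] <- La / 2
            e
        },
        drought = {
            e <- numeric(n)
            e[b$drought_up] <- Ld; e[b$drought_down] <- -Ld
            e
        },
        canonical = { e <- numeric(n); e[b$canonical_drought] <- sc$programLfc; e },
        iron = { e <- numeric(n); e[b$iron_starvation] <- sc$programLfc; e })
    markerEff <- sapply(tissues, function(t) {
        e <- numeric(n); e[ann$markers[[t]]] <- sc$markerLfc; e
    })

    combo <- paste(meta$tissue, digestionActive, meta$condition == "MD",
                   canonical & meta$condition == "MD",
                   iron & meta$condition == "MD")
    counts <- matrix(0, n, nc)
    probs <- new.env()
    for (u in unique(combo)) {
        i <- which(combo == u)[1]
        logw <- ann$baseline + markerEff[, meta$tissue[i]] +
            digestionActive[i] * progEffects$digestion +
            (meta$condition[i] == "MD") * progEffects$drought +
            (canonical[i] && meta$condition[i] == "MD") * progEffects$canonical +
            (iron[i] && meta$condition[i] == "MD") * progEffects$iron
        w <- 2^logw
        assign(u, w / sum(w), envir = probs)
    }
    mu <- vapply(seq_len(nc), function(j)
        meta$depth[j] * get(combo[j], envir = probs), numeric(n))
    counts <- withSeed(config@seed + 33L, {
        matrix(stats::rnbinom(length(mu), mu = mu,
                              size = 1 / config@dispersion), nrow = n)
    })
    cellIds <- sprintf("%s_c%05d", meta$sample,
                       stats::ave(seq_len(nc), meta$sample, FUN = seq_along))
    dimnames(counts) <- list(ann$ids, cellIds)
    cd <- S4Vectors::DataFrame(
        sample = meta$sample, condition = meta$condition,
        fixation = meta$fixation, tissue = meta$tissue,
        truth_escape = meta$truth_escape,
        truth_polarity = meta$truth_polarity,
        truth_gradient = meta$truth_gradient,
        truth_subpopulation = meta$truth_subpopulation,
        row.names = cellIds)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = methods::as(counts, "CsparseMatrix")),
        colData = cd, rowData = .geneTruthFrame(ann, n))
    S4Vectors::metadata(sce)$simConfig <- config
    sce
}
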