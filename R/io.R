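# Disk formats: Matrix Market + TSV sidecars for cells, plain TSV for bulk
# counts and design, one-gene-per-line signatures, JSON reports.

.writeTsv <- function(df, file) {
    df <- as.data.frame(df)
    for (j in seq_along(df))
        if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
            df[[j]] <- sprintf("%.17g", df[[j]])
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' Write / read a single-cell table
#'
#' \code{writeCellTable} stores the counts as Matrix Market
#' (\code{matrix.mtx}, genes x cells), gene metadata as \code{genes.tsv},
#' cell metadata as \code{cells.tsv} and an \code{orientation.json}
#' sidecar naming the matrix orientation. \code{readCellTable} restores
#' the \code{SingleCellExperiment}; writing then reading reproduces counts
#' and metadata exactly.
#'
#' @param cells a \code{SingleCellExperiment}.
#' @param dir directory (created if needed).
#' @return \code{writeCellTable}: \code{dir}, invisibly.
#'   \code{readCellTable}: a \code{SingleCellExperiment}.
#' @export
writeCellTable <- function(cells, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cts <- .counts(cells)
    Matrix::writeMM(methods::as(cts, "CsparseMatrix"),
                    file.path(dir, "matrix.mtx"))
    rd <- as.data.frame(SummarizedExperiment::rowData(cells))
    .writeTsv(cbind(gene = rownames(cells), rd),
              file.path(dir, "genes.tsv"))
    cd <- as.data.frame(SummarizedExperiment::colData(cells))
    .writeTsv(cbind(cell = colnames(cells), cd),
              file.path(dir, "cells.tsv"))
    jsonlite::write_json(list(orientation = "genes_x_cells"),
                         file.path(dir, "orientation.json"),
                         auto_unbox = TRUE)
    invisible(dir)
}

#' @rdname writeCellTable
#' @export
readCellTable <- function(dir) {
    need <- c("matrix.mtx", "genes.tsv", "cells.tsv")
    missing <- need[!file.exists(file.path(dir, need))]
    if (length(missing))
        stop("missing file(s) in ", dir, ": ",
             paste(missing, collapse = ", "))
    m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                     "CsparseMatrix")
    genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
    cellsMeta <- utils::read.table(file.path(dir, "cells.tsv"), sep = "\t",
                                   header = TRUE, stringsAsFactors = FALSE)
    if (nrow(genes) != nrow(m))
        stop("genes.tsv has ", nrow(genes), " rows but the matrix has ",
             nrow(m), " genes")
    if (nrow(cellsMeta) != ncol(m))
        stop("cells.tsv has ", nrow(cellsMeta), " rows but the matrix has ",
             ncol(m), " cells")
    if (anyDuplicated(genes$gene)) stop("duplicate gene ids in genes.tsv")
    if (anyDuplicated(cellsMeta$cell)) stop("duplicate cell ids in cells.tsv")
    dimnames(m) <- list(genes$gene, cellsMeta$cell)
    m <- Matrix::drop0(m)
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m),
        colData = S4Vectors::DataFrame(
            cellsMeta[, setdiff(colnames(cellsMeta), "cell"), drop = FALSE],
            row.names = cellsMeta$cell),
        rowData = S4Vectors::DataFrame(
            genes[, setdiff(colnames(genes), "gene"), drop = FALSE],
            row.names = genes$gene))
}

#' Write / read bulk counts and design
#'
#' Counts as a genes x samples TSV (first column \code{gene}, header =
#' sample ids); design as a TSV with columns \code{sample},
#' \code{digestion}, \code{condition}, \code{replicate}.
#'
#' @param se a \code{SummarizedExperiment} from [simulateBulk()] or
#'   equivalent.
#' @param countsFile,designFile output/input paths.
#' @return \code{writeBulkCounts}: invisibly \code{countsFile}.
#'   \code{readBulkCounts}: a \code{SummarizedExperiment}.
#' @export
writeBulkCounts <- function(se, countsFile, designFile) {
    cts <- .counts(se)
    .writeTsv(cbind(gene = rownames(cts), as.data.frame(cts)), countsFile)
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    .writeTsv(cd[, c("sample", "digestion", "condition", "replicate")],
              designFile)
    invisible(countsFile)
}

#' @rdname writeBulkCounts
#' @export
readBulkCounts <- function(countsFile, designFile) {
    tab <- utils::read.table(countsFile, sep = "\t", header = TRUE,
                             check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (anyDuplicated(tab$gene)) stop("duplicate gene ids")
    cts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(cts) <- tab$gene
    design <- utils::read.table(designFile, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
    if (!setequal(design$sample, colnames(cts)))
        stop("design samples do not match count columns")
    design <- design[match(colnames(cts), design$sample), , drop = FALSE]
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = cts),
        colData = S4Vectors::DataFrame(design, row.names = design$sample))
}

#' Write / read a gene signature
#'
#' One gene per line, in ranking order.
#'
#' @param signature a \linkS4class{SignatureSet} or character vector.
#' @param file path.
#' @return \code{readSignature}: character vector of gene ids.
#' @export
writeSignature <- function(signature, file) {
    genes <- if (is(signature, "SignatureSet"))
        signatureGenes(signature) else as.character(signature)
    writeLines(genes, file)
    invisible(file)
}

#' @rdname writeSignature
#' @export
readSignature <- function(file) readLines(file)

#' Read a simulation configuration from YAML
#'
#' The document's top-level keys must be arguments of [simConfig()];
#' unknown keys (at either level) are rejected rather than ignored.
#'
#' @param file path to a YAML document.
#' @return a \linkS4class{SimConfig}.
#' @export
readSimConfig <- function(file) {
    if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the 'yaml' package")
    cfg <- yaml::read_yaml(file)
    known <- names(formals(simConfig))
    bad <- setdiff(names(cfg), known)
    if (length(bad))
        stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    if (!is.null(cfg$scParams$tissueProportions))
        cfg$scParams$tissueProportions <-
            unlist(cfg$scParams$tissueProportions)
    do.call(simConfig, cfg)
}

#' Write a run report as JSON
#'
#' @param report list as returned by [runPipeline()].
#' @param file path.
#' @export
writeRunReport <- function(report, file) {
    jsonlite::write_json(report, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(file)
}
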