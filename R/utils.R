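# Internal helpers shared across modules.

# Evaluate expr under a local RNG stream; the caller's .Random.seed is
# untouched, so no hidden global state leaks out of seeded operations.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

# Half-away-from-zero integer rounding, matching printed percentages such
# as 28% (= 195/701) and 24% (= 16107/66904).
roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

pctOf <- function(num, den) {
    if (den == 0) return(0)
    as.integer(roundHalfUp(100 * num / den))
}

# counts accessor tolerant of plain matrices and (Single)SummarizedExperiment
.counts <- function(object) {
    if (is(object, "SummarizedExperiment"))
        SummarizedExperiment::assay(object, "counts")
    else object
}

.logcounts <- function(object) {
    if (is(object, "SummarizedExperiment")) {
        if (!"logcounts" %in% SummarizedExperiment::assayNames(object))
            stop("no 'logcounts' assay; run logNormalizeCells() first")
        SummarizedExperiment::assay(object, "logcounts")
    } else object
}
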