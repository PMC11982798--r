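# Independent brute-force oracles used to validate the fast implementations.

# Benjamini-Hochberg by direct application of the step-up definition:
# adj_(i) = min_{k >= i} min(1, n * p_(k) / k) on the sorted p-values.
bruteForceBH <- function(p) {
    n <- length(p)
    ord <- order(p)
    ps <- p[ord]
    adj <- numeric(n)
    for (i in seq_len(n))
        adj[i] <- min(1, min(n * ps[i:n] / (i:n)))
    out <- numeric(n)
    out[ord] <- adj
    out
}

# Kendall tau-b by explicit enumeration of all pairs with tie corrections.
bruteForceKendallTau <- function(x, y) {
    n <- length(x)
    conc <- disc <- tx <- ty <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        dx <- x[j] - x[i]; dy <- y[j] - y[i]
        s <- sign(dx) * sign(dy)
        if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
        else if (dx == 0) tx <- tx + 1
        else if (dy == 0) ty <- ty + 1
        else if (s > 0) conc <- conc + 1
        else disc <- disc + 1
    }
    n0 <- n * (n - 1) / 2
    (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Exclusive set intersections by per-element membership lookup.
bruteForceIntersections <- function(sets) {
    universe <- unique(unlist(sets))
    sig <- vapply(universe, function(e)
        paste(names(sets)[vapply(sets, function(s) e %in% s, logical(1))],
              collapse = "&"), character(1))
    as.list(table(sig))
}

# Exact two-sided Wilcoxon rank-sum p by enumerating every assignment of
# the pooled observations to the first group.
bruteForceWilcoxonP <- function(a, b) {
    pooled <- c(a, b)
    r <- rank(pooled)
    na <- length(a)
    uObs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    combos <- utils::combn(length(pooled), na)
    uAll <- apply(combos, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
    mu <- na * length(b) / 2
    mean(abs(uAll - mu) >= abs(uObs - mu) - 1e-9)
}

# Median-of-ratios size factors recomputed directly.
bruteForceSizeFactors <- function(m) {
    geo <- apply(m, 1, function(r) exp(mean(log(r))))
    ok <- is.finite(geo) & geo > 0
    sf <- apply(m, 2, function(col) stats::median(col[ok] / geo[ok]))
    sf / exp(mean(log(sf)))
}
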