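# Independent oracles used to cross-check the package implementations.
# These are deliberately naive (enumeration / O(n^2) counting / direct
# formula) and share no code with the functions they verify.

# Upper-tail hypergeometric probability by explicit enumeration of the pmf
# from binomial coefficients.
oracleHyperTail <- function(x, X, PN, N) {
    i <- seq(x, min(X, PN))
    sum(choose(PN, i) * choose(N - PN, X - i)) / choose(N, X)
}

# Benjamini-Hochberg step-up, written directly from the definition.
oracleStepUp <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    out
}

# Tau-b by brute-force pair counting with explicit tie corrections.
oracleTauB <- function(x, y) {
    n <- length(x)
    dx <- sign(outer(x, x, "-")); dy <- sign(outer(y, y, "-"))
    up <- upper.tri(dx)
    conc <- sum(dx[up] * dy[up] > 0)
    disc <- sum(dx[up] * dy[up] < 0)
    n0 <- n * (n - 1) / 2
    tx <- table(x); ty <- table(y)
    n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
    (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

# PPI score by enumeration of all gene pairs of the bicluster against an
# explicit edge list (weights already thresholded by the caller).
oraclePPIScore <- function(bicGenes, edgeFrom, edgeTo, dbIds) {
    hasPartner <- vapply(bicGenes, function(g) {
        others <- setdiff(bicGenes, g)
        any((edgeFrom == g & edgeTo %in% others) |
            (edgeTo == g & edgeFrom %in% others))
    }, logical(1))
    I <- sum(hasPartner)
    M <- sum(!bicGenes %in% dbIds)
    N <- length(bicGenes)
    if (N == M) 0 else I / (N - M)
}

# Small reusable fixtures -------------------------------------------------

# Annotation map: 100-gene universe, three terms of sizes 10 / 5 / 20 with
# one shared gene, 30 annotated genes in total.
toyAnnotation <- function() {
    g <- sprintf("g%03d", 1:100)
    AnnotationMap(
        gene = c(g[1:10], g[11:15], g[15:34]),
        term = rep(c("T1", "T2", "T3"), c(10, 5, 20)),
        universe = g)
}

toyNetwork <- function(threshold = 0.7) {
    PPINetwork(
        from = c("a", "a", "b", "c", "d", "x"),
        to = c("b", "c", "c", "d", "e", "y"),
        weight = c(0.9, 0.8, 0.95, 0.75, 0.3, 0.85),
        threshold = threshold)
}

tmpfile <- function(ext = ".tsv") withr::local_tempfile(fileext = ext,
    .local_envir = parent.frame())
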