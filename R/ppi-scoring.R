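#' PPI coherence score of a bicluster
#'
#' Scores how strongly a bicluster's genes interact with one another in a
#' confidence-thresholded protein-protein interaction network:
#' \deqn{PPI = I / (N - M)}
#' where `N` is the bicluster gene count, `I` the number of bicluster genes
#' with at least one retained (above-threshold) edge to another gene of the
#' same bicluster (genes are counted, not edges), and `M` the number of
#' bicluster genes unknown to the interaction source. Under
#' `mMode = "database"` (default) a gene counts toward `M` when it is absent
#' from the full pre-threshold identifier roster of the source file — i.e. it
#' has not been found to interact with anything according to all the data;
#' under `mMode = "graph"` it counts when absent from the thresholded graph.
#' Edges to genes outside the bicluster never contribute to `I`.
#'
#' When every bicluster gene is unknown (`N == M`) the score is undefined; it
#' is reported as 0 with `undefined = TRUE` so such biclusters rank last.
#'
#' @param b a [Bicluster-class].
#' @param net a [PPINetwork-class].
#' @param mMode `"database"` or `"graph"`; see Details.
#' @return list with elements `biclusterId`, `I`, `M`, `N`, `score` and
#'   `undefined`.
#' @examples
#' net <- PPINetwork(c("a", "a", "b"), c("b", "c", "c"),
#'     c(0.9, 0.8, 0.95), threshold = 0.7)
#' b <- Bicluster("b1", "ISA", c("a", "b", "c"), "c1")
#' ppiScore(b, net)$score  # 1: the bicluster is a retained triangle
#' @export
ppiScore <- function(b, net, mMode = c("database", "graph")) {
    mMode <- match.arg(mMode)
    stopifnot(is(b, "Bicluster"), is(net, "PPINetwork"))
    g <- genes(b)
    N <- length(g)
    known <- switch(mMode,
        database = databaseGenes(net),
        graph = nodes(net))
    M <- sum(!g %in% known)
    e <- edges(net)
    within <- e$from %in% g & e$to %in% g
    I <- length(unique(c(e$from[within], e$to[within])))
    undefined <- N == M
    score <- if (undefined) 0 else I / (N - M)
    list(biclusterId = biclusterId(b), I = as.integer(I), M = as.integer(M),
        N = as.integer(N), score = score, undefined = undefined)
}
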