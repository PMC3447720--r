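#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of drawing at least `x` term-annotated genes when `X` genes are
#' sampled without replacement from a universe of `N` genes of which `PN`
#' carry the term. Delegates to the hypergeometric survival function
#' (`stats::phyper` with `lower.tail = FALSE`), which is numerically stable
#' for tail probabilities far below 1e-12 — never computed as 1 minus a CDF.
#'
#' @param x observed overlap count, `0 <= x <= min(X, PN)`.
#' @param X number of genes drawn (bicluster genes entering the test).
#' @param PN number of universe genes annotated to the term.
#' @param N universe size.
#' @return p-value in \[0,1\]; vectorised over `x`.
#' @examples
#' hypergeomPValue(4, X = 5, PN = 10, N = 50)  # 8652 / choose(50, 5)
#' hypergeomPValue(0, X = 5, PN = 10, N = 100) # 1
#' @export
hypergeomPValue <- function(x, X, PN, N) {
    x <- as.numeric(x); X <- as.numeric(X)
    PN <- as.numeric(PN); N <- as.numeric(N)
    if (any(X > N) || any(PN > N))
        stop("X and PN must not exceed the universe size N")
    if (any(x < 0) || any(x > pmin(X, PN)))
        stop("x must satisfy 0 <= x <= min(X, PN)")
    stats::phyper(x - 1, m = PN, n = N - PN, k = X, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (`stats::p.adjust(method = "BH")`),
#' returned in input order; adjusted values never fall below the raw ones and
#' are capped at 1.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @return adjusted p-values, same length and order.
#' @export
bhFDR <- function(p) {
    p <- as.numeric(p)
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0,1]")
    stats::p.adjust(p, method = "BH")
}

#' Per-term enrichment score on the -log scale
#'
#' `s = -log(p)` in the configured base (default 10, so the score reads as
#' orders of magnitude of significance); `s(1) = 0`. p-values are floored at
#' 1e-300 upstream, keeping the score finite.
#'
#' @param p scoring p-value(s) in (0, 1\].
#' @param logBase base of the logarithm (10 or `exp(1)`).
#' @return non-negative score(s).
#' @examples
#' termScore(0.001)  # 3
#' @export
termScore <- function(p, logBase = 10) {
    p <- as.numeric(p)
    if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]")
    -log(p, base = logBase)
}

.P_FLOOR <- 1e-300

#' GO enrichment of one bicluster
#'
#' Tests every term with at least one annotated bicluster gene with the
#' upper-tail hypergeometric test, adjusts across exactly those tested terms
#' with Benjamini-Hochberg (the multiple-testing family is per bicluster),
#' and keeps terms with adjusted p at or below `alpha`. The number of genes
#' entering each test (`X` of the hypergeometric) is the count of bicluster
#' genes carrying at least one annotation: genes without any annotation can
#' not contribute to a term overlap, and excluding them is what makes the
#' downstream weighted-enrichment score exactly invariant to unannotated
#' genes. The score column uses the adjusted p by default (significance is
#' decided on the adjusted scale, so scoring the same quantity is
#' self-consistent); set `scoreOn = "raw"` to score raw p-values.
#'
#' @param b a [Bicluster-class].
#' @param ann an [AnnotationMap-class].
#' @param alpha significance level on the adjusted p-values (default 0.05).
#' @param scoreOn `"adjusted"` (default) or `"raw"`: which p enters the -log
#'   score.
#' @param logBase base for [termScore()].
#' @return data.frame with one row per significant term, columns `term`, `x`
#'   (bicluster genes annotated to the term), `PN` (term size in the
#'   universe), `p` (raw), `q` (BH-adjusted), `s` (score), sorted by `q` then
#'   term id. Zero rows when nothing is significant. If no bicluster gene is
#'   annotated the result additionally carries attribute
#'   `noAnnotation = TRUE` and a warning is raised.
#' @export
enrichBicluster <- function(b, ann, alpha = 0.05,
                            scoreOn = c("adjusted", "raw"), logBase = 10) {
    scoreOn <- match.arg(scoreOn)
    stopifnot(is(b, "Bicluster"), is(ann, "AnnotationMap"))
    empty <- data.frame(term = character(), x = integer(), PN = integer(),
        p = numeric(), q = numeric(), s = numeric(), stringsAsFactors = FALSE)
    annGenes <- intersect(genes(b), annotatedGenes(ann))
    if (length(annGenes) == 0L) {
        warning("no gene of bicluster '", biclusterId(b),
            "' is annotated; returning empty enrichment")
        attr(empty, "noAnnotation") <- TRUE
        return(empty)
    }
    X <- length(annGenes)
    N <- universeSize(ann)
    hits <- unlist(ann@geneToTerms[annGenes], use.names = FALSE)
    xTab <- table(hits)
    terms <- names(xTab)
    x <- as.integer(xTab)
    PN <- as.integer(termSize(ann, terms))
    p <- hypergeomPValue(x, X = X, PN = PN, N = N)
    q <- bhFDR(p)
    keep <- q <= alpha
    if (!any(keep)) return(empty)
    pScore <- pmax(if (scoreOn == "adjusted") q[keep] else p[keep], .P_FLOOR)
    out <- data.frame(term = terms[keep], x = x[keep], PN = PN[keep],
        p = p[keep], q = q[keep], s = termScore(pScore, logBase),
        stringsAsFactors = FALSE)
    out <- out[order(out$q, out$term), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Count annotated-but-unenriched bicluster genes
#'
#' `non` is the number of bicluster genes that carry at least one annotation
#' but are not annotated to any of the significantly enriched terms. Genes
#' with no annotation at all are excluded: they cancel out of the weighted
#' enrichment score.
#'
#' @param b a [Bicluster-class].
#' @param ann an [AnnotationMap-class].
#' @param terms enrichment table from [enrichBicluster()] for this bicluster.
#' @return non-negative integer.
#' @export
computeNon <- function(b, ann, terms) {
    stopifnot(is(b, "Bicluster"), is(ann, "AnnotationMap"))
    annGenes <- intersect(genes(b), annotatedGenes(ann))
    if (nrow(terms) == 0L) return(length(annGenes))
    covered <- unique(unlist(lapply(terms$term, function(t)
        intersect(termGenes(ann, t), annGenes)), use.names = FALSE))
    length(annGenes) - length(covered)
}

#' Weighted enrichment (WE) score from per-term components
#'
#' The WE score of a bicluster is the gene-count-weighted mean of its
#' significant terms' -log p scores, with annotated-but-unenriched genes
#' diluting the denominator:
#' \deqn{WE = (x_1 s_1 + \dots + x_n s_n) / (x_1 + \dots + x_n + non)}
#' A bicluster with no significant term scores 0 (the lowest possible value),
#' so it ranks last rather than dropping out; this case is flagged in the
#' result. The score does not depend on the bicluster size `X` or on genes
#' without annotation.
#'
#' @param terms enrichment table ([enrichBicluster()] output); may have zero
#'   rows.
#' @param non count of annotated-but-unenriched genes ([computeNon()]).
#' @param X bicluster gene count (carried through for reporting only).
#' @return list with elements `weScore`, `n` (number of significant terms),
#'   `non`, `X`, and `noEnrichment` (TRUE when `n == 0`).
#' @examples
#' t1 <- data.frame(term = c("A", "B"), x = c(3, 2), PN = c(10, 10),
#'     p = c(1e-5, 1e-2), q = c(1e-5, 1e-2), s = c(5, 2))
#' weScore(t1, non = 5)$weScore  # (3*5 + 2*2) / (3 + 2 + 5) = 1.9
#' @export
weScore <- function(terms, non, X = NA_integer_) {
    non <- as.numeric(non)
    if (is.na(non) || non < 0) stop("'non' must be a non-negative count")
    n <- nrow(terms)
    score <- if (n == 0L) 0
        else sum(terms$x * terms$s) / (sum(terms$x) + non)
    list(weScore = score, n = n, non = as.integer(non), X = as.integer(X),
        noEnrichment = n == 0L)
}

#' Full WE scoring of one bicluster
#'
#' Convenience wrapper: enrichment, `non` computation and aggregation in one
#' call.
#'
#' @inheritParams enrichBicluster
#' @return list as from [weScore()], plus `biclusterId`, `annotated` (count
#'   of annotated bicluster genes), `terms` (the enrichment table) and
#'   `noAnnotation`.
#' @export
scoreWE <- function(b, ann, alpha = 0.05, scoreOn = c("adjusted", "raw"),
                    logBase = 10) {
    terms <- enrichBicluster(b, ann, alpha = alpha, scoreOn = scoreOn,
        logBase = logBase)
    non <- computeNon(b, ann, terms)
    res <- weScore(terms, non, X = length(genes(b)))
    res$biclusterId <- biclusterId(b)
    res$annotated <- length(intersect(genes(b), annotatedGenes(ann)))
    res$terms <- terms
    res$noAnnotation <- isTRUE(attr(terms, "noAnnotation"))
    res
}
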