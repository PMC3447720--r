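#' Unified ranking of scored biclusters across algorithms
#'
#' Pools biclusters from all algorithms and ranks them by one score,
#' descending (higher score = more biologically significant). Ties receive
#' the mean rank; the presentation order breaks ties deterministically by
#' (algorithm, bicluster id). Entries are then assigned to `nSections`
#' contiguous rank bands (quartiles by default) whose sizes differ by at most
#' one, best scores in section 1.
#'
#' @param scored data.frame with columns `bicluster_id`, `algorithm`,
#'   `score` (finite numeric; map undefined scores to 0 beforehand).
#' @param nSections number of rank sections (>= 2).
#' @param scoreName label stored on the result (`"WE"` or `"PPI"`, free-form).
#' @return data.frame with columns `bicluster_id`, `algorithm`, `score`,
#'   `rank` (mean ranks, 1 = best) and `section` (integer in 1..nSections),
#'   ordered by rank then algorithm then id; attribute `scoreName`. Empty
#'   input gives an empty table.
#' @examples
#' sc <- data.frame(bicluster_id = c("a", "b", "c"),
#'     algorithm = "ISA", score = c(3, 1, 2))
#' combinedRanking(sc, nSections = 2)
#' @export
combinedRanking <- function(scored, nSections = 4L, scoreName = "score") {
    nSections <- as.integer(nSections)
    stopifnot(nSections >= 2L)
    need <- c("bicluster_id", "algorithm", "score")
    miss <- setdiff(need, names(scored))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
    out <- scored[, need, drop = FALSE]
    n <- nrow(out)
    if (n == 0L) {
        out$rank <- numeric(); out$section <- integer()
        attr(out, "scoreName") <- scoreName
        return(out)
    }
    if (any(!is.finite(out$score)))
        stop("scores must be finite; map undefined scores to 0 first")
    out$rank <- rank(-out$score, ties.method = "average")
    o <- order(out$rank, out$algorithm, out$bicluster_id)
    out <- out[o, , drop = FALSE]
    # contiguous bands whose sizes differ by at most one
    sizes <- rep(n %/% nSections, nSections) +
        c(rep(1L, n %% nSections), rep(0L, nSections - n %% nSections))
    out$section <- rep(seq_len(nSections), sizes)
    rownames(out) <- NULL
    attr(out, "scoreName") <- scoreName
    out
}

#' Per-algorithm counts across rank sections
#'
#' Summarises a unified ranking as a matrix of counts `D[algorithm, section]`
#' — the diagnostic used to compare biclustering algorithms: a good algorithm
#' concentrates its biclusters in the top sections. Row sums equal each
#' algorithm's bicluster count; column sums equal the section sizes.
#'
#' @param ranked output of [combinedRanking()].
#' @return integer matrix, algorithms in rows, sections in columns.
#' @export
rankDistribution <- function(ranked) {
    if (nrow(ranked) == 0L) stop("empty ranking")
    nSec <- max(ranked$section)
    tab <- table(factor(ranked$algorithm),
        factor(ranked$section, levels = seq_len(nSec)))
    m <- matrix(as.integer(tab), nrow = nrow(tab),
        dimnames = list(rownames(tab), paste0("section", seq_len(nSec))))
    m
}

#' Kendall tau rank correlation between two score lists
#'
#' Tie-corrected tau-b over paired observations, with the significance test
#' from `stats::cor.test(method = "kendall")`: exact enumeration for small
#' tie-free samples, otherwise the normal approximation with tie-adjusted
#' variance. Symmetric in its arguments.
#'
#' @param xs,ys paired numeric vectors of equal length >= 2.
#' @return list with `tau`, `pValue` (two-sided) and `nPairs`.
#' @examples
#' kendallTau(1:4, c(2, 1, 4, 3))$tau
#' @export
kendallTau <- function(xs, ys) {
    xs <- as.numeric(xs); ys <- as.numeric(ys)
    if (length(xs) != length(ys))
        stop("xs and ys must have equal length")
    if (length(xs) < 2L) stop("need at least 2 pairs")
    ct <- suppressWarnings(stats::cor.test(xs, ys, method = "kendall"))
    list(tau = unname(ct$estimate), pValue = ct$p.value,
        nPairs = length(xs))
}
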