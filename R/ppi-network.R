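#' Construct a PPINetwork from an edge table
#'
#' Edges are made undirected (endpoint order canonicalised), self-loops
#' dropped silently, and parallel edges collapsed keeping the maximum weight.
#' Only edges with weight strictly above `threshold` are retained in the
#' graph; `database` records every identifier known to the interaction
#' source before thresholding (defaults to all endpoints in `from`/`to`).
#'
#' @param from,to character vectors of interaction endpoints.
#' @param weight numeric combined-confidence scores in (0,1].
#' @param threshold confidence cutoff; retention requires weight > threshold.
#' @param database optional character vector of all identifiers known to the
#'   source (pre-thresholding roster used by [ppiScore()]'s database mode).
#' @return A [PPINetwork-class].
#' @examples
#' net <- PPINetwork(c("a", "b"), c("b", "c"), c(0.9, 0.5), threshold = 0.7)
#' nodes(net)          # "a" "b"
#' databaseGenes(net)  # "a" "b" "c"
#' @export
PPINetwork <- function(from, to, weight, threshold = 0.7, database = NULL) {
    from <- as.character(from); to <- as.character(to)
    weight <- as.numeric(weight)
    stopifnot(length(from) == length(to), length(from) == length(weight))
    allIds <- unique(c(from, to))
    if (is.null(database)) database <- allIds
    else database <- unique(c(as.character(database), allIds))
    keep <- from != to
    from <- from[keep]; to <- to[keep]; weight <- weight[keep]
    a <- pmin(from, to); b <- pmax(from, to)
    if (length(a)) {
        key <- paste0(a, "\r", b)
        # collapse parallel edges to the maximum weight
        w <- tapply(weight, key, max)
        parts <- strsplit(names(w), "\r", fixed = TRUE)
        a <- vapply(parts, `[`, character(1), 1L)
        b <- vapply(parts, `[`, character(1), 2L)
        weight <- as.numeric(w)
    }
    keep <- weight > threshold
    e <- data.frame(from = a[keep], to = b[keep], weight = weight[keep],
        stringsAsFactors = FALSE)
    o <- order(e$from, e$to)
    e <- e[o, , drop = FALSE]
    rownames(e) <- NULL
    new("PPINetwork", edges = e, nodes = sort(unique(c(e$from, e$to))),
        database = sort(database), threshold = as.numeric(threshold))
}

#' @rdname network-accessors
#' @param x a [PPINetwork-class].
#' @export
setMethod("edges", "PPINetwork", function(x) x@edges)

#' @rdname network-accessors
#' @export
setMethod("nodes", "PPINetwork", function(x) x@nodes)

#' @rdname network-accessors
#' @export
setMethod("databaseGenes", "PPINetwork", function(x) x@database)

#' @rdname network-accessors
#' @export
setMethod("networkThreshold", "PPINetwork", function(x) x@threshold)

setMethod("show", "PPINetwork", function(object) {
    cat(sprintf(
        "PPINetwork: %d nodes, %d edges above threshold %.3g (%d ids in source)\n",
        length(object@nodes), nrow(object@edges), object@threshold,
        length(object@database)))
})
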