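#' @import methods
NULL

#' Bicluster: a gene set paired with a condition set
#'
#' A bicluster is a subset of genes together with a subset of experimental
#' conditions under which those genes show coherent expression. Identifiers
#' are opaque, case-sensitive strings; any probe-to-gene mapping is the
#' caller's responsibility. Both sets are stored deduplicated and
#' whitespace-trimmed, and must be non-empty.
#'
#' @slot id character(1) label, unique within a [BiclusterSet].
#' @slot algorithm character(1) tag naming the source biclustering method
#'   (e.g. "BIMAX", "ISA", or "random" for baseline groups).
#' @slot genes character vector of gene identifiers (no duplicates).
#' @slot conditions character vector of condition identifiers (no duplicates).
#'
#' @seealso [Bicluster()] constructor, [filterBiclusters()]
#' @exportClass Bicluster
setClass("Bicluster",
    representation(
        id = "character",
        algorithm = "character",
        genes = "character",
        conditions = "character"
    )
)

setValidity("Bicluster", function(object) {
    msg <- character()
    if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
        msg <- c(msg, "'id' must be a single non-empty string")
    if (length(object@algorithm) != 1L || is.na(object@algorithm))
        msg <- c(msg, "'algorithm' must be a single string")
    if (length(object@genes) == 0L)
        msg <- c(msg, "empty genes: a bicluster needs at least one gene")
    if (length(object@conditions) == 0L)
        msg <- c(msg, "empty conditions: a bicluster needs at least one condition")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "duplicate gene identifiers")
    if (anyDuplicated(object@conditions))
        msg <- c(msg, "duplicate condition identifiers")
    if (length(msg)) msg else TRUE
})

#' BiclusterSet: an ordered collection of biclusters
#'
#' Container preserving input order, with unique bicluster ids. Supports
#' `length()`, `[`, `[[`, `names()` and coercion to data.frame (one row per
#' bicluster with size summaries).
#'
#' @slot biclusters list of [Bicluster-class] objects.
#' @slot datasetLabel character(1) free-text label for the expression dataset
#'   the biclusters were derived from.
#'
#' @seealso [BiclusterSet()] constructor, [readBiclusters()]
#' @exportClass BiclusterSet
setClass("BiclusterSet",
    representation(
        biclusters = "list",
        datasetLabel = "character"
    ),
    prototype(biclusters = list(), datasetLabel = NA_character_)
)

setValidity("BiclusterSet", function(object) {
    msg <- character()
    ok <- vapply(object@biclusters, is, logical(1), class2 = "Bicluster")
    if (!all(ok))
        msg <- c(msg, "all elements must be Bicluster objects")
    else {
        ids <- vapply(object@biclusters, function(b) b@id, character(1))
        if (anyDuplicated(ids))
            msg <- c(msg, sprintf("duplicate bicluster ids: %s",
                paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    }
    if (length(object@datasetLabel) != 1L)
        msg <- c(msg, "'datasetLabel' must be a single string (may be NA)")
    if (length(msg)) msg else TRUE
})

#' AnnotationMap: bidirectional gene/term membership over a gene universe
#'
#' Holds the gene-to-term and term-to-gene maps used for enrichment testing,
#' plus the declared gene universe. The two maps are exact transposes of one
#' another; every annotated gene belongs to the universe, while the universe
#' may contain unannotated genes. The universe size is the `N` of the
#' hypergeometric test ("total number of genes in the whole genome"), and each
#' term's gene count is that term's `PN`.
#'
#' @slot geneToTerms named list: gene id -> character vector of term ids.
#' @slot termToGenes named list: term id -> character vector of gene ids.
#' @slot universe character vector of all gene identifiers considered.
#'
#' @seealso [readAnnotations()], [synthAnnotations()], [enrichBicluster()]
#' @exportClass AnnotationMap
setClass("AnnotationMap",
    representation(
        geneToTerms = "list",
        termToGenes = "list",
        universe = "character"
    )
)

setValidity("AnnotationMap", function(object) {
    msg <- character()
    if (length(object@termToGenes) == 0L)
        msg <- c(msg, "empty annotation set")
    ann <- names(object@geneToTerms)
    if (length(ann) && !all(ann %in% object@universe))
        msg <- c(msg, "annotated genes outside the declared universe")
    if (anyDuplicated(object@universe))
        msg <- c(msg, "duplicate genes in universe")
    # transpose consistency (pairs match in both directions)
    fwd <- sort(paste(rep(ann, lengths(object@geneToTerms)),
        unlist(object@geneToTerms, use.names = FALSE)))
    trm <- names(object@termToGenes)
    rev <- sort(paste(unlist(object@termToGenes, use.names = FALSE),
        rep(trm, lengths(object@termToGenes))))
    if (!identical(fwd, rev))
        msg <- c(msg, "geneToTerms and termToGenes are not transposes")
    if (length(msg)) msg else TRUE
})

#' PPINetwork: a confidence-thresholded undirected interaction network
#'
#' Undirected weighted graph of protein-protein interactions retained at a
#' combined-score confidence cutoff, together with the full roster of
#' identifiers seen in the source file before thresholding ("known to the
#' database"). The roster is what lets the PPI score distinguish a gene absent
#' from the interaction source from one merely lacking a high-confidence edge.
#'
#' @slot edges data.frame with columns `from`, `to` (character, lexicographically
#'   ordered within each row) and `weight` (numeric in (0,1]); no self-loops,
#'   each unordered pair at most once, all weights strictly above `threshold`.
#' @slot nodes character vector: endpoints of retained edges.
#' @slot database character vector: every identifier present in the source,
#'   before thresholding.
#' @slot threshold numeric(1) confidence cutoff applied at read time.
#'
#' @seealso [readPPINetwork()], [synthPPI()], [ppiScore()]
#' @exportClass PPINetwork
setClass("PPINetwork",
    representation(
        edges = "data.frame",
        nodes = "character",
        database = "character",
        threshold = "numeric"
    )
)

setValidity("PPINetwork", function(object) {
    msg <- character()
    e <- object@edges
    if (!all(c("from", "to", "weight") %in% names(e)))
        msg <- c(msg, "edges must have columns from, to, weight")
    else {
        if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
        if (any(e$from > e$to)) msg <- c(msg, "edge endpoints must be ordered from < to")
        if (anyDuplicated(paste(e$from, e$to))) msg <- c(msg, "duplicate edges")
        if (nrow(e) && any(e$weight <= object@threshold))
            msg <- c(msg, "all retained edge weights must exceed the threshold")
        if (!all(c(e$from, e$to) %in% object@nodes))
            msg <- c(msg, "edge endpoints missing from nodes")
    }
    if (!all(object@nodes %in% object@database))
        msg <- c(msg, "nodes must be a subset of the database roster")
    if (length(object@threshold) != 1L || object@threshold < 0 || object@threshold > 1)
        msg <- c(msg, "threshold must be a single value in [0,1]")
    if (length(msg)) msg else TRUE
})
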