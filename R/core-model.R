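#' Construct a validated Bicluster
#'
#' Gene and condition identifiers are whitespace-trimmed and deduplicated;
#' empty strings are rejected. An empty gene or condition collection (after
#' cleaning) is an error naming the offending field.
#'
#' @param id single string, the bicluster label.
#' @param algorithm single string naming the source algorithm.
#' @param genes character vector of gene identifiers.
#' @param conditions character vector of condition identifiers.
#' @return A [Bicluster-class] object.
#' @examples
#' b <- Bicluster("b1", "BIMAX", c("g1", "g2", "g2", "g3"), c("c1", "c2"))
#' length(genes(b))  # 3: duplicates collapsed
#' @export
Bicluster <- function(id, algorithm, genes, conditions) {
    genes <- .cleanIds(genes, "genes")
    conditions <- .cleanIds(conditions, "conditions")
    if (length(genes) == 0L)
        stop("empty genes in bicluster '", id, "'")
    if (length(conditions) == 0L)
        stop("empty conditions in bicluster '", id, "'")
    new("Bicluster", id = as.character(id), algorithm = as.character(algorithm),
        genes = genes, conditions = conditions)
}

.cleanIds <- function(x, what) {
    x <- trimws(as.character(x))
    x <- x[!is.na(x) & nzchar(x)]
    unique(x)
}

#' Construct a BiclusterSet
#'
#' @param biclusters list of [Bicluster-class] objects (input order is kept).
#' @param datasetLabel optional single string labelling the source dataset.
#' @return A [BiclusterSet-class].
#' @examples
#' bs <- BiclusterSet(list(
#'     Bicluster("b1", "BIMAX", c("g1", "g2"), c("c1", "c2")),
#'     Bicluster("b2", "ISA", c("g3"), c("c1"))))
#' length(bs)
#' @export
BiclusterSet <- function(biclusters = list(), datasetLabel = NA_character_) {
    new("BiclusterSet", biclusters = biclusters,
        datasetLabel = as.character(datasetLabel))
}

#' @rdname accessors
#' @param x a [Bicluster-class] or [BiclusterSet-class].
#' @aliases genes,Bicluster-method
#' @export
setMethod("genes", "Bicluster", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("conditions", "Bicluster", function(x) x@conditions)

#' @rdname accessors
#' @export
setMethod("algorithm", "Bicluster", function(x) x@algorithm)

#' @rdname accessors
#' @export
setMethod("biclusterId", "Bicluster", function(x) x@id)

#' @rdname accessors
#' @export
setMethod("datasetLabel", "BiclusterSet", function(x) x@datasetLabel)

#' @export
setMethod("length", "BiclusterSet", function(x) length(x@biclusters))

#' @export
setMethod("names", "BiclusterSet", function(x)
    vapply(x@biclusters, biclusterId, character(1)))

#' @export
setMethod("[[", "BiclusterSet", function(x, i) {
    if (is.character(i)) i <- match(i, names(x))
    x@biclusters[[i]]
})

#' @export
setMethod("[", "BiclusterSet", function(x, i) {
    if (is.character(i)) i <- match(i, names(x))
    initialize(x, biclusters = x@biclusters[i])
})

setMethod("show", "Bicluster", function(object) {
    cat(sprintf("Bicluster '%s' [%s]: %d genes x %d conditions\n",
        object@id, object@algorithm,
        length(object@genes), length(object@conditions)))
})

setMethod("show", "BiclusterSet", function(object) {
    cat(sprintf("BiclusterSet of %d bicluster(s)", length(object)))
    if (!is.na(object@datasetLabel))
        cat(sprintf(" [dataset: %s]", object@datasetLabel))
    cat("\n")
    if (length(object)) {
        df <- as(object, "data.frame")
        print(utils::head(df, 8))
        if (length(object) > 8) cat("...\n")
    }
})

setAs("BiclusterSet", "data.frame", function(from) {
    data.frame(
        bicluster_id = names(from),
        algorithm = vapply(from@biclusters, algorithm, character(1)),
        n_genes = vapply(from@biclusters, function(b) length(genes(b)), integer(1)),
        n_conditions = vapply(from@biclusters, function(b) length(conditions(b)),
            integer(1)),
        stringsAsFactors = FALSE
    )
})

#' Drop biclusters below size thresholds
#'
#' Retains exactly the biclusters with at least `minGenes` genes and at least
#' `minConditions` conditions ("fewer than k" is strict, so a bicluster with
#' exactly `minGenes` genes is kept). Input order is preserved and the input
#' object is unmodified. Typical settings are 5 genes / 2 conditions for a
#' large microarray compendium and 5 genes / 3 conditions for a smaller
#' pathway-focused matrix.
#'
#' @param bset a [BiclusterSet-class].
#' @param minGenes,minConditions positive integer thresholds.
#' @return The filtered [BiclusterSet-class] (possibly empty).
#' @examples
#' bs <- BiclusterSet(list(
#'     Bicluster("small", "ISA", paste0("g", 1:4), paste0("c", 1:3)),
#'     Bicluster("kept", "ISA", paste0("g", 1:5), paste0("c", 1:2))))
#' names(filterBiclusters(bs, 5, 2))
#' @export
filterBiclusters <- function(bset, minGenes = 5L, minConditions = 2L) {
    stopifnot(is(bset, "BiclusterSet"))
    minGenes <- as.integer(minGenes)
    minConditions <- as.integer(minConditions)
    if (minGenes < 1L || minConditions < 1L)
        stop("size thresholds must be >= 1")
    keep <- vapply(bset@biclusters, function(b)
        length(b@genes) >= minGenes && length(b@conditions) >= minConditions,
        logical(1))
    initialize(bset, biclusters = bset@biclusters[keep])
}
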