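#' Build an AnnotationMap from gene/term pairs
#'
#' Duplicate (gene, term) pairs are collapsed. The universe defaults to the
#' set of annotated genes; passing an explicit universe (e.g. every gene on
#' the array) widens `N` without annotating the extra genes. The universe must
#' contain all annotated genes.
#'
#' @param gene character vector of gene ids (paired with `term`).
#' @param term character vector of term ids, same length as `gene`.
#' @param universe optional character vector of all genes considered.
#' @return An [AnnotationMap-class].
#' @examples
#' ann <- AnnotationMap(c("g1", "g2", "g2"), c("T1", "T1", "T2"))
#' universeSize(ann)  # 2
#' termSize(ann, "T1")  # 2
#' @export
AnnotationMap <- function(gene, term, universe = NULL) {
    gene <- trimws(as.character(gene))
    term <- trimws(as.character(term))
    if (length(gene) != length(term))
        stop("gene and term vectors must have equal length")
    keep <- nzchar(gene) & nzchar(term) & !is.na(gene) & !is.na(term)
    gene <- gene[keep]; term <- term[keep]
    if (length(gene) == 0L)
        stop("empty annotation set")
    dup <- duplicated(paste0(gene, "\r", term))
    gene <- gene[!dup]; term <- term[!dup]
    g2t <- split(term, gene)
    t2g <- split(gene, term)
    if (is.null(universe)) {
        universe <- sort(unique(gene))
    } else {
        universe <- unique(trimws(as.character(universe)))
        missing <- setdiff(names(g2t), universe)
        if (length(missing))
            stop("universe smaller than the annotated gene set; missing e.g. ",
                paste(utils::head(missing, 3), collapse = ", "))
    }
    new("AnnotationMap", geneToTerms = g2t, termToGenes = t2g,
        universe = universe)
}

#' @rdname annotation-accessors
#' @param x an [AnnotationMap-class].
#' @param term term identifier(s); if missing, sizes of all terms.
#' @export
setMethod("universe", "AnnotationMap", function(x) x@universe)

#' @rdname annotation-accessors
#' @export
setMethod("universeSize", "AnnotationMap", function(x) length(x@universe))

#' @rdname annotation-accessors
#' @export
setMethod("annotatedGenes", "AnnotationMap", function(x) names(x@geneToTerms))

#' @rdname annotation-accessors
#' @export
setMethod("termSize", "AnnotationMap", function(x, term) {
    if (missing(term)) return(lengths(x@termToGenes))
    lengths(x@termToGenes[term])
})

#' Genes annotated to a term
#' @param x an [AnnotationMap-class].
#' @param term single term identifier.
#' @return character vector of gene ids (empty if the term is unknown).
#' @export
termGenes <- function(x, term) {
    stopifnot(is(x, "AnnotationMap"))
    g <- x@termToGenes[[term]]
    if (is.null(g)) character() else g
}

#' Terms annotated to a gene
#' @param x an [AnnotationMap-class].
#' @param gene single gene identifier.
#' @return character vector of term ids (empty if unannotated).
#' @export
geneTerms <- function(x, gene) {
    stopifnot(is(x, "AnnotationMap"))
    t <- x@geneToTerms[[gene]]
    if (is.null(t)) character() else t
}

setMethod("show", "AnnotationMap", function(object) {
    cat(sprintf(
        "AnnotationMap: %d terms, %d annotated genes, universe N = %d\n",
        length(object@termToGenes), length(object@geneToTerms),
        length(object@universe)))
})
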