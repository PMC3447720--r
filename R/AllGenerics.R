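#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname accessors
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))

#' @rdname accessors
#' @export
setGeneric("algorithm", function(x) standardGeneric("algorithm"))

#' @rdname accessors
#' @export
setGeneric("biclusterId", function(x) standardGeneric("biclusterId"))

#' @rdname accessors
#' @export
setGeneric("datasetLabel", function(x) standardGeneric("datasetLabel"))

#' @rdname annotation-accessors
#' @export
setGeneric("universe", function(x) standardGeneric("universe"))

#' @rdname annotation-accessors
#' @export
setGeneric("universeSize", function(x) standardGeneric("universeSize"))

#' @rdname annotation-accessors
#' @export
setGeneric("annotatedGenes", function(x) standardGeneric("annotatedGenes"))

#' @rdname annotation-accessors
#' @export
setGeneric("termSize", function(x, term) standardGeneric("termSize"))

#' @rdname network-accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname network-accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname network-accessors
#' @export
setGeneric("databaseGenes", function(x) standardGeneric("databaseGenes"))

#' @rdname network-accessors
#' @export
setGeneric("networkThreshold", function(x) standardGeneric("networkThreshold"))
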