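#' Read bicluster memberships from a long TSV or JSON file
#'
#' The long TSV schema has a header and four columns: `bicluster_id`,
#' `algorithm`, `element_type` (one of `gene`, `condition`) and `element_id`;
#' one row per membership. The JSON schema is an array of objects with fields
#' `id`, `algorithm`, `genes`, `conditions`. Validation (trimming,
#' deduplication, non-emptiness) goes through [Bicluster()]. Biclusters are
#' returned in first-appearance order.
#'
#' @param path file path.
#' @param format `"long-tsv"` or `"json"` (default guessed from extension).
#' @param datasetLabel optional label stored on the returned set.
#' @return A [BiclusterSet-class].
#' @seealso [writeBiclusters()]
#' @export
readBiclusters <- function(path, format = c("auto", "long-tsv", "json"),
                           datasetLabel = NA_character_) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
            else "long-tsv"
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "json") {
        recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
        bl <- lapply(recs, function(r)
            Bicluster(r$id, r$algorithm, unlist(r$genes), unlist(r$conditions)))
        return(BiclusterSet(bl, datasetLabel))
    }
    df <- utils::read.delim(path, header = TRUE, colClasses = "character",
        stringsAsFactors = FALSE)
    need <- c("bicluster_id", "algorithm", "element_type", "element_id")
    if (!all(need %in% names(df)))
        stop("long-tsv must have columns: ", paste(need, collapse = ", "))
    bad <- which(!df$element_type %in% c("gene", "condition"))
    if (length(bad))
        stop(sprintf("unknown element_type '%s' at line %d of %s",
            df$element_type[bad[1]], bad[1] + 1L, path))
    ids <- unique(df$bicluster_id)
    bl <- lapply(ids, function(id) {
        sub <- df[df$bicluster_id == id, , drop = FALSE]
        algs <- unique(sub$algorithm)
        if (length(algs) != 1L)
            stop(sprintf(
                "bicluster '%s' carries conflicting algorithm tags (%s) near line %d",
                id, paste(algs, collapse = ", "),
                which(df$bicluster_id == id)[1] + 1L))
        Bicluster(id, algs,
            sub$element_id[sub$element_type == "gene"],
            sub$element_id[sub$element_type == "condition"])
    })
    BiclusterSet(bl, datasetLabel)
}

#' Write bicluster memberships
#'
#' Inverse of [readBiclusters()]; `readBiclusters(writeBiclusters(x))` is the
#' identity on ids, tags and membership sets.
#'
#' @param bset a [BiclusterSet-class].
#' @param path output file path.
#' @param format `"long-tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
writeBiclusters <- function(bset, path, format = c("long-tsv", "json")) {
    format <- match.arg(format)
    stopifnot(is(bset, "BiclusterSet"))
    if (format == "json") {
        recs <- lapply(bset@biclusters, function(b) list(
            id = b@id, algorithm = b@algorithm,
            genes = as.list(b@genes), conditions = as.list(b@conditions)))
        jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
        return(invisible(path))
    }
    rows <- lapply(bset@biclusters, function(b) data.frame(
        bicluster_id = b@id, algorithm = b@algorithm,
        element_type = rep(c("gene", "condition"),
            c(length(b@genes), length(b@conditions))),
        element_id = c(b@genes, b@conditions),
        stringsAsFactors = FALSE))
    df <- .rbindRows(rows)
    if (is.null(df))
        df <- data.frame(bicluster_id = character(), algorithm = character(),
            element_type = character(), element_id = character())
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a gene annotation map
#'
#' Two supported dialects: a headerless two-column TSV of (gene id, term id)
#' pairs, or GAF 2.x, of which columns 2 (DB object id), 4 (qualifier) and
#' 5 (GO id) are used; rows whose qualifier contains `NOT` are skipped, as are
#' `!` comment lines. Duplicate pairs are collapsed. Without an explicit
#' `universe` the universe is the set of genes appearing in the file.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gaf"`.
#' @param universe optional explicit gene universe.
#' @return An [AnnotationMap-class].
#' @export
readAnnotations <- function(path, format = c("tsv", "gaf"), universe = NULL) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "tsv") {
        df <- utils::read.delim(path, header = FALSE, colClasses = "character",
            stringsAsFactors = FALSE)
        if (ncol(df) < 2L) stop("annotation TSV needs two columns: ", path)
        return(AnnotationMap(df[[1L]], df[[2L]], universe))
    }
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    if (length(lines) == 0L) stop("empty annotation set in ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 5L)
    if (length(short))
        stop("malformed GAF row (fewer than 5 columns) at data line ", short[1])
    gene <- vapply(fields, `[`, character(1), 2L)
    qual <- vapply(fields, `[`, character(1), 4L)
    term <- vapply(fields, `[`, character(1), 5L)
    keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
    if (!any(keep)) stop("empty annotation set in ", path, " (all rows NOT-qualified)")
    AnnotationMap(gene[keep], term[keep], universe)
}

#' Read a STRING-dialect interaction file into a thresholded network
#'
#' Expects whitespace- or tab-separated columns `protein1 protein2
#' combined_score`; a header row is detected by a non-numeric third field.
#' STRING distributes combined scores either as integers in 0-999 (thousandths
#' of the unit confidence) or on the unit scale; `scoreScale = "auto"` divides
#' by 1000 when any score exceeds 1. Edges are retained when the normalised
#' score is strictly greater than `threshold` ("higher than" the cutoff); 0.7
#' is the conventional high-confidence setting. All identifiers seen in the
#' file, including those whose every edge falls below the cutoff, are recorded
#' as known to the database for use by [ppiScore()].
#'
#' @param path file path.
#' @param threshold confidence cutoff in \[0,1\].
#' @param scoreScale `"auto"`, `"unit"` or `"thousandths"`.
#' @return A [PPINetwork-class].
#' @export
readPPINetwork <- function(path, threshold = 0.7,
                           scoreScale = c("auto", "unit", "thousandths")) {
    scoreScale <- match.arg(scoreScale)
    if (!file.exists(path)) stop("file not found: ", path)
    stopifnot(threshold >= 0, threshold <= 1)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty network file: ", path)
    fields <- strsplit(trimws(lines), "[ \t]+")
    short <- which(lengths(fields) < 3L)
    if (length(short))
        stop("fewer than 3 columns at line ", short[1], " of ", path)
    first <- 1L
    if (is.na(suppressWarnings(as.numeric(fields[[1L]][3L])))) first <- 2L
    if (first > length(fields)) stop("no data rows in ", path)
    fields <- fields[first:length(fields)]
    p1 <- vapply(fields, `[`, character(1), 1L)
    p2 <- vapply(fields, `[`, character(1), 2L)
    raw <- vapply(fields, `[`, character(1), 3L)
    score <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(score))
    if (length(bad))
        stop(sprintf("non-numeric combined_score '%s' at line %d of %s",
            raw[bad[1]], bad[1] + first - 1L, path))
    divide <- switch(scoreScale,
        unit = FALSE,
        thousandths = TRUE,
        auto = any(score > 1))
    if (divide) score <- score / 1000
    PPINetwork(p1, p2, score, threshold = threshold)
}

#' Read / write a genes-by-conditions expression matrix
#'
#' TSV with a header row of condition ids and gene ids in the first column.
#' Row and column labels must be unique and all cells numeric.
#'
#' @param path file path.
#' @return `readExpressionMatrix`: a numeric matrix (genes x conditions).
#' @export
readExpressionMatrix <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
        colClasses = "character", stringsAsFactors = FALSE)
    g <- df[[1L]]
    if (anyDuplicated(g))
        stop("duplicate gene labels in ", path, ": ",
            paste(utils::head(unique(g[duplicated(g)]), 3), collapse = ", "))
    if (anyDuplicated(names(df)[-1L]))
        stop("duplicate condition labels in ", path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    mode(m) <- "numeric"
    if (anyNA(m)) stop("non-numeric cell in ", path)
    rownames(m) <- g
    m
}

#' @rdname readExpressionMatrix
#' @param mat numeric matrix with rownames (genes) and colnames (conditions).
#' @return `writeExpressionMatrix`: `path`, invisibly.
#' @export
writeExpressionMatrix <- function(mat, path) {
    stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
    df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
        stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write / read a bicluster score report
#'
#' One row per scored bicluster with columns `bicluster_id`, `algorithm`,
#' `we_score`, `ppi_score`, `we_rank`, `ppi_rank` (ranks optional, `NA` when
#' not yet ranked). Rows are ordered by `we_rank` (then id) when ranks are
#' present, else by id; floats are rendered with 6 significant digits.
#'
#' @param records data.frame with at least `bicluster_id`, `algorithm`,
#'   `we_score`, `ppi_score`; optionally `we_rank`, `ppi_rank`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeScores <- function(records, path) {
    cols <- c("bicluster_id", "algorithm", "we_score", "ppi_score",
        "we_rank", "ppi_rank")
    for (cc in c("we_rank", "ppi_rank"))
        if (is.null(records[[cc]]))
            records[[cc]] <- rep(NA_real_, nrow(records))
    miss <- setdiff(cols, names(records))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
    records <- records[, cols, drop = FALSE]
    if (nrow(records)) {
        o <- if (all(is.na(records$we_rank)))
            order(records$bicluster_id)
        else order(records$we_rank, records$bicluster_id)
        records <- records[o, , drop = FALSE]
    }
    for (cc in c("we_score", "ppi_score", "we_rank", "ppi_rank"))
        records[[cc]] <- signif(as.numeric(records[[cc]]), 6)
    utils::write.table(records, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' @rdname writeScores
#' @return `readScores`: the score report as a data.frame.
#' @export
readScores <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}
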