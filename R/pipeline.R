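# rbind a list of data.frames, tolerating NULL entries and empty lists
.rbindRows <- function(rows) {
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) return(NULL)
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Score every bicluster of a set with both quality scores
#'
#' Applies the weighted-enrichment and interaction-coherence scores to each
#' bicluster and returns one report row per bicluster. Undefined interaction
#' scores (no bicluster gene known to the database) are reported as 0 with
#' `ppi_undefined = TRUE`, and biclusters with no significant term carry
#' `we_no_enrichment = TRUE`.
#'
#' @param bset a [BiclusterSet-class] (already filtered if desired).
#' @param ann an [AnnotationMap-class].
#' @param net a [PPINetwork-class].
#' @param alpha,scoreOn,logBase passed to [scoreWE()].
#' @param mMode passed to [ppiScore()].
#' @return data.frame with columns `bicluster_id`, `algorithm`, `n_genes`,
#'   `n_conditions`, `we_score`, `we_n_terms`, `we_non`, `we_no_enrichment`,
#'   `ppi_score`, `ppi_I`, `ppi_M`, `ppi_undefined`.
#' @export
scoreBiclusters <- function(bset, ann, net, alpha = 0.05,
                            scoreOn = c("adjusted", "raw"), logBase = 10,
                            mMode = c("database", "graph")) {
    scoreOn <- match.arg(scoreOn); mMode <- match.arg(mMode)
    stopifnot(is(bset, "BiclusterSet"))
    rows <- lapply(bset@biclusters, function(b) {
        we <- suppressWarnings(scoreWE(b, ann, alpha = alpha,
            scoreOn = scoreOn, logBase = logBase))
        pp <- ppiScore(b, net, mMode = mMode)
        data.frame(bicluster_id = biclusterId(b), algorithm = algorithm(b),
            n_genes = length(genes(b)),
            n_conditions = length(conditions(b)),
            we_score = we$weScore, we_n_terms = we$n, we_non = we$non,
            we_no_enrichment = we$noEnrichment,
            ppi_score = pp$score, ppi_I = pp$I, ppi_M = pp$M,
            ppi_undefined = pp$undefined, stringsAsFactors = FALSE)
    })
    out <- .rbindRows(rows)
    if (is.null(out))
        out <- data.frame(bicluster_id = character(), algorithm = character(),
            n_genes = integer(), n_conditions = integer(),
            we_score = numeric(), we_n_terms = integer(), we_non = integer(),
            we_no_enrichment = logical(), ppi_score = numeric(),
            ppi_I = integer(), ppi_M = integer(), ppi_undefined = logical())
    out
}

#' Scoring pipeline: filter, enrich, score, report
#'
#' Reads bicluster membership files, drops undersized biclusters, computes
#' both quality scores against the given annotation map and interaction
#' network, and writes a score report (`scores.tsv`) plus a long per-term
#' enrichment table (`terms.tsv`) into `outDir`.
#'
#' @param biclusterFiles character vector of membership files
#'   ([readBiclusters()] formats); several files are pooled.
#' @param annotationFile annotation file ([readAnnotations()]).
#' @param ppiFile interaction file ([readPPINetwork()]).
#' @param outDir output directory (created if missing).
#' @param minGenes,minConditions size filter thresholds.
#' @param alpha,scoreOn,logBase,mMode scoring options.
#' @param ppiThreshold,scoreScale network reading options.
#' @param annotationFormat,universe passed to [readAnnotations()].
#' @return the score report data.frame, invisibly.
#' @export
runScore <- function(biclusterFiles, annotationFile, ppiFile, outDir,
                     minGenes = 5L, minConditions = 2L, alpha = 0.05,
                     scoreOn = "adjusted", logBase = 10, mMode = "database",
                     ppiThreshold = 0.7, scoreScale = "auto",
                     annotationFormat = "tsv", universe = NULL) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    sets <- lapply(biclusterFiles, readBiclusters)
    bl <- unlist(lapply(sets, function(s) s@biclusters), recursive = FALSE)
    bset <- filterBiclusters(BiclusterSet(bl), minGenes, minConditions)
    if (length(bset) == 0L)
        warning("no bicluster passed the size filter; writing an empty report")
    ann <- readAnnotations(annotationFile, format = annotationFormat,
        universe = universe)
    net <- readPPINetwork(ppiFile, threshold = ppiThreshold,
        scoreScale = scoreScale)
    report <- scoreBiclusters(bset, ann, net, alpha = alpha,
        scoreOn = scoreOn, logBase = logBase, mMode = mMode)
    writeScores(report, file.path(outDir, "scores.tsv"))
    termRows <- lapply(bset@biclusters, function(b) {
        tt <- suppressWarnings(enrichBicluster(b, ann, alpha = alpha,
            scoreOn = scoreOn, logBase = logBase))
        if (nrow(tt)) cbind(bicluster_id = biclusterId(b), tt) else NULL
    })
    terms <- .rbindRows(termRows)
    if (is.null(terms))
        terms <- data.frame(bicluster_id = character(), term = character(),
            x = integer(), PN = integer(), p = numeric(), q = numeric(),
            s = numeric())
    utils::write.table(terms, file.path(outDir, "terms.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    invisible(report)
}

#' Ranking pipeline: unified ranking, section distributions, consistency
#'
#' Pools one or more score reports (e.g. one per dataset), builds the unified
#' descending ranking for each score, tabulates per-algorithm section counts,
#' and measures the Kendall tau-b consistency between the paired score lists.
#' Writes `ranking_we.tsv`, `ranking_ppi.tsv`, `rank_distribution_we.tsv`,
#' `rank_distribution_ppi.tsv` and `kendall.tsv` into `outDir`.
#'
#' @param reportPaths character vector of score reports ([writeScores()]
#'   layout).
#' @param outDir output directory (created if missing).
#' @param nSections number of rank sections.
#' @return list with `weRanking`, `ppiRanking`, `weDistribution`,
#'   `ppiDistribution`, `kendall`, invisibly.
#' @export
runRank <- function(reportPaths, outDir, nSections = 4L) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    reports <- lapply(reportPaths, readScores)
    pooled <- .rbindRows(reports)
    if (is.null(pooled) || nrow(pooled) == 0L)
        stop("no scored biclusters in the given reports")
    bad <- !is.finite(pooled$we_score) | !is.finite(pooled$ppi_score)
    if (any(bad))
        stop("non-finite scores for: ",
            paste(utils::head(pooled$bicluster_id[bad], 5), collapse = ", "))
    mk <- function(col, nm) combinedRanking(
        data.frame(bicluster_id = pooled$bicluster_id,
            algorithm = pooled$algorithm, score = pooled[[col]],
            stringsAsFactors = FALSE),
        nSections = nSections, scoreName = nm)
    weR <- mk("we_score", "WE"); ppiR <- mk("ppi_score", "PPI")
    kd <- kendallTau(pooled$we_score, pooled$ppi_score)
    wd <- rankDistribution(weR); pd <- rankDistribution(ppiR)
    utils::write.table(weR, file.path(outDir, "ranking_we.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    utils::write.table(ppiR, file.path(outDir, "ranking_ppi.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(algorithm = rownames(wd), wd),
        file.path(outDir, "rank_distribution_we.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(algorithm = rownames(pd), pd),
        file.path(outDir, "rank_distribution_ppi.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    utils::write.table(
        data.frame(tau = kd$tau, p_value = kd$pValue, n_pairs = kd$nPairs),
        file.path(outDir, "kendall.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(list(weRanking = weR, ppiRanking = ppiR, weDistribution = wd,
        ppiDistribution = pd, kendall = kd))
}

#' Simulation pipeline: write a complete synthetic fixture directory
#'
#' Generates a consistent synthetic world from one config — annotation map,
#' interaction edge list (pre-threshold, unit scale), expression matrix,
#' implanted truth biclusters and size-matched random gene groups — and
#' writes everything in the package's file formats so the scoring and
#' ranking pipelines can run end-to-end from files. A `manifest.json`
#' records the full config including the seed.
#'
#' @param cfg a [synthConfig()].
#' @param outDir output directory.
#' @param nRandom number of random baseline groups.
#' @param force overwrite a non-empty `outDir`.
#' @return named character vector of the written file paths, invisibly.
#' @export
runSimulate <- function(cfg = synthConfig(), outDir, nRandom = 15L,
                        force = FALSE) {
    stopifnot(inherits(cfg, "SynthConfig"))
    if (dir.exists(outDir) && length(dir(outDir)) && !force)
        stop("output directory ", outDir,
            " is not empty; use force = TRUE to overwrite")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    ann <- synthAnnotations(cfg)
    rawEdges <- .synthPPIEdges(cfg)
    sim <- synthExpressionWithBiclusters(cfg)
    rand <- randomGeneGroups(universe(ann),
        colnames(sim$expression), k = nRandom, reference = sim$truth,
        seed = cfg$seed + 3L)
    paths <- c(
        annotations = file.path(outDir, "annotations.tsv"),
        ppi = file.path(outDir, "ppi_links.tsv"),
        expression = file.path(outDir, "expression.tsv"),
        truth = file.path(outDir, "truth_biclusters.tsv"),
        random = file.path(outDir, "random_groups.tsv"),
        universe = file.path(outDir, "universe.txt"),
        manifest = file.path(outDir, "manifest.json"))
    writeLines(universe(ann), paths["universe"])
    pairs <- data.frame(
        gene = rep(annotatedGenes(ann), lengths(ann@geneToTerms)),
        term = unlist(ann@geneToTerms, use.names = FALSE))
    utils::write.table(pairs, paths["annotations"], sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    ppiDf <- data.frame(protein1 = rawEdges$from, protein2 = rawEdges$to,
        combined_score = signif(rawEdges$weight, 6))
    utils::write.table(ppiDf, paths["ppi"], sep = "\t", quote = FALSE,
        row.names = FALSE)
    writeExpressionMatrix(round(sim$expression, 6), paths["expression"])
    writeBiclusters(sim$truth, paths["truth"])
    writeBiclusters(rand, paths["random"])
    jsonlite::write_json(c(unclass(cfg), list(nRandom = as.integer(nRandom))),
        paths["manifest"], auto_unbox = TRUE, digits = NA)
    invisible(paths)
}
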