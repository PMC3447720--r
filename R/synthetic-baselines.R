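# Run code under a fixed seed, restoring the caller's RNG state afterwards.
.withSeed <- function(seed, code) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else suppressWarnings(rm(".Random.seed", envir = genv))
    })
    set.seed(as.integer(seed) %% .Machine$integer.max)
    code
}

#' Configuration for the synthetic data generators
#'
#' Bundles and validates the parameters shared by [synthAnnotations()],
#' [synthPPI()] and [synthExpressionWithBiclusters()]. The same config (and
#' seed) yields a consistent world: the annotation terms and the interaction
#' modules are the same disjoint partition of the annotated genes, so a gene
#' group drawn from one term is coherent under both scores, mimicking a
#' functional module that is simultaneously GO-coherent and densely
#' interacting. Defaults emulate a filtered microarray compendium: a universe
#' of 1000 genes under 16 conditions, 80% annotation coverage split into
#' disjoint terms of 20 genes, interaction modules matching the terms with
#' within-module edge probability 0.6 and high-confidence weights, sparse
#' sub-threshold background edges, and 5 implanted coherent biclusters of 10
#' genes drawn from single terms.
#'
#' @param nGenes gene universe size.
#' @param nConditions number of expression conditions.
#' @param nTerms number of annotation terms (disjoint gene sets).
#' @param termSizeRange integer (min, max) term sizes.
#' @param annotationCoverage fraction of genes carrying >= 1 annotation; must
#'   be achievable with `nTerms` disjoint terms within `termSizeRange`.
#' @param nModules number of interaction modules; with `alignModules = TRUE`
#'   (default) must equal `nTerms` and the modules are the terms.
#' @param withinModuleEdgeProb probability of an edge between two genes of
#'   the same module (weight uniform in (0.7, 1\]).
#' @param backgroundEdgeProb per-pair probability of a sub-threshold
#'   background edge (weight uniform in (0, 0.7\]).
#' @param nImplanted number of implanted truth biclusters.
#' @param implantSizeRange integer (min, max) genes per implanted bicluster;
#'   max must not exceed the minimum term size.
#' @param implantConditionsRange integer (min, max) conditions per implant.
#' @param signalShift additive expression offset of implanted blocks.
#' @param noiseSd standard deviation of the background noise.
#' @param ppiThreshold confidence cutoff for the generated network.
#' @param alignModules logical; keep interaction modules identical to terms.
#' @param seed integer seed fixing all downstream randomness.
#' @return validated config list of class `SynthConfig`.
#' @export
synthConfig <- function(nGenes = 1000L, nConditions = 16L, nTerms = 40L,
                        termSizeRange = c(20L, 20L), annotationCoverage = 0.8,
                        nModules = nTerms, withinModuleEdgeProb = 0.6,
                        backgroundEdgeProb = 0.002, nImplanted = 5L,
                        implantSizeRange = c(10L, 10L),
                        implantConditionsRange = c(4L, 8L),
                        signalShift = 3, noiseSd = 1, ppiThreshold = 0.7,
                        alignModules = TRUE, seed = 1L) {
    cfg <- list(nGenes = as.integer(nGenes),
        nConditions = as.integer(nConditions), nTerms = as.integer(nTerms),
        termSizeRange = as.integer(termSizeRange),
        annotationCoverage = annotationCoverage,
        nModules = as.integer(nModules),
        withinModuleEdgeProb = withinModuleEdgeProb,
        backgroundEdgeProb = backgroundEdgeProb,
        nImplanted = as.integer(nImplanted),
        implantSizeRange = as.integer(implantSizeRange),
        implantConditionsRange = as.integer(implantConditionsRange),
        signalShift = signalShift, noiseSd = noiseSd,
        ppiThreshold = ppiThreshold, alignModules = isTRUE(alignModules),
        seed = as.integer(seed))
    with(cfg, {
        stopifnot(nGenes >= 1, nConditions >= 1, nTerms >= 1,
            length(termSizeRange) == 2, termSizeRange[1] <= termSizeRange[2],
            termSizeRange[1] >= 1,
            annotationCoverage >= 0, annotationCoverage <= 1,
            withinModuleEdgeProb >= 0, withinModuleEdgeProb <= 1,
            backgroundEdgeProb >= 0, backgroundEdgeProb <= 1,
            length(implantSizeRange) == 2,
            implantSizeRange[1] <= implantSizeRange[2],
            length(implantConditionsRange) == 2,
            implantConditionsRange[1] <= implantConditionsRange[2],
            noiseSd >= 0, ppiThreshold >= 0, ppiThreshold <= 1)
    })
    target <- round(cfg$annotationCoverage * cfg$nGenes)
    if (target < cfg$nTerms * cfg$termSizeRange[1] ||
        target > cfg$nTerms * cfg$termSizeRange[2])
        stop(sprintf(
            "infeasible coverage: %d annotated genes cannot be partitioned into %d disjoint terms of size %d..%d",
            target, cfg$nTerms, cfg$termSizeRange[1], cfg$termSizeRange[2]))
    if (cfg$alignModules && cfg$nModules != cfg$nTerms)
        stop("alignModules = TRUE requires nModules == nTerms")
    if (cfg$nImplanted > 0 && cfg$implantSizeRange[2] > cfg$termSizeRange[1])
        stop("implant size may not exceed the minimum term size")
    if (cfg$implantConditionsRange[2] > cfg$nConditions)
        stop("implant conditions exceed nConditions")
    structure(cfg, class = "SynthConfig")
}

# sample n integers uniformly from [rng[1], rng[2]]; safe for degenerate ranges
.sampleRange <- function(rng, n = 1L) {
    if (rng[1] == rng[2]) rep(rng[1], n)
    else sample(seq(rng[1], rng[2]), n, replace = TRUE)
}

.geneIds <- function(n) sprintf("g%04d", seq_len(n))
.condIds <- function(n) sprintf("c%02d", seq_len(n))

# Deterministic disjoint partition of the annotated genes into terms; the
# same partition serves as the module structure when alignModules is set.
.synthPartition <- function(cfg) {
    .withSeed(cfg$seed, {
        genesAll <- .geneIds(cfg$nGenes)
        target <- round(cfg$annotationCoverage * cfg$nGenes)
        lo <- cfg$termSizeRange[1]; hi <- cfg$termSizeRange[2]
        sizes <- .sampleRange(c(lo, hi), cfg$nTerms)
        # nudge sizes (within range) until they partition exactly `target` genes
        while (sum(sizes) > target) {
            i <- which(sizes > lo)[1]; sizes[i] <- sizes[i] - 1L
        }
        while (sum(sizes) < target) {
            i <- which(sizes < hi)[1]; sizes[i] <- sizes[i] + 1L
        }
        annotated <- sample(genesAll, target)
        terms <- split(annotated, rep(seq_len(cfg$nTerms), sizes))
        names(terms) <- sprintf("T%03d", seq_len(cfg$nTerms))
        list(genes = genesAll, annotated = annotated, terms = terms)
    })
}

#' Synthetic annotation map
#'
#' Disjoint terms over a seeded random subset of the universe, hitting the
#' configured coverage exactly (up to rounding of `coverage * nGenes`); the
#' universe is the full gene set, so unannotated genes exist whenever
#' coverage < 1.
#'
#' @param cfg a [synthConfig()].
#' @return An [AnnotationMap-class] with `N = cfg$nGenes`.
#' @export
synthAnnotations <- function(cfg) {
    stopifnot(inherits(cfg, "SynthConfig"))
    part <- .synthPartition(cfg)
    AnnotationMap(
        gene = unlist(part$terms, use.names = FALSE),
        term = rep(names(part$terms), lengths(part$terms)),
        universe = part$genes)
}

# Raw (pre-threshold) synthetic edge table: dense high-confidence edges
# within modules, sparse low-confidence background edges elsewhere.
.synthPPIEdges <- function(cfg) {
    part <- .synthPartition(cfg)
    modules <- part$terms
    if (!cfg$alignModules) {
        modules <- .withSeed(cfg$seed + 7L, {
            msize <- round(mean(cfg$termSizeRange))
            picked <- sample(part$genes, min(cfg$nModules * msize, cfg$nGenes))
            split(picked, rep(seq_len(cfg$nModules), length.out = length(picked)))
        })
    }
    .withSeed(cfg$seed + 1L, {
        within <- lapply(modules, function(g) {
            if (length(g) < 2) return(NULL)
            pr <- t(utils::combn(g, 2))
            keep <- stats::runif(nrow(pr)) < cfg$withinModuleEdgeProb
            if (!any(keep)) return(NULL)
            data.frame(from = pr[keep, 1], to = pr[keep, 2],
                weight = 0.7 + stats::runif(sum(keep)) * 0.3,
                stringsAsFactors = FALSE)
        })
        within <- do.call(rbind, within)
        bg <- NULL
        if (cfg$backgroundEdgeProb > 0 && cfg$nGenes >= 2) {
            nPairs <- cfg$nGenes * (cfg$nGenes - 1) / 2
            nBg <- stats::rbinom(1, round(nPairs), cfg$backgroundEdgeProb)
            if (nBg > 0) {
                i <- sample(cfg$nGenes, nBg, replace = TRUE)
                j <- sample(cfg$nGenes, nBg, replace = TRUE)
                ok <- i != j
                a <- pmin(i[ok], j[ok]); b <- pmax(i[ok], j[ok])
                dup <- duplicated(paste(a, b))
                a <- a[!dup]; b <- b[!dup]
                mod <- rep(NA_integer_, cfg$nGenes)
                for (k in seq_along(modules))
                    mod[match(modules[[k]], part$genes)] <- k
                cross <- is.na(mod[a]) | is.na(mod[b]) | mod[a] != mod[b]
                a <- a[cross]; b <- b[cross]
                if (length(a))
                    bg <- data.frame(from = part$genes[a], to = part$genes[b],
                        weight = stats::runif(length(a)) * 0.7,
                        stringsAsFactors = FALSE)
            }
        }
        rbind(within, bg)
    })
}

#' Synthetic modular interaction network
#'
#' Interaction modules are the annotation terms (by default): pairs within a
#' module get an edge with probability `withinModuleEdgeProb` and a weight
#' above the confidence cutoff; cross-module pairs get sparse background
#' edges below it. After thresholding, retained edges are therefore (almost
#' surely) within-module, while background edges still register their
#' endpoints in the database roster.
#'
#' @param cfg a [synthConfig()].
#' @return A [PPINetwork-class] thresholded at `cfg$ppiThreshold`.
#' @export
synthPPI <- function(cfg) {
    stopifnot(inherits(cfg, "SynthConfig"))
    e <- .synthPPIEdges(cfg)
    if (is.null(e))
        e <- data.frame(from = character(), to = character(),
            weight = numeric())
    PPINetwork(e$from, e$to, e$weight, threshold = cfg$ppiThreshold)
}

#' Synthetic expression matrix with implanted coherent biclusters
#'
#' Background cells are `Normal(0, noiseSd)`; each implanted bicluster adds a
#' constant `signalShift` on its gene-by-condition block. Implanted gene sets
#' are drawn from single annotation terms (equivalently, single interaction
#' modules), so the truth biclusters are functionally coherent under both
#' scores.
#'
#' @param cfg a [synthConfig()].
#' @return list with `expression` (numeric matrix, genes x conditions) and
#'   `truth` (a [BiclusterSet-class] of the implanted biclusters, algorithm
#'   tag `"truth"`).
#' @export
synthExpressionWithBiclusters <- function(cfg) {
    stopifnot(inherits(cfg, "SynthConfig"))
    part <- .synthPartition(cfg)
    if (cfg$nImplanted > cfg$nTerms)
        stop("more implants requested than available terms")
    .withSeed(cfg$seed + 2L, {
        conds <- .condIds(cfg$nConditions)
        mat <- matrix(stats::rnorm(cfg$nGenes * cfg$nConditions,
                sd = cfg$noiseSd),
            nrow = cfg$nGenes, dimnames = list(part$genes, conds))
        srcTerms <- sample(names(part$terms), cfg$nImplanted)
        truth <- vector("list", cfg$nImplanted)
        for (i in seq_len(cfg$nImplanted)) {
            ng <- .sampleRange(cfg$implantSizeRange)
            nc <- .sampleRange(cfg$implantConditionsRange)
            g <- sample(part$terms[[srcTerms[i]]], ng)
            cc <- sample(conds, nc)
            mat[g, cc] <- mat[g, cc] + cfg$signalShift
            truth[[i]] <- Bicluster(sprintf("true%02d", i), "truth", g, cc)
        }
        list(expression = mat, truth = BiclusterSet(truth, "synthetic"))
    })
}

#' Size-matched random gene groups
#'
#' Draws `k` baseline biclusters whose genes and conditions are sampled
#' uniformly without replacement from the supplied universes. Sizes come from
#' `sizeSampler(i)` when given; otherwise each group copies the (gene,
#' condition) size pair of a uniformly chosen bicluster of `reference`, so the
#' baseline is size-matched and any score contrast is attributable to
#' functional coherence rather than size. Fully reproducible from `seed`;
#' algorithm tag `"random"`.
#'
#' @param geneUniverse character vector of genes to sample from.
#' @param conditionUniverse character vector of conditions to sample from.
#' @param k number of groups (the conventional baseline uses 15).
#' @param reference optional [BiclusterSet-class] to size-match against.
#' @param sizeSampler optional `function(i)` returning `c(nGenes,
#'   nConditions)` for group `i`; overrides `reference`.
#' @param seed integer seed.
#' @return A [BiclusterSet-class] with ids `rand01`, `rand02`, ...
#' @export
randomGeneGroups <- function(geneUniverse, conditionUniverse, k = 15L,
                             reference = NULL, sizeSampler = NULL, seed = 1L) {
    k <- as.integer(k)
    stopifnot(k >= 1, length(geneUniverse) >= 1,
        length(conditionUniverse) >= 1)
    if (is.null(sizeSampler)) {
        if (is.null(reference))
            stop("supply 'reference' or 'sizeSampler' to fix group sizes")
        stopifnot(is(reference, "BiclusterSet"), length(reference) >= 1)
        refSizes <- cbind(
            vapply(reference@biclusters, function(b) length(genes(b)),
                integer(1)),
            vapply(reference@biclusters, function(b) length(conditions(b)),
                integer(1)))
        sizeSampler <- function(i)
            refSizes[sample(nrow(refSizes), 1), ]
    }
    .withSeed(seed, {
        bl <- lapply(seq_len(k), function(i) {
            sz <- sizeSampler(i)
            if (sz[1] > length(geneUniverse) ||
                sz[2] > length(conditionUniverse))
                stop("requested group size exceeds the universe")
            Bicluster(sprintf("rand%02d", i), "random",
                sample(geneUniverse, sz[1]),
                sample(conditionUniverse, sz[2]))
        })
        BiclusterSet(bl, "random-baseline")
    })
}
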