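smallCfg <- function(...) synthConfig(nGenes = 200L, nConditions = 10L,
    nTerms = 8L, termSizeRange = c(15L, 25L), annotationCoverage = 0.8,
    nModules = 8L, nImplanted = 3L, implantSizeRange = c(8L, 10L),
    implantConditionsRange = c(3L, 5L), seed = 9L, ...)

test_that("config validation rejects infeasible settings", {
    expect_error(synthConfig(nGenes = 100, nTerms = 2,
        termSizeRange = c(5, 10), annotationCoverage = 0.9),
        "infeasible coverage")
    expect_error(synthConfig(implantSizeRange = c(25, 25)),
        "implant size")
    expect_error(synthConfig(nConditions = 4,
        implantConditionsRange = c(5, 6)), "conditions")
    expect_error(synthConfig(nModules = 10), "nModules == nTerms")
})

test_that("synthetic annotations honour coverage, sizes and determinism", {
    cfg <- smallCfg()
    ann <- synthAnnotations(cfg)
    expect_identical(universeSize(ann), 200L)
    expect_equal(length(annotatedGenes(ann)), 160, tolerance = 1 / 160)
    expect_true(all(termSize(ann) >= 15 & termSize(ann) <= 25))
    expect_identical(ann, synthAnnotations(smallCfg()))

    fixed <- synthConfig(nGenes = 100L, nTerms = 5L,
        termSizeRange = c(5L, 5L), annotationCoverage = 0.25,
        nModules = 5L, nImplanted = 2L, implantSizeRange = c(4L, 5L))
    expect_true(all(termSize(synthAnnotations(fixed)) == 5))
})

test_that("synthetic network is modular with sub-threshold background", {
    # saturated module: a retained clique scoring 1.0
    cfg1 <- synthConfig(nGenes = 30L, nConditions = 4L, nTerms = 2L,
        termSizeRange = c(5L, 5L), annotationCoverage = 1 / 3,
        nModules = 2L, withinModuleEdgeProb = 1, backgroundEdgeProb = 0,
        nImplanted = 1L, implantSizeRange = c(5L, 5L),
        implantConditionsRange = c(2L, 3L), seed = 4L)
    net <- synthPPI(cfg1)
    ann <- synthAnnotations(cfg1)
    mod <- termGenes(ann, "T001")
    b <- Bicluster("m", "truth", mod, "c01")
    expect_identical(ppiScore(b, net)$score, 1)
    # background prob 0: every retained edge joins genes of one module
    e <- edges(net)
    sameModule <- function(a, b) {
        ta <- geneTerms(ann, a); tb <- geneTerms(ann, b)
        length(ta) && length(tb) && ta == tb
    }
    expect_true(all(mapply(sameModule, e$from, e$to)))

    # retained edge count within a module ~ Binomial(C(m,2), p)
    m <- 12L; p <- 0.5
    draws <- vapply(1:200, function(s) {
        cfgS <- synthConfig(nGenes = 40L, nConditions = 4L, nTerms = 2L,
            termSizeRange = c(12L, 12L), annotationCoverage = 0.6,
            nModules = 2L, withinModuleEdgeProb = p, backgroundEdgeProb = 0,
            nImplanted = 0L, implantSizeRange = c(5L, 5L),
            implantConditionsRange = c(2L, 3L), seed = s)
        nrow(edges(synthPPI(cfgS))) / 2   # two modules
    }, numeric(1))
    nPairs <- choose(m, 2)
    se <- sqrt(nPairs * p * (1 - p) / 200)
    expect_lt(abs(mean(draws) - nPairs * p), 3 * se)
})

test_that("implanted expression blocks carry the configured shift", {
    cfg <- smallCfg(signalShift = 5, noiseSd = 1)
    sim <- synthExpressionWithBiclusters(cfg)
    expect_identical(dim(sim$expression), c(200L, 10L))
    expect_identical(sim$expression,
        synthExpressionWithBiclusters(smallCfg(signalShift = 5, noiseSd = 1))$expression)
    for (id in names(sim$truth)) {
        b <- sim$truth[[id]]
        block <- sim$expression[genes(b), conditions(b)]
        se <- 1 / sqrt(length(block))
        expect_lt(abs(mean(block) - 5), 3 * se)
    }
    # null case: no shift leaves the block at noise level
    cfg0 <- smallCfg(signalShift = 0, noiseSd = 1)
    sim0 <- synthExpressionWithBiclusters(cfg0)
    b0 <- sim0$truth[[1]]
    block0 <- sim0$expression[genes(b0), conditions(b0)]
    expect_lt(abs(mean(block0)), 3 / sqrt(length(block0)))
    # truth biclusters come from single annotation terms
    ann <- synthAnnotations(cfg)
    for (id in names(sim$truth))
        expect_identical(
            length(unique(unlist(lapply(genes(sim$truth[[id]]),
                geneTerms, x = ann)))), 1L)
})

test_that("random gene groups are seeded, size-matched and distinct", {
    genesU <- paste0("g", 1:1000)
    condsU <- paste0("c", 1:20)
    ref <- BiclusterSet(list(
        Bicluster("r1", "ISA", paste0("g", 1:5), paste0("c", 1:2)),
        Bicluster("r2", "ISA", paste0("g", 1:9), paste0("c", 1:4))))
    g1 <- randomGeneGroups(genesU, condsU, k = 15, reference = ref, seed = 3)
    g2 <- randomGeneGroups(genesU, condsU, k = 15, reference = ref, seed = 3)
    expect_identical(g1, g2)
    expect_length(g1, 15)
    expect_true(all(vapply(seq_len(15), function(i)
        algorithm(g1[[i]]) == "random", logical(1))))
    sizes <- as(g1, "data.frame")
    expect_true(all(sizes$n_genes %in% c(5L, 9L)))
    expect_true(all(sizes$n_conditions %in% c(2L, 4L)))

    # fixed-size sampler contract
    one <- randomGeneGroups(genesU, condsU, k = 1,
        sizeSampler = function(i) c(5L, 2L), seed = 1)
    expect_identical(length(genes(one[[1]])), 5L)
    expect_identical(length(conditions(one[[1]])), 2L)

    # different seeds give different gene sets (collision vanishingly rare)
    differ <- vapply(1:100, function(s) {
        a <- randomGeneGroups(genesU, condsU, 1,
            sizeSampler = function(i) c(10L, 3L), seed = s)
        b <- randomGeneGroups(genesU, condsU, 1,
            sizeSampler = function(i) c(10L, 3L), seed = s + 1000)
        !setequal(genes(a[[1]]), genes(b[[1]]))
    }, logical(1))
    expect_true(all(differ))

    expect_error(randomGeneGroups(genesU[1:5], condsU, 1,
        sizeSampler = function(i) c(10L, 2L), seed = 1), "exceeds")
    expect_error(randomGeneGroups(genesU, condsU, 2, seed = 1),
        "reference")
})

test_that("generators leave the caller's RNG state untouched", {
    set.seed(555)
    before <- .Random.seed
    invisible(synthAnnotations(smallCfg()))
    invisible(randomGeneGroups(paste0("g", 1:50), paste0("c", 1:5), 2,
        sizeSampler = function(i) c(5L, 2L), seed = 8))
    expect_identical(.Random.seed, before)
})
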