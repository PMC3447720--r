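#' Coherence-separation study on synthetic replicates
#'
#' Benchmarks the two quality scores against a size-matched random baseline,
#' the desk-scale analogue of validating biclustering output against random
#' gene groups. Each replicate builds a fresh synthetic world (annotation
#' map, modular interaction network, implanted coherent truth biclusters),
#' draws size-matched random gene groups, scores every group with both
#' scores, ranks truth and random groups jointly, and records:
#' the median weighted-enrichment and interaction scores of the truth
#' biclusters and of the random groups, and the fraction of truth biclusters
#' landing in the top half of each unified ranking.
#'
#' With coherent implants the truth medians should exceed the random medians
#' in essentially every replicate and the truth biclusters should concentrate
#' in the upper rank sections.
#'
#' @param nReplicates number of independently seeded replicates.
#' @param baseSeed integer; replicate r uses seed `baseSeed + r`.
#' @param nRandom random groups per replicate.
#' @param cfgFactory `function(seed)` returning a [synthConfig()]; defaults
#'   to the standard study conditions.
#' @return data.frame with one row per replicate: `seed`, `medianWeTruth`,
#'   `medianWeRandom`, `medianPpiTruth`, `medianPpiRandom`,
#'   `topHalfWe`, `topHalfPpi` (fractions of truth biclusters in the top half
#'   of the WE / PPI rankings) and `tau` (Kendall tau-b between the paired
#'   scores of that replicate).
#' @export
separationStudy <- function(nReplicates = 100L, baseSeed = 0L, nRandom = 15L,
                            cfgFactory = function(seed) synthConfig(seed = seed)) {
    rows <- lapply(seq_len(nReplicates), function(r) {
        cfg <- cfgFactory(baseSeed + r)
        ann <- synthAnnotations(cfg)
        net <- synthPPI(cfg)
        sim <- synthExpressionWithBiclusters(cfg)
        rand <- randomGeneGroups(universe(ann), .condIds(cfg$nConditions),
            k = nRandom, reference = sim$truth, seed = cfg$seed + 3L)
        pool <- BiclusterSet(c(sim$truth@biclusters, rand@biclusters))
        sc <- scoreBiclusters(pool, ann, net)
        isTruth <- sc$algorithm == "truth"
        topHalf <- function(col) {
            rk <- combinedRanking(data.frame(
                bicluster_id = sc$bicluster_id, algorithm = sc$algorithm,
                score = sc[[col]], stringsAsFactors = FALSE), nSections = 2)
            mean(rk$section[rk$algorithm == "truth"] == 1)
        }
        data.frame(seed = cfg$seed,
            medianWeTruth = stats::median(sc$we_score[isTruth]),
            medianWeRandom = stats::median(sc$we_score[!isTruth]),
            medianPpiTruth = stats::median(sc$ppi_score[isTruth]),
            medianPpiRandom = stats::median(sc$ppi_score[!isTruth]),
            topHalfWe = topHalf("we_score"),
            topHalfPpi = topHalf("ppi_score"),
            tau = kendallTau(sc$we_score, sc$ppi_score)$tau)
    })
    .rbindRows(rows)
}
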