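test_that("combined ranking sorts descending with mean-rank ties", {
    sc <- data.frame(bicluster_id = c("a", "b", "c"),
        algorithm = "ISA", score = c(3, 1, 2))
    r <- combinedRanking(sc, nSections = 2)
    expect_identical(r$bicluster_id, c("a", "c", "b"))
    expect_identical(r$rank, c(1, 2, 3))

    tied <- data.frame(bicluster_id = c("a", "b", "c", "d"),
        algorithm = "X", score = c(5, 2, 2, 1))
    rt <- combinedRanking(tied, nSections = 2)
    expect_identical(rt$rank, c(1, 2.5, 2.5, 4))

    # quartile partition: 8 entries in 4 sections of 2
    e8 <- data.frame(bicluster_id = letters[1:8], algorithm = "X", score = 8:1)
    r8 <- combinedRanking(e8, nSections = 4)
    expect_identical(r8$section, rep(1:4, each = 2))

    # uneven split: sizes differ by at most one
    e10 <- data.frame(bicluster_id = letters[1:10], algorithm = "X",
        score = 10:1)
    r10 <- combinedRanking(e10, nSections = 4)
    expect_identical(as.integer(table(r10$section)), c(3L, 3L, 2L, 2L))

    empty <- combinedRanking(e8[0, ], nSections = 4)
    expect_identical(nrow(empty), 0L)
})

test_that("ranking is invariant under input permutation", {
    set.seed(13)
    sc <- data.frame(bicluster_id = paste0("b", 1:30),
        algorithm = sample(c("A", "B", "C"), 30, TRUE),
        score = round(runif(30), 2))
    r1 <- combinedRanking(sc, 4)
    r2 <- combinedRanking(sc[sample(30), ], 4)
    rownames(r2) <- NULL
    expect_identical(r1, r2)
})

test_that("rank distribution satisfies both marginal conservation laws", {
    # single algorithm: rows split evenly across sections
    e8 <- data.frame(bicluster_id = letters[1:8], algorithm = "X", score = 8:1)
    d <- rankDistribution(combinedRanking(e8, 4))
    expect_identical(unname(d["X", ]), c(2L, 2L, 2L, 2L))

    # one algorithm strictly dominating the other lands in section 1
    dom <- data.frame(bicluster_id = paste0("b", 1:12),
        algorithm = rep(c("GOOD", "BAD"), each = 6),
        score = c(7:12, 1:6))
    d2 <- rankDistribution(combinedRanking(dom, 2))
    expect_identical(unname(d2["GOOD", ]), c(6L, 0L))
    expect_identical(unname(d2["BAD", ]), c(0L, 6L))

    set.seed(17)
    sc <- data.frame(bicluster_id = paste0("b", 1:37),
        algorithm = sample(c("A", "B", "C"), 37, TRUE),
        score = runif(37))
    rk <- combinedRanking(sc, 4)
    d3 <- rankDistribution(rk)
    expect_identical(sum(d3), 37L)
    expect_identical(as.integer(rowSums(d3)),
        as.integer(table(sc$algorithm)[rownames(d3)]))
    expect_identical(as.integer(colSums(d3)),
        as.integer(table(rk$section)))
})

test_that("Kendall tau reproduces pinned pair-counting cases", {
    expect_equal(kendallTau(1:4, 1:4)$tau, 1)
    expect_equal(kendallTau(1:4, 4:1)$tau, -1)
    # concordant - discordant = 8 - 2 = 6 over C(5,2) = 10
    expect_equal(kendallTau(1:5, c(2, 1, 4, 3, 5))$tau, 0.6)
    expect_error(kendallTau(1:3, 1:4), "equal length")
    expect_error(kendallTau(1, 1), "at least 2")
})

test_that("Kendall tau is symmetric, rank-invariant and matches brute force", {
    set.seed(23)
    for (i in 1:80) {
        n <- sample(5:50, 1)
        x <- sample(0:6, n, TRUE)   # heavy ties, like scores with many zeros
        y <- sample(0:6, n, TRUE)
        r <- kendallTau(x, y)
        expect_equal(r$tau, oracleTauB(x, y), tolerance = 1e-12)
        expect_equal(kendallTau(y, x)$tau, r$tau)
        # monotone transform of both lists leaves tau unchanged
        expect_equal(kendallTau(exp(x), y^3 + 2)$tau, r$tau)
        expect_gte(r$tau, -1); expect_lte(r$tau, 1)
        expect_gt(r$pValue, 0); expect_lte(r$pValue, 1)
    }
})
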