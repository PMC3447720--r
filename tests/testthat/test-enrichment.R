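test_that("hypergeometric tail matches enumeration on pinned cases", {
    expect_identical(hypergeomPValue(0, X = 5, PN = 10, N = 100), 1)
    expect_identical(hypergeomPValue(3, X = 3, PN = 20, N = 20), 1)
    # enumerated: [C(10,4)C(40,1) + C(10,5)C(40,0)] / C(50,5) = 8652/2118760
    expect_equal(hypergeomPValue(4, X = 5, PN = 10, N = 50), 8652 / 2118760)
    expect_error(hypergeomPValue(6, X = 5, PN = 10, N = 50), "x must")
    expect_error(hypergeomPValue(1, X = 5, PN = 60, N = 50), "universe")
})

test_that("hypergeometric tail equals brute-force enumeration for N <= 14", {
    for (N in c(3, 7, 10, 14)) {
        for (PN in 0:N) {
            for (X in 0:N) {
                x <- 0:min(X, PN)
                got <- hypergeomPValue(x, X = X, PN = PN, N = N)
                want <- vapply(x, function(xx)
                    oracleHyperTail(xx, X, PN, N), numeric(1))
                expect_equal(got, want, tolerance = 1e-12)
                # non-increasing in x
                expect_true(all(diff(got) <= 1e-12))
            }
        }
    }
})

test_that("hypergeometric tail is stable deep below 1e-12", {
    p <- hypergeomPValue(50, X = 50, PN = 50, N = 5000)
    expect_gt(p, 0)
    expect_lt(p, 1e-80)
    expect_equal(log(p), lchoose(4950, 0) + lchoose(50, 50) - lchoose(5000, 50))
})

test_that("BH adjustment matches the hand-computed and oracle step-up", {
    expect_identical(bhFDR(0.01), 0.01)
    expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFDR(rep(0.2, 5)), rep(0.2, 5))
    expect_error(bhFDR(c(0.1, 1.2)), "\\[0,1\\]")

    set.seed(101)
    for (i in 1:60) {
        p <- runif(sample(1:40, 1))
        q <- bhFDR(p)
        expect_equal(q, oracleStepUp(p), tolerance = 1e-12)
        expect_true(all(q >= p - 1e-15))
        expect_true(all(q <= 1))
    }
})

test_that("term score is -log10 with a configurable base", {
    expect_identical(termScore(1), 0)
    expect_equal(termScore(0.001), 3)
    expect_equal(termScore(0.05), 1.3010, tolerance = 1e-4)
    expect_equal(termScore(exp(-2), logBase = exp(1)), 2)
    expect_error(termScore(0), "\\(0, 1\\]")
})

test_that("bicluster enrichment finds a planted coherent term", {
    ann <- toyAnnotation()
    b <- Bicluster("b1", "ISA", sprintf("g%03d", 1:5), "c1")  # 5 genes of T1
    tt <- enrichBicluster(b, ann)
    expect_identical(tt$term, "T1")
    expect_identical(tt$x, 5L)
    expect_identical(tt$PN, 10L)
    # closed form: all 5 draws from the 10 T1 genes out of 100
    expect_equal(tt$p, oracleHyperTail(5, 5, 10, 100))
    expect_equal(tt$s, -log10(tt$q))
})

test_that("terms covering the whole universe are tested but never enriched", {
    g <- paste0("g", 1:30)
    ann <- AnnotationMap(rep(g, 2), rep(c("ALL", "ALSO_ALL"), each = 30))
    b <- Bicluster("b", "X", g[1:6], "c1")
    tt <- enrichBicluster(b, ann)
    expect_identical(nrow(tt), 0L)
})

test_that("enrichment is invariant under consistent gene relabelling", {
    ann <- toyAnnotation()
    b <- Bicluster("b", "X", sprintf("g%03d", c(1:4, 40)), "c1")
    perm <- setNames(sprintf("z%03d", sample(100)), sprintf("g%03d", 1:100))
    ann2 <- AnnotationMap(
        gene = perm[rep(annotatedGenes(ann), lengths(ann@geneToTerms))],
        term = unlist(ann@geneToTerms, use.names = FALSE),
        universe = perm[universe(ann)])
    b2 <- Bicluster("b", "X", perm[genes(b)], "c1")
    t1 <- enrichBicluster(b, ann)
    t2 <- enrichBicluster(b2, ann2)
    expect_identical(t1[c("term", "x", "PN", "p", "q", "s")],
        t2[c("term", "x", "PN", "p", "q", "s")])
})

test_that("a bicluster with no annotated gene warns and returns empty", {
    ann <- toyAnnotation()
    b <- Bicluster("b", "X", c("nope1", "nope2"), "c1")
    expect_warning(tt <- enrichBicluster(b, ann), "no gene")
    expect_identical(nrow(tt), 0L)
    expect_true(attr(tt, "noAnnotation"))
    expect_identical(computeNon(b, ann, tt), 0L)
})

test_that("non counts annotated-but-unenriched genes only", {
    # 3 T1 genes + 1 lone T2 gene + 2 unannotated; only T1 gets enriched
    ann2 <- AnnotationMap(
        gene = c(sprintf("g%03d", 1:10), sprintf("g%03d", 11:15)),
        term = rep(c("T1", "T2"), c(10, 5)),
        universe = c(sprintf("g%03d", 1:100), "u1", "u2"))
    b <- Bicluster("b", "X",
        c(sprintf("g%03d", 1:3), "g011", "u1", "u2"), "c1")
    tt <- enrichBicluster(b, ann2)
    expect_identical(tt$term, "T1")
    expect_identical(computeNon(b, ann2, tt), 1L)          # the lone T2 gene
    expect_identical(computeNon(b, ann2, tt[0, ]), 4L)     # nothing enriched
})

test_that("WE aggregation follows the weighted-mean formula", {
    t1 <- data.frame(term = "A", x = 10L, PN = 20L, p = 1e-4, q = 1e-4, s = 4)
    expect_equal(weScore(t1, non = 0)$weScore, 4)
    t2 <- data.frame(term = c("A", "B"), x = c(3L, 2L), PN = c(9L, 9L),
        p = c(1e-5, 1e-2), q = c(1e-5, 1e-2), s = c(5, 2))
    expect_equal(weScore(t2, non = 5)$weScore, 1.9)   # (15+4)/(3+2+5)
    r0 <- weScore(t2[0, ], non = 7)
    expect_identical(r0$weScore, 0)
    expect_true(r0$noEnrichment)
    expect_error(weScore(t2, non = -1), "non-negative")
})

test_that("WE score ignores unannotated genes and respects its bounds", {
    ann <- toyAnnotation()
    base <- sprintf("g%03d", c(1:6, 12:13))
    b1 <- Bicluster("b", "X", base, "c1")
    b2 <- Bicluster("b", "X", c(base, paste0("g0", 51:80)), "c1")  # +unannotated
    r1 <- scoreWE(b1, ann)
    r2 <- scoreWE(b2, ann)
    expect_identical(r1$weScore, r2$weScore)
    expect_identical(r1$non, r2$non)

    # bounds: 0 <= WE <= max term score
    set.seed(5)
    for (i in 1:25) {
        b <- Bicluster("b", "X",
            sample(universe(ann), sample(5:25, 1)), "c1")
        r <- suppressWarnings(scoreWE(b, ann))
        expect_gte(r$weScore, 0)
        if (r$n > 0) expect_lte(r$weScore, max(r$terms$s) + 1e-12)
    }
})

test_that("WE equals the single term score when it covers every annotated gene", {
    ann <- toyAnnotation()
    b <- Bicluster("b", "X", c(sprintf("g%03d", 1:7), "zz1", "zz2"), "c1")
    r <- scoreWE(b, AnnotationMap(
        gene = sprintf("g%03d", 1:10), term = rep("T1", 10),
        universe = c(sprintf("g%03d", 1:100), "zz1", "zz2")))
    expect_identical(r$n, 1L)
    expect_identical(r$non, 0L)
    expect_equal(r$weScore, r$terms$s[1])
})

test_that("raw-p scoring mode scores the unadjusted p-value", {
    ann <- toyAnnotation()
    b <- Bicluster("b", "X", sprintf("g%03d", c(1:5, 11:12)), "c1")
    adj <- enrichBicluster(b, ann, scoreOn = "adjusted")
    raw <- enrichBicluster(b, ann, scoreOn = "raw")
    expect_identical(adj$term, raw$term)
    expect_equal(raw$s, -log10(raw$p))
    expect_true(all(adj$s <= raw$s + 1e-12))  # q >= p so -log10 q <= -log10 p
})
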