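test_that("vertex temperatures follow d/(n - d) and stay in range", {
    benzene <- cycleGraph(6)
    expect_equal(vertexTemperature(benzene, "v3"), 1 / 2)
    expect_equal(vertexTemperature(benzene, "v3", rational = TRUE),
                 c(num = 1L, den = 2L))

    p3 <- pathGraph(3)
    expect_equal(vertexTemperature(p3, "v2"), 2)   # centre: 2/(3-2), > 1
    expect_equal(vertexTemperature(p3, "v1"), 1 / 2)

    k2 <- pathGraph(2)
    expect_equal(vertexTemperature(k2, "v1"), 1)   # smallest admissible graph

    expect_error(vertexTemperature(benzene, "nope"), "unknown vertex")
})

test_that("graph invariants are enforced at construction", {
    expect_error(molecularGraph(rbind(c("a", "a"))), "self-loops")
    expect_error(molecularGraph(rbind(c("a", "b"), c("b", "a"))),
                 "duplicate edges")
    expect_error(molecularGraph(rbind(c("a", "b"), c("c", "d"))),
                 "connected")
})

test_that("temperature positivity and the T < 1 criterion hold on fixtures", {
    for (g in fixtureGraphs(7L, count = 15L)) {
        n <- numVertices(g)
        d <- vertexDegrees(g)
        temps <- vapply(vertexLabels(g),
                        function(v) vertexTemperature(g, v), 1)
        expect_true(all(temps > 0))
        expect_equal(unname(temps < 1), unname(2 * d < n))
    }
})

test_that("edge classes partition the edge set by temperature pair", {
    benzene <- temperatureEdgeClasses(cycleGraph(6))
    cl <- edgeClasses(benzene)
    expect_equal(nrow(cl), 1L)
    expect_equal(cl$count, 6L)
    expect_equal(cl$tu, 1 / 2)
    expect_equal(cl$tv, 1 / 2)

    k2 <- edgeClasses(temperatureEdgeClasses(pathGraph(2)))
    expect_equal(k2[, c("tu", "tv", "count")],
                 data.frame(tu = 1, tv = 1, count = 1L))

    cnc <- edgeClasses(temperatureEdgeClasses(buildNanocone(3, 1)))
    expect_equal(cnc$tu, c(1/5, 1/5, 1/3))
    expect_equal(cnc$tv, c(1/5, 1/3, 1/3))
    expect_equal(cnc$count, c(3L, 6L, 6L))

    # counts always sum to the edge count
    for (g in fixtureGraphs(11L, count = 12L))
        expect_equal(sum(edgeClasses(temperatureEdgeClasses(g))$count),
                     numEdges(g))
})

test_that("psi maps match hand evaluation and are symmetric", {
    expect_equal(psiValue(indexSpec("HT1"), 1/5, 1/3), (8/15)^2)
    expect_equal(psiValue(indexSpec("GAT"), 0.37, 0.37), 1)
    expect_equal(psiValue(indexSpec("ABCT"), 1/3, 1/3), sqrt(12))

    set.seed(99)
    pairs <- matrix(stats::runif(40, 0.05, 3), ncol = 2L)
    specs <- c(lapply(indexFamilies()[1:13], indexSpec),
               lapply(c("T1_GENERAL", "T2_GENERAL", "F_GENERAL"),
                      indexSpec, sigma = -0.7))
    for (spec in specs) {
        for (i in seq_len(nrow(pairs))) {
            a <- pairs[i, 1L]; b <- pairs[i, 2L]
            if (spec@family == "RRPT" && (a - 1) * (b - 1) < 0) next
            expect_identical(psiValue(spec, a, b), psiValue(spec, b, a))
        }
    }
})

test_that("psi domain errors are raised, not silently absorbed", {
    expect_error(psiValue(indexSpec("FT"), -1, 2), "positive")
    expect_error(psiValue(indexSpec("RRPT"), 1/2, 2), "mixed-sign")
    # same-side pairs are fine on either side of 1
    expect_equal(psiValue(indexSpec("RRPT"), 2, 3), sqrt(2))
    expect_equal(psiValue(indexSpec("RRPT"), 1/2, 1/3), sqrt(1/3))
})

test_that("index specs validate family and sigma", {
    expect_error(indexSpec("NOPE"), "unknown index family")
    expect_error(indexSpec("F_GENERAL"), "require a finite sigma")
    expect_error(indexSpec("FT", sigma = 2), "must not carry")
    # sigma = 0 is a legal degenerate case of the parametric families
    g <- cycleGraph(5)
    expect_equal(evaluateIndex(g, indexSpec("F_GENERAL", 0)),
                 2 * numEdges(g))
    expect_equal(evaluateIndex(g, indexSpec("T1_GENERAL", 0)), numEdges(g))
})

test_that("grouped evaluation agrees with the per-edge oracle", {
    specs <- c(lapply(setdiff(names(oraclePsi), "RRPT"), indexSpec),
               lapply(c("T1_GENERAL", "T2_GENERAL", "F_GENERAL"),
                      indexSpec, sigma = 1.3))
    for (g in fixtureGraphs(5L, count = 12L)) {
        classes <- temperatureEdgeClasses(g)
        for (spec in specs) {
            psi <- if (spec@family %in% names(oraclePsi))
                oraclePsi[[spec@family]]
            else oraclePsiGeneral(spec@family, spec@sigma)
            expected <- oracleIndex(edgeMatrix(g), psi)
            expect_equal(evaluateIndex(classes, spec), expected,
                         tolerance = 1e-12)
            expect_equal(evaluateIndex(g, spec), expected,
                         tolerance = 1e-12)
        }
    }
})

test_that("FT of benzene is 3 and the named/parametric identities hold", {
    expect_equal(evaluateIndex(cycleGraph(6), indexSpec("FT")), 3)

    idPairs <- list(c("HT1", "T1_GENERAL", 2), c("ST", "T1_GENERAL", -0.5),
                    c("HT2", "T2_GENERAL", 2), c("PT", "T2_GENERAL", -0.5),
                    c("RPT", "T2_GENERAL", 0.5), c("FT", "F_GENERAL", 2))
    for (g in fixtureGraphs(3L, count = 10L)) {
        for (p in idPairs) {
            named <- evaluateIndex(g, indexSpec(p[[1L]]))
            general <- evaluateIndex(
                g, indexSpec(p[[2L]], as.numeric(p[[3L]])))
            expect_identical(named, general)
        }
    }
})

test_that("GAT <= m <= AGT with equality iff all pairs are equal", {
    for (g in fixtureGraphs(13L, count = 15L)) {
        m <- numEdges(g)
        gat <- evaluateIndex(g, indexSpec("GAT"))
        agt <- evaluateIndex(g, indexSpec("AGT"))
        expect_lte(gat, m + 1e-12)
        expect_gte(agt, m - 1e-12)
        cl <- edgeClasses(temperatureEdgeClasses(g))
        allEqual <- all(cl$tu == cl$tv)
        expect_equal(isTRUE(all.equal(gat, agt)), allEqual)
    }
})
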