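test_that("within-sample ecoparalog folds use cluster extremes", {
    m <- matrix(c(100, 300, 100, 120, 50, 50), 6, 1,
                dimnames = list(sprintf("g%01d", 1:6), "s"))
    x <- tpmExperiment(m)
    cl <- ParalogClusters(list(c1 = c("g1", "g2"), c2 = c("g3", "g4"),
                               c3 = c("g5", "g6")))
    eco <- withinSampleEcoparalogs(x, cl, "s")
    expect_equal(eco$fold, c(301 / 101, 121 / 101, 1), tolerance = 1e-12)
    expect_equal(eco$is_ecoparalog, c(TRUE, FALSE, FALSE))
    expect_equal(eco$max_gene, c("g2", "g4", "g5"))
    expect_equal(eco$min_gene, c("g1", "g3", "g6"))

    # strictly-greater rule at the boundary
    mb <- matrix(c(199, 299), 2, 1, dimnames = list(c("g1", "g2"), "s"))
    eb <- withinSampleEcoparalogs(tpmExperiment(mb),
        ParalogClusters(list(c1 = c("g1", "g2"))), "s")
    expect_equal(eb$fold, 1.5)
    expect_false(eb$is_ecoparalog)  # > 1.5 required, not >=

    # calls are non-increasing in the threshold
    n1 <- sum(withinSampleEcoparalogs(x, cl, "s", threshold = 1.2)$is_ecoparalog)
    n2 <- sum(withinSampleEcoparalogs(x, cl, "s", threshold = 2)$is_ecoparalog)
    expect_gte(n1, n2)
})

test_that("cluster folds are invariant to relabeling and count rescaling", {
    set.seed(31)
    n <- 30
    cts <- matrix(rpois(2 * n, 60) + 1, n, 2,
                  dimnames = list(sprintf("g%03d", seq_len(n)),
                                  c("a", "b")))
    x1 <- computeTPM(countExperiment(cts))
    cts2 <- cts; cts2[, "a"] <- cts2[, "a"] * 5
    x2 <- computeTPM(countExperiment(cts2))
    cl <- ParalogClusters(list(c1 = c("g001", "g002", "g003"),
                               c2 = c("g010", "g011")))
    clRev <- ParalogClusters(list(c1 = c("g003", "g001", "g002"),
                                  c2 = c("g011", "g010")))
    e1 <- withinSampleEcoparalogs(x1, cl, "a")
    expect_equal(withinSampleEcoparalogs(x1, clRev, "a")$fold, e1$fold)
    expect_equal(withinSampleEcoparalogs(x2, cl, "a")$fold, e1$fold,
                 tolerance = 1e-9)
})

test_that("extreme folds agree with all-pairs enumeration", {
    set.seed(37)
    for (i in 1:10) {
        k <- sample(2:6, 1)
        tp <- round(rexp(k, 1 / 300), 2)
        ids <- sprintf("g%01d", seq_len(k))
        m <- matrix(tp, k, 1, dimnames = list(ids, "s"))
        eco <- withinSampleEcoparalogs(tpmExperiment(m),
            ParalogClusters(list(c1 = ids)), "s")
        expect_equal(eco$fold, bruteMaxPairFold(tp), tolerance = 1e-12)
    }
})

test_that("seasonal ecoparalogs are cluster members passing the DE rule", {
    th <- deriveThresholds(2625)
    m <- matrix(c(300, 40, 100, 200, 40, 100), 3, 2,
                dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
    x <- tpmExperiment(m)
    cl <- ParalogClusters(list(c1 = c("g1", "g2")))
    # the raw-ratio reading of the boundary rule: 300 vs 200 is 1.5-fold
    se0 <- seasonalEcoparalogs(x, cl, "a", "b", th, pseudo = 0)
    expect_equal(se0$gene_id, "g1")
    expect_equal(se0$fold, 1.5)
    expect_equal(se0$direction, "higher_a")
    # all members similar across seasons -> empty
    flat <- matrix(c(300, 40, 300, 40), 2, 2,
                   dimnames = list(c("g1", "g2"), c("a", "b")))
    expect_equal(nrow(seasonalEcoparalogs(tpmExperiment(flat),
        ParalogClusters(list(c1 = c("g1", "g2"))), "a", "b", th)), 0L)
})

test_that("planted seasonal ecoparalogs are recovered at depth", {
    cfg <- simulationConfig(nGenes = 600, librarySize = c(5e6, 5e6),
        nDE = 3, deSplit = c(3, 0), deFoldRange = c(2, 2),
        hotspotGenes = 0, islandSizes = integer(),
        islandMultipliers = numeric(), nClusters = 12, clusterGenes = 30,
        clusterFoldRange = c(1, 1), includeCulture = FALSE,
        seasonalEcoparalogFolds = c(1.8, 2.0, 2.2), seed = 23)
    sim <- simulateExperiment(cfg)
    x <- computeTPM(sim$experiment)
    se <- seasonalEcoparalogs(x, sim$clusters, "summer", "winter",
                              deriveThresholds(nrow(x)))
    expect_setequal(se$gene_id,
                    sim$truth@seasonalEcoparalogGenes)
    expect_true(all(se$direction == "higher_a"))
})

test_that("cross-season extremes pick the stronger orientation", {
    m <- matrix(c(500, 100, 50, 200), 2, 2,
                dimnames = list(c("g1", "g2"), c("summer", "winter")))
    x <- tpmExperiment(m)
    cl <- ParalogClusters(list(c1 = c("g1", "g2")))
    cs <- crossSeasonExtremes(x, cl, "summer", "winter")
    expect_equal(cs$ratio, 501 / 51, tolerance = 1e-12)
    expect_equal(cs$season_of_max, "summer")
    expect_equal(cs$max_gene, "g1")
    expect_equal(cs$min_gene, "g1")

    # all four TPM equal -> both orientations are 1
    mEq <- matrix(100, 2, 2, dimnames = dimnames(m))
    expect_equal(crossSeasonExtremes(tpmExperiment(mEq), cl,
                                     "summer", "winter")$ratio, 1)

    # zero in the other season stays finite through the pseudocount
    m0 <- matrix(c(400, 100, 0, 0), 2, 2, dimnames = dimnames(m))
    expect_equal(crossSeasonExtremes(tpmExperiment(m0), cl,
                                     "summer", "winter")$ratio, 401)
})

test_that("cross-season ratio dominates the within-sample fold when one gene holds both extremes", {
    set.seed(41)
    for (i in 1:10) {
        k <- sample(2:5, 1)
        ids <- sprintf("g%01d", seq_len(k))
        m <- matrix(round(rexp(2 * k, 1 / 250), 1), k, 2,
                    dimnames = list(ids, c("a", "b")))
        x <- tpmExperiment(m)
        cl <- ParalogClusters(list(c1 = ids))
        cs <- crossSeasonExtremes(x, cl, "a", "b")
        s <- cs$season_of_max
        w <- withinSampleEcoparalogs(x, cl, s)
        if (w$max_gene == cs$max_gene && w$min_gene == cs$min_gene) {
            # brute-force check of the dominance property
            other <- setdiff(c("a", "b"), s)
            minOther <- min(m[, other])
            minSame <- min(m[, s])
            if (minOther <= minSame) expect_gte(cs$ratio, w$fold)
        }
    }
})
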