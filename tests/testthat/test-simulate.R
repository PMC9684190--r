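smallCfg <- function(seed = 1, librarySize = c(3e5, 3e5), ...) {
    simulationConfig(nGenes = 300, librarySize = librarySize,
        nDE = 20, deSplit = c(8, 12), hotspotGenes = 15,
        islandSizes = rep(6L, 2), islandMultipliers = c(0.5, 0.4),
        nClusters = 8, clusterGenes = 20, cultureHighN = 15,
        seed = seed, ...)
}

test_that("simulation is reproducible from the seed", {
    s1 <- simulateExperiment(smallCfg())
    s2 <- simulateExperiment(smallCfg())
    expect_identical(counts(s1$experiment), counts(s2$experiment))
    expect_identical(s1$truth@deGenes$gene_id, s2$truth@deGenes$gene_id)
    s3 <- simulateExperiment(smallCfg(seed = 2))
    expect_false(identical(counts(s1$experiment), counts(s3$experiment)))
})

test_that("counts respect the library size exactly", {
    sim <- simulateExperiment(smallCfg())
    expect_equal(unname(colSums(counts(sim$experiment))[c("summer", "winter")]),
                 c(3e5, 3e5))
})

test_that("infeasible configurations fail before sampling", {
    expect_error(simulationConfig(nGenes = 100, nDE = 150,
        deSplit = c(50, 100), hotspotGenes = 0, islandSizes = integer(),
        islandMultipliers = numeric(), nClusters = 0, clusterGenes = 0),
        "exceeds")
    expect_error(simulationConfig(nGenes = 100, deSplit = c(10, 10)),
        "sum to nDE")
    expect_error(simulationConfig(islandMultipliers = rep(1.2, 4)),
        "island multipliers")
})

test_that("planted structure lands where the truth says", {
    sim <- simulateExperiment(smallCfg())
    x <- computeTPM(sim$experiment)
    # islands sit below the genome average in both seasons
    isl <- islandExpression(x, sim$islands, "summer", "winter")
    expect_true(all(isl$ratio_vs_genome < 1))
    # planted island members lie inside the emitted island span
    ann <- sim$annotation
    m1 <- sim$truth@islandMembers[[1]]
    expect_true(all(GenomicRanges::start(ann[m1]) >=
                        GenomicRanges::start(sim$islands[1]) &
                    GenomicRanges::end(ann[m1]) <=
                        GenomicRanges::end(sim$islands[1])))
    # cluster layout matches the configuration
    sizes <- lengths(clusterMembers(sim$clusters))
    expect_equal(sum(sizes), 20L)
    expect_true(all(sizes >= 2L))
    # hotspot genes are contiguous on the chromosome
    hsIdx <- match(sim$truth@hotspotGenes, names(x))
    expect_equal(hsIdx, seq(min(hsIdx), max(hsIdx)))
})

test_that("a null simulation classifies almost everything as similar", {
    cfg <- simulationConfig(nGenes = 2625, librarySize = c(1e7, 1e7),
        nDE = 0, deSplit = c(0, 0), hotspotGenes = 0,
        islandSizes = integer(), islandMultipliers = numeric(),
        nClusters = 0, clusterGenes = 0, includeCulture = FALSE,
        seasonalEcoparalogFolds = numeric(), seed = 8)
    sim <- simulateExperiment(cfg)
    x <- computeTPM(sim$experiment)
    tl <- callTallies(classifyAll(x, "summer", "winter"))
    expect_gt(tl[["n_similar"]] / 2625, 0.95)
})

test_that("recovery scoring handles the trivial cases", {
    sim <- simulateExperiment(smallCfg(librarySize = c(2e6, 2e6),
                                       deFoldRange = c(2.5, 3)))
    x <- computeTPM(sim$experiment)
    calls <- classifyAll(x, "summer", "winter")
    rec <- evaluateRecovery(sim$truth, calls)
    expect_true(rec$de_recall >= 0 && rec$de_recall <= 1)

    # perfect calls give precision = recall = 1; empty calls recall 0 / NA
    cc <- callTable(calls)
    cc$significant <- cc$gene_id %in%
        c(sim$truth@deGenes$gene_id, sim$truth@hotspotGenes)
    cc$direction <- ifelse(cc$gene_id %in% sim$truth@deGenes$gene_id,
        ifelse(sim$truth@deGenes$direction[
            match(cc$gene_id, sim$truth@deGenes$gene_id)] == "summer",
            "higher_a", "higher_b"), cc$direction)
    perfect <- new("GeneCallSet", calls = cc,
                   samples = c("summer", "winter"),
                   thresholds = deriveThresholds(nrow(x)))
    recP <- evaluateRecovery(sim$truth, perfect)
    expect_equal(recP$de_recall, 1)
    expect_equal(recP$de_precision, 1)
    expect_equal(recP$de_direction_accuracy, 1)

    cc0 <- callTable(calls); cc0$significant <- FALSE
    none <- new("GeneCallSet", calls = cc0,
                samples = c("summer", "winter"),
                thresholds = deriveThresholds(nrow(x)))
    rec0 <- evaluateRecovery(sim$truth, none)
    expect_equal(rec0$de_recall, 0)
    expect_true(is.na(rec0$de_precision))
})

test_that("DE recovery improves with sequencing depth", {
    depths <- c(3e4, 3e5, 3e6)
    recalls <- vapply(depths, function(d) {
        mean(vapply(1:3, function(s) {
            cfg <- simulationConfig(nGenes = 400,
                librarySize = c(d, d), nDE = 30, deSplit = c(10, 20),
                hotspotGenes = 0, islandSizes = integer(),
                islandMultipliers = numeric(), nClusters = 0,
                clusterGenes = 0, includeCulture = FALSE,
                seasonalEcoparalogFolds = numeric(), seed = 100 + s)
            sim <- simulateExperiment(cfg)
            x <- computeTPM(sim$experiment)
            evaluateRecovery(sim$truth,
                classifyAll(x, "summer", "winter"))$de_recall
        }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(recalls) >= 0))
    expect_gt(recalls[3], recalls[1])
})

test_that("simulated files round-trip through the package readers", {
    sim <- simulateExperiment(smallCfg())
    dir <- withr::local_tempdir()
    paths <- writeSimulation(sim, dir)
    ann <- readGeneAnnotation(paths[["annotation_gff3"]],
        repliconOrder = c("chromosome", "plasmid"))
    expect_equal(names(ann), names(sim$annotation))
    se <- readCounts(paths[["counts"]], ann)
    expect_equal(counts(se), counts(sim$experiment))
    isl <- readIntervals(paths[["islands"]])
    expect_equal(GenomicRanges::start(isl),
                 GenomicRanges::start(sim$islands))
    cl <- readClusters(paths[["clusters"]], ann)
    expect_equal(clusterMembers(cl)[sort(names(clusterMembers(cl)))],
                 clusterMembers(sim$clusters)[
                     sort(names(clusterMembers(sim$clusters)))])
})
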