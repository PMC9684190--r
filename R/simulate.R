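#' Configuration for a synthetic metatranscriptome experiment
#'
#' The defaults reproduce the study conditions of the *Haloquadratum
#' walsbyi* saltern comparison: 2,625 protein-coding genes on a chromosome
#' (~90%) plus plasmid (~10%); two natural samples (summer, winter) whose
#' TPM distribution is bell-shaped around the genome average `10^6/N` on a
#' log scale; an optional culture sample with a low bulk (50-150 TPM) and
#' a small very-high tail (144 genes above 1,000 TPM); 195 planted
#' differentially expressed genes (55 summer-higher / 140 winter-higher,
#' folds 1.5-3.5 with 3.5 the strongest observed seasonal fold); one
#' 51-gene hotspot block at 1.86-fold (the strongest reported region);
#' four genomic islands with below-average expression; and 150 paralogous
#' genes in 63 clusters with within-sample fold divergence up to ~9 (8.8
#' was the strongest within-sample ecoparalog contrast). Library sizes
#' default to the mRNA read yields of the two metatranscriptomes
#' (~2.3M summer, ~3.6M winter).
#'
#' @param nGenes total gene count.
#' @param repliconNames,repliconFraction replicon names and gene-count
#'   fractions (must sum to 1).
#' @param geneLengthMeanLog,geneLengthSdLog log-normal law for gene length
#'   in bp.
#' @param sampleNames names of the two natural samples.
#' @param librarySize mapped mRNA reads per natural sample.
#' @param naturalSdLog log-sd of the natural expression-level law around
#'   `10^6/nGenes`.
#' @param includeCulture add a culture sample?
#' @param cultureName,cultureLibrarySize name and depth of the culture
#'   sample.
#' @param cultureBulkRange TPM-scale range of the culture bulk
#'   (log-uniform).
#' @param cultureHighN,cultureHighRange size and log-uniform range of the
#'   culture high tail.
#' @param nDE planted seasonally differential genes.
#' @param deSplit planted DE genes higher in sample 1 / sample 2 (sums to
#'   `nDE`).
#' @param deFoldRange uniform range of planted DE folds.
#' @param hotspotGenes,hotspotFold size and fold of the planted hotspot
#'   block (0 genes disables it); all but one block gene are higher in
#'   sample 2.
#' @param islandSizes,islandMultipliers genes per island and their
#'   expression multipliers (in (0,1): islands are expressed below the
#'   genome average).
#' @param nClusters,clusterGenes,clusterFoldRange paralog-cluster layout
#'   and the log-uniform law of planted within-sample divergence folds.
#' @param seasonalEcoparalogFolds seasonal folds (higher in sample 1)
#'   planted on one member of this many distinct clusters; they use part
#'   of the sample-1 DE quota.
#' @param seed RNG seed; the whole experiment is reproducible from it.
#' @return A `SimulationConfig`.
#' @export
simulationConfig <- function(
        nGenes = 2625,
        repliconNames = c("chromosome", "plasmid"),
        repliconFraction = c(0.9, 0.1),
        geneLengthMeanLog = log(900), geneLengthSdLog = 0.35,
        sampleNames = c("summer", "winter"),
        librarySize = c(2.3e6, 3.6e6),
        naturalSdLog = 0.35,
        includeCulture = TRUE,
        cultureName = "culture", cultureLibrarySize = 2.3e6,
        cultureBulkRange = c(50, 150),
        cultureHighN = 144, cultureHighRange = c(1000, 10000),
        nDE = 195, deSplit = c(55, 140), deFoldRange = c(1.5, 3.5),
        hotspotGenes = 51, hotspotFold = 1.86,
        islandSizes = rep(25L, 4),
        islandMultipliers = c(0.6, 0.5, 0.4, 0.3),
        nClusters = 63, clusterGenes = 150, clusterFoldRange = c(1, 9),
        seasonalEcoparalogFolds = c(1.5, 1.7, 1.7),
        seed = 1) {
    new("SimulationConfig",
        nGenes = as.integer(nGenes),
        repliconNames = repliconNames,
        repliconFraction = repliconFraction,
        geneLengthMeanLog = geneLengthMeanLog,
        geneLengthSdLog = geneLengthSdLog,
        sampleNames = sampleNames,
        librarySize = librarySize,
        naturalSdLog = naturalSdLog,
        includeCulture = includeCulture,
        cultureName = cultureName,
        cultureLibrarySize = cultureLibrarySize,
        cultureBulkRange = cultureBulkRange,
        cultureHighN = as.integer(cultureHighN),
        cultureHighRange = cultureHighRange,
        nDE = as.integer(nDE),
        deSplit = as.integer(deSplit),
        deFoldRange = deFoldRange,
        hotspotGenes = as.integer(hotspotGenes),
        hotspotFold = hotspotFold,
        islandSizes = as.integer(islandSizes),
        islandMultipliers = islandMultipliers,
        nClusters = as.integer(nClusters),
        clusterGenes = as.integer(clusterGenes),
        clusterFoldRange = clusterFoldRange,
        seasonalEcoparalogFolds = seasonalEcoparalogFolds,
        seed = as.integer(seed))
}

#' Simulate a metatranscriptome experiment with planted truth
#'
#' Draws per-gene expression levels from the configured laws, plants the
#' differential, hotspot, island and paralog-cluster structure, links
#' levels to reads via expected count proportional to level x length (so
#' TPM recovers the level), and samples counts multinomially at the exact
#' library size. Planted seasonal folds are applied symmetrically (level
#' times sqrt(f) in one sample, divided by sqrt(f) in the other), so a
#' planted fold perturbs combined expression as little as possible.
#' Everything is reproducible from `cfg@seed`.
#'
#' @param cfg a [simulationConfig()].
#' @return A list with components `annotation` (`GRanges`), `experiment`
#'   (a [SalternExperiment][SalternExperiment-class] with counts),
#'   `islands` (`GRanges`), `clusters` (`ParalogClusters`), `truth`
#'   (`PlantedTruth`) and `config`.
#' @export
simulateExperiment <- function(cfg) {
    stopifnot(is(cfg, "SimulationConfig"))
    validObject(cfg)
    set.seed(cfg@seed)
    n <- cfg@nGenes

    # --- genome layout -------------------------------------------------
    len <- pmax(90, round(stats::rlnorm(n, cfg@geneLengthMeanLog,
                                        cfg@geneLengthSdLog)))
    repCounts <- diff(round(cumsum(c(0, cfg@repliconFraction)) * n))
    replicon <- base::rep(cfg@repliconNames, repCounts)
    starts <- integer(n); ends <- integer(n)
    pos <- 1L
    current <- ""
    gaps <- sample(20:200, n, replace = TRUE)
    for (i in seq_len(n)) {
        if (replicon[i] != current) { pos <- 1L; current <- replicon[i] }
        starts[i] <- pos
        ends[i] <- pos + len[i] - 1L
        pos <- ends[i] + gaps[i]
    }
    ids <- sprintf("SIM_RS%05d", seq_len(n) * 5L)
    ann <- GRanges(replicon, IRanges(starts, ends),
                   strand = sample(c("+", "-"), n, replace = TRUE))
    mcols(ann)$gene_id <- ids
    mcols(ann)$product <- "hypothetical protein"
    names(ann) <- ids
    GenomeInfoDb::seqlevels(ann) <- cfg@repliconNames

    chromIdx <- which(replicon == cfg@repliconNames[1L])

    # --- planted structural blocks on the chromosome -------------------
    hotspotIdx <- integer()
    if (cfg@hotspotGenes > 0L) {
        s <- length(chromIdx) - cfg@hotspotGenes - 10L
        if (s < 1L)
            stop("chromosome too small for the hotspot block",
                 call. = FALSE)
        hotspotIdx <- chromIdx[s:(s + cfg@hotspotGenes - 1L)]
    }
    nIsl <- length(cfg@islandSizes)
    islandIdx <- list()
    if (nIsl > 0L) {
        offsets <- seq(0.05, 0.65, length.out = max(nIsl, 2L))[seq_len(nIsl)]
        for (j in seq_len(nIsl)) {
            s <- max(1L, round(offsets[j] * length(chromIdx)))
            block <- chromIdx[s:(s + cfg@islandSizes[j] - 1L)]
            islandIdx[[j]] <- block
        }
        blocks <- c(islandIdx, list(hotspotIdx))
        if (anyDuplicated(unlist(blocks)))
            stop("island/hotspot blocks overlap; reduce sizes or counts",
                 call. = FALSE)
    }

    blocked <- c(hotspotIdx, unlist(islandIdx))
    pool <- setdiff(seq_len(n), blocked)

    # --- paralog clusters ----------------------------------------------
    clusterIdx <- list()
    clusterFolds <- numeric()
    if (cfg@nClusters > 0L && cfg@clusterGenes > 0L) {
        members <- sample(pool, cfg@clusterGenes)
        pool <- setdiff(pool, members)
        sizes <- base::rep(2L, cfg@nClusters)
        extra <- cfg@clusterGenes - 2L * cfg@nClusters
        if (extra > 0L)
            sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
        clusterIdx <- split(members, base::rep(seq_len(cfg@nClusters), sizes))
        names(clusterIdx) <- sprintf("cluster_%02d", seq_len(cfg@nClusters))
        clusterFolds <- exp(stats::runif(cfg@nClusters,
            log(cfg@clusterFoldRange[1L]), log(cfg@clusterFoldRange[2L])))
        names(clusterFolds) <- names(clusterIdx)
    }

    # --- seasonal DE assignment ----------------------------------------
    seGenes <- integer()
    seFolds <- cfg@seasonalEcoparalogFolds
    if (length(seFolds) && length(clusterIdx) >= length(seFolds)) {
        # one member (the divergent top member) of distinct clusters
        seGenes <- vapply(seq_along(seFolds),
                          function(j) clusterIdx[[j]][1L], integer(1))
    } else seFolds <- numeric()
    nA <- cfg@deSplit[1L] - length(seGenes)
    nB <- cfg@deSplit[2L]
    if (nA < 0L)
        stop("sample-1 DE quota smaller than the seasonal-ecoparalog set",
             call. = FALSE)
    deIdx <- sample(pool, nA + nB)
    deDir <- base::rep(cfg@sampleNames, c(nA, nB))
    deFold <- stats::runif(nA + nB, cfg@deFoldRange[1L], cfg@deFoldRange[2L])
    deIdx <- c(deIdx, seGenes)
    deDir <- c(deDir, base::rep(cfg@sampleNames[1L], length(seGenes)))
    deFold <- c(deFold, seFolds)

    # --- expression levels ---------------------------------------------
    A <- 1e6 / n
    base <- stats::rlnorm(n, log(A), cfg@naturalSdLog)
    for (j in seq_along(clusterIdx)) {
        # members share a base level; the planted divergence is applied
        # symmetrically (top member up, bottom member down by sqrt(f)) so
        # the cluster's total expression stays at its base
        m <- clusterIdx[[j]]
        base[m] <- base[m[1L]]
        sqf <- sqrt(clusterFolds[j])
        base[m[1L]] <- base[m[1L]] * sqf
        base[m[length(m)]] <- base[m[length(m)]] / sqf
    }
    for (j in seq_along(islandIdx))
        base[islandIdx[[j]]] <- base[islandIdx[[j]]] *
            cfg@islandMultipliers[j]
    lvl <- cbind(base, base)
    colnames(lvl) <- cfg@sampleNames
    up <- ifelse(deDir == cfg@sampleNames[1L], 1L, 2L)
    sq <- sqrt(deFold)
    lvl[cbind(deIdx, up)] <- lvl[cbind(deIdx, up)] * sq
    lvl[cbind(deIdx, 3L - up)] <- lvl[cbind(deIdx, 3L - up)] / sq
    hsDir <- character()
    if (length(hotspotIdx)) {
        # all block genes respond in sample 2 except one contrarian
        hsDir <- base::rep(cfg@sampleNames[2L], length(hotspotIdx))
        hsDir[ceiling(length(hotspotIdx) / 2)] <- cfg@sampleNames[1L]
        hup <- ifelse(hsDir == cfg@sampleNames[1L], 1L, 2L)
        hsq <- sqrt(cfg@hotspotFold)
        lvl[cbind(hotspotIdx, hup)] <- lvl[cbind(hotspotIdx, hup)] * hsq
        lvl[cbind(hotspotIdx, 3L - hup)] <-
            lvl[cbind(hotspotIdx, 3L - hup)] / hsq
    }

    # --- counts ---------------------------------------------------------
    sampleNames <- cfg@sampleNames
    libs <- round(cfg@librarySize)
    cts <- sapply(seq_len(2L), function(s)
        stats::rmultinom(1L, libs[s], prob = lvl[, s] * len)[, 1L])
    colnames(cts) <- sampleNames
    if (cfg@includeCulture) {
        cl <- exp(stats::runif(n, log(cfg@cultureBulkRange[1L]),
                               log(cfg@cultureBulkRange[2L])))
        hi <- sample(n, cfg@cultureHighN)
        cl[hi] <- exp(stats::runif(cfg@cultureHighN,
            log(cfg@cultureHighRange[1L]), log(cfg@cultureHighRange[2L])))
        cc <- stats::rmultinom(1L, round(cfg@cultureLibrarySize),
                               prob = cl * len)[, 1L]
        cts <- cbind(cts, cc)
        colnames(cts) <- c(sampleNames, cfg@cultureName)
    }
    rownames(cts) <- ids
    se <- SalternExperiment(counts = cts, annotation = ann)

    # --- deliverable side tables ----------------------------------------
    islands <- GRanges()
    if (nIsl > 0L) {
        islands <- GRanges(
            base::rep(cfg@repliconNames[1L], nIsl),
            IRanges(vapply(islandIdx, function(i) min(starts[i]), numeric(1)),
                    vapply(islandIdx, function(i) max(ends[i]), numeric(1))))
        names(islands) <- paste0("GI", seq_len(nIsl))
    }
    clusters <- ParalogClusters(lapply(clusterIdx, function(i) ids[i]))

    hsSpan <- GRanges()
    if (length(hotspotIdx))
        hsSpan <- GRanges(cfg@repliconNames[1L],
            IRanges(min(starts[hotspotIdx]), max(ends[hotspotIdx])))
    truth <- new("PlantedTruth",
        deGenes = DataFrame(
            gene_id = ids[deIdx], direction = deDir, fold = deFold,
            base_level = base[deIdx]),
        hotspotGenes = ids[hotspotIdx],
        hotspotSpan = hsSpan,
        islandMembers = lapply(islandIdx, function(i) ids[i]),
        clusterFolds = clusterFolds,
        seasonalEcoparalogGenes = ids[seGenes])

    list(annotation = ann, experiment = se, islands = islands,
         clusters = clusters, truth = truth, config = cfg)
}

#' Write a simulated experiment in the standard file formats
#'
#' Emits the annotation (GFF3 + TSV), count table (TSV), islands (BED) and
#' cluster membership (TSV) so a simulated experiment can be re-read with
#' the package's own readers.
#'
#' @param sim output of [simulateExperiment()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
        annotation_gff3 = file.path(dir, "annotation.gff3"),
        annotation_tsv = file.path(dir, "annotation.tsv"),
        counts = file.path(dir, "counts.tsv"),
        islands = file.path(dir, "islands.bed"),
        clusters = file.path(dir, "clusters.tsv"))
    writeGeneAnnotation(sim$annotation, paths["annotation_gff3"], "gff3")
    writeGeneAnnotation(sim$annotation, paths["annotation_tsv"], "tsv")
    writeMatrix(sim$experiment, paths["counts"], "counts")
    if (length(sim$islands))
        writeIntervals(sim$islands, paths["islands"])
    if (length(clusterMembers(sim$clusters)))
        writeClusters(sim$clusters, paths["clusters"])
    invisible(paths)
}

#' Score recovery of the planted truth
#'
#' Compares analysis output against a `PlantedTruth`: precision and recall
#' of significant differential-expression calls (hotspot-block genes count
#' as true positives — they are genuinely perturbed — but recall is
#' reported over the planted DE set), direction accuracy among recovered
#' DE genes, the Jaccard index between detected hotspot-region gene
#' membership and the planted block, and precision/recall of ecoparalog
#' cluster calls against the planted divergence folds.
#'
#' @param truth a `PlantedTruth` from [simulateExperiment()].
#' @param calls a [GeneCallSet][classifyAll()] for the two natural
#'   samples.
#' @param hotspots optional [hotspotScan()] output.
#' @param ecoparalogs optional [withinSampleEcoparalogs()] output.
#' @param ecoparalogThreshold fold defining a planted-positive cluster.
#' @return A list with `de_recall`, `de_precision` (`NA` when nothing is
#'   called), `de_direction_accuracy`, `n_called`, `hotspot_jaccard`,
#'   `ecoparalog_recall`, `ecoparalog_precision`.
#' @export
evaluateRecovery <- function(truth, calls, hotspots = NULL,
                             ecoparalogs = NULL,
                             ecoparalogThreshold = 1.5) {
    stopifnot(is(truth, "PlantedTruth"), is(calls, "GeneCallSet"))
    cc <- callTable(calls)
    universe <- cc$gene_id
    planted <- truth@deGenes$gene_id
    if (!all(planted %in% universe))
        stop("planted genes missing from the call set", call. = FALSE)
    called <- cc$gene_id[cc$significant]
    positives <- union(planted, truth@hotspotGenes)
    deRecall <- if (length(planted))
        length(intersect(called, planted)) / length(planted) else NA_real_
    dePrecision <- if (length(called))
        length(intersect(called, positives)) / length(called) else NA_real_
    # direction: truth stores the sample name of the higher side
    dirAcc <- NA_real_
    recovered <- intersect(called, planted)
    if (length(recovered)) {
        want <- truth@deGenes$direction[match(recovered, planted)]
        got <- cc$direction[match(recovered, cc$gene_id)]
        gotSample <- ifelse(got == "higher_a", calls@samples[1L],
                     ifelse(got == "higher_b", calls@samples[2L], NA))
        dirAcc <- mean(gotSample == want)
    }
    hj <- NA_real_
    if (!is.null(hotspots) && length(truth@hotspotGenes)) {
        detected <- unique(unlist(mcols(hotspots)$genes))
        hj <- length(intersect(detected, truth@hotspotGenes)) /
            length(union(detected, truth@hotspotGenes))
    }
    er <- ep <- NA_real_
    if (!is.null(ecoparalogs) && length(truth@clusterFolds)) {
        truthPos <- names(truth@clusterFolds)[
            truth@clusterFolds > ecoparalogThreshold]
        det <- ecoparalogs$cluster_id[ecoparalogs$is_ecoparalog]
        er <- if (length(truthPos))
            length(intersect(det, truthPos)) / length(truthPos)
            else NA_real_
        ep <- if (length(det))
            length(intersect(det, truthPos)) / length(det) else NA_real_
    }
    list(de_recall = deRecall, de_precision = dePrecision,
         de_direction_accuracy = dirAcc, n_called = length(called),
         hotspot_jaccard = hj,
         ecoparalog_recall = er, ecoparalog_precision = ep)
}
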