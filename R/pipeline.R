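#' Run the full expression-analysis battery
#'
#' Orchestrates the whole downstream analysis for one pair of samples:
#' TPM normalization, the average-anchored threshold chain, per-sample
#' distribution summaries, gene-by-gene seasonal classification with
#' tallies, high-expression and unexpressed gene sets with their
#' intersections, top-N tables and their overlap, island expression
#' summaries (when islands are given), the hotspot scan, and the
#' ecoparalog battery (when clusters are given). All result tables can be
#' written as TSV plus one machine-readable JSON summary.
#'
#' Either per-gene counts (the normal entry) or a ready-made TPM matrix
#' (an "expression-only" entry for published expression tables) can drive
#' the run.
#'
#' @param x a [SalternExperiment][SalternExperiment-class]; if it has only
#'   counts, TPM is computed first.
#' @param sampleA,sampleB the two samples to compare; default the first
#'   two.
#' @param islands optional `GRanges` of genomic islands.
#' @param clusters optional `ParalogClusters`.
#' @param foldMin minimum significant fold (default 1.5).
#' @param pseudo pseudocount in TPM for fold computations.
#' @param window,minGenes hotspot-scan tuning (see [hotspotScan()]).
#' @param topN length of the top-expressed tables.
#' @param cutoffs TPM cutoffs for the distribution summaries.
#' @param outDir optional directory; when given, every table is written as
#'   TSV (regions additionally as BED) plus `summary.json`.
#' @return A list with components `thresholds`, `distributions`, `calls`
#'   (a [GeneCallSet][callTallies()]), `tallies`, `high`, `unexpressed`,
#'   `top` (per-sample tables), `topOverlap`, `islands`, `hotspots`,
#'   `ecoparalogs` (`within_a`, `within_b`, `seasonal`, `cross_season`),
#'   and `genome_mean_fold`.
#' @export
runAnalysis <- function(x, sampleA = colnames(x)[1L],
                        sampleB = colnames(x)[2L],
                        islands = NULL, clusters = NULL,
                        foldMin = 1.5, pseudo = 1,
                        window = 20, minGenes = 10,
                        topN = 25, cutoffs = c(571, 1000),
                        outDir = NULL) {
    if (ncol(x) < 2L)
        stop("at least two samples required", call. = FALSE)
    if (!"tpm" %in% assayNames(x))
        x <- tryCatch(computeTPM(x),
            error = function(e) stop("stage quantify: ", conditionMessage(e),
                                     call. = FALSE))
    th <- deriveThresholds(nrow(x), foldMin)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
    }
    dists <- stage("quantify", lapply(
        stats::setNames(nm = c(sampleA, sampleB)),
        function(s) distributionSummary(x, s, cutoffs = cutoffs)))
    calls <- stage("seasonal", classifyAll(x, sampleA, sampleB, th, pseudo))
    tallies <- callTallies(calls)
    high <- highExpressionSets(x, c(sampleA, sampleB), th)
    unexp <- unexpressedSets(x, c(sampleA, sampleB))
    top <- lapply(stats::setNames(nm = c(sampleA, sampleB)),
                  function(s) topExpressed(x, s, min(topN, nrow(x))))
    tov <- topOverlap(top[[1L]], top[[2L]])
    gmf <- genomeMeanFold(x, sampleA, sampleB, pseudo)
    isl <- if (!is.null(islands) && length(islands))
        stage("regions", islandExpression(x, islands, sampleA, sampleB,
                                          pseudo)) else NULL
    hs <- stage("regions",
                hotspotScan(x, sampleA, sampleB, window, minGenes, pseudo))
    eco <- NULL
    if (!is.null(clusters) && length(clusterMembers(clusters)))
        eco <- stage("ecoparalog", list(
            within_a = withinSampleEcoparalogs(x, clusters, sampleA,
                                               pseudo = pseudo),
            within_b = withinSampleEcoparalogs(x, clusters, sampleB,
                                               pseudo = pseudo),
            seasonal = seasonalEcoparalogs(x, clusters, sampleA, sampleB,
                                           th, pseudo),
            cross_season = crossSeasonExtremes(x, clusters, sampleA,
                                               sampleB, pseudo)))
    report <- list(thresholds = th, samples = c(sampleA, sampleB),
                   distributions = dists, calls = calls, tallies = tallies,
                   high = high, unexpressed = unexp, top = top,
                   topOverlap = tov, islands = isl, hotspots = hs,
                   ecoparalogs = eco, genome_mean_fold = gmf)
    .checkReportInvariants(report, nrow(x))
    if (!is.null(outDir))
        writeReport(report, x, outDir)
    report
}

.checkReportInvariants <- function(report, nGenes) {
    tl <- report$tallies
    stopifnot(
        tl[["n_similar"]] + tl[["n_higher_a"]] + tl[["n_higher_b"]] ==
            nGenes,
        tl[["n_sig"]] == tl[["n_sig_a"]] + tl[["n_sig_b"]],
        length(report$high$intersection) <=
            min(lengths(report$high$sets)))
    invisible(TRUE)
}

#' Write an analysis report bundle
#'
#' TSV for every table, BED for hotspot regions (score = 1000 * mean fold,
#' capped at 1000), and a `summary.json` with the thresholds, tallies and
#' headline numbers. Output is deterministic for a fixed input.
#'
#' @param report output of [runAnalysis()].
#' @param x the analyzed [SalternExperiment][SalternExperiment-class].
#' @param outDir output directory (created if needed).
#' @return Invisibly, `outDir`.
#' @export
writeReport <- function(report, x, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    tsv <- function(df, name)
        utils::write.table(df, file.path(outDir, name), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    writeMatrix(x, file.path(outDir, "tpm.tsv"), "tpm")
    tsv(as.data.frame(callTable(report$calls)), "gene_calls.tsv")
    sig <- as.data.frame(callTable(report$calls))
    tsv(sig[sig$significant, ], "significant_genes.tsv")
    for (s in names(report$top))
        tsv(report$top[[s]], sprintf("top_%s.tsv", s))
    for (s in names(report$distributions))
        tsv(report$distributions[[s]]$histogram,
            sprintf("tpm_histogram_%s.tsv", s))
    if (!is.null(report$islands))
        tsv(report$islands, "island_expression.tsv")
    hs <- report$hotspots
    if (length(hs)) {
        df <- data.frame(name = names(hs),
            replicon = as.character(seqnames(hs)),
            start = start(hs), end = end(hs),
            n_genes = mcols(hs)$n_genes,
            mean_fold = mcols(hs)$mean_fold,
            mean_tpm_a = mcols(hs)$mean_tpm_a,
            mean_tpm_b = mcols(hs)$mean_tpm_b)
        tsv(df, "hotspots.tsv")
        writeIntervals(hs, file.path(outDir, "hotspots.bed"),
                       score = pmin(1000, 1000 * mcols(hs)$mean_fold))
    }
    if (!is.null(report$ecoparalogs)) {
        tsv(report$ecoparalogs$within_a, "ecoparalogs_sample_a.tsv")
        tsv(report$ecoparalogs$within_b, "ecoparalogs_sample_b.tsv")
        tsv(report$ecoparalogs$seasonal, "ecoparalogs_seasonal.tsv")
        tsv(report$ecoparalogs$cross_season, "ecoparalogs_cross_season.tsv")
    }
    th <- report$thresholds
    summary <- list(
        samples = report$samples,
        thresholds = list(
            average_tpm = averageTPM(th),
            average_tpm_reported = roundHalfUp(averageTPM(th)),
            similarity_delta = similarityThreshold(th),
            combined_min = combinedThreshold(th),
            high_min = highThreshold(th),
            fold_min = minFold(th)),
        tallies = as.list(report$tallies),
        high_expressed = lengths(report$high$sets),
        high_expressed_both = length(report$high$intersection),
        unexpressed = lengths(report$unexpressed$sets),
        unexpressed_both = length(report$unexpressed$intersection),
        top_overlap = report$topOverlap$n,
        genome_mean_fold = report$genome_mean_fold,
        n_hotspots = length(report$hotspots))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(outDir)
}
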