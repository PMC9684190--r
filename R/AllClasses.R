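#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames assay<- rowRanges colData
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

setClass("ThresholdSet",
    representation(
        average = "numeric",
        delta = "numeric",
        combined = "numeric",
        high = "numeric",
        foldMin = "numeric"
    )
)

setValidity("ThresholdSet", function(object) {
    msg <- character()
    for (s in c("average", "delta", "combined", "high", "foldMin")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v) || v <= 0)
            msg <- c(msg, sprintf("'%s' must be a single positive number", s))
    }
    if (!length(msg)) {
        if (object@delta != roundHalfUp(object@average / 10))
            msg <- c(msg, "delta must equal round(average/10)")
        if (object@combined != 2 * object@delta)
            msg <- c(msg, "combined must equal 2*delta")
        if (object@high != roundHalfUp(1.5 * object@average))
            msg <- c(msg, "high must equal round(1.5*average)")
    }
    if (length(msg)) msg else TRUE
})

#' SalternExperiment: counts and TPM for one reference genome
#'
#' A thin extension of [SummarizedExperiment::RangedSummarizedExperiment]
#' holding per-gene mapped-read counts (assay `"counts"`) and/or TPM values
#' (assay `"tpm"`) for two or more samples, with the gene annotation as
#' `rowRanges` (1-based inclusive coordinates; `gene_id` and `product`
#' metadata columns; row names are gene ids).
#'
#' Validity requires at least one of the two assays; counts must be
#' non-negative and integer-valued, TPM non-negative. The per-sample TPM sum
#' of 10^6 is a guarantee of [computeTPM()] (and is property-tested), not a
#' validity constraint, so that expression-only slices such as published
#' top-N tables can be represented.
#'
#' @seealso [computeTPM()], [readCounts()], [readGeneAnnotation()]
#' @aliases SalternExperiment-class
#' @exportClass SalternExperiment
setClass("SalternExperiment",
    contains = "RangedSummarizedExperiment")

setValidity("SalternExperiment", function(object) {
    msg <- character()
    an <- assayNames(object)
    if (!any(c("counts", "tpm") %in% an))
        msg <- c(msg, "need a 'counts' and/or 'tpm' assay")
    if ("counts" %in% an) {
        cts <- assay(object, "counts")
        if (any(!is.finite(cts)) || any(cts < 0))
            msg <- c(msg, "counts must be finite and non-negative")
        else if (any(cts != floor(cts)))
            msg <- c(msg, "counts must be integer-valued (mapped-read counts)")
    }
    if ("tpm" %in% an) {
        tp <- assay(object, "tpm")
        if (any(!is.finite(tp)) || any(tp < 0))
            msg <- c(msg, "tpm must be finite and non-negative")
    }
    if (is.null(rownames(object)))
        msg <- c(msg, "rownames (gene ids) are required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample names must be unique")
    if (length(msg)) msg else TRUE
})

setClass("ParalogClusters",
    representation(clusters = "list")
)

setValidity("ParalogClusters", function(object) {
    cl <- object@clusters
    msg <- character()
    if (length(cl)) {
        if (is.null(names(cl)) || anyDuplicated(names(cl)))
            msg <- c(msg, "cluster ids must be unique and named")
        sizes <- lengths(cl)
        if (any(sizes < 2L))
            msg <- c(msg, sprintf("singleton cluster: %s",
                paste(names(cl)[sizes < 2L], collapse = ", ")))
        members <- unlist(cl, use.names = FALSE)
        if (anyDuplicated(members))
            msg <- c(msg, sprintf("gene in more than one cluster: %s",
                paste(unique(members[duplicated(members)]), collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

setClass("GeneCallSet",
    representation(
        calls = "DataFrame",
        samples = "character",
        thresholds = "ThresholdSet"
    )
)

setValidity("GeneCallSet", function(object) {
    msg <- character()
    need <- c("gene_id", "tpm_a", "tpm_b", "diff", "fold", "direction",
              "significant", "high_a", "high_b",
              "unexpressed_a", "unexpressed_b")
    if (!all(need %in% colnames(object@calls)))
        msg <- c(msg, "calls table is missing required columns")
    if (length(object@samples) != 2L)
        msg <- c(msg, "exactly two sample names required")
    if (!length(msg)) {
        cc <- object@calls
        if (any(cc$significant & cc$direction == "similar"))
            msg <- c(msg, "significant calls must not be 'similar'")
        if (any(cc$fold < 1))
            msg <- c(msg, "fold must be >= 1")
    }
    if (length(msg)) msg else TRUE
})

setClass("SimulationConfig",
    representation(
        nGenes = "integer",
        repliconNames = "character",
        repliconFraction = "numeric",
        geneLengthMeanLog = "numeric",
        geneLengthSdLog = "numeric",
        sampleNames = "character",
        librarySize = "numeric",
        naturalSdLog = "numeric",
        includeCulture = "logical",
        cultureName = "character",
        cultureLibrarySize = "numeric",
        cultureBulkRange = "numeric",
        cultureHighN = "integer",
        cultureHighRange = "numeric",
        nDE = "integer",
        deSplit = "integer",
        deFoldRange = "numeric",
        hotspotGenes = "integer",
        hotspotFold = "numeric",
        islandSizes = "integer",
        islandMultipliers = "numeric",
        nClusters = "integer",
        clusterGenes = "integer",
        clusterFoldRange = "numeric",
        seasonalEcoparalogFolds = "numeric",
        seed = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    n <- object@nGenes
    if (n < 1L) msg <- c(msg, "nGenes must be >= 1")
    if (length(object@repliconFraction) != length(object@repliconNames) ||
        abs(sum(object@repliconFraction) - 1) > 1e-9 ||
        any(object@repliconFraction <= 0))
        msg <- c(msg, "repliconFraction must be positive and sum to 1")
    if (length(object@sampleNames) != 2L ||
        anyDuplicated(object@sampleNames))
        msg <- c(msg, "exactly two distinct natural sample names required")
    if (length(object@librarySize) != 2L || any(object@librarySize < 1))
        msg <- c(msg, "two positive library sizes required")
    if (sum(object@deSplit) != object@nDE)
        msg <- c(msg, "deSplit must sum to nDE")
    if (any(object@deFoldRange < 1) || length(object@deFoldRange) != 2L)
        msg <- c(msg, "deFoldRange must be two values >= 1")
    planted <- object@nDE + object@hotspotGenes + sum(object@islandSizes) +
        object@clusterGenes
    if (planted > n)
        msg <- c(msg, sprintf(
            "planted structure (%d genes) exceeds nGenes (%d)", planted, n))
    if (object@clusterGenes > 0L && object@clusterGenes < 2L * object@nClusters)
        msg <- c(msg, "clusterGenes must be >= 2 per cluster")
    if (object@includeCulture && object@cultureHighN > n)
        msg <- c(msg, "cultureHighN exceeds nGenes")
    if (length(object@islandSizes) != length(object@islandMultipliers))
        msg <- c(msg, "one multiplier per island required")
    if (any(object@islandMultipliers >= 1) || any(object@islandMultipliers <= 0))
        msg <- c(msg, "island multipliers must lie in (0, 1)")
    if (length(msg)) msg else TRUE
})

setClass("PlantedTruth",
    representation(
        deGenes = "DataFrame",
        hotspotGenes = "character",
        hotspotSpan = "GRanges",
        islandMembers = "list",
        clusterFolds = "numeric",
        seasonalEcoparalogGenes = "character"
    )
)
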