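#' Accessors for salternSeasons classes
#'
#' `tpm()` returns the TPM assay of a [SalternExperiment]; `counts()` the
#' mapped-read counts. `averageTPM()`, `similarityThreshold()`,
#' `combinedThreshold()`, `highThreshold()` and `minFold()` extract the
#' members of a [ThresholdSet][deriveThresholds()]. `clusterMembers()`
#' returns the member list of a `ParalogClusters` object, `callTable()` and
#' `callTallies()` the per-gene table and summary tallies of a
#' [GeneCallSet][classifyAll()].
#'
#' @param object a salternSeasons object.
#' @return See the individual descriptions.
#' @name accessors
#' @aliases tpm counts averageTPM similarityThreshold combinedThreshold
#'   highThreshold minFold clusterMembers callTable callTallies
#' @examples
#' th <- deriveThresholds(2625)
#' similarityThreshold(th)  # 38
NULL

#' @rdname accessors
#' @export
setGeneric("tpm", function(object) standardGeneric("tpm"))

#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("averageTPM", function(object) standardGeneric("averageTPM"))

#' @rdname accessors
#' @export
setGeneric("similarityThreshold",
    function(object) standardGeneric("similarityThreshold"))

#' @rdname accessors
#' @export
setGeneric("combinedThreshold",
    function(object) standardGeneric("combinedThreshold"))

#' @rdname accessors
#' @export
setGeneric("highThreshold", function(object) standardGeneric("highThreshold"))

#' @rdname accessors
#' @export
setGeneric("minFold", function(object) standardGeneric("minFold"))

#' @rdname accessors
#' @export
setGeneric("clusterMembers",
    function(object) standardGeneric("clusterMembers"))

#' @rdname accessors
#' @export
setGeneric("callTable", function(object) standardGeneric("callTable"))

#' @rdname accessors
#' @export
setGeneric("callTallies", function(object) standardGeneric("callTallies"))

setMethod("tpm", "SalternExperiment", function(object) .tpmAssay(object))

setMethod("counts", "SalternExperiment", function(object) {
    if (!"counts" %in% assayNames(object))
        stop("no 'counts' assay (expression-only object)", call. = FALSE)
    assay(object, "counts")
})

setMethod("averageTPM", "ThresholdSet", function(object) object@average)
setMethod("similarityThreshold", "ThresholdSet", function(object) object@delta)
setMethod("combinedThreshold", "ThresholdSet", function(object) object@combined)
setMethod("highThreshold", "ThresholdSet", function(object) object@high)
setMethod("minFold", "ThresholdSet", function(object) object@foldMin)

setMethod("clusterMembers", "ParalogClusters",
    function(object) object@clusters)

setMethod("callTable", "GeneCallSet", function(object) object@calls)

setMethod("callTallies", "GeneCallSet", function(object) {
    cc <- object@calls
    c(n_similar = sum(cc$direction == "similar"),
      n_higher_a = sum(cc$direction == "higher_a"),
      n_higher_b = sum(cc$direction == "higher_b"),
      n_sig = sum(cc$significant),
      n_sig_a = sum(cc$significant & cc$direction == "higher_a"),
      n_sig_b = sum(cc$significant & cc$direction == "higher_b"))
})

setMethod("show", "ThresholdSet", function(object) {
    cat("ThresholdSet (average-anchored expression cutoffs)\n")
    cat(sprintf("  average TPM      : %.2f (reported %d)\n",
        object@average, roundHalfUp(object@average)))
    cat(sprintf("  similarity delta : %g TPM\n", object@delta))
    cat(sprintf("  combined minimum : %g TPM\n", object@combined))
    cat(sprintf("  high expression  : %g TPM\n", object@high))
    cat(sprintf("  minimum fold     : %g\n", object@foldMin))
})

setMethod("show", "ParalogClusters", function(object) {
    cl <- object@clusters
    cat(sprintf("ParalogClusters: %d clusters, %d genes\n",
        length(cl), length(unlist(cl, use.names = FALSE))))
})

setMethod("show", "GeneCallSet", function(object) {
    tl <- callTallies(object)
    cat(sprintf("GeneCallSet: %s vs %s, %d genes\n",
        object@samples[1L], object@samples[2L], nrow(object@calls)))
    cat(sprintf("  similar %d | higher in %s %d | higher in %s %d\n",
        tl[["n_similar"]], object@samples[1L], tl[["n_higher_a"]],
        object@samples[2L], tl[["n_higher_b"]]))
    cat(sprintf("  significant %d (%d / %d)\n",
        tl[["n_sig"]], tl[["n_sig_a"]], tl[["n_sig_b"]]))
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(
        "SimulationConfig: %d genes on %s; samples %s (+%s); seed %d\n",
        object@nGenes, paste(object@repliconNames, collapse = "+"),
        paste(object@sampleNames, collapse = "/"),
        if (object@includeCulture) object@cultureName else "no culture",
        object@seed))
    cat(sprintf(
        "  planted: %d DE (%s), hotspot %d genes x%.2f, %d islands, %d clusters\n",
        object@nDE, paste(object@deSplit, collapse = "/"),
        object@hotspotGenes, object@hotspotFold,
        length(object@islandSizes), object@nClusters))
})

setMethod("show", "PlantedTruth", function(object) {
    cat(sprintf(
        "PlantedTruth: %d DE genes, %d hotspot genes, %d islands, %d clusters, %d seasonal ecoparalogs\n",
        nrow(object@deGenes), length(object@hotspotGenes),
        length(object@islandMembers), length(object@clusterFolds),
        length(object@seasonalEcoparalogGenes)))
})
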