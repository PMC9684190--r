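# in-code fixtures: annotations and experiments built from matrices

toyAnnotation <- function(n, replicon = "chr", lengths = 1000L,
                          ids = sprintf("g%03d", seq_len(n))) {
    lengths <- rep_len(lengths, n)
    replicon <- rep_len(replicon, n)
    starts <- integer(n)
    pos <- 1L
    current <- ""
    for (i in seq_len(n)) {
        if (replicon[i] != current) { pos <- 1L; current <- replicon[i] }
        starts[i] <- pos
        pos <- pos + lengths[i] + 100L
    }
    ann <- GenomicRanges::GRanges(replicon,
        IRanges::IRanges(starts, width = lengths), strand = "+")
    S4Vectors::mcols(ann)$gene_id <- ids
    S4Vectors::mcols(ann)$product <- "hypothetical protein"
    names(ann) <- ids
    ann
}

# experiment with a given TPM matrix (genes x samples)
tpmExperiment <- function(tpmMat, lengths = 1000L) {
    if (is.null(rownames(tpmMat)))
        rownames(tpmMat) <- sprintf("g%03d", seq_len(nrow(tpmMat)))
    ann <- toyAnnotation(nrow(tpmMat), lengths = lengths,
                         ids = rownames(tpmMat))
    SalternExperiment(tpm = tpmMat, annotation = ann)
}

countExperiment <- function(countMat, lengths = 1000L) {
    if (is.null(rownames(countMat)))
        rownames(countMat) <- sprintf("g%03d", seq_len(nrow(countMat)))
    ann <- toyAnnotation(nrow(countMat), lengths = lengths,
                         ids = rownames(countMat))
    SalternExperiment(counts = countMat, annotation = ann)
}

extfile <- function(name)
    system.file("extdata", name, package = "salternSeasons",
                mustWork = TRUE)
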