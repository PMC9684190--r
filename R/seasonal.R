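#' Average-anchored classification thresholds
#'
#' The whole classification scheme hangs off one analytic anchor: with N
#' genes, TPM averages exactly `A = 10^6/N` per gene. From it derive
#' `delta = round(A/10)` (two samples are "similar" on a gene when their
#' TPM difference is below delta), `C = 2*delta` (minimum combined
#' expression for a significant call), and `H = round(1.5*A)` (high
#' expression). For the 2,625 protein-coding genes of *Haloquadratum
#' walsbyi* HBSQ001 this chain is 381 / 38 / 76 / 571 TPM. Rounding is
#' nearest integer, halves away from zero.
#'
#' @param nGenes number of genes in the normalized set.
#' @param foldMin minimum fold difference for a significant call
#'   (default 1.5).
#' @return A `ThresholdSet`; see [averageTPM()], [similarityThreshold()],
#'   [combinedThreshold()], [highThreshold()], [minFold()].
#' @examples
#' deriveThresholds(2625)
#' @export
deriveThresholds <- function(nGenes, foldMin = 1.5) {
    A <- meanTPM(nGenes)
    new("ThresholdSet",
        average = A,
        delta = roundHalfUp(A / 10),
        combined = 2 * roundHalfUp(A / 10),
        high = roundHalfUp(1.5 * A),
        foldMin = foldMin)
}

#' Symmetric pseudocounted fold change
#'
#' `max(a+pseudo, b+pseudo) / min(a+pseudo, b+pseudo)`: symmetric in its
#' arguments and always >= 1. The default pseudocount of 1 TPM keeps folds
#' finite for genes with zero expression in one sample ("not a single
#' read"); set `pseudo = 0` for the raw TPM ratio.
#'
#' @param a,b TPM values (vectorized).
#' @param pseudo pseudocount in TPM units.
#' @return Fold difference(s), >= 1.
#' @examples
#' foldChange(100, 200, pseudo = 0)  # 2
#' foldChange(0, 99)                 # 100
#' @export
foldChange <- function(a, b, pseudo = 1) {
    if (any(a < 0) || any(b < 0))
        stop("TPM values must be non-negative", call. = FALSE)
    if (pseudo < 0)
        stop("pseudo must be non-negative", call. = FALSE)
    pmax(a + pseudo, b + pseudo) / pmin(a + pseudo, b + pseudo)
}

#' Classify one gene (or vectors of genes) between two samples
#'
#' Direction: "similar" when `|a - b| < delta`, else higher of the two.
#' Significant: combined expression `a + b >= C`, fold `>= foldMin`, and
#' direction not similar. High expression: TPM `>= H` (inclusive, "at
#' least"). Unexpressed: TPM exactly 0. The absolute difference (vs delta)
#' decides direction; the fold ratio enters only the significance rule —
#' the two criteria select different gene sets.
#'
#' @param tpmA,tpmB TPM in the two samples (vectorized).
#' @param th a `ThresholdSet` from [deriveThresholds()].
#' @param pseudo pseudocount for [foldChange()].
#' @return A `data.frame` with columns `tpm_a`, `tpm_b`, `diff`, `fold`,
#'   `direction`, `significant`, `high_a`, `high_b`, `unexpressed_a`,
#'   `unexpressed_b`.
#' @examples
#' th <- deriveThresholds(2625)
#' classifyGene(100, 200, th)$significant  # TRUE
#' classifyGene(400, 420, th)$direction    # "similar": diff 20 < 38
#' classifyGene(10, 60, th)$significant    # FALSE: combined 70 < 76
#' @export
classifyGene <- function(tpmA, tpmB, th, pseudo = 1) {
    stopifnot(is(th, "ThresholdSet"))
    if (any(tpmA < 0) || any(tpmB < 0))
        stop("negative TPM", call. = FALSE)
    d <- abs(tpmA - tpmB)
    fold <- foldChange(tpmA, tpmB, pseudo)
    direction <- ifelse(d < th@delta, "similar",
                 ifelse(tpmA > tpmB, "higher_a", "higher_b"))
    significant <- (tpmA + tpmB >= th@combined) & (fold >= th@foldMin) &
        direction != "similar"
    data.frame(
        tpm_a = tpmA, tpm_b = tpmB, diff = d, fold = fold,
        direction = direction, significant = significant,
        high_a = tpmA >= th@high, high_b = tpmB >= th@high,
        unexpressed_a = tpmA == 0, unexpressed_b = tpmB == 0,
        stringsAsFactors = FALSE)
}

#' Classify every gene between two samples
#'
#' Applies [classifyGene()] across the genome and returns a
#' [GeneCallSet][callTallies()] whose tallies partition the gene set:
#' `n_similar + n_higher_a + n_higher_b = n_genes` and
#' `n_sig = n_sig_a + n_sig_b`.
#'
#' @param x a [SalternExperiment][SalternExperiment-class] with TPM.
#' @param sampleA,sampleB the two sample names (e.g. summer, winter).
#' @param th a `ThresholdSet`; defaults to `deriveThresholds(nrow(x))`.
#' @param pseudo pseudocount for [foldChange()].
#' @return A `GeneCallSet`.
#' @export
classifyAll <- function(x, sampleA, sampleB, th = NULL, pseudo = 1) {
    a <- .tpmVector(x, sampleA)
    b <- .tpmVector(x, sampleB)
    if (is.null(th)) th <- deriveThresholds(nrow(x))
    calls <- classifyGene(a, b, th, pseudo)
    calls <- DataFrame(gene_id = rownames(x), calls)
    new("GeneCallSet", calls = calls,
        samples = c(sampleA, sampleB), thresholds = th)
}

#' Highly expressed gene sets and their intersection
#'
#' Per sample, the set of genes with TPM at or above the high-expression
#' threshold H, plus the intersection across all requested samples.
#'
#' @param x a [SalternExperiment][SalternExperiment-class] with TPM.
#' @param samples sample names (two or more).
#' @param th a `ThresholdSet`; defaults to `deriveThresholds(nrow(x))`.
#' @return A list with `sets` (named list of gene-id vectors) and
#'   `intersection` (gene ids high in every sample).
#' @export
highExpressionSets <- function(x, samples = colnames(x), th = NULL) {
    if (is.null(th)) th <- deriveThresholds(nrow(x))
    sets <- lapply(samples, function(s) {
        tp <- .tpmVector(x, s)
        names(tp)[tp >= th@high]
    })
    names(sets) <- samples
    list(sets = sets, intersection = Reduce(intersect, sets))
}

#' Unexpressed genes per sample
#'
#' Genes with not a single mapped read (TPM exactly 0).
#'
#' @inheritParams highExpressionSets
#' @return A list with `sets` per sample and their `intersection` (genes
#'   silent in every sample).
#' @export
unexpressedSets <- function(x, samples = colnames(x)) {
    sets <- lapply(samples, function(s) {
        tp <- .tpmVector(x, s)
        names(tp)[tp == 0]
    })
    names(sets) <- samples
    list(sets = sets, intersection = Reduce(intersect, sets))
}

#' Top-N expressed genes of a sample
#'
#' Ranked descending by TPM; ties broken by ascending gene id so the
#' ranking is deterministic.
#'
#' @param x a [SalternExperiment][SalternExperiment-class] with TPM, or a
#'   named numeric vector of TPM values.
#' @param sample sample name (ignored for a vector input).
#' @param n list length.
#' @return A `data.frame` with columns `gene_id`, `tpm`, in rank order.
#' @export
topExpressed <- function(x, sample = NULL, n = 25) {
    tp <- if (is.numeric(x)) x else .tpmVector(x, sample)
    if (n > length(tp))
        stop("n exceeds the number of genes", call. = FALSE)
    ord <- order(-tp, names(tp))
    top <- tp[ord][seq_len(n)]
    data.frame(gene_id = names(top), tpm = unname(top),
               stringsAsFactors = FALSE)
}

#' Overlap between two top-N gene lists
#'
#' @param listA,listB outputs of [topExpressed()] (or character vectors of
#'   gene ids).
#' @return A list with `n` (size of the intersection) and `shared`
#'   (gene ids, sorted).
#' @export
topOverlap <- function(listA, listB) {
    ids <- function(l) if (is.character(l)) l else l$gene_id
    shared <- sort(intersect(ids(listA), ids(listB)))
    list(n = length(shared), shared = shared)
}
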