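#' TPM normalization of per-gene read counts
#'
#' Converts mapped-read counts to transcripts per million. Per gene the
#' length-normalized read rate is `count / (length in kb)`; TPM is the rate
#' divided by the per-sample rate sum, times 10^6, so every sample sums to
#' exactly 10^6 (up to floating tolerance). Gene length is the annotated
#' span `end - start + 1`; no effective-length correction is applied,
#' matching quantification by counting aligned reads per annotated gene.
#' Zero-count genes keep TPM 0 — "not expressed at all" stays detectable;
#' pseudocounts enter only in fold-change computations downstream.
#'
#' @param x a [SalternExperiment][SalternExperiment-class] with a `counts`
#'   assay.
#' @return `x` with a `tpm` assay added.
#' @examples
#' ann <- GenomicRanges::GRanges("chr",
#'     IRanges::IRanges(c(1, 601, 1701), c(500, 1600, 3700)))
#' names(ann) <- S4Vectors::mcols(ann)$gene_id <- c("g1", "g2", "g3")
#' se <- SalternExperiment(
#'     counts = matrix(c(10, 20, 30), 3, 1,
#'                     dimnames = list(c("g1", "g2", "g3"), "s")),
#'     annotation = ann)
#' tpm(computeTPM(se))[, "s"]  # rates 20:20:15 -> 363636.4 363636.4 272727.3
#' @export
computeTPM <- function(x) {
    cts <- counts(x)
    zero <- colSums(cts) == 0
    if (any(zero))
        stop("sample with no mapped reads: ",
             paste(colnames(cts)[zero], collapse = ", "), call. = FALSE)
    len <- width(rowRanges(x))
    if (any(len <= 0))
        stop("gene with non-positive length", call. = FALSE)
    rate <- cts / (len / 1000)
    tp <- sweep(rate, 2L, colSums(rate), "/") * 1e6
    assay(x, "tpm") <- tp
    validObject(x)
    x
}

#' Analytic genome-average TPM
#'
#' Because TPM sums to 10^6 per sample, the mean TPM over `nGenes` genes is
#' identically `10^6 / nGenes` for any count table — the anchor from which
#' all classification thresholds derive (2,625 genes give 380.95..., the
#' reported 381 TPM).
#'
#' @param nGenes number of genes in the normalized set.
#' @return The mean TPM, `10^6 / nGenes`.
#' @examples
#' meanTPM(2625)  # 380.9524
#' @export
meanTPM <- function(nGenes) {
    if (length(nGenes) != 1L || is.na(nGenes) || nGenes < 1)
        stop("nGenes must be a positive count", call. = FALSE)
    1e6 / nGenes
}

#' Recruitment and coverage summary for one sample
#'
#' Summarizes how a metatranscriptome maps to the reference: percentages of
#' recruited and mRNA-assigned reads, the number of genes with at least one
#' read, mean reads per covered gene, and mean per-gene fold coverage
#' (`count * readLength / geneLength`, averaged over covered genes).
#'
#' @param x a [SalternExperiment][SalternExperiment-class] with counts.
#' @param sample sample name.
#' @param totalReads total sequenced reads for the sample.
#' @param recruitedReads reads recruited to the reference genome.
#' @param mrnaReads recruited reads assigned to mRNA genes; defaults to the
#'   column sum of the count table.
#' @param readLength read length in bp used for fold coverage.
#' @return A list with fields `total_reads`, `recruited_reads`,
#'   `mrna_reads`, `pct_recruited`, `pct_mrna_of_recruited`,
#'   `pct_mrna_of_total`, `genes_covered`, `mean_reads_per_gene`,
#'   `mean_fold_coverage`, `read_length`.
#' @export
summarizeRecruitment <- function(x, sample, totalReads, recruitedReads,
                                 mrnaReads = NULL, readLength = 100) {
    .checkSample(x, sample)
    if (readLength <= 0)
        stop("readLength must be positive", call. = FALSE)
    if (recruitedReads > totalReads)
        stop("recruited_reads exceeds total_reads", call. = FALSE)
    cts <- counts(x)[, sample]
    if (is.null(mrnaReads)) mrnaReads <- sum(cts)
    if (mrnaReads > recruitedReads)
        stop("mrna_reads exceeds recruited_reads", call. = FALSE)
    covered <- cts >= 1
    len <- width(rowRanges(x))
    cov <- cts * readLength / len
    list(
        total_reads = totalReads,
        recruited_reads = recruitedReads,
        mrna_reads = mrnaReads,
        pct_recruited = 100 * recruitedReads / totalReads,
        pct_mrna_of_recruited = 100 * mrnaReads / recruitedReads,
        pct_mrna_of_total = 100 * mrnaReads / totalReads,
        genes_covered = sum(covered),
        mean_reads_per_gene = sum(cts) / sum(covered),
        mean_fold_coverage = mean(cov[covered]),
        read_length = readLength)
}

#' Characterize a sample's TPM distribution
#'
#' Computes the mean, median, a histogram on log-spaced bins, and
#' exceedance counts — the numbers behind the contrast between the
#' bell-shaped natural TPM distribution (median close to the 10^6/N
#' average) and the culture profile (low bulk, small very-high tail).
#'
#' The default bins are 40 log10-spaced intervals spanning 10^0..10^4,
#' with a dedicated zero bin plus underflow (0,1) and overflow (10^4, Inf)
#' bins so counts always sum to the number of genes.
#'
#' @param x a [SalternExperiment][SalternExperiment-class] with TPM.
#' @param sample sample name.
#' @param bins optional increasing vector of positive bin edges.
#' @param cutoffs TPM cutoffs; for each, the number of genes with TPM
#'   strictly above it is reported.
#' @return A list with fields `sample`, `mean`, `median`, `histogram`
#'   (data.frame `lower`, `upper`, `count`) and `n_above` (named numeric).
#' @export
distributionSummary <- function(x, sample, bins = NULL,
                                cutoffs = c(571, 1000)) {
    tp <- .tpmVector(x, sample)
    if (is.null(bins))
        bins <- 10^seq(0, 4, length.out = 41L)
    breaks <- unique(c(0, bins, Inf))
    cnt <- as.vector(table(cut(tp[tp > 0], breaks = breaks)))
    # first row is the dedicated zero bin [0, 0]
    hist <- data.frame(
        lower = c(0, breaks[-length(breaks)]),
        upper = c(0, breaks[-1L]),
        count = c(sum(tp == 0), cnt))
    nAbove <- vapply(cutoffs, function(c) sum(tp > c), numeric(1))
    names(nAbove) <- as.character(cutoffs)
    stopifnot(sum(hist$count) == length(tp))
    list(sample = sample, mean = mean(tp), median = stats::median(tp),
         histogram = hist, n_above = nAbove)
}
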