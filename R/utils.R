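# Rounding convention for reported whole-TPM values: nearest integer, halves
# away from zero (380.95 -> 381), unlike base round()'s round-half-even.
roundHalfUp <- function(x) trunc(x + 0.5 * sign(x))

# shared argument checks -------------------------------------------------

.checkSample <- function(x, sample) {
    if (!sample %in% colnames(x))
        stop("unknown sample: '", sample, "'", call. = FALSE)
    invisible(sample)
}

.tpmAssay <- function(x) {
    if (!"tpm" %in% assayNames(x))
        stop("no 'tpm' assay; run computeTPM() first", call. = FALSE)
    assay(x, "tpm")
}

.tpmVector <- function(x, sample) {
    .checkSample(x, sample)
    tp <- .tpmAssay(x)[, sample]
    names(tp) <- rownames(x)
    tp
}
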