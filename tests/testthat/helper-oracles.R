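# independent brute-force oracles (naive from-definition loops)

# TPM by direct evaluation of the definition, one gene at a time
bruteTPM <- function(counts, lengths) {
    rates <- numeric(length(counts))
    for (i in seq_along(counts))
        rates[i] <- counts[i] / (lengths[i] / 1000)
    out <- numeric(length(counts))
    for (i in seq_along(counts))
        out[i] <- 1e6 * rates[i] / sum(rates)
    out
}

# hotspot regions from the definition: enumerate every window, mark hot
# ones, collect covered genes, split runs, trim ends, filter
bruteHotspotGenes <- function(foldsByReplicon, geneIdsByReplicon,
                              window, minGenes) {
    gmf <- mean(unlist(foldsByReplicon))
    regions <- list()
    for (r in seq_along(foldsByReplicon)) {
        f <- foldsByReplicon[[r]]
        ids <- geneIdsByReplicon[[r]]
        ng <- length(f)
        if (ng < window) next
        covered <- rep(FALSE, ng)
        for (s in seq_len(ng - window + 1L)) {
            if (mean(f[s:(s + window - 1L)]) > gmf)
                covered[s:(s + window - 1L)] <- TRUE
        }
        i <- 1L
        while (i <= ng) {
            if (!covered[i]) { i <- i + 1L; next }
            j <- i
            while (j < ng && covered[j + 1L]) j <- j + 1L
            lo <- i; hi <- j
            repeat {
                if (lo > hi) break
                if (f[lo] < mean(f[lo:hi])) { lo <- lo + 1L; next }
                if (f[hi] < mean(f[lo:hi])) { hi <- hi - 1L; next }
                break
            }
            if (lo <= hi && hi - lo + 1L >= minGenes &&
                mean(f[lo:hi]) > gmf)
                regions[[length(regions) + 1L]] <- ids[lo:hi]
            i <- j + 1L
        }
    }
    regions
}

# per-cluster maximum pairwise pseudocounted fold, all pairs enumerated
bruteMaxPairFold <- function(tpmValues, pseudo = 1) {
    n <- length(tpmValues)
    best <- 1
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            f <- max(tpmValues[i] + pseudo, tpmValues[j] + pseudo) /
                 min(tpmValues[i] + pseudo, tpmValues[j] + pseudo)
            if (f > best) best <- f
        }
    }
    best
}
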