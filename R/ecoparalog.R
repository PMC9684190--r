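#' Within-sample ecoparalog detection
#'
#' Ecoparalogs are paralogous genes (similar proteins encoded in one
#' genome) expressed at clearly different levels within the same sample,
#' putatively serving the same function under different conditions. Per
#' cluster the fold between the highest and lowest expressed member,
#' `(max TPM + pseudo) / (min TPM + pseudo)`, is computed; a cluster
#' qualifies when that fold strictly exceeds the threshold (the rule is
#' ">1.5-fold", hence strict, unlike the inclusive seasonal rule). Because
#' the pseudocounted pairwise fold is maximized by the extremes, the
#' max/min fold equals the maximum over all member pairs.
#'
#' @param x a [SalternExperiment][SalternExperiment-class] with TPM.
#' @param clusters a `ParalogClusters` object (see [readClusters()]).
#' @param sample sample name.
#' @param threshold fold above which a cluster is called (default 1.5,
#'   strict).
#' @param pseudo pseudocount in TPM.
#' @return A `data.frame` with columns `cluster_id`, `sample`, `max_gene`,
#'   `min_gene`, `fold`, `is_ecoparalog`.
#' @export
withinSampleEcoparalogs <- function(x, clusters, sample, threshold = 1.5,
                                    pseudo = 1) {
    tp <- .tpmVector(x, sample)
    cl <- clusterMembers(clusters)
    missing <- setdiff(unlist(cl, use.names = FALSE), names(tp))
    if (length(missing))
        stop("cluster member not in the expression matrix: ",
             paste(utils::head(missing, 5L), collapse = ", "),
             call. = FALSE)
    rows <- lapply(names(cl), function(id) {
        v <- tp[cl[[id]]]
        # deterministic extreme pick: ties broken by gene id
        ord <- order(-v, names(v))
        mx <- names(v)[ord[1L]]
        mn <- names(v)[ord[length(v)]]
        fold <- (v[[mx]] + pseudo) / (v[[mn]] + pseudo)
        data.frame(cluster_id = id, sample = sample, max_gene = mx,
                   min_gene = mn, fold = fold,
                   is_ecoparalog = fold > threshold,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Seasonally differentially expressed ecoparalog members
#'
#' Applies the seasonal significance rule ([classifyGene()]: combined
#' expression >= C and fold >= foldMin) to every cluster member and
#' returns the significant ones with their cluster, direction and fold —
#' the screen behind the seasonal-ecoparalog genes.
#'
#' @param x a [SalternExperiment][SalternExperiment-class] with TPM.
#' @param clusters a `ParalogClusters` object.
#' @param sampleA,sampleB the two seasons.
#' @param th a `ThresholdSet`; defaults to `deriveThresholds(nrow(x))`.
#' @param pseudo pseudocount for [foldChange()].
#' @return A `data.frame` with columns `cluster_id`, `gene_id`, `tpm_a`,
#'   `tpm_b`, `fold`, `direction`; zero rows when no member is
#'   significant.
#' @export
seasonalEcoparalogs <- function(x, clusters, sampleA, sampleB, th = NULL,
                                pseudo = 1) {
    if (is.null(th)) th <- deriveThresholds(nrow(x))
    a <- .tpmVector(x, sampleA)
    b <- .tpmVector(x, sampleB)
    cl <- clusterMembers(clusters)
    genes <- unlist(cl, use.names = FALSE)
    cluster <- rep(names(cl), lengths(cl))
    calls <- classifyGene(a[genes], b[genes], th, pseudo)
    keep <- calls$significant
    data.frame(cluster_id = cluster[keep], gene_id = genes[keep],
               tpm_a = calls$tpm_a[keep], tpm_b = calls$tpm_b[keep],
               fold = calls$fold[keep], direction = calls$direction[keep],
               stringsAsFactors = FALSE)
}

#' Cross-season extreme expression ratio per cluster
#'
#' For each cluster, the highest expressed member in one season divided by
#' the lowest expressed member of the cluster in the other season
#' (pseudocounted). Both orientations are computed and the larger is
#' reported together with the season holding the maximum.
#'
#' @inheritParams seasonalEcoparalogs
#' @return A `data.frame` with columns `cluster_id`, `season_of_max`,
#'   `ratio`, `max_gene`, `min_gene`.
#' @export
crossSeasonExtremes <- function(x, clusters, sampleA, sampleB, pseudo = 1) {
    a <- .tpmVector(x, sampleA)
    b <- .tpmVector(x, sampleB)
    cl <- clusterMembers(clusters)
    rows <- lapply(names(cl), function(id) {
        g <- cl[[id]]
        pick <- function(v, decreasing) {
            ord <- order(if (decreasing) -v else v, g)
            g[ord[1L]]
        }
        maxA <- pick(a[g], TRUE); minA <- pick(a[g], FALSE)
        maxB <- pick(b[g], TRUE); minB <- pick(b[g], FALSE)
        rAB <- (a[[maxA]] + pseudo) / (b[[minB]] + pseudo)
        rBA <- (b[[maxB]] + pseudo) / (a[[minA]] + pseudo)
        if (rAB >= rBA)
            data.frame(cluster_id = id, season_of_max = sampleA,
                       ratio = rAB, max_gene = maxA, min_gene = minB,
                       stringsAsFactors = FALSE)
        else
            data.frame(cluster_id = id, season_of_max = sampleB,
                       ratio = rBA, max_gene = maxB, min_gene = minA,
                       stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
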