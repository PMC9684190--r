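#' Read a gene annotation (GFF3 or TSV)
#'
#' Reads the gene models that define gene identity, length and genome order
#' for all downstream analyses. GFF3 input goes through
#' [rtracklayer::import()]; rows of type `gene` (or `CDS` when no `gene`
#' rows exist) are kept and the gene id is taken from the `ID`, `locus_tag`
#' or `Name` attribute, in that order. TSV input has columns
#' `gene_id, replicon, start, end, strand, product` (1-based inclusive
#' coordinates; a header row is optional and detected by its first cell).
#'
#' Records are returned as a [GenomicRanges::GRanges] ordered by
#' `(replicon, start)`, replicons sorted lexicographically unless
#' `repliconOrder` is given (the convention puts a chromosome named e.g.
#' `"chr"` before a plasmid named `"plasmid"`). Row names and the `gene_id`
#' metadata column hold the gene ids; `product` holds the annotation text.
#'
#' @param path path to the annotation file.
#' @param format `"auto"` (by file extension), `"gff3"` or `"tsv"`.
#' @param repliconOrder optional character vector fixing replicon order for
#'   genome scans.
#' @return A `GRanges` with metadata columns `gene_id` and `product`.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines("g1\tchr\t1\t300\t+\tprotX", tsv)
#' ann <- readGeneAnnotation(tsv)
#' width(ann)  # 300
#' @export
readGeneAnnotation <- function(path, format = c("auto", "gff3", "tsv"),
                               repliconOrder = NULL) {
    format <- match.arg(format)
    if (format == "auto") {
        format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE))
            "gff3" else "tsv"
    }
    if (!file.exists(path))
        stop("annotation file not found: ", path, call. = FALSE)
    if (format == "gff3") {
        gr <- rtracklayer::import(path, format = "gff3")
        keep <- mcols(gr)$type %in% "gene"
        if (!any(keep)) keep <- mcols(gr)$type %in% "CDS"
        gr <- gr[keep]
        mc <- mcols(gr)
        id <- mc$ID
        if (is.null(id)) id <- rep(NA_character_, length(gr))
        for (alt in c("locus_tag", "Name")) {
            if (!is.null(mc[[alt]]))
                id <- ifelse(is.na(id), as.character(mc[[alt]]), id)
        }
        if (anyNA(id))
            stop("GFF3 gene records without ID/locus_tag/Name attribute",
                 call. = FALSE)
        product <- if (!is.null(mc$product)) as.character(mc$product)
                   else rep(NA_character_, length(gr))
        ann <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                       strand = strand(gr))
        mcols(ann)$gene_id <- as.character(id)
        mcols(ann)$product <- product
    } else {
        first <- readLines(path, n = 1L)
        header <- startsWith(first, "gene_id")
        df <- utils::read.delim(path, header = header,
                                stringsAsFactors = FALSE)
        if (ncol(df) < 5L)
            stop("annotation TSV needs columns gene_id, replicon, start, ",
                 "end, strand[, product]", call. = FALSE)
        if (!header)
            colnames(df)[1:5] <- c("gene_id", "replicon", "start", "end",
                                   "strand")
        if (ncol(df) >= 6L && colnames(df)[6L] != "product")
            colnames(df)[6L] <- "product"
        bad <- which(df$end < df$start)
        if (length(bad))
            stop(sprintf("end < start at line %d (gene '%s')",
                bad[1L] + header, df$gene_id[bad[1L]]), call. = FALSE)
        ann <- GRanges(df$replicon, IRanges(df$start, df$end),
                       strand = df$strand)
        mcols(ann)$gene_id <- as.character(df$gene_id)
        mcols(ann)$product <- if ("product" %in% colnames(df))
            as.character(df$product) else NA_character_
    }
    dup <- mcols(ann)$gene_id[duplicated(mcols(ann)$gene_id)]
    if (length(dup))
        stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "),
             call. = FALSE)
    ann <- sortAnnotation(ann, repliconOrder)
    names(ann) <- mcols(ann)$gene_id
    ann
}

# (replicon, start) ascending; replicon order lexicographic unless given
sortAnnotation <- function(ann, repliconOrder = NULL) {
    lev <- if (is.null(repliconOrder)) sort(unique(as.character(seqnames(ann))))
           else repliconOrder
    lev <- union(lev, as.character(GenomeInfoDb::seqlevels(ann)))
    GenomeInfoDb::seqlevels(ann) <- lev
    ann[order(match(as.character(seqnames(ann)), lev), start(ann))]
}

#' Write a gene annotation
#'
#' Inverse of [readGeneAnnotation()]; coordinates are emitted 1-based
#' inclusive in both formats (the GFF3 convention; the TSV mirrors it).
#'
#' @param ann a `GRanges` annotation.
#' @param path output path.
#' @param format `"tsv"` or `"gff3"`.
#' @export
writeGeneAnnotation <- function(ann, path, format = c("tsv", "gff3")) {
    format <- match.arg(format)
    if (format == "tsv") {
        df <- data.frame(
            gene_id = mcols(ann)$gene_id,
            replicon = as.character(seqnames(ann)),
            start = start(ann), end = end(ann),
            strand = as.character(strand(ann)),
            product = mcols(ann)$product,
            stringsAsFactors = FALSE)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else {
        out <- ann
        mcols(out) <- NULL
        mcols(out)$type <- "gene"
        mcols(out)$ID <- mcols(ann)$gene_id
        mcols(out)$product <- mcols(ann)$product
        rtracklayer::export(out, path, format = "gff3")
    }
    invisible(path)
}

#' Construct a SalternExperiment from matrices and an annotation
#'
#' @param counts optional genes x samples matrix of mapped-read counts.
#' @param tpm optional genes x samples matrix of TPM values.
#' @param annotation `GRanges` from [readGeneAnnotation()]; rows of the
#'   matrices are matched to it by name and reordered to genome order.
#' @return A [SalternExperiment][SalternExperiment-class].
#' @export
SalternExperiment <- function(counts = NULL, tpm = NULL, annotation) {
    ids <- names(annotation)
    if (is.null(ids))
        stop("annotation must carry gene ids as names", call. = FALSE)
    asy <- list()
    for (nm in c("counts", "tpm")) {
        m <- switch(nm, counts = counts, tpm = tpm)
        if (is.null(m)) next
        m <- as.matrix(m)
        if (is.null(rownames(m)))
            stop(nm, " matrix needs gene ids as rownames", call. = FALSE)
        missing <- setdiff(ids, rownames(m))
        if (length(missing))
            stop(nm, " matrix is missing annotated genes: ",
                 paste(utils::head(missing, 5L), collapse = ", "),
                 call. = FALSE)
        unknown <- setdiff(rownames(m), ids)
        if (length(unknown))
            stop(nm, " matrix has genes absent from the annotation: ",
                 paste(utils::head(unknown, 5L), collapse = ", "),
                 call. = FALSE)
        asy[[nm]] <- m[ids, , drop = FALSE]
    }
    se <- SummarizedExperiment(assays = asy, rowRanges = annotation)
    new("SalternExperiment", se)
}

#' Read a per-gene count table
#'
#' Tab-separated, header row with sample names, first column gene ids.
#' Counts must be non-negative integers; every annotated gene must appear
#' unless `fillMissing = TRUE`, in which case absent genes get count 0
#' (reported via a message). Genes not present in the annotation are an
#' error.
#'
#' @param path path to the TSV count table.
#' @param annotation `GRanges` from [readGeneAnnotation()].
#' @param fillMissing fill genes absent from the file with 0 instead of
#'   failing.
#' @return A [SalternExperiment][SalternExperiment-class] with a `counts`
#'   assay.
#' @export
readCounts <- function(path, annotation, fillMissing = FALSE) {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("count table needs a gene_id column plus >= 1 sample",
             call. = FALSE)
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (anyDuplicated(ids))
        stop("duplicate gene_id in count table: ",
             ids[duplicated(ids)][1L], call. = FALSE)
    rownames(m) <- ids
    storage.mode(m) <- "double"
    bad <- which(!is.finite(m) | m < 0 | m != floor(m), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf(
            "invalid count for gene '%s', sample '%s' (must be a non-negative integer)",
            ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]), call. = FALSE)
    unknown <- setdiff(ids, names(annotation))
    if (length(unknown))
        stop("unknown gene_id in count table: ",
             paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
    missing <- setdiff(names(annotation), ids)
    if (length(missing)) {
        if (!fillMissing)
            stop(length(missing), " annotated genes missing from count ",
                 "table (first: ", missing[1L],
                 "); use fillMissing = TRUE to set them to 0", call. = FALSE)
        message("filling ", length(missing),
                " genes absent from the count table with 0")
        fill <- matrix(0, nrow = length(missing), ncol = ncol(m),
                       dimnames = list(missing, colnames(m)))
        m <- rbind(m, fill)
    }
    SalternExperiment(counts = m, annotation = annotation)
}

#' Write a count or TPM matrix as TSV
#'
#' @param x a [SalternExperiment][SalternExperiment-class].
#' @param path output path.
#' @param assay `"counts"` or `"tpm"`.
#' @export
writeMatrix <- function(x, path, assay = c("counts", "tpm")) {
    assay <- match.arg(assay)
    m <- SummarizedExperiment::assay(x, assay)
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read genomic intervals (BED)
#'
#' Reads 3+ column BED (0-based half-open) via [rtracklayer::import()] into
#' a 1-based inclusive `GRanges`. Unnamed intervals get names
#' `region_1, region_2, ...`. Overlapping intervals are kept with a
#' warning. An empty file yields an empty set.
#'
#' @param path path to the BED file.
#' @return A named `GRanges`.
#' @export
readIntervals <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines))
        return(GRanges())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    for (i in seq_along(fields)) {
        f <- fields[[i]]
        if (length(f) < 3L ||
            anyNA(suppressWarnings(as.numeric(f[2:3]))) ||
            as.numeric(f[3L]) < as.numeric(f[2L]))
            stop(sprintf("malformed BED line %d: '%s'", i, lines[i]),
                 call. = FALSE)
    }
    gr <- rtracklayer::import(path, format = "BED")
    nm <- mcols(gr)$name
    if (is.null(nm) || anyNA(nm))
        nm <- paste0("region_", seq_along(gr))
    if (anyDuplicated(nm))
        stop("duplicate interval names: ", nm[duplicated(nm)][1L],
             call. = FALSE)
    names(gr) <- nm
    mcols(gr) <- NULL
    if (sum(IRanges::countOverlaps(gr, gr) > 1L))
        warning("overlapping intervals in ", path, "; all kept",
                call. = FALSE)
    gr
}

#' Write intervals as BED (0-based half-open)
#'
#' @param gr a named `GRanges`.
#' @param path output path.
#' @param score optional numeric score per interval.
#' @export
writeIntervals <- function(gr, path, score = NULL) {
    out <- gr
    mcols(out) <- NULL
    mcols(out)$name <- names(gr)
    if (!is.null(score))
        mcols(out)$score <- score
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' Read paralog cluster membership
#'
#' Two-column TSV `cluster_id, gene_id` (header optional, detected by the
#' literal first cell `cluster_id`). Clusters must have at least two
#' members and a gene may belong to at most one cluster; violations are
#' errors.
#'
#' @param path path to the TSV.
#' @param annotation optional `GRanges`; membership of every gene in the
#'   annotation is then enforced.
#' @return A `ParalogClusters` object; see [clusterMembers()].
#' @export
readClusters <- function(path, annotation = NULL) {
    first <- readLines(path, n = 1L)
    header <- startsWith(first, "cluster_id")
    df <- utils::read.delim(path, header = header,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("cluster table needs columns cluster_id, gene_id",
             call. = FALSE)
    colnames(df)[1:2] <- c("cluster_id", "gene_id")
    if (!is.null(annotation)) {
        unknown <- setdiff(df$gene_id, names(annotation))
        if (length(unknown))
            stop("cluster member absent from annotation: ",
                 paste(utils::head(unknown, 5L), collapse = ", "),
                 call. = FALSE)
    }
    ParalogClusters(split(as.character(df$gene_id),
                          factor(df$cluster_id,
                                 levels = unique(df$cluster_id))))
}

#' @rdname readClusters
#' @param clusters a named list of character vectors (>= 2 gene ids each).
#' @export
ParalogClusters <- function(clusters) {
    new("ParalogClusters", clusters = lapply(clusters, as.character))
}

#' @rdname readClusters
#' @param x a `ParalogClusters` object.
#' @export
writeClusters <- function(x, path) {
    cl <- clusterMembers(x)
    df <- data.frame(
        cluster_id = rep(names(cl), lengths(cl)),
        gene_id = unlist(cl, use.names = FALSE),
        stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a published expression table (gene_id + TPM)
#'
#' Loads a printed expression table — such as the top-25 highest expressed
#' gene lists of the summer and winter populations shipped under
#' `inst/extdata/` — as a data frame usable with [topExpressed()] /
#' [topOverlap()].
#'
#' @param path TSV with header columns `gene_id` and `tpm` (extra columns
#'   kept).
#' @return A `data.frame` with at least `gene_id` and `tpm`.
#' @examples
#' t2 <- readExpressionTable(system.file("extdata",
#'     "table2_summer_top25.tsv", package = "salternSeasons"))
#' t2$gene_id[which.max(t2$tpm)]  # HQ_RS01075
#' @export
readExpressionTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "tpm") %in% colnames(df)))
        stop("expression table needs 'gene_id' and 'tpm' columns",
             call. = FALSE)
    if (anyDuplicated(df$gene_id))
        stop("duplicate gene_id in expression table", call. = FALSE)
    df
}
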