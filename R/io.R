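.readCountTable <- function(path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
        stop("duplicate gene identifiers in ", path)
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m))
        stop("non-numeric entries in ", path)
    if (any(m < 0)) stop("negative counts in ", path)
    if (any(abs(m - round(m)) > 1e-8))
        stop("non-integer counts in ", path,
             " (FPKM or other normalized rates are not valid input; ",
             "supply raw or TMM-effective integer counts)")
    rownames(m) <- ids
    m
}

#' Read paired count matrices from delimited text
#'
#' Both files must be TSV (or CSV, by extension) with a header row of sample
#' IDs and a first column of gene/transcript IDs. Rows of the post matrix
#' are realigned to the gene order of the pre matrix by ID; columns are
#' paired by position. Library sizes come from an optional TSV with columns
#' \code{sample}, \code{libPre}, \code{libPost} (one row per individual, in
#' column order), or default to the column sums of each matrix.
#'
#' @param prePath,postPath count matrix files.
#' @param libPath optional library-size file.
#' @return a \linkS4class{PairedCounts}.
#' @export
readPairedCounts <- function(prePath, postPath, libPath = NULL) {
    pre <- .readCountTable(prePath)
    post <- .readCountTable(postPath)
    if (ncol(pre) != ncol(post))
        stop("pre and post matrices have different numbers of individuals")
    if (!setequal(rownames(pre), rownames(post)))
        stop("gene identifiers differ between pre and post matrices")
    post <- post[rownames(pre), , drop = FALSE]
    if (!is.null(libPath)) {
        lib <- utils::read.table(libPath, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
        if (!all(c("libPre", "libPost") %in% colnames(lib)))
            stop("library-size file must have columns 'libPre' and 'libPost'")
        if (nrow(lib) != ncol(pre))
            stop("library-size file has ", nrow(lib), " rows but matrices have ",
                 ncol(pre), " individuals")
        libPre <- lib$libPre; libPost <- lib$libPost
    } else {
        libPre <- colSums(pre); libPost <- colSums(post)
    }
    PairedCounts(pre, post, libPre = libPre, libPost = libPost)
}

#' Write a PairedCounts object to delimited text
#'
#' @param data a \linkS4class{PairedCounts}.
#' @param prePath,postPath output TSV paths for the count matrices.
#' @param libPath optional output path for the library sizes.
#' @return invisibly, NULL.
#' @export
writePairedCounts <- function(data, prePath, postPath, libPath = NULL) {
    .writeMat <- function(m, path) {
        df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    .writeMat(countsPre(data), prePath)
    .writeMat(countsPost(data), postPath)
    if (!is.null(libPath)) {
        lib <- data.frame(sample = colnames(data),
                          libPre = libSizePre(data),
                          libPost = libSizePost(data))
        utils::write.table(lib, libPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(NULL)
}

#' Remove weakly expressed genes before analysis
#'
#' A gene is removed when, in the reference condition, its total count is
#' below \code{minTotal} OR it has zero counts in \code{kZero} or more
#' individuals. The default reference is the baseline (pre-treatment)
#' condition. With \code{reference = "both"}, totals are summed over both
#' conditions and an individual counts as zero only when both its counts
#' are zero.
#'
#' @param data a \linkS4class{PairedCounts}.
#' @param minTotal minimum total count in the reference condition
#'   (default 10).
#' @param kZero remove genes with zero counts in at least this many
#'   individuals (default 6); NULL selects the fractional rule
#'   ceiling(0.6 n), which reproduces the default when n = 10.
#' @param reference which condition the rule inspects.
#' @return list with elements \code{data} (filtered PairedCounts) and
#'   \code{removed} (data.frame: gene_id, low_total, many_zeros).
#' @export
filterLowExpression <- function(data, minTotal = 10, kZero = 6,
                                reference = c("pre", "post", "both")) {
    reference <- match.arg(reference)
    n <- ncol(data)
    if (is.null(kZero)) kZero <- ceiling(0.6 * n)
    ref <- switch(reference,
                  pre = countsPre(data),
                  post = countsPost(data),
                  both = countsPre(data) + countsPost(data))
    zeros <- switch(reference,
                    pre = rowSums(countsPre(data) == 0),
                    post = rowSums(countsPost(data) == 0),
                    both = rowSums(countsPre(data) == 0 &
                                   countsPost(data) == 0))
    lowTotal <- rowSums(ref) < minTotal
    manyZeros <- zeros >= kZero
    drop <- lowTotal | manyZeros
    if (all(drop))
        stop("filter removed all genes")
    removed <- data.frame(gene_id = rownames(data)[drop],
                          low_total = lowTotal[drop],
                          many_zeros = manyZeros[drop],
                          row.names = NULL)
    list(data = data[!drop, ], removed = removed)
}
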