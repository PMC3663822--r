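#' PairedCounts: paired RNA-seq count data
#'
#' Container for a paired RNA-seq experiment in which each individual
#' contributes a baseline (pre-treatment) and a post-treatment sample.
#' Extends \linkS4class{SummarizedExperiment} with two assays, \code{"pre"}
#' and \code{"post"}, whose columns are paired by individual, and per-sample
#' library sizes stored in \code{colData} (columns \code{libPre},
#' \code{libPost}).
#'
#' Library sizes are accepted as positive reals, not forced to integers:
#' between-sample normalization (e.g. trimmed-mean) is expected to happen
#' upstream, so effective sizes may be fractional.
#'
#' @slot .  inherits all slots from SummarizedExperiment.
#' @name PairedCounts-class
#' @aliases PairedCounts-class
#' @exportClass PairedCounts
setClass("PairedCounts", contains = "SummarizedExperiment")

.validPairedCounts <- function(object) {
    msg <- NULL
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("pre", "post") %in% an))
        return("assays 'pre' and 'post' are required")
    pre <- SummarizedExperiment::assay(object, "pre")
    post <- SummarizedExperiment::assay(object, "post")
    if (!identical(dim(pre), dim(post)))
        msg <- c(msg, "'pre' and 'post' assays must have identical dimensions")
    for (m in list(pre, post)) {
        if (!is.numeric(m))
            msg <- c(msg, "counts must be numeric")
        else {
            if (any(m < 0, na.rm = TRUE))
                msg <- c(msg, "counts must be non-negative")
            if (any(abs(m - round(m)) > 1e-8, na.rm = TRUE))
                msg <- c(msg, "counts must be integers (FPKM or other rate units are not valid input)")
            if (any(!is.finite(m)))
                msg <- c(msg, "counts must be finite")
        }
    }
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("libPre", "libPost") %in% colnames(cd))) {
        msg <- c(msg, "colData must contain 'libPre' and 'libPost'")
    } else {
        if (any(!is.finite(cd$libPre)) || any(cd$libPre <= 0))
            msg <- c(msg, "'libPre' library sizes must be positive and finite")
        if (any(!is.finite(cd$libPost)) || any(cd$libPost <= 0))
            msg <- c(msg, "'libPost' library sizes must be positive and finite")
    }
    if (is.null(msg)) TRUE else msg
}

setValidity("PairedCounts", .validPairedCounts)

#' Construct a PairedCounts object
#'
#' @param pre,post gene-by-individual matrices of non-negative integer counts;
#'   columns are paired by position (column i of both matrices is the same
#'   individual).
#' @param libPre,libPost per-individual library sizes (positive reals, e.g.
#'   TMM-normalized effective totals). Default: column sums of the respective
#'   count matrix.
#' @param geneIds gene/transcript identifiers; default taken from
#'   \code{rownames(pre)} or generated.
#' @return A \linkS4class{PairedCounts} object.
#' @examples
#' pre <- matrix(rpois(20, 5), nrow = 5)
#' post <- matrix(rpois(20, 5), nrow = 5)
#' pc <- PairedCounts(pre, post)
#' countsPre(pc)
#' @export
PairedCounts <- function(pre, post,
                         libPre = colSums(pre), libPost = colSums(post),
                         geneIds = rownames(pre)) {
    pre <- as.matrix(pre)
    post <- as.matrix(post)
    if (!identical(dim(pre), dim(post)))
        stop("'pre' and 'post' must have identical dimensions")
    if (is.null(geneIds))
        geneIds <- paste0("gene", seq_len(nrow(pre)))
    if (anyDuplicated(geneIds))
        stop("duplicate gene identifiers")
    rownames(pre) <- rownames(post) <- geneIds
    cn <- colnames(pre)
    if (is.null(cn)) cn <- paste0("ind", seq_len(ncol(pre)))
    colnames(pre) <- colnames(post) <- cn
    cd <- S4Vectors::DataFrame(libPre = as.numeric(libPre),
                               libPost = as.numeric(libPost),
                               row.names = cn)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(pre = pre, post = post), colData = cd)
    methods::new("PairedCounts", se)
}

#' @describeIn PairedCounts baseline (pre-treatment) count matrix
#' @param x a PairedCounts object
#' @export
countsPre <- function(x) SummarizedExperiment::assay(x, "pre")

#' @describeIn PairedCounts post-treatment count matrix
#' @export
countsPost <- function(x) SummarizedExperiment::assay(x, "post")

#' @describeIn PairedCounts baseline library sizes
#' @export
libSizePre <- function(x) SummarizedExperiment::colData(x)$libPre

#' @describeIn PairedCounts post-treatment library sizes
#' @export
libSizePost <- function(x) SummarizedExperiment::colData(x)$libPost

#' @describeIn PairedCounts number of individuals (pairs)
#' @export
nIndividuals <- function(x) ncol(x)
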