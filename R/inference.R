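#' Per-gene posterior summaries and DE calls
#'
#' @slot table data.frame with columns gene_id, p_de, fold_change,
#'   log2_fold_change, call (rows in input gene order).
#' @slot fdr estimated false discovery rate among genes called DE at the
#'   threshold; NA when no gene is called (never silently 0).
#' @slot threshold the posterior-probability threshold used.
#' @exportClass PosteriorSummary
setClass("PosteriorSummary",
    representation(table = "data.frame", fdr = "numeric",
                   threshold = "numeric"))

setValidity("PosteriorSummary", function(object) {
    msg <- NULL
    need <- c("gene_id", "p_de", "fold_change", "log2_fold_change", "call")
    if (!all(need %in% colnames(object@table)))
        msg <- c(msg, "table must have columns gene_id, p_de, fold_change, log2_fold_change, call")
    else {
        if (any(object@table$p_de < 0 | object@table$p_de > 1))
            msg <- c(msg, "p_de must lie in [0, 1]")
        if (any(object@table$fold_change <= 0))
            msg <- c(msg, "fold_change must be positive")
        if (!all(object@table$call %in% c("EE", "DE")))
            msg <- c(msg, "call must be 'EE' or 'DE'")
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "PosteriorSummary", function(object) {
    nde <- sum(object@table$call == "DE")
    cat("PosteriorSummary:", nrow(object@table), "genes |", nde,
        "called DE at p >", object@threshold, "\n")
    cat(" estimated FDR:",
        if (is.na(object@fdr)) "undefined (no gene called)"
        else signif(object@fdr, 4), "\n")
})

#' Posterior-mean fold change
#'
#' chi-hat_g = exp of the average of log chi_g over retained iterations,
#' i.e. the geometric mean of the sampled fold changes.
#'
#' @param trace a \linkS4class{ChainTrace} with at least one retained sample.
#' @return G-vector of positive fold-change estimates.
#' @export
posteriorFoldChange <- function(trace) {
    if (nRetained(trace) == 0L) stop("empty trace")
    exp(colMeans(log(chiSamples(trace))))
}

#' Posterior probability of differential expression
#'
#' p_g = proportion of retained sweeps in which z_g = 1.
#'
#' @param trace a \linkS4class{ChainTrace}.
#' @return G-vector of probabilities.
#' @export
posteriorDEProbability <- function(trace) {
    if (nRetained(trace) == 0L) stop("empty trace")
    colMeans(zSamples(trace))
}

#' Posterior-probability FDR estimate
#'
#' Mean of (1 - p_g) over genes with p_g strictly above the threshold. When
#' no gene exceeds the threshold the FDR is undefined and NA is returned
#' with a warning (never 0, which would be silently optimistic).
#'
#' @param pDE G-vector of posterior DE probabilities.
#' @param pThres threshold in (0, 1).
#' @return a single value in [0, 1], or NA.
#' @export
estimateFDR <- function(pDE, pThres = 0.5) {
    stopifnot(all(pDE >= 0 & pDE <= 1), pThres > 0, pThres < 1)
    sel <- pDE > pThres
    if (!any(sel)) {
        warning("no gene exceeds the threshold; FDR undefined")
        return(NA_real_)
    }
    mean(1 - pDE[sel])
}

#' Classify genes as DE or EE
#'
#' DE iff p_g > pThres (strict). The default threshold 0.5 is the Bayes rule
#' for the two-class case: assign the state with the larger posterior
#' probability.
#'
#' @param pDE G-vector of posterior DE probabilities.
#' @param pThres threshold in (0, 1).
#' @return character vector of "EE"/"DE".
#' @export
classifyDE <- function(pDE, pThres = 0.5) {
    stopifnot(pThres > 0, pThres < 1)
    ifelse(pDE > pThres, "DE", "EE")
}

#' Summarize a chain into per-gene results
#'
#' @param trace a \linkS4class{ChainTrace}.
#' @param pThres posterior-probability threshold for the DE call.
#' @param geneIds optional gene identifiers (default gene1..geneG).
#' @return a \linkS4class{PosteriorSummary}.
#' @export
posteriorSummary <- function(trace, pThres = 0.5, geneIds = NULL) {
    p <- posteriorDEProbability(trace)
    fc <- posteriorFoldChange(trace)
    if (is.null(geneIds)) geneIds <- paste0("gene", seq_along(p))
    tab <- data.frame(gene_id = as.character(geneIds), p_de = p,
                      fold_change = fc, log2_fold_change = log2(fc),
                      call = classifyDE(p, pThres),
                      stringsAsFactors = FALSE, row.names = NULL)
    fdr <- suppressWarnings(estimateFDR(p, pThres))
    methods::new("PosteriorSummary", table = tab, fdr = fdr,
                 threshold = pThres)
}

#' Rank genes for ROC-style comparisons
#'
#' Orders genes by posterior DE probability (descending), breaking ties by
#' absolute log fold change (descending).
#'
#' @param summary a \linkS4class{PosteriorSummary}.
#' @return integer vector of row indices into the summary table, best first.
#' @export
rankGenes <- function(summary) {
    tab <- summary@table
    order(-tab$p_de, -abs(log(tab$fold_change)))
}

#' Write the per-gene results table as TSV
#'
#' Columns gene_id, p_de, fold_change, log2_fold_change, call; header line;
#' rows in input gene order.
#'
#' @param summary a \linkS4class{PosteriorSummary}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeResults <- function(summary, path) {
    utils::write.table(summary@table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
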