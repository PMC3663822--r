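#' Hyperparameters of the two-component log-fold-change mixture
#'
#' Holds the mixing weight of the null (equal-expression) component and the
#' parameters of the two log-normal components for the fold change chi_g:
#' log(chi) ~ N(0, sigma0Sq) when z = 0 and N(mu1, sigma1Sq) when z = 1.
#' The non-null weight Pi1 is always 1 - pi0 (never stored separately).
#'
#' @slot pi0 probability of equal expression (z = 0), in [0, 1].
#' @slot sigma0Sq variance of the null log-fold-change component (> 0).
#' @slot mu1 mean of the non-null log-fold-change component.
#' @slot sigma1Sq variance of the non-null component (> 0).
#' @exportClass MixtureHyperparams
setClass("MixtureHyperparams",
    representation(pi0 = "numeric", sigma0Sq = "numeric",
                   mu1 = "numeric", sigma1Sq = "numeric"))

setValidity("MixtureHyperparams", function(object) {
    msg <- NULL
    if (length(object@pi0) != 1L || object@pi0 < 0 || object@pi0 > 1)
        msg <- c(msg, "'pi0' must be a single value in [0, 1]")
    if (length(object@sigma0Sq) != 1L || object@sigma0Sq <= 0)
        msg <- c(msg, "'sigma0Sq' must be a single positive value")
    if (length(object@sigma1Sq) != 1L || object@sigma1Sq <= 0)
        msg <- c(msg, "'sigma1Sq' must be a single positive value")
    if (length(object@mu1) != 1L || !is.finite(object@mu1))
        msg <- c(msg, "'mu1' must be a single finite value")
    if (is.null(msg)) TRUE else msg
})

#' @rdname MixtureHyperparams-class
#' @param pi0,sigma0Sq,mu1,sigma1Sq see class slots.
#' @return a \code{MixtureHyperparams} object.
#' @export
mixtureHyperparams <- function(pi0 = 0.9, sigma0Sq = 0.01, mu1 = 1.5,
                               sigma1Sq = 0.25) {
    methods::new("MixtureHyperparams", pi0 = pi0, sigma0Sq = sigma0Sq,
                 mu1 = mu1, sigma1Sq = sigma1Sq)
}

#' @rdname MixtureHyperparams-class
#' @param x a MixtureHyperparams object.
#' @export
pi1 <- function(x) 1 - x@pi0

setMethod("show", "MixtureHyperparams", function(object) {
    cat("MixtureHyperparams: Pi0 =", signif(object@pi0, 4),
        "| Pi1 =", signif(1 - object@pi0, 4), "\n",
        " null:     logFC ~ N(0,", signif(object@sigma0Sq, 4), ")\n",
        " non-null: logFC ~ N(", signif(object@mu1, 4), ",",
        signif(object@sigma1Sq, 4), ")\n")
})

#' Retained MCMC samples for the paired-count mixture model
#'
#' @slot chi T x G matrix of sampled fold changes (post-burn-in, thinned).
#' @slot z T x G matrix of sampled latent DE states (0/1).
#' @slot alpha,beta optional T x G matrices of Gamma shape/rate samples
#'   (0 x 0 unless retained).
#' @slot hyper T x 5 matrix with columns pi0, pi1, mu1, sigma0Sq, sigma1Sq.
#' @slot acceptance named per-block acceptance rates in [0, 1].
#' @slot config the sampler configuration used (list).
#' @exportClass ChainTrace
setClass("ChainTrace",
    representation(chi = "matrix", z = "matrix",
                   alpha = "matrix", beta = "matrix",
                   hyper = "matrix", acceptance = "numeric",
                   config = "list"))

setValidity("ChainTrace", function(object) {
    msg <- NULL
    if (!identical(dim(object@chi), dim(object@z)))
        msg <- c(msg, "'chi' and 'z' must have the same dimensions")
    if (ncol(object@hyper) != 5L ||
        !identical(colnames(object@hyper),
                   c("pi0", "pi1", "mu1", "sigma0Sq", "sigma1Sq")))
        msg <- c(msg, "'hyper' must have columns pi0, pi1, mu1, sigma0Sq, sigma1Sq")
    if (nrow(object@hyper) != nrow(object@chi))
        msg <- c(msg, "'hyper' and 'chi' must have the same number of rows")
    if (nrow(object@hyper) > 0) {
        if (max(abs(object@hyper[, "pi0"] + object@hyper[, "pi1"] - 1)) > 1e-12)
            msg <- c(msg, "each hyper row must satisfy pi0 + pi1 = 1")
        if (any(object@hyper[, c("sigma0Sq", "sigma1Sq")] <= 0))
            msg <- c(msg, "sampled variances must be positive")
    }
    if (any(object@chi <= 0))
        msg <- c(msg, "sampled fold changes must be positive")
    if (!all(object@z %in% c(0, 1)))
        msg <- c(msg, "'z' samples must be binary")
    if (is.null(msg)) TRUE else msg
})

#' @rdname ChainTrace-class
#' @param x a ChainTrace.
#' @export
chiSamples <- function(x) x@chi

#' @rdname ChainTrace-class
#' @export
zSamples <- function(x) x@z

#' @rdname ChainTrace-class
#' @export
hyperSamples <- function(x) x@hyper

#' @rdname ChainTrace-class
#' @export
alphaSamples <- function(x) x@alpha

#' @rdname ChainTrace-class
#' @export
betaSamples <- function(x) x@beta

#' @rdname ChainTrace-class
#' @export
acceptanceRates <- function(x) x@acceptance

#' @rdname ChainTrace-class
#' @export
nRetained <- function(x) nrow(x@chi)

setMethod("show", "ChainTrace", function(object) {
    cat("ChainTrace:", nrow(object@chi), "retained samples x",
        ncol(object@chi), "genes\n")
    hm <- colMeans(object@hyper)
    cat(" posterior means: Pi1 =", signif(hm["pi1"], 4),
        "| mu1 =", signif(hm["mu1"], 4),
        "| sigma0Sq =", signif(hm["sigma0Sq"], 4),
        "| sigma1Sq =", signif(hm["sigma1Sq"], 4), "\n")
    cat(" acceptance rates:",
        paste(names(object@acceptance),
              signif(object@acceptance, 3), collapse = ", "), "\n")
})
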