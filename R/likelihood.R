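#' Marginal log-likelihood of one gene's paired counts
#'
#' Log density of the observed pair of count vectors for a single gene under
#' the hierarchical Poisson-Gamma model, with the individual-level baseline
#' rate lambda_gi integrated out analytically. Each individual contributes
#'
#' \deqn{\log\Gamma(y_1+y_2+\alpha) - \log\Gamma(y_1+1) - \log\Gamma(y_2+1)
#'   - \log\Gamma(\alpha) + \alpha\log\frac{\beta}{\beta+N_1+N_2\chi}
#'   + y_1\log\frac{N_1}{\beta+N_1+N_2\chi}
#'   + y_2\log\frac{N_2\chi}{\beta+N_1+N_2\chi}}
#'
#' and the function returns the sum over individuals. All arithmetic is in
#' log space via \code{lgamma}; no Gamma function is evaluated directly, so
#' the result stays finite for counts well beyond 1e5. The normalizing
#' constants \code{-lgamma(y+1)} are retained so that the result is a true
#' log probability mass (they cancel in Metropolis-Hastings ratios anyway).
#'
#' @param yPre,yPost count vectors over individuals (same length).
#' @param libPre,libPost library sizes per individual (positive reals).
#' @param alpha,beta Gamma shape and rate of the gene's baseline rate (> 0).
#' @param chi fold change after treatment (> 0).
#' @return a single log density value.
#' @export
marginalLogLik <- function(yPre, yPost, libPre, libPost, alpha, beta, chi) {
    n <- length(yPre)
    if (length(yPost) != n || length(libPre) != n || length(libPost) != n)
        stop("count and library-size vectors must have equal length")
    if (!all(is.finite(c(alpha, beta, chi))) || alpha <= 0 || beta <= 0 ||
        chi <= 0)
        stop("'alpha', 'beta' and 'chi' must be positive and finite")
    if (any(yPre < 0) || any(yPost < 0))
        stop("counts must be non-negative")
    if (any(libPre <= 0) || any(libPost <= 0))
        stop("library sizes must be positive")
    denom <- beta + libPre + libPost * chi
    sum(lgamma(yPre + yPost + alpha) - lgamma(yPre + 1) - lgamma(yPost + 1) -
        lgamma(alpha) +
        alpha * (log(beta) - log(denom)) +
        yPre * (log(libPre) - log(denom)) +
        yPost * (log(libPost) + log(chi) - log(denom)))
}

#' Log-normal mixture prior density of a fold change
#'
#' Log density of the fold change chi under the mixture component selected by
#' the latent state z: LogNormal(0, sigma0Sq) for z = 0 (equal expression),
#' LogNormal(mu1, sigma1Sq) for z = 1 (differential expression). The 1/chi
#' Jacobian of the log transform is included, i.e. this is a proper density
#' on the chi scale.
#'
#' @param chi fold change(s), > 0.
#' @param z latent state(s), 0 or 1 (recycled against \code{chi}).
#' @param hyper a \linkS4class{MixtureHyperparams} object.
#' @return log density value(s).
#' @export
logFoldChangePrior <- function(chi, z, hyper) {
    if (any(chi <= 0)) stop("'chi' must be positive")
    if (!all(z %in% c(0, 1))) stop("'z' must be 0 or 1")
    stats::dlnorm(chi,
                  meanlog = ifelse(z == 1, hyper@mu1, 0),
                  sdlog = ifelse(z == 1, sqrt(hyper@sigma1Sq),
                                 sqrt(hyper@sigma0Sq)),
                  log = TRUE)
}

#' Marginal variance of a baseline count
#'
#' Variance of a Gamma-mixed Poisson count with library size N and baseline
#' rate lambda ~ Gamma(alpha, rate = beta):
#' Var(Y) = N (alpha/beta) (1 + N/beta), i.e. the Poisson mean inflated by
#' the between-individual rate variance.
#'
#' @param alpha,beta Gamma shape and rate (> 0).
#' @param lib library size N (> 0).
#' @return the marginal count variance.
#' @export
overdispersedVariance <- function(alpha, beta, lib) {
    if (any(alpha <= 0) || any(beta <= 0) || any(lib <= 0))
        stop("all arguments must be positive")
    lib * (alpha / beta) * (1 + lib / beta)
}
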