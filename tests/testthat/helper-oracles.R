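# Independent oracles and tiny fixtures shared across test files.

# log of the marginal likelihood for one individual's pair, by adaptive
# quadrature over the baseline rate lambda (Poisson x Poisson x Gamma),
# stabilized by factoring out the integrand's maximum.
quadratureMarginalLog <- function(y1, y2, N1, N2, alpha, beta, chi) {
    logf <- function(l)
        stats::dpois(y1, N1 * l, log = TRUE) +
        stats::dpois(y2, N2 * l * chi, log = TRUE) +
        stats::dgamma(l, alpha, rate = beta, log = TRUE)
    # the integrand is lambda^(y1+y2+alpha-1) exp(-(beta+N1+N2 chi) lambda)
    # up to constants, so gamma quantiles bracket all of its mass
    sh <- y1 + y2 + alpha
    rt <- beta + N1 + N2 * chi
    lims <- stats::qgamma(c(1e-14, 1 - 1e-14), shape = sh, rate = rt)
    C <- logf(stats::qgamma(0.5, shape = sh, rate = rt))
    q <- stats::integrate(function(l) exp(logf(l) - C), lims[1], lims[2],
                          rel.tol = 1e-12, subdivisions = 500L)$value
    C + log(q)
}

# 1-gene, 2-individual fixture used for the stationary-distribution oracles
tinyPairedCounts <- function() {
    PairedCounts(matrix(c(12L, 30L), 1), matrix(c(20L, 8L), 1),
                 libPre = c(100, 110), libPost = c(95, 105))
}

# CDF function from a density evaluated on a fine grid (log scale input)
gridCDF <- function(grid, logDens) {
    d <- exp(logDens - max(logDens))
    cdf <- cumsum(d)
    stats::approxfun(grid, cdf / cdf[length(cdf)], yleft = 0, yright = 1)
}
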