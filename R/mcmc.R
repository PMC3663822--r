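#' Sampler configuration
#'
#' @param nIter total number of MCMC sweeps.
#' @param burnin number of initial sweeps discarded (< nIter).
#' @param sigmaAlpha random-walk proposal sd for the Gamma shape alpha_g.
#' @param sigmaBeta random-walk proposal sd for the Gamma rate beta_g.
#' @param seed integer seed; the chain is fully deterministic given it.
#' @param thin keep every thin-th post-burn-in sweep.
#' @param pThres posterior-probability threshold for DE classification.
#' @param nSmallThreshold sample-size boundary for the small-sample proposal
#'   variance rule (see \code{\link{computeProposalMoments}}).
#' @param direction orientation of the log-ratio used for the fold-change
#'   proposal mean: \code{"postPre"} (log post-rate over pre-rate, the
#'   orientation consistent with chi multiplying the post-treatment rate) or
#'   \code{"prePost"}.
#' @param keepAlphaBeta retain per-gene alpha/beta samples in the trace
#'   (memory grows as T x G per parameter).
#' @param varianceFloor lower bound applied to proposal variances and to
#'   inverse-Gamma scale parameters to keep degenerate (zero-variance) genes
#'   from collapsing the chain.
#' @param verbose print progress every \code{reportEvery} sweeps.
#' @param reportEvery progress interval.
#' @return a classed list of settings.
#' @export
samplerConfig <- function(nIter = 12000, burnin = 8000, sigmaAlpha = 0.1,
                          sigmaBeta = 1, seed = 1L, thin = 1L, pThres = 0.5,
                          nSmallThreshold = 6L,
                          direction = c("postPre", "prePost"),
                          keepAlphaBeta = FALSE, varianceFloor = 1e-8,
                          verbose = FALSE, reportEvery = 1000L) {
    direction <- match.arg(direction)
    if (burnin < 0 || burnin >= nIter)
        stop("'burnin' must be non-negative and smaller than 'nIter'")
    if (sigmaAlpha <= 0 || sigmaBeta <= 0) stop("proposal sds must be positive")
    if (thin < 1) stop("'thin' must be >= 1")
    if (pThres <= 0 || pThres >= 1) stop("'pThres' must be in (0, 1)")
    structure(list(nIter = as.integer(nIter), burnin = as.integer(burnin),
                   sigmaAlpha = sigmaAlpha, sigmaBeta = sigmaBeta,
                   seed = as.integer(seed), thin = as.integer(thin),
                   pThres = pThres, nSmallThreshold = as.integer(nSmallThreshold),
                   direction = direction, keepAlphaBeta = keepAlphaBeta,
                   varianceFloor = varianceFloor, verbose = verbose,
                   reportEvery = as.integer(reportEvery)),
              class = "samplerConfig")
}

#' Data-driven moments of the fold-change proposal
#'
#' For each gene, the independence-chain proposal for chi_g is log-normal
#' with location M_g and variance V_g computed from the observed counts.
#' Only individuals with non-zero counts in both conditions contribute. M_g
#' is the median of the per-individual log rate ratios
#' log((y2/N2)/(y1/N1)) (or the reverse orientation for
#' \code{direction = "prePost"}). V_g is the variance of those values after
#' trimming at the 25th/75th percentiles when the number of individuals is
#' at least \code{nSmallThreshold}; for smaller sample sizes every V_g is
#' replaced by the median of the per-gene (untrimmed) variances. Genes with
#' fewer than two qualifying individuals receive M_g = 0 and the global
#' median V.
#'
#' @param data a \linkS4class{PairedCounts}.
#' @param nSmallThreshold boundary of the small-sample rule (default 6).
#' @param direction see \code{\link{samplerConfig}}.
#' @param varianceFloor lower bound for V_g.
#' @return list with numeric vectors \code{m} and \code{v} (length G).
#' @export
computeProposalMoments <- function(data, nSmallThreshold = 6L,
                                   direction = c("postPre", "prePost"),
                                   varianceFloor = 1e-8) {
    direction <- match.arg(direction)
    y1 <- countsPre(data); y2 <- countsPost(data)
    n1 <- libSizePre(data); n2 <- libSizePost(data)
    G <- nrow(y1); n <- ncol(y1)
    lr <- log(y2) - log(rep(n2, each = G)) - log(y1) + log(rep(n1, each = G))
    if (direction == "prePost") lr <- -lr
    qual <- y1 > 0 & y2 > 0
    lr[!qual] <- NA_real_
    nq <- rowSums(qual)
    m <- rep(0, G)
    v <- rep(NA_real_, G)
    usable <- nq >= 2L
    if (!any(usable))
        stop("no gene has >= 2 individuals with non-zero counts in both conditions")
    trim <- n >= nSmallThreshold
    for (g in which(usable)) {
        vals <- lr[g, qual[g, ]]
        m[g] <- stats::median(vals)
        if (trim) {
            q <- stats::quantile(vals, c(0.25, 0.75), names = FALSE)
            kept <- vals[vals >= q[1] & vals <= q[2]]
            v[g] <- if (length(kept) >= 2L) stats::var(kept) else stats::var(vals)
        } else {
            v[g] <- stats::var(vals)
        }
    }
    globalV <- stats::median(v, na.rm = TRUE)
    if (!is.finite(globalV)) globalV <- varianceFloor
    if (!trim) {
        v[] <- globalV            # small-sample rule: one shared proposal variance
    } else {
        v[!usable | !is.finite(v)] <- globalV
    }
    v <- pmax(v, varianceFloor)
    list(m = m, v = v)
}

# EM fit of the two-component normal mixture (one component pinned at mean
# 0) to the per-gene log-fold locations M_g. Used for the starting state:
# genes whose chi posterior is sharply pinned by high counts effectively
# keep their initial z (the cross-component proposal rarely lands inside
# the narrow likelihood window), so the initial labeling must already be
# mixture-consistent, not a fixed-threshold guess.
.emLogFoldMixture <- function(m, maxIter = 100L, tol = 1e-8) {
    s <- max(stats::mad(m, center = 0), 1e-3)
    z <- abs(m) > 2 * s
    pi1 <- min(max(mean(z), 0.01), 0.99)
    mu1 <- if (any(z)) mean(m[z]) else 0
    v0 <- max(stats::var(m[!z]), 1e-6)
    v1 <- if (sum(z) > 1) max(stats::var(m[z]), 1e-6) else 1
    ll0 <- -Inf
    for (i in seq_len(maxIter)) {
        d0 <- (1 - pi1) * stats::dnorm(m, 0, sqrt(v0))
        d1 <- pi1 * stats::dnorm(m, mu1, sqrt(v1))
        tot <- d0 + d1
        ll <- sum(log(tot))
        r1 <- d1 / tot
        pi1 <- min(max(mean(r1), 0.01), 0.99)
        w1 <- sum(r1)
        mu1 <- sum(r1 * m) / w1
        v0 <- max(sum((1 - r1) * m^2) / sum(1 - r1), 1e-6)
        v1 <- max(sum(r1 * (m - mu1)^2) / w1, 1e-6)
        if (is.finite(ll) && abs(ll - ll0) < tol * abs(ll)) break
        ll0 <- ll
    }
    list(pi1 = pi1, mu1 = mu1, v0 = v0, v1 = v1, resp1 = r1)
}
#' Initial chain state from the data
#'
#' @param data a \linkS4class{PairedCounts}.
#' @param props proposal moments from \code{\link{computeProposalMoments}}.
#' @param varianceFloor lower bound for variance estimates.
#' @return list with elements alpha, beta, chi, z, pi0, mu1, sigma0Sq,
#'   sigma1Sq.
#' @export
initializeChain <- function(data, props, varianceFloor = 1e-8) {
    y1 <- countsPre(data)
    n1 <- libSizePre(data)
    G <- nrow(y1)
    lam <- sweep(y1, 2, n1, "/")
    m <- rowMeans(lam)
    v <- apply(lam, 1, stats::var)
    beta0 <- pmin(pmax(m / pmax(v, 1e-12), 1e-3), 1e9)
    alpha0 <- pmax(m * beta0, 1e-3)
    chi0 <- exp(props$m)
    em <- .emLogFoldMixture(props$m)
    z0 <- as.integer(em$resp1 > 0.5)
    list(alpha = alpha0, beta = beta0, chi = chi0, z = z0,
         pi0 = 1 - em$pi1, mu1 = em$mu1, sigma0Sq = em$v0,
         sigma1Sq = em$v1)
}

# --- internal update blocks -------------------------------------------------
# All blocks operate on `state` (list: alpha, beta, chi, z, pi0, mu1,
# sigma0Sq, sigma1Sq) and `pre` (precomputed data: Y1, Y2, Ysum, S2, N1, N2,
# M1 = matrix(N1, G, n, byrow), G, n). They return the updated state; an
# `accepted` attribute carries the per-sweep acceptance fraction.

.checkFinite <- function(logr, ok, block) {
    bad <- ok & is.na(logr)
    if (any(bad))
        stop("non-finite log density in ", block, " update for gene(s) ",
             paste(utils::head(which(bad), 5), collapse = ", "))
}

.updateAlpha <- function(state, pre, sigmaProp) {
    G <- pre$G; n <- pre$n
    aOld <- state$alpha
    aNew <- aOld + stats::rnorm(G, 0, sigmaProp)
    ok <- aNew > 0
    aEval <- ifelse(ok, aNew, 1)
    # log of beta/(beta + N1 + N2*chi) summed over individuals
    D <- state$chi %o% pre$N2 + pre$M1 + state$beta
    L <- n * log(state$beta) - rowSums(log(D))
    llOld <- rowSums(lgamma(pre$Ysum + aOld)) - n * lgamma(aOld) + aOld * L
    llNew <- rowSums(lgamma(pre$Ysum + aEval)) - n * lgamma(aEval) + aEval * L
    logr <- llNew - llOld
    .checkFinite(logr, ok, "alpha")
    acc <- ok & log(stats::runif(G)) < logr
    state$alpha <- ifelse(acc, aNew, aOld)
    attr(state, "accepted") <- mean(acc)
    state
}

.updateBeta <- function(state, pre, sigmaProp) {
    G <- pre$G; n <- pre$n
    bOld <- state$beta
    bNew <- bOld + stats::rnorm(G, 0, sigmaProp)
    ok <- bNew > 0
    bEval <- ifelse(ok, bNew, 1)
    C2 <- state$chi %o% pre$N2 + pre$M1    # N1 + N2*chi, per gene x individual
    A <- pre$Ysum + state$alpha
    llOld <- n * state$alpha * log(bOld) - rowSums(A * log(C2 + bOld))
    llNew <- n * state$alpha * log(bEval) - rowSums(A * log(C2 + bEval))
    logr <- llNew - llOld
    .checkFinite(logr, ok, "beta")
    acc <- ok & log(stats::runif(G)) < logr
    state$beta <- ifelse(acc, bNew, bOld)
    attr(state, "accepted") <- mean(acc)
    state
}

# joint (chi, z) independence-chain move: propose z from the current mixing
# weight and chi from the data-driven log-normal proposal for that state;
# accept or reject the pair together. One log-space code path covers all
# four (z_old, z_new) combinations.
.updateChiZ <- function(state, pre, props) {
    G <- pre$G
    zNew <- stats::rbinom(G, 1L, 1 - state$pi0)
    propMean <- ifelse(zNew == 1L, props$m, 0)
    propSd <- sqrt(props$v)
    chiNew <- stats::rlnorm(G, propMean, propSd)
    A <- pre$Ysum + state$alpha
    C2 <- state$chi %o% pre$N2 + pre$M1
    C2new <- chiNew %o% pre$N2 + pre$M1
    logtOld <- pre$S2 * log(state$chi) - rowSums(A * log(C2 + state$beta))
    logtNew <- pre$S2 * log(chiNew) - rowSums(A * log(C2new + state$beta))
    mixSd <- c(sqrt(state$sigma0Sq), sqrt(state$sigma1Sq))
    mixMean <- c(0, state$mu1)
    lmixOld <- stats::dlnorm(state$chi, mixMean[state$z + 1L],
                             mixSd[state$z + 1L], log = TRUE)
    lmixNew <- stats::dlnorm(chiNew, mixMean[zNew + 1L], mixSd[zNew + 1L],
                             log = TRUE)
    lpropOld <- stats::dlnorm(state$chi, ifelse(state$z == 1L, props$m, 0),
                              propSd, log = TRUE)
    lpropNew <- stats::dlnorm(chiNew, propMean, propSd, log = TRUE)
    logr <- (lmixNew + logtNew - lpropNew) - (lmixOld + logtOld - lpropOld)
    .checkFinite(logr, rep(TRUE, G), "chi/z")
    acc <- log(stats::runif(G)) < logr
    state$chi <- ifelse(acc, chiNew, state$chi)
    state$z <- ifelse(acc, zNew, state$z)
    attr(state, "accepted") <- mean(acc)
    state
}

# conjugate draws for (sigma0Sq, mu1, sigma1Sq); an empty mixture component
# keeps its current values for that sweep (counted, reported once per run).
.updateVarianceHyper <- function(state, varianceFloor = 1e-8) {
    lz <- log(state$chi)
    n0 <- sum(state$z == 0L)
    n1 <- sum(state$z == 1L)
    skipped <- character(0)
    if (n0 > 0L) {
        scale0 <- max(0.5 * sum(lz[state$z == 0L]^2), varianceFloor)
        state$sigma0Sq <- scale0 / stats::rgamma(1, n0 / 2)
    } else skipped <- c(skipped, "null")
    if (n1 > 0L) {
        s1 <- sum(lz[state$z == 1L])
        state$mu1 <- stats::rnorm(1, s1 / n1, sqrt(state$sigma1Sq / n1))
        scale1 <- max(0.5 * sum((lz[state$z == 1L] - state$mu1)^2),
                      varianceFloor)
        state$sigma1Sq <- scale1 / stats::rgamma(1, n1 / 2)
    } else skipped <- c(skipped, "non-null")
    attr(state, "skipped") <- skipped
    state
}

.updateMixing <- function(state) {
    n0 <- sum(state$z == 0L)
    n1 <- sum(state$z == 1L)
    state$pi0 <- stats::rbeta(1, 1 + n0, 1 + n1)
    state
}

.precomputeData <- function(data) {
    Y1 <- countsPre(data); Y2 <- countsPost(data)
    G <- nrow(Y1); n <- ncol(Y1)
    N1 <- libSizePre(data); N2 <- libSizePost(data)
    list(Y1 = Y1, Y2 = Y2, Ysum = Y1 + Y2, S2 = rowSums(Y2),
         N1 = N1, N2 = N2, M1 = matrix(N1, G, n, byrow = TRUE),
         G = G, n = n)
}

#' Run the Metropolis-within-Gibbs sampler
#'
#' Executes, per sweep, the five update blocks in fixed order: (1)
#' random-walk MH on each Gamma shape alpha_g, (2) random-walk MH on each
#' Gamma rate beta_g (using the freshly updated alpha_g), (3) a joint
#' independence-chain MH move on the pair (chi_g, z_g), (4) conjugate
#' inverse-Gamma/Normal draws for (sigma0Sq, mu1, sigma1Sq), and (5) a
#' Dirichlet (Beta) draw for the mixing proportions. Post-burn-in samples
#' are retained at the configured thinning. The chain is deterministic given
#' \code{config$seed}.
#'
#' @param data a \linkS4class{PairedCounts}, already filtered
#'   (\code{\link{filterLowExpression}}).
#' @param config a \code{\link{samplerConfig}}.
#' @param init optional starting state (as from \code{\link{initializeChain}});
#'   computed from the data when NULL.
#' @param props optional proposal moments; computed when NULL.
#' @return a \linkS4class{ChainTrace}.
#' @export
runChain <- function(data, config = samplerConfig(), init = NULL,
                     props = NULL) {
    stopifnot(methods::is(data, "PairedCounts"))
    set.seed(config$seed)
    pre <- .precomputeData(data)
    if (is.null(props))
        props <- computeProposalMoments(data, config$nSmallThreshold,
                                        config$direction,
                                        config$varianceFloor)
    state <- if (is.null(init)) initializeChain(data, props,
                                                config$varianceFloor) else init
    Tkeep <- (config$nIter - config$burnin) %/% config$thin
    G <- pre$G
    chiS <- matrix(NA_real_, Tkeep, G)
    zS <- matrix(NA_integer_, Tkeep, G)
    hyperS <- matrix(NA_real_, Tkeep, 5,
                     dimnames = list(NULL, c("pi0", "pi1", "mu1",
                                             "sigma0Sq", "sigma1Sq")))
    keepAB <- isTRUE(config$keepAlphaBeta)
    alphaS <- if (keepAB) matrix(NA_real_, Tkeep, G) else matrix(0, 0, 0)
    betaS <- if (keepAB) matrix(NA_real_, Tkeep, G) else matrix(0, 0, 0)
    accSum <- c(alpha = 0, beta = 0, chi_z = 0)
    nSkip0 <- 0L; nSkip1 <- 0L
    k <- 0L
    for (it in seq_len(config$nIter)) {
        state <- .updateAlpha(state, pre, config$sigmaAlpha)
        accSum["alpha"] <- accSum["alpha"] + attr(state, "accepted")
        state <- .updateBeta(state, pre, config$sigmaBeta)
        accSum["beta"] <- accSum["beta"] + attr(state, "accepted")
        state <- .updateChiZ(state, pre, props)
        accSum["chi_z"] <- accSum["chi_z"] + attr(state, "accepted")
        state <- .updateVarianceHyper(state, config$varianceFloor)
        sk <- attr(state, "skipped")
        if ("null" %in% sk) nSkip0 <- nSkip0 + 1L
        if ("non-null" %in% sk) nSkip1 <- nSkip1 + 1L
        state <- .updateMixing(state)
        if (it > config$burnin &&
            (it - config$burnin) %% config$thin == 0L) {
            k <- k + 1L
            chiS[k, ] <- state$chi
            zS[k, ] <- state$z
            hyperS[k, ] <- c(state$pi0, 1 - state$pi0, state$mu1,
                             state$sigma0Sq, state$sigma1Sq)
            if (keepAB) { alphaS[k, ] <- state$alpha; betaS[k, ] <- state$beta }
        }
        if (config$verbose && it %% config$reportEvery == 0L)
            message(sprintf("sweep %d/%d | Pi1 = %.3f | mu1 = %.3f", it,
                            config$nIter, 1 - state$pi0, state$mu1))
    }
    if (nSkip0 + nSkip1 > 0L)
        warning("empty mixture component: hyperparameter draw skipped in ",
                nSkip0, " (null) / ", nSkip1, " (non-null) sweeps")
    methods::new("ChainTrace", chi = chiS, z = zS, alpha = alphaS,
                 beta = betaS, hyper = hyperS,
                 acceptance = accSum / config$nIter,
                 config = unclass(config))
}
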