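test_that("proposal location is the median log rate ratio (post over pre by default)", {
    pc <- PairedCounts(matrix(c(10L, 20L, 40L), 1),
                       matrix(c(20L, 40L, 80L), 1),
                       libPre = c(1, 1, 1), libPost = c(1, 1, 1))
    pm <- computeProposalMoments(pc)
    expect_equal(pm$m, log(2))
    # identical ratios: variance collapses to the floor
    expect_equal(pm$v, 1e-8)
    # printed (pre over post) orientation is the sign flip
    pm2 <- computeProposalMoments(pc, direction = "prePost")
    expect_equal(pm2$m, -log(2))
})

test_that("individuals with a zero count in either condition are excluded", {
    # without exclusion the zero pair would drag the median off log 3
    pc <- PairedCounts(matrix(c(0L, 10L, 10L, 10L), 1),
                       matrix(c(50L, 30L, 30L, 30L), 1),
                       libPre = rep(1, 4), libPost = rep(1, 4))
    pm <- computeProposalMoments(pc)
    expect_equal(pm$m, log(3))
})

test_that("genes with fewer than two qualifying individuals take fallback moments", {
    y1 <- rbind(c(5L, 5L, 5L), c(0L, 0L, 7L))
    y2 <- rbind(c(10L, 11L, 9L), c(3L, 2L, 0L))
    pc <- PairedCounts(y1, y2, libPre = rep(1, 3), libPost = rep(1, 3))
    pm <- computeProposalMoments(pc)
    expect_equal(pm$m[2], 0)
    expect_equal(pm$v[2], pm$v[1])  # global median V (one usable gene)
    # all genes unusable is a hard error
    pcBad <- PairedCounts(matrix(c(0L, 1L), 1), matrix(c(1L, 0L), 1),
                          libPre = c(1, 1), libPost = c(1, 1))
    expect_error(computeProposalMoments(pcBad), "non-zero")
})

test_that("proposal variance is IQR-trimmed for large n and shared for small n", {
    y2 <- c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 6L, 20L)
    pc <- PairedCounts(matrix(rep(1L, 10), 1), matrix(y2, 1),
                       libPre = rep(1, 10), libPost = rep(1, 10))
    vals <- log(y2)
    q <- quantile(vals, c(0.25, 0.75), names = FALSE)
    expected <- var(vals[vals >= q[1] & vals <= q[2]])
    pm <- computeProposalMoments(pc, nSmallThreshold = 6)
    expect_equal(pm$v, expected)
    expect_lt(pm$v, var(vals))   # trimming removes the outlier
    # small-sample rule: every gene gets the median per-gene variance
    y1s <- rbind(c(2L, 3L, 5L), c(4L, 9L, 2L), c(1L, 1L, 2L))
    y2s <- rbind(c(4L, 5L, 6L), c(8L, 3L, 7L), c(9L, 2L, 2L))
    pcs <- PairedCounts(y1s, y2s, libPre = rep(1, 3), libPost = rep(1, 3))
    pms <- computeProposalMoments(pcs, nSmallThreshold = 6)
    perGene <- apply(log(y2s) - log(y1s), 1, var)
    expect_equal(pms$v, rep(median(perGene), 3))
})

test_that("a vanishing proposal sd freezes the random-walk blocks", {
    pc <- tinyPairedCounts()
    pre <- pairedDE:::.precomputeData(pc)
    st <- list(alpha = 1.3, beta = 12, chi = 1.1, z = 1L, pi0 = 0.5,
               mu1 = 0, sigma0Sq = 0.1, sigma1Sq = 0.5)
    set.seed(1)
    for (i in 1:50) st <- pairedDE:::.updateAlpha(st, pre, 1e-13)
    expect_equal(unname(st$alpha), 1.3, tolerance = 1e-10)
    for (i in 1:50) st <- pairedDE:::.updateBeta(st, pre, 1e-12)
    expect_equal(unname(st$beta), 12, tolerance = 1e-10)
})

test_that("variance hyperparameter draws follow their conjugate conditionals", {
    lz0 <- rep(sqrt(0.5), 4)           # four null genes, sum of squares = 2
    lz1 <- c(0.8, 1.3, 1.7)
    mkState <- function() list(alpha = 1, beta = 1,
                               chi = exp(c(lz0, lz1)),
                               z = c(rep(0L, 4), rep(1L, 3)),
                               pi0 = 0.5, mu1 = 1, sigma0Sq = 0.2,
                               sigma1Sq = 0.3)
    set.seed(99)
    n <- 4000
    s0 <- mu <- s1 <- numeric(n)
    for (i in seq_len(n)) {
        st <- pairedDE:::.updateVarianceHyper(mkState())
        s0[i] <- st$sigma0Sq; mu[i] <- st$mu1; s1[i] <- st$sigma1Sq
    }
    # sigma0^2 ~ InvGamma(2, 1): P(X <= x) = P(Gamma(2) >= 1/x)
    ksa <- ks.test(s0, function(x) pgamma(1 / x, 2, lower.tail = FALSE))
    expect_gt(ksa$p.value, 0.01)
    # mu1 ~ Normal(mean(lz1), sigma1Sq/3) with sigma1Sq at its reset value
    ksb <- ks.test(mu, pnorm, mean(lz1), sqrt(0.3 / 3))
    expect_gt(ksb$p.value, 0.01)
    # sigma1^2 compounds over the fresh mu1: compare against an
    # independently coded oracle of the same two-stage draw
    set.seed(77)
    muO <- rnorm(n, mean(lz1), sqrt(0.3 / 3))
    s1O <- vapply(muO, function(m)
        0.5 * sum((lz1 - m)^2) / rgamma(1, 3 / 2), 0)
    ksc <- suppressWarnings(ks.test(s1, s1O))
    expect_gt(ksc$p.value, 0.01)
})

test_that("an empty mixture component retains its hyperparameters for the sweep", {
    st <- list(alpha = 1, beta = 1, chi = c(2, 3), z = c(1L, 1L),
               pi0 = 0.5, mu1 = 0.5, sigma0Sq = 0.123, sigma1Sq = 0.3)
    set.seed(5)
    out <- pairedDE:::.updateVarianceHyper(st)
    expect_equal(out$sigma0Sq, 0.123)   # null component empty: kept
    expect_false(out$sigma1Sq == 0.3)   # non-null component drawn
})

test_that("mixing proportions follow Beta(1 + n0, 1 + n1)", {
    st <- list(z = c(rep(0L, 90), rep(1L, 10)))
    set.seed(11)
    draws <- replicate(20000, pairedDE:::.updateMixing(st)$pi0)
    m <- mean(1 - draws)
    expect_lt(abs(m - 11 / 102), 3 * sd(1 - draws) / sqrt(length(draws)))
    # no genes: prior recovery, Dirichlet(1,1) = Uniform
    st0 <- list(z = integer(0))
    d0 <- replicate(20000, pairedDE:::.updateMixing(st0)$pi0)
    expect_gt(suppressWarnings(ks.test(d0, punif)$p.value), 0.01)
})

test_that("the chain is deterministic given the seed", {
    sim <- simulateModelBased(simulationConfig("modelBased", nGenes = 60,
                                               seed = 4))
    cfg <- samplerConfig(nIter = 80, burnin = 40, seed = 123)
    tr1 <- runChain(simData(sim), cfg)
    tr2 <- runChain(simData(sim), cfg)
    expect_identical(chiSamples(tr1), chiSamples(tr2))
    expect_identical(zSamples(tr1), zSamples(tr2))
    expect_identical(hyperSamples(tr1), hyperSamples(tr2))
})

test_that("trace dimensions, thinning and invariants hold", {
    sim <- simulateModelBased(simulationConfig("modelBased", nGenes = 50,
                                               seed = 9))
    tr <- runChain(simData(sim),
                   samplerConfig(nIter = 61, burnin = 21, thin = 2,
                                 seed = 2))
    expect_equal(nRetained(tr), 20)    # (61 - 21) %/% 2
    hs <- hyperSamples(tr)
    expect_true(all(abs(hs[, "pi0"] + hs[, "pi1"] - 1) < 1e-12))
    expect_true(all(hs[, c("sigma0Sq", "sigma1Sq")] > 0))
    expect_true(all(is.finite(chiSamples(tr))))
    expect_true(all(chiSamples(tr) > 0))
    expect_true(all(zSamples(tr) %in% 0:1))
    expect_true(validObject(tr))
    # boundary: burn-in 0 with a single sweep yields one retained sample
    tr1 <- runChain(simData(sim), samplerConfig(nIter = 1, burnin = 0,
                                                seed = 2))
    expect_equal(nRetained(tr1), 1)
})

test_that("MH acceptance rates are strictly between 0 and 1 on simulated data", {
    # moderate library sizes so the beta conditional has curvature on the
    # scale of the proposal sd
    cfg <- simulationConfig("modelBased", nGenes = 80, nIndividuals = 8,
                            libSizeRange = c(500, 2000), lambdaShape = 2,
                            lambdaRate = 20, seed = 21)
    tr <- runChain(simData(simulateModelBased(cfg)),
                   samplerConfig(nIter = 300, burnin = 100, seed = 3))
    acc <- acceptanceRates(tr)
    expect_true(all(acc > 0 & acc < 1))
})

test_that("alpha/beta samples are retained only on request", {
    sim <- simulateModelBased(simulationConfig("modelBased", nGenes = 30,
                                               seed = 14))
    tr <- runChain(simData(sim), samplerConfig(nIter = 30, burnin = 10,
                                               seed = 5))
    expect_equal(dim(alphaSamples(tr)), c(0L, 0L))
    trAB <- runChain(simData(sim),
                     samplerConfig(nIter = 30, burnin = 10, seed = 5,
                                   keepAlphaBeta = TRUE))
    expect_equal(dim(alphaSamples(trAB)), c(20L, 30L))
    expect_true(all(alphaSamples(trAB) > 0))
    expect_true(all(betaSamples(trAB) > 0))
})
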