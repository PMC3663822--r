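#' Simulation configuration
#'
#' Defaults depend on the mode. Model-based mode reproduces the validation
#' design of the model itself: 10,000 genes, 10 individuals, library sizes
#' Uniform(7e6, 1.8e7), baseline rates lambda ~ Gamma(shape 0.1, rate 1000),
#' 90\% null genes with log-fold sd 0.1 and 10\% non-null with mean 1.5 and
#' sd 0.5, and no minimum-fold filter. Empirical mode resamples gene rows of
#' a baseline count matrix: 5,000 genes, library sizes Uniform(1.8e6, 3e6),
#' null log-fold variance 4e-4, non-null log-fold N(0, 1), and non-null
#' genes with fold change below 1.4 redrawn.
#'
#' @param mode "modelBased" or "empirical".
#' @param nGenes,nIndividuals dimensions of the simulated matrices.
#' @param libSizeRange range (min, max) of the uniform library-size draw;
#'   pre- and post-treatment sizes are drawn independently.
#' @param lambdaShape,lambdaRate Gamma shape/rate of the baseline relative
#'   expression (model-based mode).
#' @param pi1 prior fraction of non-null (DE) genes.
#' @param sigma0 sd of the null log-fold-change component.
#' @param mu1,sigma1 mean and sd of the non-null log-fold-change component.
#' @param foldFilterMin minimum fold change (max(chi, 1/chi)) required of
#'   non-null genes; offending genes are redrawn. NULL disables the filter.
#' @param seed integer seed.
#' @return a classed list.
#' @export
simulationConfig <- function(mode = c("modelBased", "empirical"),
                             nGenes = NULL, nIndividuals = 10,
                             libSizeRange = NULL, lambdaShape = 0.1,
                             lambdaRate = 1000, pi1 = NULL, sigma0 = NULL,
                             mu1 = NULL, sigma1 = NULL,
                             foldFilterMin = NULL, seed = 1L) {
    mode <- match.arg(mode)
    if (mode == "modelBased") {
        if (is.null(nGenes)) nGenes <- 10000
        if (is.null(libSizeRange)) libSizeRange <- c(7e6, 1.8e7)
        if (is.null(pi1)) pi1 <- 0.1
        if (is.null(sigma0)) sigma0 <- 0.1
        if (is.null(mu1)) mu1 <- 1.5
        if (is.null(sigma1)) sigma1 <- 0.5
    } else {
        if (is.null(nGenes)) nGenes <- 5000
        if (is.null(libSizeRange)) libSizeRange <- c(1.8e6, 3e6)
        if (is.null(pi1)) pi1 <- 0.2
        if (is.null(sigma0)) sigma0 <- 0.02   # null log-fold variance 4e-4
        if (is.null(mu1)) mu1 <- 0
        if (is.null(sigma1)) sigma1 <- 1
        if (is.null(foldFilterMin)) foldFilterMin <- 1.4
    }
    if (libSizeRange[1] >= libSizeRange[2] || any(libSizeRange <= 0))
        stop("'libSizeRange' must be an increasing pair of positive values")
    if (lambdaShape <= 0 || lambdaRate <= 0)
        stop("Gamma parameters must be positive")
    if (pi1 < 0 || pi1 >= 1) stop("'pi1' must be in [0, 1)")
    if (sigma0 < 0 || sigma1 < 0) stop("sds must be non-negative")
    structure(list(mode = mode, nGenes = as.integer(nGenes),
                   nIndividuals = as.integer(nIndividuals),
                   libSizeRange = libSizeRange, lambdaShape = lambdaShape,
                   lambdaRate = lambdaRate, pi1 = pi1, sigma0 = sigma0,
                   mu1 = mu1, sigma1 = sigma1,
                   foldFilterMin = foldFilterMin, seed = as.integer(seed)),
              class = "simulationConfig")
}

#' Simulated paired dataset with known truth
#'
#' @slot data the simulated \linkS4class{PairedCounts}.
#' @slot trueChi,trueZ generating fold changes and DE states per gene.
#' @slot trueLambda G x n matrix of generating baseline rates.
#' @slot config the \code{\link{simulationConfig}} used.
#' @exportClass SimulatedDataset
setClass("SimulatedDataset",
    representation(data = "PairedCounts", trueChi = "numeric",
                   trueZ = "integer", trueLambda = "matrix",
                   config = "list"))

setValidity("SimulatedDataset", function(object) {
    G <- nrow(object@data)
    if (length(object@trueChi) != G || length(object@trueZ) != G)
        return("truth vectors must align with data rows")
    TRUE
})

setMethod("show", "SimulatedDataset", function(object) {
    cat("SimulatedDataset (", object@config$mode, "): ",
        nrow(object@data), " genes x ", ncol(object@data),
        " individuals | ", sum(object@trueZ), " true DE genes\n", sep = "")
})

#' @rdname SimulatedDataset-class
#' @param x a SimulatedDataset.
#' @export
simData <- function(x) x@data

#' @rdname SimulatedDataset-class
#' @export
trueChi <- function(x) x@trueChi

#' @rdname SimulatedDataset-class
#' @export
trueZ <- function(x) x@trueZ

.drawLogFold <- function(G, cfg) {
    z <- stats::rbinom(G, 1L, cfg$pi1)
    lf <- stats::rnorm(G, ifelse(z == 1L, cfg$mu1, 0),
                       ifelse(z == 1L, cfg$sigma1, cfg$sigma0))
    list(z = as.integer(z), logChi = lf)
}

#' Model-based paired count simulation
#'
#' Draws library sizes, Gamma baseline rates, the latent DE states, the
#' log-normal fold changes, and Poisson counts
#' Y_pre ~ Pois(N1 lambda), Y_post ~ Pois(N2 lambda chi), exactly the
#' generative model the sampler fits. Defaults reproduce the validation
#' design (see \code{\link{simulationConfig}}).
#'
#' @param cfg a \code{\link{simulationConfig}} with mode "modelBased".
#' @return a \linkS4class{SimulatedDataset}.
#' @export
simulateModelBased <- function(cfg = simulationConfig("modelBased")) {
    stopifnot(cfg$mode == "modelBased")
    set.seed(cfg$seed)
    G <- cfg$nGenes; n <- cfg$nIndividuals
    N1 <- stats::runif(n, cfg$libSizeRange[1], cfg$libSizeRange[2])
    N2 <- stats::runif(n, cfg$libSizeRange[1], cfg$libSizeRange[2])
    lambda <- matrix(stats::rgamma(G * n, shape = cfg$lambdaShape,
                                   rate = cfg$lambdaRate), G, n)
    zf <- .drawLogFold(G, cfg)
    if (!is.null(cfg$foldFilterMin)) {
        bad <- which(zf$z == 1L & abs(zf$logChi) < log(cfg$foldFilterMin))
        while (length(bad) > 0) {
            zf$logChi[bad] <- stats::rnorm(length(bad), cfg$mu1, cfg$sigma1)
            bad <- bad[abs(zf$logChi[bad]) < log(cfg$foldFilterMin)]
        }
    }
    chi <- exp(zf$logChi)
    y1 <- matrix(stats::rpois(G * n, lambda * rep(N1, each = G)), G, n)
    y2 <- matrix(stats::rpois(G * n, lambda * chi * rep(N2, each = G)), G, n)
    pc <- PairedCounts(y1, y2, libPre = N1, libPost = N2)
    methods::new("SimulatedDataset", data = pc, trueChi = chi, trueZ = zf$z,
                 trueLambda = lambda, config = unclass(cfg))
}

#' Empirical-style paired count simulation
#'
#' Resamples gene rows (with replacement) of a supplied baseline count
#' matrix to preserve its mean-specific dispersion, converts each resampled
#' row to relative expression (value over column total), assigns the first
#' ceil((1 - pi1) G) genes to the null component and the remainder to the
#' non-null component, and generates counts from the Poisson model with
#' uniform library sizes. Non-null log folds are drawn N(mu1, sigma1^2)
#' unless a nominal fold vector is supplied, in which case folds are sampled
#' from it. Non-null genes whose fold change (max(chi, 1/chi)) falls below
#' \code{foldFilterMin} are redrawn, keeping G fixed.
#'
#' @param baseline non-negative integer matrix (genes x individuals), e.g.
#'   from \code{\link{makeSurrogateBaseline}}.
#' @param cfg a \code{\link{simulationConfig}} with mode "empirical".
#' @param nominalFold optional vector of fold changes to sample non-null
#'   genes from (entries below the filter are ignored).
#' @return a \linkS4class{SimulatedDataset}.
#' @export
simulateEmpirical <- function(baseline, cfg = simulationConfig("empirical"),
                              nominalFold = NULL) {
    stopifnot(cfg$mode == "empirical")
    baseline <- as.matrix(baseline)
    if (any(baseline < 0) || any(baseline != round(baseline)))
        stop("'baseline' must contain non-negative integer counts")
    tot <- colSums(baseline)
    if (any(tot == 0)) stop("'baseline' has an all-zero column")
    if (ncol(baseline) < cfg$nIndividuals)
        stop("'baseline' has fewer individuals than requested")
    set.seed(cfg$seed)
    G <- cfg$nGenes; n <- cfg$nIndividuals
    idx <- sample.int(nrow(baseline), G, replace = TRUE)
    lambda <- sweep(baseline[idx, seq_len(n), drop = FALSE], 2,
                    tot[seq_len(n)], "/")
    nNull <- as.integer(ceiling((1 - cfg$pi1) * G))
    z <- c(rep(0L, nNull), rep(1L, G - nNull))
    logChi <- numeric(G)
    logChi[z == 0L] <- stats::rnorm(nNull, 0, cfg$sigma0)
    nAlt <- G - nNull
    if (nAlt > 0) {
        fmin <- if (is.null(cfg$foldFilterMin)) 0 else log(cfg$foldFilterMin)
        if (is.null(nominalFold)) {
            lf <- stats::rnorm(nAlt, cfg$mu1, cfg$sigma1)
            bad <- which(abs(lf) < fmin)
            while (length(bad) > 0) {
                lf[bad] <- stats::rnorm(length(bad), cfg$mu1, cfg$sigma1)
                bad <- bad[abs(lf[bad]) < fmin]
            }
        } else {
            pool <- log(nominalFold[nominalFold > 0])
            pool <- pool[abs(pool) >= fmin]
            if (length(pool) == 0)
                stop("no entry of 'nominalFold' passes the fold filter")
            lf <- sample(pool, nAlt, replace = TRUE)
        }
        logChi[z == 1L] <- lf
    }
    chi <- exp(logChi)
    N1 <- stats::runif(n, cfg$libSizeRange[1], cfg$libSizeRange[2])
    N2 <- stats::runif(n, cfg$libSizeRange[1], cfg$libSizeRange[2])
    y1 <- matrix(stats::rpois(G * n, lambda * rep(N1, each = G)), G, n)
    y2 <- matrix(stats::rpois(G * n, lambda * chi * rep(N2, each = G)), G, n)
    pc <- PairedCounts(y1, y2, libPre = N1, libPost = N2)
    methods::new("SimulatedDataset", data = pc, trueChi = chi, trueZ = z,
                 trueLambda = lambda, config = unclass(cfg))
}

#' Synthetic surrogate baseline count matrix
#'
#' Generates a long-tailed RNA-seq-like count matrix for use as the baseline
#' of \code{\link{simulateEmpirical}} when no real matrix is available. Gene
#' relative abundances are log-normal (heavy upper tail), per-gene
#' dispersions vary, and counts are Gamma-Poisson, so the mean-variance
#' relation is supra-Poisson as in real data. This is a synthetic surrogate,
#' not any study's data.
#'
#' @param nGenes,nIndividuals dimensions.
#' @param libSizeRange target range of column totals.
#' @param seed integer seed.
#' @return an integer count matrix.
#' @export
makeSurrogateBaseline <- function(nGenes = 5000, nIndividuals = 10,
                                  libSizeRange = c(1.8e6, 3e6), seed = 1L) {
    stopifnot(nGenes > 0, nIndividuals > 0)
    set.seed(seed)
    # inset draw keeps realized totals inside the configured range despite
    # Poisson noise in the column sums
    pad <- 0.04 * diff(libSizeRange)
    tot <- stats::runif(nIndividuals, libSizeRange[1] + pad,
                        libSizeRange[2] - pad)
    ab <- stats::rlnorm(nGenes, 0, 2)
    ab <- ab / sum(ab)
    disp <- stats::runif(nGenes, 0.05, 0.5)   # per-gene overdispersion
    mu <- ab %o% tot
    lam <- matrix(stats::rgamma(nGenes * nIndividuals, shape = 1 / disp,
                                rate = 1 / (disp * mu)), nGenes)
    # rescale each column so its expected total hits the drawn library
    # size; keeps per-gene between-individual dispersion, and realized
    # totals stay inside the configured range (Poisson noise only)
    lam <- sweep(lam, 2, tot / colSums(lam), "*")
    y <- matrix(stats::rpois(nGenes * nIndividuals, lam), nGenes)
    dimnames(y) <- list(paste0("gene", seq_len(nGenes)),
                        paste0("ind", seq_len(nIndividuals)))
    y
}

#' Write a simulated dataset and its truth to TSV files
#'
#' Writes the pre/post count matrices, library sizes, a per-gene truth table
#' and a JSON echo of the configuration into \code{dir}.
#'
#' @param sim a \linkS4class{SimulatedDataset}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSimulatedDataset <- function(sim, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    pc <- sim@data
    writePairedCounts(pc, file.path(dir, "counts_pre.tsv"),
                      file.path(dir, "counts_post.tsv"),
                      file.path(dir, "lib_sizes.tsv"))
    truth <- data.frame(gene_id = rownames(pc), true_chi = sim@trueChi,
                        true_z = sim@trueZ)
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg <- sim@config
    writeLines(paste0(names(cfg), ": ",
                      vapply(cfg, function(x)
                          paste(format(x, digits = 15), collapse = ", "),
                          character(1))),
               file.path(dir, "config.yaml"))
    invisible(dir)
}
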