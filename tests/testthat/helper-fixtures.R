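# Shared fixtures, built in code.

# raw vector with exactly the requested mean, SD and n
makeRaw <- function(m, s, n, seed = 7) {
    x <- withr_seedless_rnorm(n, seed)
    m + s * (x - mean(x)) / sd(x)
}

withr_seedless_rnorm <- function(n, seed) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    rnorm(n)
}

# independent quadrature oracle for E[S | X = x] under the normexp model,
# integrating the posterior of S over its effective support
quadratureSignal <- function(x, p) {
    lo <- max(0, x - p$mu - 12 * p$sigma)
    hi <- max(x - p$mu + 12 * p$sigma, lo + 20 * p$sigma)
    f <- function(s) s * dnorm(x - s, p$mu, p$sigma) * dexp(s, 1 / p$alpha)
    g <- function(s) dnorm(x - s, p$mu, p$sigma) * dexp(s, 1 / p$alpha)
    integrate(f, lo, hi, rel.tol = 1e-12)$value /
        integrate(g, lo, hi, rel.tol = 1e-12)$value
}

# the curated example network: six down-regulated miRNAs, four targets
exampleNetwork <- function() {
    edges <- exampleMtiEdges()
    edges$score <- NA_real_
    edges$source <- "validated"
    dirs <- setNames(rep("down", 6), unique(edges$mirna))
    buildNetwork(edges, dirs)
}

# minimal two-color experiment with the given normalized log ratios
# injected directly (bypasses background correction, which needs
# array-scale data); M equals the supplied matrix exactly
maeFromLog2 <- function(sampleLog2, group, base = 1000) {
    s <- base * 2^sampleLog2
    r <- matrix(base, nrow(sampleLog2), ncol(sampleLog2),
                dimnames = dimnames(sampleLog2))
    mae <- MirArrayExperiment(s, r, group = group)
    SummarizedExperiment::assay(mae, "sampleBg") <- s
    SummarizedExperiment::assay(mae, "referenceBg") <- r
    SummarizedExperiment::assay(mae, "M") <- sampleLog2
    SummarizedExperiment::assay(mae, "A") <- (log2(s) + log2(base)) / 2
    SummarizedExperiment::assay(mae, "Mnorm") <- sampleLog2
    mae
}
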