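test_that("lowess normalization removes constant and smooth bias", {
    set.seed(21)
    A <- runif(500, 4, 14)
    # constant bias
    Mc <- rep(0.7, 500)
    expect_true(all(abs(lowessNormalize(Mc, A)) < 1e-6))
    # planted smooth intensity-dependent bias
    M <- 0.5 * sin(A / 2) + rnorm(500, 0, 0.05)
    Mn <- lowessNormalize(M, A)
    refit <- lowess(A, Mn, f = 0.3, iter = 3)
    interior <- refit$x > quantile(A, 0.05) & refit$x < quantile(A, 0.95)
    expect_lt(max(abs(refit$y[interior])), 0.05)
    # idempotence: exact on trends the local-linear smoother reproduces,
    # approximate (well below the removed bias) on noisy data
    Ml <- 0.3 + 0.05 * A
    expect_lt(max(abs(lowessNormalize(lowessNormalize(Ml, A), A))), 1e-10)
    Mn2 <- lowessNormalize(Mn, A)
    expect_lt(max(abs(Mn2 - Mn)), 0.1 * 0.5)   # < 10% of the bias amplitude
    # degenerate A
    expect_warning(out <- lowessNormalize(M[1:20], rep(1, 20)), "identical")
    expect_equal(out, M[1:20] - mean(M[1:20]))
})

test_that("array tables round-trip through TSV and are validated", {
    sim <- simulateArrays(nProbes = 30, seed = 3,
                          plantedEffects = c("mir-x" = -1))
    d <- withr::local_tempdir()
    writeArrayTable(sim$mae, file.path(d, "int.tsv"), file.path(d, "meta.tsv"),
                    header = "config_hash=deadbeef")
    back <- readArrayTable(file.path(d, "int.tsv"), file.path(d, "meta.tsv"))
    expect_equal(SummarizedExperiment::assay(back, "sample"),
                 SummarizedExperiment::assay(sim$mae, "sample"))
    expect_equal(arrayGroups(back), arrayGroups(sim$mae))
    # duplicated (probe, array, channel) rows are rejected
    tab <- read.delim(file.path(d, "int.tsv"), comment.char = "#")
    write.table(rbind(tab, tab[1, ]), file.path(d, "dup.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readArrayTable(file.path(d, "dup.tsv"),
                                file.path(d, "meta.tsv")), "duplicated")
    # negative foregrounds are rejected by the class validity
    s <- SummarizedExperiment::assay(sim$mae, "sample")
    s[1, 1] <- -5
    expect_error(MirArrayExperiment(
        s, SummarizedExperiment::assay(sim$mae, "reference"),
        group = arrayGroups(sim$mae)), "non-negative")
})

test_that("cross-group comparisons enumerate all neuropathy/control pairs", {
    l2 <- matrix(rnorm(40, 5), 10, 4,
                 dimnames = list(sprintf("p%02d", 1:10),
                                 c("c1", "c2", "n1", "n2")))
    mae <- maeFromLog2(l2, c("control", "control", "neuropathy", "neuropathy"))
    cmp <- crossGroupComparisons(mae)
    expect_identical(ncol(cmp), 4L)   # 2 x 2 arrays
    expect_setequal(colnames(cmp), c("n1/c1", "n1/c2", "n2/c1", "n2/c2"))
    expect_equal(cmp[, "n1/c1"], l2[, "n1"] - l2[, "c1"])

    one <- maeFromLog2(l2[, c(1, 3)], c("control", "neuropathy"))
    expect_identical(ncol(crossGroupComparisons(one)), 1L)

    # identical arrays in both groups give all-zero ratios
    m <- l2[, c(1, 1, 1, 1)]
    colnames(m) <- c("a", "b", "c", "d")
    same <- maeFromLog2(m, c("control", "control", "neuropathy", "neuropathy"))
    expect_lt(max(abs(crossGroupComparisons(same))), 1e-12)
})

test_that("selection rule tiers calls by magnitude and significance", {
    res <- classifyDE(meanLog2 = c(-1.95, 0.63, -0.50, 1.2, -0.7),
                      pValue = c(0.03, 0.20, 0.001, NA, 0.04))
    expect_equal(res$direction, c("down", "up", "none", "up", "down"))
    expect_equal(res$tier, c("significant", "candidate", "not_selected",
                             "candidate",    # missing p caps the tier
                             "significant"))
})

test_that("planted differential expression is recovered on 2v2 arrays", {
    sim <- simulateArrays(seed = 1)
    mae <- normalizeArrays(backgroundCorrectArrays(sim$mae))
    de <- callDifferentialExpression(mae)
    m <- merge(de, sim$truth, by.x = "mirna", by.y = "probe")
    planted <- m[m$true_log2_effect != 0, ]
    null <- m[m$true_log2_effect == 0, ]
    expect_identical(nrow(planted), 8L)
    # all eight directions recovered
    expect_true(all(sign(planted$mean_log2_ratio) ==
                    sign(planted$true_log2_effect)))
    # magnitude: median absolute error under 0.3 log2 units
    expect_lt(median(abs(planted$mean_log2_ratio - planted$true_log2_effect)),
              0.3)
    # no null probe crosses the selection threshold
    expect_true(all(abs(null$mean_log2_ratio) < 0.6))
    # effects clearly above the cut are selected (candidate or better)
    clear <- planted[abs(planted$true_log2_effect) >= 0.86, ]
    expect_true(all(clear$tier %in% c("candidate", "significant")))
})

test_that("detection filtering excludes low-intensity probes only", {
    sim <- simulateArrays(seed = 4)
    mae <- normalizeArrays(backgroundCorrectArrays(sim$mae))
    all <- callDifferentialExpression(mae, detectQuantile = 0)
    some <- callDifferentialExpression(mae, detectQuantile = 0.2)
    expect_identical(nrow(all), 300L)
    expect_lt(nrow(some), 300L)
    expect_true(all(some$mirna %in% all$mirna))
})

test_that("normalization flattens the dye-bias trend in M", {
    sim <- simulateArrays(seed = 8, plantedEffects = setNames(numeric(0),
                                                              character(0)))
    mae <- normalizeArrays(backgroundCorrectArrays(sim$mae))
    trend <- function(M, A) {
        f <- lowess(A, M, f = 0.3, iter = 3)
        max(abs(f$y[f$x > quantile(A, 0.05) & f$x < quantile(A, 0.95)]))
    }
    A <- SummarizedExperiment::assay(mae, "A")[, 1]
    raw <- trend(SummarizedExperiment::assay(mae, "M")[, 1], A)
    norm <- trend(SummarizedExperiment::assay(mae, "Mnorm")[, 1], A)
    expect_gt(raw, 0.2)    # the planted bias is visible pre-normalization
    expect_lt(norm, 0.05)  # and removed afterwards
})
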