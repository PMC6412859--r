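ctFrom <- function(...) {
    # build a Ct table from per-assay named lists of control/neuropathy Cp
    assays <- list(...)
    do.call(rbind, lapply(names(assays), function(a) {
        cp <- assays[[a]]
        n <- length(cp$ctl)
        m <- length(cp$neu)
        data.frame(sample_id = c(sprintf("c%d", 1:n), sprintf("t%d", 1:m)),
                   group = rep(c("control", "neuropathy"), c(n, m)),
                   assay = a, cp = c(cp$ctl, cp$neu),
                   stringsAsFactors = FALSE)
    }))
}

test_that("abundance classes follow the delta-Ct thresholds", {
    expect_equal(classifyAbundance(25, 20), "high")          # delta 5
    expect_equal(classifyAbundance(31, 20), "low")           # delta 11
    expect_equal(classifyAbundance(20, 20), "high")          # the reference
    expect_equal(classifyAbundance(28, 20), "intermediate")  # delta 8
    # boundaries are intermediate (strict inequalities)
    expect_equal(classifyAbundance(26, 20), "intermediate")
    expect_equal(classifyAbundance(30, 20), "intermediate")
    expect_error(classifyAbundance(NA, 20), "finite")
})

test_that("miRNA group change recovers a planted log2 shift", {
    assays <- data.frame(assay = "rno-miR-1-3p", baseline_cp = 19,
                         planted_log2_effect = -2.85)
    sim <- simulateCt(assays, nSamplesPerGroup = 6, sdCt = 0.2, seed = 17)
    res <- mirnaGroupChange(sim$ct, "rno-miR-1-3p")
    expect_true(res$detected)
    expect_lt(abs(res$mean_log2_change - (-2.85)), 0.3)
    # fold change consistent with the log2 estimate, near -7.21
    expect_equal(res$signed_fold_change,
                 signedFoldChange(res$mean_log2_change))
    expect_lt(abs(res$signed_fold_change - (-7.21)), 7.21 * (2^0.3 - 1))
    expect_lt(res$p_value, 0.01)
    expect_equal(res$direction, "down")
})

test_that("identical groups give zero change and unit fold change", {
    ct <- ctFrom(x = list(ctl = c(25, 25.2, 24.8), neu = c(25, 25.2, 24.8)))
    res <- mirnaGroupChange(ct, "x")
    expect_equal(res$mean_log2_change, 0)
    expect_equal(res$signed_fold_change, 1)
})

test_that("undetected assays are reported n.d.", {
    ct <- ctFrom(x = list(ctl = c(25, 26, 24), neu = c(25, 26, 24)),
                 y = list(ctl = rep(NA_real_, 3), neu = rep(NA_real_, 3)))
    res <- mirnaGroupChange(ct, "y")
    expect_false(res$detected)
    expect_equal(res$direction, "n.d.")
    expect_true(is.na(res$mean_log2_change))
})

test_that("group swap negates the log2 change exactly", {
    sim <- simulateCt(data.frame(assay = "a", baseline_cp = 28,
                                 planted_log2_effect = 1.4),
                      seed = 23)
    ct <- sim$ct
    swapped <- ct
    swapped$group <- ifelse(ct$group == "control", "neuropathy", "control")
    expect_equal(mirnaGroupChange(swapped, "a")$mean_log2_change,
                 -mirnaGroupChange(ct, "a")$mean_log2_change)
})

test_that("ddCp arithmetic on forced values is exact", {
    ct <- ctFrom(gene = list(ctl = c(25, 25, 25), neu = c(24, 24, 24)),
                 ref = list(ctl = c(20, 20, 20), neu = c(20, 20, 20)))
    suppressWarnings(res <- ddcpRelativeLevel(ct, "gene", "ref"))
    expect_equal(res$perSample$level[res$perSample$group == "control"],
                 rep(1, 3))
    expect_equal(res$perSample$level[res$perSample$group == "neuropathy"],
                 rep(2, 3))
    expect_equal(res$ratio, 2)
    # all samples identical -> every level 1
    same <- ctFrom(gene = list(ctl = c(25, 25), neu = c(25, 25)),
                   ref = list(ctl = c(20, 20), neu = c(20, 20)))
    suppressWarnings(r2 <- ddcpRelativeLevel(same, "gene", "ref"))
    expect_equal(r2$perSample$level, rep(1, 4))
})

test_that("control calibration anchors the control geometric mean at 1", {
    sim <- simulateCt(defaultMrnaCtAssays(), sdCt = 0.15,
                      sampleShiftSd = 0.5, seed = 31)
    res <- ddcpRelativeLevel(sim$ct, "IGF-1", "GAPDH")
    ctlLevels <- res$perSample$level[res$perSample$group == "control"]
    expect_equal(exp(mean(log(ctlLevels))), 1, tolerance = 1e-12)
})

test_that("ddCp recovers a planted 1.8-fold increase within 15%", {
    sim <- simulateCt(defaultMrnaCtAssays(), nSamplesPerGroup = 6,
                      sdCt = 0.15, sampleShiftSd = 0.5, seed = 41)
    for (g in c("IGF-1", "SLC2a-12", "EIF-4e", "ULK-2")) {
        res <- ddcpRelativeLevel(sim$ct, g, "GAPDH")
        expect_lt(abs(res$ratio - 1.8) / 1.8, 0.15)
        expect_lt(res$p_value, 0.05)
    }
})

test_that("efficiency correction generalizes the base-2 method", {
    ct <- ctFrom(gene = list(ctl = c(25, 25, 25), neu = c(24, 24, 24)),
                 ref = list(ctl = c(20, 20, 20), neu = c(20, 20, 20)))
    reg <- function(eT, eR) data.frame(target = c("gene", "ref"),
                                       efficiency = c(eT, eR))
    # perfect doubling reproduces the classical method
    suppressWarnings({
        e2 <- efficiencyCorrectedLevel(ct, "gene", "ref", reg(2, 2))
        b2 <- ddcpRelativeLevel(ct, "gene", "ref")
    })
    expect_equal(e2$perSample$level,
                 b2$perSample$level[match(e2$perSample$sample_id,
                                          b2$perSample$sample_id)])
    # ddCp = -1 at efficiency 1.966 gives level 1.966
    suppressWarnings(e196 <- efficiencyCorrectedLevel(ct, "gene", "ref",
                                                      reg(1.966, 2)))
    expect_equal(e196$ratio, 1.966, tolerance = 1e-12)
    # efficiency near 1: no amplification, no discrimination
    suppressWarnings(e1 <- efficiencyCorrectedLevel(ct, "gene", "ref",
                                                    reg(1.0001, 2)))
    expect_lt(abs(e1$ratio - 1), 1e-3)
    expect_error(efficiencyCorrectedLevel(ct, "gene", "ref", reg(2.5, 2)),
                 "efficiency")
    expect_error(efficiencyCorrectedLevel(ct, "gene", "ref", reg(1.0, 2)),
                 "efficiency")
})

test_that("array and qRT-PCR calls reconcile as printed", {
    rec <- reconcileCalls(exampleArrayCalls(), exampleQpcrValidation())
    expect_equal(unname(rec$summary["n_confirmed"]), 6)
    expect_equal(unname(rec$summary["n_down"]), 7)
    expect_equal(unname(rec$summary["n_up"]), 1)
    calls <- rec$calls
    row <- function(m) calls[calls$mirna == m, ]
    # array-up but qPCR significantly down: overruled, not confirmed
    expect_equal(row("rno-miR-34b-3p")$confirmation, "no")
    expect_equal(row("rno-miR-34b-3p")$final_direction, "down")
    # not detectable by qPCR: n.d., array call stands
    expect_equal(row("rno-miR-344b-1-3p")$confirmation, "n.d.")
    expect_equal(row("rno-miR-344b-1-3p")$final_direction, "down")
    # concordant significant call: confirmed
    expect_equal(row("rno-miR-1-3p")$confirmation, "yes")
    expect_equal(row("rno-miR-1-3p")$final_direction, "down")
})

test_that("reconciliation handles edge cases", {
    arr <- data.frame(mirna = c("m1", "m2"), direction = c("down", "down"))
    # every selected miRNA needs a qPCR entry
    qp1 <- data.frame(assay = "m1", detected = TRUE, direction = "down",
                      significant = TRUE)
    expect_error(reconcileCalls(arr, qp1), "m2")
    # detected but non-significant: not confirmed, array call stands, flagged
    qp2 <- rbind(qp1, data.frame(assay = "m2", detected = TRUE,
                                 direction = "up", significant = FALSE))
    rec <- reconcileCalls(arr, qp2)
    m2 <- rec$calls[rec$calls$mirna == "m2", ]
    expect_equal(m2$confirmation, "no")
    expect_equal(m2$final_direction, "down")
    expect_equal(m2$flag, "qpcr_nonsignificant")
    # empty selection reconciles to an empty, valid summary
    empty <- reconcileCalls(arr[0, ], qp2)
    expect_identical(nrow(empty$calls), 0L)
    expect_equal(unname(empty$summary["n_confirmed"]), 0L)
})
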