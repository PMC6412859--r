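writeMti <- function(df, dir, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
}

test_that("MTI sources load with per-dialect validation", {
    d <- withr::local_tempdir()
    hg <- data.frame(mirna = sprintf("mir-%d", 1:10), target = "G1",
                     score = 90)
    lg <- data.frame(mirna = sprintf("mir-%d", 1:10), target = "G2",
                     score = -2)
    va <- data.frame(mirna = sprintf("mir-%d", 1:10), target = "G3")
    paths <- c(writeMti(hg, d, "hg.tsv"), writeMti(lg, d, "lg.tsv"),
               writeMti(va, d, "va.tsv"))
    rec <- loadMtiSources(paths, c("predicted_high_good",
                                   "predicted_low_good", "validated"))
    expect_identical(nrow(rec), 30L)
    expect_identical(attr(rec, "n_rejected"), 0L)

    # a predicted row without a score is rejected and counted
    hg2 <- hg
    hg2$score[3] <- NA
    expect_message(r2 <- readMtiTable(writeMti(hg2, d, "hg2.tsv"),
                                      "predicted_high_good"), "rejected")
    expect_identical(nrow(r2), 9L)
    expect_identical(attr(r2, "n_rejected"), 1L)

    # validated rows never need a score
    r3 <- readMtiTable(paths[3], "validated")
    expect_identical(nrow(r3), 10L)

    expect_error(readMtiTable(paths[1], "not_a_dialect"), "dialect")

    # duplicate rows survive loading; de-duplication happens at edge level
    dup <- rbind(hg, hg[1, ])
    r4 <- readMtiTable(writeMti(dup, d, "dup.tsv"), "predicted_high_good")
    expect_identical(nrow(r4), 11L)
})

test_that("score filters remove poor predictions at the printed boundaries", {
    rec <- data.frame(
        mirna = "m", target = sprintf("t%d", 1:6),
        source = c("predicted_high_good", "predicted_high_good",
                   "predicted_low_good", "predicted_low_good",
                   "validated", "validated"),
        score = c(80.0, 80.1, -1.2, -1.5, NA, NA),
        stringsAsFactors = FALSE)
    kept <- filterMti(rec)
    expect_setequal(kept$target, c("t2", "t4", "t5", "t6"))
    # idempotent
    expect_identical(filterMti(kept), kept)
    # monotone under tightening
    tighter <- filterMti(rec, highGoodMin = 90, lowGoodMax = -2)
    expect_true(all(paste(tighter$mirna, tighter$target) %in%
                    paste(kept$mirna, kept$target)))
})

test_that("the network is a deduplicated bipartite union over sources", {
    rec <- data.frame(
        mirna = c("mir-a", "MIR-A", "mir-b"),
        target = c("G1", "G1", "G1"),
        source = c("predicted_high_good", "validated", "validated"),
        score = c(95, NA, NA), stringsAsFactors = FALSE)
    net <- buildNetwork(rec, c("mir-a" = "down", "mir-b" = "down"))
    e <- networkEdges(net)
    expect_identical(nrow(e), 2L)   # case-insensitive merge of mir-a rows
    expect_equal(e$sources[e$mirna == "mir-a"],
                 "predicted_high_good;validated")
    # records without a direction are dropped with a message
    expect_message(
        net2 <- buildNetwork(rbind(rec, data.frame(
            mirna = "mir-z", target = "G9", source = "validated",
            score = NA)), c("mir-a" = "down", "mir-b" = "down")),
        "dropped")
    expect_false("G9" %in% targetNodes(net2))
    # empty input gives a valid empty network
    empty <- buildNetwork(rec[0, ], c("mir-a" = "down"))
    expect_identical(nrow(networkEdges(empty)), 0L)
    expect_length(mirnaNodes(empty), 0)
})

test_that("the curated example network has the printed structure", {
    net <- exampleNetwork()
    expect_length(mirnaNodes(net), 6)
    expect_length(targetNodes(net), 4)
    expect_identical(nrow(networkEdges(net)), 12L)
    # bipartite handshake: miRNA degrees and target degrees both sum to
    # the edge count
    e <- networkEdges(net)
    expect_equal(sum(targetDegree(net)), nrow(e))
    expect_equal(sum(table(e$mirna)), nrow(e))
})

test_that("hub selection finds the four degree-3 targets, predicted up", {
    hubs <- findHubs(exampleNetwork(), minDegree = 3)
    expect_setequal(hubs$target, c("IGF-1", "SLC2a-12", "EIF-4e", "ULK-2"))
    expect_true(all(hubs$degree == 3))
    expect_true(all(hubs$predicted_direction == "up"))
    # IGF-1 is regulated by the printed trio
    expect_equal(hubs$regulators[hubs$target == "IGF-1"],
                 "rno-miR-1-3p;rno-miR-206-3p;rno-miR-466b-1-3p")
    # empty network -> no hubs
    empty <- buildNetwork(networkEdges(exampleNetwork())[0, ],
                          c("x" = "down"))
    expect_identical(nrow(findHubs(empty)), 0L)
})

test_that("direction prediction follows the regulator consensus", {
    expect_equal(predictTargetDirection(c("down", "down", "down")), "up")
    expect_equal(predictTargetDirection(c("up", "up", "up")), "down")
    expect_equal(predictTargetDirection(c("down", "down", "up")), "ambiguous")
    expect_equal(predictTargetDirection(c("down", "down", "up"),
                                        rule = "majority"), "up")
    expect_error(predictTargetDirection(c("down", NA)), "direction")
})

test_that("planted hubs among decoys are recovered exactly", {
    dirs <- setNames(rep("down", 6),
                     c("mir-a", "mir-b", "mir-c", "mir-d", "mir-e", "mir-f"))
    sim <- simulateMti(dirs, nPlantedHubs = 5, hubDegree = 3:5,
                       nDecoyTargets = 200, seed = 12)
    d <- withr::local_tempdir()
    paths <- writeMtiTables(sim, d)
    rec <- loadMtiSources(paths, names(paths))
    net <- buildNetwork(filterMti(rec), dirs)
    hubs <- findHubs(net, minDegree = 3)
    # sensitivity and specificity both 1
    expect_setequal(hubs$target, sim$truth$target)
    # recovered regulator sets match the planted truth
    expect_equal(hubs$regulators[match(sim$truth$target, hubs$target)],
                 sim$truth$regulators)
    expect_equal(sort(hubs$degree, decreasing = TRUE),
                 sort(sim$truth$degree, decreasing = TRUE))
})

test_that("network exports round-trip and SIF mirrors the edge list", {
    net <- exampleNetwork()
    hubs <- findHubs(net)
    d <- withr::local_tempdir()
    paths <- exportNetwork(net, d, hubs = hubs, header = "config_hash=1")
    sif <- readLines(paths["sif"])
    expect_length(sif, 12)
    expect_true(all(grepl("\ttargets\t", sif)))
    nodes <- read.delim(paths["nodes"], comment.char = "#")
    expect_identical(nrow(nodes), 10L)
    expect_setequal(nodes$id[nodes$is_hub], hubs$target)
    # GraphML round trip reproduces the network ...
    back <- readNetworkGraphml(paths["graphml"])
    expect_equal(networkEdges(back), networkEdges(net))
    expect_equal(mirnaDirections(back)[mirnaNodes(net)],
                 mirnaDirections(net)[mirnaNodes(net)])
    # ... and re-export is byte-identical
    d2 <- withr::local_tempdir()
    paths2 <- exportNetwork(back, d2, hubs = findHubs(back),
                            header = "config_hash=1")
    expect_identical(readLines(paths2["nodes"]), readLines(paths["nodes"]))
    expect_identical(readLines(paths2["edges"]), readLines(paths["edges"]))
    # an empty network still exports valid files with headers
    empty <- buildNetwork(networkEdges(net)[0, ], c(x = "down"))
    p3 <- exportNetwork(empty, withr::local_tempdir())
    expect_identical(nrow(read.delim(p3["edges"])), 0L)
    expect_length(readLines(p3["sif"]), 0)
})
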