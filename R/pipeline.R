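## End-to-end orchestration: simulate inputs -> array preprocessing and
## DE calling -> miRNA qRT-PCR -> reconciliation -> MTI filtering and
## bipartite network -> hub targets with predicted directions -> mRNA
## ddCp validation and concordance -> summary report.  Every stage
## output is written as TSV with a config-hash header before the next
## stage starts.

#' Default run configuration
#'
#' Nested list of all pipeline parameters with the workflow's canonical
#' defaults: normexp offset 10, lowess span 0.3, selection thresholds
#' |log2| > 0.6 and p < 0.05, MTI score filters (high-good > 80.0,
#' low-good < -1.2), hub minimum degree 3, unanimity direction rule, and
#' synthetic-data settings emulating the study design (300 probes, 2
#' arrays/group, 6 qRT-PCR samples/group, 4 planted hubs among 200
#' decoys).
#'
#' @param seed master integer seed; stage seeds are derived from it.
#' @param outDir output directory for all stage files.
#' @return Config list accepted by [runPipeline()].
#' @export
defaultRunConfig <- function(seed = 1, outDir = tempfile("mirtarnet_run_")) {
    list(
        seed = seed,
        outDir = outDir,
        array = list(nProbes = 300, nArraysPerGroup = 2, bgMean = 50,
                     bgSd = 5, signalScale = 1000, dyeBiasAmplitude = 0.4,
                     noiseSd = 0.1, refNoiseSd = 0.05,
                     plantedEffects = defaultPlantedEffects()),
        de = list(log2Threshold = 0.6, pThreshold = 0.05, span = 0.3,
                  offset = 10, detectQuantile = 0.05),
        qpcrMirna = list(assays = defaultMirnaCtAssays(),
                         nSamplesPerGroup = 6, sdCt = 0.2),
        qpcrMrna = list(assays = defaultMrnaCtAssays(),
                        nSamplesPerGroup = 6, sdCt = 0.15,
                        sampleShiftSd = 0.5),
        mti = list(nPlantedHubs = 4, hubDegree = 3, nDecoyTargets = 200,
                   highGoodMin = 80.0, lowGoodMax = -1.2),
        network = list(minDegree = 3, rule = "unanimity",
                       majorityFraction = 0.5),
        selectedGenes = c("IGF-1", "SLC2a-12", "EIF-4e", "ULK-2"),
        referenceGene = "GAPDH")
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the defaults of
#' [defaultRunConfig()]; everything else keeps its default.
#'
#' @param path YAML file.
#' @return Config list.
#' @export
readRunConfig <- function(path) {
    user <- yaml::read_yaml(path)
    cfg <- defaultRunConfig(seed = user$seed %||% 1,
                            outDir = user$outDir %||%
                                tempfile("mirtarnet_run_"))
    modifyList(cfg, user)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## deterministic FNV-1a hash of the deparsed config, for file headers
configHash <- function(config) {
    txt <- paste(deparse(config), collapse = "\n")
    h <- 0
    for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
    sprintf("config_hash=%08x", h)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes, in order: array simulation, normexp background correction,
#' lowess MA normalization, differential-expression calling; miRNA
#' qRT-PCR simulation and per-assay group changes; reconciliation of
#' array and qRT-PCR calls; MTI simulation, score filtering, bipartite
#' network construction, hub selection and target-direction prediction;
#' mRNA ddCp quantification for the selected genes and concordance with
#' the hub predictions.  Each stage's output TSV is written before the
#' next stage starts; all files carry a config-hash header comment.
#'
#' @param config list from [defaultRunConfig()] or [readRunConfig()].
#' @return A run report: list with \code{counts}, \code{de},
#'   \code{qpcr}, \code{reconciliation}, \code{hubs},
#'   \code{concordance}, \code{paths} and \code{configHash}.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
    if (!dir.exists(config$outDir))
        dir.create(config$outDir, recursive = TRUE)
    hash <- configHash(config)
    out <- function(name) file.path(config$outDir, name)
    paths <- c()

    ## stage 1: arrays -> DE calls
    aCfg <- config$array
    sim <- simulateArrays(nProbes = aCfg$nProbes,
                          nArraysPerGroup = aCfg$nArraysPerGroup,
                          bgMean = aCfg$bgMean, bgSd = aCfg$bgSd,
                          signalScale = aCfg$signalScale,
                          dyeBiasAmplitude = aCfg$dyeBiasAmplitude,
                          plantedEffects = aCfg$plantedEffects,
                          noiseSd = aCfg$noiseSd,
                          refNoiseSd = aCfg$refNoiseSd,
                          seed = config$seed)
    writeArrayTable(sim$mae, out("array_intensities.tsv"),
                    out("array_metadata.tsv"), header = hash)
    writeTsv(sim$truth, out("array_truth.tsv"), header = hash)
    mae <- backgroundCorrectArrays(sim$mae, offset = config$de$offset)
    mae <- normalizeArrays(mae, span = config$de$span)
    de <- callDifferentialExpression(mae,
                                     log2Threshold = config$de$log2Threshold,
                                     pThreshold = config$de$pThreshold,
                                     detectQuantile = config$de$detectQuantile)
    writeDEResults(de, out("de_results.tsv"), header = hash)
    paths["de"] <- out("de_results.tsv")

    ## stage 2: miRNA qRT-PCR
    mCfg <- config$qpcrMirna
    ctSim <- simulateCt(assays = mCfg$assays,
                        nSamplesPerGroup = mCfg$nSamplesPerGroup,
                        sdCt = mCfg$sdCt, seed = config$seed + 1L)
    writeTsv(ctSim$ct, out("mirna_ct.tsv"), header = hash)
    qpcr <- qpcrGroupChanges(ctSim$ct)
    writeQpcrResults(qpcr, out("qpcr_results.tsv"), header = hash)
    paths["qpcr"] <- out("qpcr_results.tsv")

    ## stage 3: reconciliation on the array-selected miRNAs with assays
    selected <- de[de$tier %in% c("significant", "candidate"), ]
    validated <- selected[selected$mirna %in% qpcr$assay, ]
    nUnvalidated <- nrow(selected) - nrow(validated)
    rec <- reconcileCalls(validated, qpcr,
                          pThreshold = config$de$pThreshold)
    writeTsv(rec$calls, out("reconciliation.tsv"), header = hash)
    paths["reconciliation"] <- out("reconciliation.tsv")

    ## stage 4: MTI network and hubs, directions from the final calls
    dirs <- setNames(rec$calls$final_direction, rec$calls$mirna)
    dirs <- dirs[dirs %in% c("up", "down")]
    nCfg <- config$mti
    mtiSim <- simulateMti(mirnaDirections = dirs,
                          nPlantedHubs = nCfg$nPlantedHubs,
                          hubDegree = nCfg$hubDegree,
                          nDecoyTargets = nCfg$nDecoyTargets,
                          seed = config$seed + 2L)
    mtiPaths <- writeMtiTables(mtiSim, config$outDir)
    writeTsv(mtiSim$truth, out("mti_truth.tsv"), header = hash)
    records <- loadMtiSources(mtiPaths, names(mtiPaths))
    retained <- filterMti(records, highGoodMin = nCfg$highGoodMin,
                          lowGoodMax = nCfg$lowGoodMax)
    network <- buildNetwork(retained, dirs)
    hubs <- findHubs(network, minDegree = config$network$minDegree,
                     rule = config$network$rule,
                     majorityFraction = config$network$majorityFraction)
    netPaths <- exportNetwork(network, config$outDir, hubs = hubs,
                              header = hash)
    writeTsv(hubs, out("hubs.tsv"), header = hash)
    paths["hubs"] <- out("hubs.tsv")

    ## stage 5: mRNA ddCp validation of hub targets + concordance
    gCfg <- config$qpcrMrna
    mrnaSim <- simulateCt(assays = gCfg$assays,
                          nSamplesPerGroup = gCfg$nSamplesPerGroup,
                          sdCt = gCfg$sdCt,
                          sampleShiftSd = gCfg$sampleShiftSd,
                          seed = config$seed + 3L)
    writeTsv(mrnaSim$ct, out("mrna_ct.tsv"), header = hash)
    ## measured genes in the synthetic run are the planted hub targets;
    ## the annotation list maps them onto the configured gene panel
    measuredGenes <- setdiff(unique(mrnaSim$ct$assay), config$referenceGene)
    ddcp <- lapply(measuredGenes, function(g)
        ddcpRelativeLevel(mrnaSim$ct, g, config$referenceGene))
    names(ddcp) <- measuredGenes
    hubGenes <- hubs$target
    geneMap <- if (length(hubGenes) && length(measuredGenes))
        setNames(rep(measuredGenes, length.out = length(hubGenes)), hubGenes)
    else setNames(character(0), character(0))
    conc <- validateConcordance(hubs, ddcp, geneMap = geneMap,
                                pThreshold = config$de$pThreshold)
    writeTsv(conc, out("concordance.tsv"), header = hash)
    paths["concordance"] <- out("concordance.tsv")

    counts <- c(probes_tested = nrow(de),
                selected = nrow(selected),
                selected_unvalidated = nUnvalidated,
                rec$summary,
                edges = nrow(networkEdges(network)),
                hubs = nrow(hubs),
                hubs_predicted_up = sum(hubs$predicted_direction == "up"),
                concordant = sum(conc$concordant, na.rm = TRUE))
    report <- list(counts = counts, de = de, qpcr = qpcr,
                   reconciliation = rec$calls, hubs = hubs,
                   concordance = conc, paths = paths, configHash = hash)
    writeTsv(data.frame(quantity = names(counts), value = unname(counts)),
             out("report.tsv"), header = hash)
    writeLines(c(paste0("# ", hash),
                 "miRNA-target network pipeline report",
                 paste0(format(names(counts), width = 24), counts)),
               out("report.txt"))
    report
}

#' Compare predicted hub directions with measured mRNA levels
#'
#' For every hub target: the predicted direction (from its regulators),
#' the measured direction (sign of the ddCp group ratio, with a
#' significance flag) and whether the two agree.  Genes without a
#' measurement are marked unmeasured.
#'
#' @param hubs hub table from [findHubs()].
#' @param ddcpResults named list of [ddcpRelativeLevel()] results.
#' @param geneMap optional named character vector mapping hub target
#'   names to measured assay names (defaults to identity).
#' @param pThreshold significance threshold for the measured call.
#' @return data.frame: \code{target}, \code{predicted_direction},
#'   \code{measured_direction}, \code{measured_ratio}, \code{p_value},
#'   \code{significant}, \code{concordant}.
#' @export
validateConcordance <- function(hubs, ddcpResults,
                                geneMap = setNames(hubs$target, hubs$target),
                                pThreshold = 0.05) {
    if (!nrow(hubs))
        return(data.frame(target = character(),
                          predicted_direction = character(),
                          measured_direction = character(),
                          measured_ratio = numeric(), p_value = numeric(),
                          significant = logical(), concordant = logical(),
                          stringsAsFactors = FALSE))
    do.call(rbind, lapply(seq_len(nrow(hubs)), function(i) {
        tgt <- hubs$target[i]
        assay <- unname(geneMap[tgt])
        res <- if (!is.na(assay)) ddcpResults[[assay]] else NULL
        if (is.null(res)) {
            data.frame(target = tgt,
                       predicted_direction = hubs$predicted_direction[i],
                       measured_direction = "unmeasured",
                       measured_ratio = NA_real_, p_value = NA_real_,
                       significant = NA, concordant = NA,
                       stringsAsFactors = FALSE)
        } else {
            sig <- is.finite(res$p_value) && res$p_value < pThreshold
            mdir <- if (res$ratio > 1) "up" else if (res$ratio < 1) "down"
                    else "none"
            data.frame(target = tgt,
                       predicted_direction = hubs$predicted_direction[i],
                       measured_direction = mdir,
                       measured_ratio = res$ratio, p_value = res$p_value,
                       significant = sig,
                       concordant = sig &&
                           mdir == hubs$predicted_direction[i],
                       stringsAsFactors = FALSE)
        }
    }))
}
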