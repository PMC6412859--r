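## Synthetic-data generators with known ground truth for every pipeline
## stage: two-color array intensities under the normexp generative model
## with planted group effects and an intensity-dependent dye bias, Ct
## tables with planted fold changes, and MTI source tables with planted
## hub targets among decoys.  Every generator is a pure function of its
## arguments including the mandatory seed.

## evaluate code under a temporary RNG state; no global side effects
withSeed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

#' Default planted array log2 effects
#'
#' The eight differentially expressed cardiac miRNAs of the bundled
#' example study with their array-scale log2 changes (neuropathy vs
#' control), used as the default planted truth of [simulateArrays()].
#'
#' @return Named numeric vector of log2 effects.
#' @export
defaultPlantedEffects <- function() {
    c("rno-miR-344b-1-3p" = -1.95,
      "rno-miR-466b-1-3p" = -1.10,
      "rno-miR-98-5p"     = -1.07,
      "rno-let-7a-5p"     = -1.03,
      "rno-miR-1-3p"      = -0.88,
      "rno-miR-206-3p"    = -0.86,
      "rno-miR-34b-3p"    =  0.63,
      "rno-miR-181a-2-3p" =  0.75)
}

## smooth sinusoid-plus-trend dye bias as a function of the spot's log2
## abundance, with fixed anchors spanning the bulk of the exponential
## signal distribution so the curve is the same on every array
.dyeBias <- function(x, amplitude, lo = -7, hi = 3) {
    if (amplitude == 0) return(rep(0, length(x)))
    r <- pmin(pmax((x - lo) / (hi - lo), 0), 1)
    amplitude * (sin(2 * pi * r) + (r - 0.5))
}

#' Simulate a two-color miRNA array experiment
#'
#' Generates foreground intensities under the normexp model the
#' preprocessing assumes: per probe a baseline signal drawn from an
#' exponential distribution with mean \code{signalScale} (so the
#' across-probe signal marginal is exponential), per array/channel a
#' log-normal measurement perturbation, planted log2 effects added to
#' the sample channel of neuropathy arrays, a smooth intensity-dependent
#' dye bias added to the sample channel, and additive normal background.
#' Negative draws are floored at 0 and counted.
#'
#' @param nProbes number of probes (planted-effect probes come first).
#' @param nArraysPerGroup arrays per group (default 2, the pooled
#'   two-samples-per-group design).
#' @param bgMean,bgSd normal background mean and SD.
#' @param signalScale mean of the exponential across-probe signal.
#' @param dyeBiasAmplitude amplitude (log2 units) of the sample-channel
#'   dye bias (default 0.4; 0 disables it).
#' @param plantedEffects named log2 effects (default
#'   [defaultPlantedEffects()]).
#' @param noiseSd per-array sample-channel log2 measurement SD.
#' @param refNoiseSd reference-channel log2 measurement SD (the common
#'   reference is the same pooled RNA on every array).
#' @param expressedQuantile planted-effect probes draw their baseline
#'   signal from above this quantile of the exponential signal
#'   distribution (default 0.3), so planted effects sit on expressed,
#'   detectable probes.
#' @param seed mandatory integer seed.
#' @return list with \code{mae} (a \linkS4class{MirArrayExperiment}),
#'   \code{truth} (data.frame \code{probe}, \code{true_log2_effect}) and
#'   \code{nFloored}.
#' @export
simulateArrays <- function(nProbes = 300, nArraysPerGroup = 2,
                           bgMean = 50, bgSd = 5, signalScale = 1000,
                           dyeBiasAmplitude = 0.4,
                           plantedEffects = defaultPlantedEffects(),
                           noiseSd = 0.1, refNoiseSd = 0.05,
                           expressedQuantile = 0.3, seed) {
    stopifnot(!missing(seed), nProbes >= length(plantedEffects),
              nArraysPerGroup >= 1, bgSd > 0, signalScale > 0,
              noiseSd >= 0, refNoiseSd >= 0)
    withSeed(seed, {
        nDecoy <- nProbes - length(plantedEffects)
        probes <- c(names(plantedEffects),
                    sprintf("sim-mir-%03d", seq_len(nDecoy)))
        effects <- setNames(c(unname(plantedEffects), rep(0, nDecoy)), probes)
        arrays <- c(sprintf("ctl_%d", seq_len(nArraysPerGroup)),
                    sprintf("neu_%d", seq_len(nArraysPerGroup)))
        groups <- rep(c("control", "neuropathy"), each = nArraysPerGroup)
        ## across-probe signal marginal ~ Exponential(signalScale); the
        ## planted-effect probes are drawn from the expressed upper part
        ## of that distribution (a differential call on a probe at
        ## background level is not meaningful), decoys from the whole
        u <- rexp(nProbes, rate = 1)
        nPl <- length(plantedEffects)
        if (nPl > 0)
            u[seq_len(nPl)] <- qexp(runif(nPl, expressedQuantile, 1))
        baseExpr <- log2(u)                 # signal = scale * 2^expr
        nFloored <- 0L
        mk <- function() matrix(NA_real_, nProbes, length(arrays),
                                dimnames = list(probes, arrays))
        sampleFg <- mk(); refFg <- mk()
        for (j in seq_along(arrays)) {
            isNeu <- groups[j] == "neuropathy"
            ## dye bias depends on the spot's actual abundance (mean of
            ## the two channels), as it would on a scanned array
            bias <- .dyeBias(baseExpr + effects * isNeu / 2,
                             dyeBiasAmplitude)
            sExpr <- baseExpr + bias + effects * isNeu +
                rnorm(nProbes, 0, noiseSd)
            rExpr <- baseExpr + rnorm(nProbes, 0, refNoiseSd)
            s <- rnorm(nProbes, bgMean, bgSd) + signalScale * 2^sExpr
            r <- rnorm(nProbes, bgMean, bgSd) + signalScale * 2^rExpr
            nFloored <- nFloored + sum(s < 0) + sum(r < 0)
            sampleFg[, j] <- pmax(s, 0)
            refFg[, j] <- pmax(r, 0)
        }
        if (nFloored > 0)
            message(nFloored, " negative intensities floored at 0")
        list(mae = MirArrayExperiment(sampleFg, refFg, group = groups),
             truth = data.frame(probe = probes,
                                true_log2_effect = unname(effects),
                                stringsAsFactors = FALSE),
             nFloored = nFloored)
    })
}

#' Default qRT-PCR miRNA assay panel
#'
#' Baseline Cp values and planted qRT-PCR-scale log2 effects for the
#' eight example miRNAs.  miR-344b is given a baseline above the
#' 45-cycle detection ceiling so it comes out undetermined ("n.d."), as
#' in the example study.
#'
#' @return data.frame with \code{assay}, \code{baseline_cp},
#'   \code{planted_log2_effect}.
#' @export
defaultMirnaCtAssays <- function() {
    data.frame(
        assay = c("rno-miR-344b-1-3p", "rno-miR-466b-1-3p", "rno-miR-98-5p",
                  "rno-let-7a-5p", "rno-miR-1-3p", "rno-miR-206-3p",
                  "rno-miR-34b-3p", "rno-miR-181a-2-3p"),
        baseline_cp = c(46, 33, 29, 26, 19, 27, 31, 32),
        planted_log2_effect = c(0, -3.19, -2.45, -2.03, -2.85, -5.19,
                                -2.93, 3.81),
        stringsAsFactors = FALSE)
}

#' Default qRT-PCR mRNA assay panel
#'
#' The four hub target genes with a planted 1.8-fold (log2 0.85)
#' increase, plus the stable GAPDH reference gene.
#'
#' @return data.frame as [defaultMirnaCtAssays()].
#' @export
defaultMrnaCtAssays <- function() {
    data.frame(
        assay = c("IGF-1", "SLC2a-12", "EIF-4e", "ULK-2", "GAPDH"),
        baseline_cp = c(26, 29, 24, 30, 18),
        planted_log2_effect = c(log2(1.8), log2(1.8), log2(1.8), log2(1.8), 0),
        stringsAsFactors = FALSE)
}

#' Simulate a Ct/Cp table with planted fold changes
#'
#' Cp_s = baseline - planted_log2_effect * I(neuropathy) + sample shift
#' + Normal(0, sdCt); one extra expression doubling removes one cycle.
#' Values beyond the 45-cycle ceiling are recorded as undetermined (NA).
#' \code{sampleShiftSd} adds a per-sample shift common to all assays of
#' that sample (template-loading variation), which reference-gene
#' normalization is meant to remove.
#'
#' @param assays data.frame with \code{assay}, \code{baseline_cp},
#'   \code{planted_log2_effect} (defaults to [defaultMirnaCtAssays()]).
#' @param nSamplesPerGroup samples per group (default 6).
#' @param sdCt technical Cp SD in cycles.
#' @param sampleShiftSd SD of the per-sample common shift (default 0).
#' @param ceiling detection ceiling in cycles (default 45).
#' @param seed mandatory integer seed.
#' @return list with \code{ct} (long Ct table) and \code{truth}
#'   (per-assay planted log2 effect and signed fold change).
#' @export
simulateCt <- function(assays = defaultMirnaCtAssays(),
                       nSamplesPerGroup = 6, sdCt = 0.2,
                       sampleShiftSd = 0, ceiling = 45, seed) {
    stopifnot(!missing(seed), sdCt >= 0, sampleShiftSd >= 0,
              nSamplesPerGroup >= 2,
              all(c("assay", "baseline_cp", "planted_log2_effect") %in%
                  colnames(assays)))
    withSeed(seed, {
        samples <- c(sprintf("ctl_s%d", seq_len(nSamplesPerGroup)),
                     sprintf("neu_s%d", seq_len(nSamplesPerGroup)))
        groups <- rep(c("control", "neuropathy"), each = nSamplesPerGroup)
        shift <- rnorm(length(samples), 0, sampleShiftSd)
        rows <- lapply(seq_len(nrow(assays)), function(i) {
            cp <- assays$baseline_cp[i] -
                assays$planted_log2_effect[i] * (groups == "neuropathy") +
                shift + rnorm(length(samples), 0, sdCt)
            cp[cp > ceiling] <- NA_real_
            data.frame(sample_id = samples, group = groups,
                       assay = assays$assay[i], cp = cp,
                       stringsAsFactors = FALSE)
        })
        ct <- do.call(rbind, rows)
        rownames(ct) <- NULL
        truth <- data.frame(
            assay = assays$assay,
            true_log2_effect = assays$planted_log2_effect,
            true_fold_change = signedFoldChange(assays$planted_log2_effect),
            stringsAsFactors = FALSE)
        list(ct = ct, truth = truth)
    })
}

#' Simulate MTI source tables with planted hub targets
#'
#' Builds three interaction tables (one per dialect) in which
#' \code{nPlantedHubs} target genes each receive \code{hubDegree}
#' interactions with threshold-passing scores, spread across the
#' dialects, while decoy targets receive either low-degree passing
#' interactions (retained degree 1--2) or interactions whose scores fail
#' the filters (retained degree 0).  Hub recovery downstream is
#' therefore exact by construction.
#'
#' @param mirnaDirections named \code{"up"}/\code{"down"} vector of
#'   differentially expressed miRNAs.
#' @param nPlantedHubs number of hub targets.
#' @param hubDegree distinct regulators per hub, scalar or vector
#'   recycled over hubs (>= downstream \code{minDegree}).
#' @param nDecoyTargets number of decoy targets.
#' @param hubRegulatorPool miRNAs hubs are drawn from (default: the
#'   down-regulated ones, so hubs are predicted up).
#' @param seed mandatory integer seed.
#' @return list with \code{tables} (named list of three data.frames:
#'   \code{mirna}, \code{target}, \code{score}) and \code{truth}
#'   (per planted hub: regulators and degree).
#' @export
simulateMti <- function(mirnaDirections, nPlantedHubs = 4, hubDegree = 3,
                        nDecoyTargets = 200,
                        hubRegulatorPool =
                            names(mirnaDirections)[mirnaDirections == "down"],
                        seed) {
    stopifnot(!missing(seed), nPlantedHubs >= 0, nDecoyTargets >= 0,
              all(mirnaDirections %in% c("up", "down")))
    if (nPlantedHubs > 0 && max(hubDegree) > length(hubRegulatorPool))
        stop("infeasible config: hubDegree exceeds the regulator pool size")
    hubDegrees <- if (nPlantedHubs > 0)
        rep_len(hubDegree, nPlantedHubs) else integer(0)
    withSeed(seed, {
        dialects <- c("predicted_high_good", "predicted_low_good", "validated")
        drawScore <- function(dialect, pass) {
            switch(dialect,
                   predicted_high_good =
                       if (pass) runif(1, 85, 99.9) else runif(1, 50, 80),
                   predicted_low_good =
                       if (pass) runif(1, -3, -1.3) else runif(1, -1.2, -0.1),
                   validated = NA_real_)
        }
        rows <- list()
        addRow <- function(mirna, target, dialect, pass) {
            rows[[length(rows) + 1L]] <<- data.frame(
                mirna = mirna, target = target, source = dialect,
                score = drawScore(dialect, pass), stringsAsFactors = FALSE)
        }
        hubNames <- if (nPlantedHubs > 0)
            sprintf("HUB-%02d", seq_len(nPlantedHubs)) else character(0)
        truth <- list()
        for (k in seq_along(hubNames)) {
            h <- hubNames[k]
            regs <- sample(hubRegulatorPool, hubDegrees[k])
            for (m in regs) addRow(m, h, sample(dialects, 1), pass = TRUE)
            truth[[h]] <- data.frame(target = h,
                                     regulators = paste(sort(regs),
                                                        collapse = ";"),
                                     degree = hubDegrees[k],
                                     stringsAsFactors = FALSE)
        }
        allMirs <- names(mirnaDirections)
        for (d in seq_len(nDecoyTargets)) {
            target <- sprintf("DECOY-%03d", d)
            if (runif(1) < 0.5) {   # low-degree decoy, passing scores
                regs <- sample(allMirs, sample(1:2, 1))
                for (m in regs) addRow(m, target, sample(dialects, 1), TRUE)
            } else {                # failing-score decoy (never validated)
                regs <- sample(allMirs, sample(1:3, 1))
                for (m in regs)
                    addRow(m, target, sample(dialects[1:2], 1), FALSE)
            }
        }
        all <- if (length(rows)) do.call(rbind, rows)
               else data.frame(mirna = character(), target = character(),
                               source = character(), score = numeric(),
                               stringsAsFactors = FALSE)
        tables <- lapply(setNames(dialects, dialects), function(d) {
            t <- all[all$source == d, c("mirna", "target", "score")]
            rownames(t) <- NULL
            t
        })
        list(tables = tables,
             truth = if (length(truth)) do.call(rbind, truth)
                     else data.frame(target = character(),
                                     regulators = character(),
                                     degree = integer(),
                                     stringsAsFactors = FALSE))
    })
}

#' Write simulated MTI tables to one TSV per dialect
#'
#' @param sim result of [simulateMti()].
#' @param dir output directory.
#' @return Named character vector of paths, names = dialects.
#' @export
writeMtiTables <- function(sim, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- vapply(names(sim$tables), function(d) {
        p <- file.path(dir, paste0("mti_", d, ".tsv"))
        writeTsv(sim$tables[[d]], p)
        p
    }, character(1))
    paths
}
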