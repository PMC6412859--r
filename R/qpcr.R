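## qRT-PCR quantification: abundance classes from delta-Ct, per-group
## log2 changes for miRNA assays, 2^-ddCp relative mRNA levels with
## optional primer-efficiency correction, and reconciliation of array
## and qRT-PCR calls.

#' Read a Ct/Cp table
#'
#' TSV with columns \code{sample_id}, \code{group} (control/neuropathy),
#' \code{assay}, \code{cp}; an empty \code{cp} cell means undetermined
#' (no amplification before the cycle ceiling).  Cp values must lie in
#' (0, 45], the 45-cycle protocol.
#'
#' @param path TSV path.
#' @return data.frame with the four columns, \code{cp} numeric with NA
#'   for undetermined.
#' @export
readCtTable <- function(path) {
    ct <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    validateCtTable(ct)
}

validateCtTable <- function(ct) {
    need <- c("sample_id", "group", "assay", "cp")
    if (!all(need %in% colnames(ct)))
        stop("Ct table needs columns: ", paste(need, collapse = ", "))
    ct$cp <- suppressWarnings(as.numeric(ct$cp))
    if (!all(ct$group %in% c("control", "neuropathy")))
        stop("group must be 'control' or 'neuropathy'")
    bad <- !is.na(ct$cp) & (ct$cp <= 0 | ct$cp > 45)
    if (any(bad)) stop("Cp values must lie in (0, 45]")
    if (anyDuplicated(paste(ct$sample_id, ct$assay, sep = "\r")))
        stop("one Cp value per (sample, assay) expected")
    ct
}

#' Classify miRNA abundance from a delta-Ct against a reference miRNA
#'
#' The mean Ct of an abundant reference miRNA (here typically miR-1, one
#' of the most abundant cardiac miRNAs) is subtracted from the assay's
#' mean Ct; a difference below 6 cycles marks a high-abundance miRNA,
#' above 10 a low-abundance one, anything between (bounds included) is
#' intermediate.
#'
#' @param meanCpAssay,meanCpReference finite mean Cp values, or a single
#'   precomputed difference via \code{meanCpReference = 0}.
#' @return character vector: \code{"high"}, \code{"intermediate"} or
#'   \code{"low"}.
#' @export
classifyAbundance <- function(meanCpAssay, meanCpReference) {
    if (any(!is.finite(meanCpAssay)) || any(!is.finite(meanCpReference)))
        stop("mean Cp values must be finite")
    delta <- meanCpAssay - meanCpReference
    ifelse(delta < 6, "high", ifelse(delta > 10, "low", "intermediate"))
}

.groupCp <- function(ct, assay) {
    sub <- ct[ct$assay == assay, ]
    list(ctl = sub$cp[sub$group == "control"],
         neu = sub$cp[sub$group == "neuropathy"])
}

#' Per-group expression change of a qRT-PCR assay
#'
#' Computes the neuropathy-vs-control log2 expression change of one assay
#' from per-sample Cp values: each extra cycle is a halving, so
#' mean_log2_change = -(mean dCp neuropathy - mean dCp control), with
#' dCp the raw Cp by default or Cp minus a reference assay's Cp in the
#' same sample when \code{referenceAssay} is given.  The p-value is a
#' Welch test on the per-sample dCp values.  An assay amplifying in
#' fewer than 2 samples per group is reported undetected (all numeric
#' fields NA, regulation \code{"n.d."}).
#'
#' @param ct Ct table (see [readCtTable()]).
#' @param assay assay name.
#' @param referenceAssay optional reference assay for per-sample dCp.
#' @return one-row data.frame: \code{assay}, \code{detected},
#'   \code{mean_log2_change}, \code{sd_log2}, \code{signed_fold_change},
#'   \code{p_value}, \code{direction}.
#' @export
mirnaGroupChange <- function(ct, assay, referenceAssay = NULL) {
    ct <- validateCtTable(ct)
    sub <- ct[ct$assay == assay & !is.na(ct$cp), ]
    if (!is.null(referenceAssay)) {
        ref <- ct[ct$assay == referenceAssay & !is.na(ct$cp), ]
        idx <- match(sub$sample_id, ref$sample_id)
        drop <- is.na(idx)
        if (any(drop))
            message(sum(drop), " sample(s) dropped for '", assay,
                    "': reference assay missing")
        sub <- sub[!drop, ]
        sub$cp <- sub$cp - ref$cp[idx[!drop]]
    }
    ctl <- sub$cp[sub$group == "control"]
    neu <- sub$cp[sub$group == "neuropathy"]
    if (length(ctl) < 2 || length(neu) < 2) {
        return(data.frame(assay = assay, detected = FALSE,
                          mean_log2_change = NA_real_, sd_log2 = NA_real_,
                          signed_fold_change = NA_real_, p_value = NA_real_,
                          direction = "n.d.", stringsAsFactors = FALSE))
    }
    ml2 <- -(mean(neu) - mean(ctl))
    ## per-comparison spread of the log2 change, from per-sample dCp
    sdl2 <- sqrt(var(neu) + var(ctl))
    p <- suppressWarnings(welchTTest(neu, ctl)$p.value)
    data.frame(assay = assay, detected = TRUE,
               mean_log2_change = ml2, sd_log2 = sdl2,
               signed_fold_change = signedFoldChange(ml2),
               p_value = p,
               direction = if (ml2 < 0) "down" else if (ml2 > 0) "up"
                           else "none",
               stringsAsFactors = FALSE)
}

#' Group changes for every assay in a Ct table
#'
#' @inheritParams mirnaGroupChange
#' @param assays assay names (default: all in the table, minus the
#'   reference assay if used).
#' @return data.frame, one row per assay (see [mirnaGroupChange()]).
#' @export
qpcrGroupChanges <- function(ct, assays = NULL, referenceAssay = NULL) {
    ct <- validateCtTable(ct)
    if (is.null(assays))
        assays <- setdiff(unique(ct$assay), referenceAssay)
    do.call(rbind, lapply(assays, function(a)
        mirnaGroupChange(ct, a, referenceAssay)))
}

#' Relative mRNA levels by the 2^-ddCp method
#'
#' Per sample s: dCp_s = Cp_target,s - Cp_reference,s; ddCp_s = dCp_s -
#' mean(dCp over control samples); level_s = 2^-ddCp_s.  The control
#' group is the calibrator, anchored at its arithmetic-mean dCp, so the
#' control geometric-mean level is exactly 1.  The group ratio reported
#' is 2 to the minus difference of group-mean dCp (the group-level ddCp),
#' and the p-value is a Welch test on per-sample levels
#' (\code{testOn = "level"}, default) or on per-sample dCp.
#'
#' @param ct Ct table.
#' @param target target gene assay name.
#' @param referenceGene reference (housekeeping) gene assay name, e.g.
#'   GAPDH.
#' @param testOn scale for the group test: \code{"level"} or
#'   \code{"dcp"}.
#' @param base amplification base (2 for the classical method).
#' @return list with \code{perSample} (sample_id, group, dcp, ddcp,
#'   level), \code{summary} (group means +/- SD of levels), \code{ratio}
#'   (neuropathy/control group-level ratio), \code{p_value}, and
#'   \code{target}.
#' @export
ddcpRelativeLevel <- function(ct, target, referenceGene,
                              testOn = c("level", "dcp"), base = 2) {
    testOn <- match.arg(testOn)
    ct <- validateCtTable(ct)
    tt <- ct[ct$assay == target & !is.na(ct$cp), ]
    rr <- ct[ct$assay == referenceGene & !is.na(ct$cp), ]
    if (!nrow(tt)) stop("target assay '", target, "' not measured")
    if (!nrow(rr)) stop("reference assay '", referenceGene, "' not measured")
    idx <- match(tt$sample_id, rr$sample_id)
    drop <- is.na(idx)
    if (any(drop))
        message(sum(drop), " sample(s) dropped for '", target,
                "': reference gene missing")
    tt <- tt[!drop, ]
    dcp <- tt$cp - rr$cp[idx[!drop]]
    calib <- mean(dcp[tt$group == "control"])
    if (!is.finite(calib)) stop("no control samples for calibrator")
    ddcp <- dcp - calib
    level <- base^(-ddcp)
    per <- data.frame(sample_id = tt$sample_id, group = tt$group,
                      dcp = dcp, ddcp = ddcp, level = level,
                      stringsAsFactors = FALSE)
    agg <- function(g, f) f(per$level[per$group == g])
    summ <- data.frame(group = c("control", "neuropathy"),
                       mean_level = c(agg("control", mean),
                                      agg("neuropathy", mean)),
                       sd_level = c(agg("control", sd),
                                    agg("neuropathy", sd)),
                       n = c(sum(per$group == "control"),
                             sum(per$group == "neuropathy")))
    ratio <- base^(-(mean(per$dcp[per$group == "neuropathy"]) - calib))
    p <- if (testOn == "level") {
        suppressWarnings(welchTTest(per$level[per$group == "neuropathy"],
                                    per$level[per$group == "control"])$p.value)
    } else {
        suppressWarnings(welchTTest(per$dcp[per$group == "neuropathy"],
                                    per$dcp[per$group == "control"])$p.value)
    }
    list(target = target, perSample = per, summary = summ,
         ratio = ratio, p_value = p)
}

#' Efficiency-corrected relative mRNA levels
#'
#' As [ddcpRelativeLevel()] but with each assay's own amplification
#' efficiency E in (1, 2] replacing base 2 (E = 2 is perfect doubling):
#' level_s = E_target^-ddCp_target,s / E_reference^-ddCp_reference,s,
#' where each gene's ddCp is anchored to its own control-group mean Cp.
#'
#' @inheritParams ddcpRelativeLevel
#' @param assays data.frame registry with columns \code{target} and
#'   \code{efficiency} (see [readPrimerAssays()]).
#' @return As [ddcpRelativeLevel()].
#' @export
efficiencyCorrectedLevel <- function(ct, target, referenceGene, assays,
                                     testOn = c("level", "dcp")) {
    testOn <- match.arg(testOn)
    eff <- function(g) {
        e <- assays$efficiency[assays$target == g]
        if (!length(e)) stop("no efficiency for assay '", g, "'")
        if (e <= 1 || e > 2) stop("efficiency must lie in (1, 2]")
        e
    }
    eT <- eff(target); eR <- eff(referenceGene)
    ct <- validateCtTable(ct)
    tt <- ct[ct$assay == target & !is.na(ct$cp), ]
    rr <- ct[ct$assay == referenceGene & !is.na(ct$cp), ]
    idx <- match(tt$sample_id, rr$sample_id)
    keep <- !is.na(idx)
    tt <- tt[keep, ]
    rcp <- rr$cp[idx[keep]]
    ctlSel <- tt$group == "control"
    ddT <- tt$cp - mean(tt$cp[ctlSel])
    ddR <- rcp - mean(rcp[ctlSel])
    level <- eT^(-ddT) / eR^(-ddR)
    per <- data.frame(sample_id = tt$sample_id, group = tt$group,
                      ddcp_target = ddT, ddcp_reference = ddR,
                      level = level, stringsAsFactors = FALSE)
    agg <- function(g, f) f(per$level[per$group == g])
    summ <- data.frame(group = c("control", "neuropathy"),
                       mean_level = c(agg("control", mean),
                                      agg("neuropathy", mean)),
                       sd_level = c(agg("control", sd),
                                    agg("neuropathy", sd)),
                       n = c(sum(per$group == "control"),
                             sum(per$group == "neuropathy")))
    neuSel <- per$group == "neuropathy"
    ratio <- eT^(-mean(ddT[neuSel])) / eR^(-mean(ddR[neuSel]))
    p <- if (testOn == "level") {
        suppressWarnings(welchTTest(per$level[neuSel],
                                    per$level[ctlSel])$p.value)
    } else {
        suppressWarnings(welchTTest((ddT - ddR)[neuSel],
                                    (ddT - ddR)[ctlSel])$p.value)
    }
    list(target = target, perSample = per, summary = summ,
         ratio = ratio, p_value = p)
}

#' Read a primer/assay registry
#'
#' TSV mirroring a primer table: columns \code{target},
#' \code{forward_primer}, \code{reverse_primer} (annotation only),
#' \code{efficiency} (amplification factor per cycle, in (1, 2]) and
#' \code{product_size}.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readPrimerAssays <- function(path) {
    a <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    if (!all(c("target", "efficiency") %in% colnames(a)))
        stop("assay registry needs columns target, efficiency")
    if (any(a$efficiency <= 1 | a$efficiency > 2))
        stop("efficiencies must lie in (1, 2]")
    a
}

#' Reconcile microarray and qRT-PCR calls per miRNA
#'
#' For every array-selected miRNA: confirmation is \code{"yes"} when the
#' qRT-PCR result is detected, significant and direction-concordant with
#' the array call; \code{"no"} when detected but discordant or
#' non-significant (the latter flagged); \code{"n.d."} when undetected.
#' The final direction is the qRT-PCR sign when detected and significant,
#' otherwise the array sign.
#'
#' @param arrayResults data.frame with columns \code{mirna} and
#'   \code{direction} (\code{up}/\code{down}/\code{none}), e.g. from
#'   [callDifferentialExpression()].
#' @param qpcrResults data.frame with columns \code{assay} (or
#'   \code{mirna}), \code{detected}, \code{direction} and either
#'   \code{p_value} or a logical \code{significant}.
#' @param pThreshold significance threshold when \code{p_value} is used.
#' @return list with \code{calls} (per-miRNA table: array_direction,
#'   qpcr_direction, final_direction, confirmation, flag) and
#'   \code{summary} (n_down, n_up, n_confirmed, n_nd).
#' @export
reconcileCalls <- function(arrayResults, qpcrResults, pThreshold = 0.05) {
    if (!"mirna" %in% colnames(qpcrResults))
        qpcrResults$mirna <- qpcrResults$assay
    if (!"significant" %in% colnames(qpcrResults)) {
        if (!"p_value" %in% colnames(qpcrResults))
            stop("qpcrResults needs 'significant' or 'p_value'")
        qpcrResults$significant <- !is.na(qpcrResults$p_value) &
            qpcrResults$p_value < pThreshold
    }
    if (!nrow(arrayResults)) {
        calls <- data.frame(mirna = character(),
                            array_direction = character(),
                            qpcr_direction = character(),
                            final_direction = character(),
                            confirmation = character(), flag = character(),
                            stringsAsFactors = FALSE)
        return(list(calls = calls,
                    summary = c(n_down = 0L, n_up = 0L, n_confirmed = 0L,
                                n_nd = 0L)))
    }
    missing <- setdiff(arrayResults$mirna, qpcrResults$mirna)
    if (length(missing))
        stop("no qRT-PCR entry for: ", paste(missing, collapse = ", "))
    idx <- match(arrayResults$mirna, qpcrResults$mirna)
    q <- qpcrResults[idx, ]
    calls <- do.call(rbind, lapply(seq_len(nrow(arrayResults)), function(i) {
        arrDir <- arrayResults$direction[i]
        det <- isTRUE(q$detected[i])
        sig <- isTRUE(q$significant[i])
        qDir <- if (det) q$direction[i] else "n.d."
        if (!det) {
            conf <- "n.d."; final <- arrDir; flag <- ""
        } else if (!sig) {
            conf <- "no"; final <- arrDir; flag <- "qpcr_nonsignificant"
        } else if (qDir == arrDir) {
            conf <- "yes"; final <- qDir; flag <- ""
        } else {
            conf <- "no"; final <- qDir; flag <- "discordant"
        }
        data.frame(mirna = arrayResults$mirna[i],
                   array_direction = arrDir, qpcr_direction = qDir,
                   final_direction = final, confirmation = conf,
                   flag = flag, stringsAsFactors = FALSE)
    }))
    list(calls = calls,
         summary = c(n_down = sum(calls$final_direction == "down"),
                     n_up = sum(calls$final_direction == "up"),
                     n_confirmed = sum(calls$confirmation == "yes"),
                     n_nd = sum(calls$confirmation == "n.d.")))
}

#' Write qRT-PCR results as TSV (2-decimal log2/fold columns)
#'
#' @param res data.frame from [qpcrGroupChanges()].
#' @param path output path.
#' @param header optional comment line.
#' @export
writeQpcrResults <- function(res, path, header = NULL) {
    for (col in c("mean_log2_change", "sd_log2", "signed_fold_change"))
        if (col %in% colnames(res)) res[[col]] <- round(res[[col]], 2)
    writeTsv(res, path, header)
}
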