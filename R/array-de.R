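## Array preprocessing (normexp background correction, global lowess MA
## normalization) and differential-expression calling with the joint
## p < 0.05 / |log2 ratio| > 0.6 selection rule.

#' Background-correct a two-color array experiment
#'
#' Fits the normexp model per array and channel ([normexpFit()]) and
#' replaces foregrounds by the posterior-mean signal plus offset
#' ([normexpSignal()]).  Adds assays \code{sampleBg} and
#' \code{referenceBg}; the fitted parameters are stored in
#' \code{metadata(mae)$normexp}.
#'
#' @param mae a \linkS4class{MirArrayExperiment}.
#' @param offset offset added to corrected signals (default 10).
#' @param method parameter estimator, \code{"moments"} or \code{"mle"}.
#' @return The updated \code{MirArrayExperiment}.
#' @export
backgroundCorrectArrays <- function(mae, offset = 10,
                                    method = c("moments", "mle")) {
    method <- match.arg(method)
    stopifnot(is(mae, "MirArrayExperiment"), offset >= 0)
    fits <- list()
    for (ch in c("sample", "reference")) {
        m <- SummarizedExperiment::assay(mae, ch)
        corrected <- m
        for (a in colnames(m)) {
            fit <- normexpFit(m[, a], method = method)
            corrected[, a] <- normexpSignal(m[, a], fit, offset = offset)
            fits[[paste(a, ch, sep = ".")]] <- fit
        }
        SummarizedExperiment::assay(mae, paste0(ch, "Bg")) <- corrected
    }
    S4Vectors::metadata(mae)$normexp <- fits
    S4Vectors::metadata(mae)$normexp_offset <- offset
    mae
}

#' Lowess-normalize a vector of log ratios against intensity
#'
#' Global MA normalization: fits a locally weighted regression of M
#' (log2 between-channel ratio) on A (mean log2 intensity) with tricube
#' weights and robustness iterations, and subtracts the fit, removing
#' intensity-dependent dye bias.  If all A are identical the fit is
#' undefined and the mean of M is subtracted instead (with a warning).
#'
#' @param M,A equal-length finite numeric vectors (length >= 10).
#' @param span smoother span in (0, 1] (fraction of points in each local
#'   window; default 0.3).
#' @param iter robustness iterations (default 3).
#' @return The normalized M vector.
#' @export
lowessNormalize <- function(M, A, span = 0.3, iter = 3) {
    stopifnot(length(M) == length(A), length(M) >= 10,
              all(is.finite(M)), all(is.finite(A)),
              span > 0, span <= 1)
    if (diff(range(A)) == 0) {
        warning("all A values identical; subtracting mean(M)")
        return(M - mean(M))
    }
    fit <- lowess(A, M, f = span, iter = iter)
    M - approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
}

#' MA-transform and normalize a corrected array experiment
#'
#' Computes per array M = log2(sampleBg/referenceBg) and
#' A = mean log2 intensity, then applies [lowessNormalize()] per array.
#' Adds assays \code{M}, \code{A} and \code{Mnorm}.
#'
#' @inheritParams backgroundCorrectArrays
#' @param span,iter passed to [lowessNormalize()].
#' @return The updated \code{MirArrayExperiment}.
#' @export
normalizeArrays <- function(mae, span = 0.3, iter = 3) {
    stopifnot(is(mae, "MirArrayExperiment"))
    if (!all(c("sampleBg", "referenceBg") %in%
             SummarizedExperiment::assayNames(mae)))
        stop("run backgroundCorrectArrays() first")
    sl <- log2(SummarizedExperiment::assay(mae, "sampleBg"))
    rl <- log2(SummarizedExperiment::assay(mae, "referenceBg"))
    M <- sl - rl
    A <- (sl + rl) / 2
    Mn <- M
    for (a in colnames(M)) {
        ok <- is.finite(M[, a]) & is.finite(A[, a])
        Mn[ok, a] <- lowessNormalize(M[ok, a], A[ok, a],
                                     span = span, iter = iter)
    }
    SummarizedExperiment::assay(mae, "M") <- M
    SummarizedExperiment::assay(mae, "A") <- A
    SummarizedExperiment::assay(mae, "Mnorm") <- Mn
    mae
}

#' All cross-group comparisons of normalized log ratios
#'
#' Forms every (neuropathy array, control array) pair -- 2 x 2 = 4 for a
#' two-arrays-per-group design -- and computes the per-probe log2
#' difference of normalized sample-channel log ratios, the "individual
#' parallel comparisons" whose mean and SD summarize each probe.
#'
#' @param mae a normalized \linkS4class{MirArrayExperiment}.
#' @return probe x pair matrix of log2 ratios; column names
#'   \code{"<neuropathy array>/<control array>"}.
#' @export
crossGroupComparisons <- function(mae) {
    stopifnot(is(mae, "MirArrayExperiment"))
    if (!"Mnorm" %in% SummarizedExperiment::assayNames(mae))
        stop("run normalizeArrays() first")
    g <- arrayGroups(mae)
    neu <- names(g)[g == "neuropathy"]
    ctl <- names(g)[g == "control"]
    if (!length(neu) || !length(ctl))
        stop("need at least one array per group")
    Mn <- SummarizedExperiment::assay(mae, "Mnorm")
    pairs <- expand.grid(neu = neu, ctl = ctl, stringsAsFactors = FALSE)
    out <- Mn[, pairs$neu, drop = FALSE] - Mn[, pairs$ctl, drop = FALSE]
    colnames(out) <- paste(pairs$neu, pairs$ctl, sep = "/")
    out
}

#' Classify one probe's differential-expression evidence
#'
#' Applies the selection rule: \code{direction} is \code{down} when the
#' mean log2 ratio is below \code{-log2Threshold}, \code{up} above it,
#' otherwise \code{none}; \code{tier} is \code{significant} when the
#' magnitude passes and p < \code{pThreshold}, \code{candidate} when only
#' the magnitude passes (a missing p caps the tier at candidate), else
#' \code{not_selected}.  The default 0.6 log2 cut corresponds to roughly
#' a 1.5-fold change.
#'
#' @param meanLog2 numeric vector of mean log2 ratios.
#' @param pValue numeric vector of p-values (may be NA).
#' @param log2Threshold,pThreshold selection thresholds (defaults 0.6 and
#'   0.05).
#' @return data.frame with columns \code{direction} and \code{tier}.
#' @export
classifyDE <- function(meanLog2, pValue, log2Threshold = 0.6,
                       pThreshold = 0.05) {
    stopifnot(log2Threshold > 0, pThreshold > 0)
    direction <- ifelse(meanLog2 < -log2Threshold, "down",
                 ifelse(meanLog2 > log2Threshold, "up", "none"))
    passMag <- abs(meanLog2) > log2Threshold
    sig <- passMag & !is.na(pValue) & pValue < pThreshold
    tier <- ifelse(sig, "significant",
            ifelse(passMag, "candidate", "not_selected"))
    data.frame(direction = direction, tier = tier,
               stringsAsFactors = FALSE)
}

#' Call differential expression on a two-color array experiment
#'
#' Runs the detection filter, summarizes every cross-group comparison
#' ([crossGroupComparisons()]) into a per-probe mean and SD of log2
#' ratios, tests normalized sample-channel log ratios between groups with
#' [welchTTest()], and classifies each probe with [classifyDE()].
#'
#' A probe is detected on an array when its corrected sample-channel
#' foreground exceeds the \code{detectQuantile} quantile of that array's
#' corrected foregrounds; probes failing detection on more than half the
#' arrays are excluded from testing.
#'
#' @param mae a normalized \linkS4class{MirArrayExperiment}.
#' @param log2Threshold,pThreshold selection thresholds.
#' @param detectQuantile detection quantile (default 0.05); set to 0 to
#'   disable filtering.
#' @return data.frame with one row per tested probe: \code{mirna},
#'   \code{mean_log2_ratio}, \code{sd_log2}, \code{p_value},
#'   \code{n_comparisons}, \code{direction}, \code{tier}.
#' @export
callDifferentialExpression <- function(mae, log2Threshold = 0.6,
                                       pThreshold = 0.05,
                                       detectQuantile = 0.05) {
    stopifnot(is(mae, "MirArrayExperiment"))
    sbg <- SummarizedExperiment::assay(mae, "sampleBg")
    det <- sapply(colnames(sbg), function(a)
        sbg[, a] > quantile(sbg[, a], detectQuantile, na.rm = TRUE))
    keep <- rowSums(!det, na.rm = TRUE) <= ncol(det) / 2
    cmp <- crossGroupComparisons(mae)
    g <- arrayGroups(mae)
    Mn <- SummarizedExperiment::assay(mae, "Mnorm")
    neu <- Mn[, names(g)[g == "neuropathy"], drop = FALSE]
    ctl <- Mn[, names(g)[g == "control"], drop = FALSE]
    probes <- rownames(cmp)[keep]
    res <- lapply(probes, function(p) {
        v <- cmp[p, ]
        v <- v[is.finite(v)]
        pval <- if (ncol(neu) >= 2 && ncol(ctl) >= 2 &&
                    sum(is.finite(neu[p, ])) >= 2 &&
                    sum(is.finite(ctl[p, ])) >= 2) {
            suppressWarnings(welchTTest(neu[p, ], ctl[p, ])$p.value)
        } else NA_real_
        data.frame(mirna = p,
                   mean_log2_ratio = mean(v),
                   sd_log2 = if (length(v) >= 2) sd(v) else NA_real_,
                   p_value = pval,
                   n_comparisons = length(v),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out <- cbind(out, classifyDE(out$mean_log2_ratio, out$p_value,
                                 log2Threshold, pThreshold))
    rownames(out) <- NULL
    out
}

#' Write differential-expression results as TSV
#'
#' Log2 and fold-change style columns are rounded to 2 decimals at
#' serialization only.
#'
#' @param de result of [callDifferentialExpression()].
#' @param path output TSV path.
#' @param header optional comment line.
#' @export
writeDEResults <- function(de, path, header = NULL) {
    de$mean_log2_ratio <- round(de$mean_log2_ratio, 2)
    de$sd_log2 <- round(de$sd_log2, 2)
    writeTsv(de, path, header)
}
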