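## Shared statistical primitives: Welch's unequal-variance t-test (raw and
## summary-statistic forms) and the signed linear fold-change transform.

welchFromMoments <- function(meanA, sdA, nA, meanB, sdB, nB) {
    vA <- sdA^2 / nA
    vB <- sdB^2 / nB
    se2 <- vA + vB
    degenerate <- FALSE
    if (se2 == 0) {
        ## zero variance in both groups: convention p = 1 for equal means,
        ## p = 0 otherwise (not defined by the t distribution)
        degenerate <- TRUE
        if (meanA == meanB) {
            t <- 0; df <- nA + nB - 2; p <- 1
        } else {
            t <- sign(meanA - meanB) * Inf; df <- nA + nB - 2; p <- 0
        }
    } else {
        t <- (meanA - meanB) / sqrt(se2)
        df <- se2^2 / (vA^2 / (nA - 1) + vB^2 / (nB - 1))
        p <- 2 * pt(-abs(t), df)
    }
    list(t = t, df = df, p = p, degenerate = degenerate)
}

asHtest <- function(w, estimate, method, dataName) {
    if (w$degenerate)
        warning("zero variance in both groups; p-value set by convention")
    structure(list(statistic = c(t = w$t),
                   parameter = c(df = w$df),
                   p.value = w$p,
                   estimate = estimate,
                   alternative = "two.sided",
                   method = method,
                   data.name = dataName,
                   degenerate = w$degenerate),
              class = "htest")
}

#' Welch two-sample unequal-variance t-test
#'
#' Two-tailed two-sample t-test without the equal-variance assumption,
#' using the Welch--Satterthwaite degrees of freedom and the exact t
#' distribution (no normal approximation; group sizes in this kind of
#' study are 2--6).  When both groups have zero variance the p-value is
#' set by convention: 1 if the means are equal, 0 otherwise, with a
#' warning.
#'
#' @param x,y numeric vectors, at least 2 finite values each.
#' @return An object of class \code{"htest"} with the t statistic,
#'   Welch--Satterthwaite degrees of freedom and two-sided p-value.
#' @examples
#' welchTTest(c(1.1, 2.0, 2.9, 1.8), c(3.5, 4.1, 2.9, 4.4))
#' @seealso [welchTTestSummary()] for the mean/SD/n form.
#' @export
welchTTest <- function(x, y) {
    x <- as.numeric(x); y <- as.numeric(y)
    if (sum(is.finite(x)) < 2L || sum(is.finite(y)) < 2L)
        stop("each sample needs at least 2 finite values")
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    w <- welchFromMoments(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
    asHtest(w, c(`mean of x` = mean(x), `mean of y` = mean(y)),
            "Welch two-sample t-test",
            paste(deparse1(substitute(x)), "and", deparse1(substitute(y))))
}

#' Welch t-test from group summary statistics
#'
#' Identical formulas to [welchTTest()] applied directly to per-group
#' mean, SD and n, enabling checks against published mean +/- SD tables.
#'
#' @param meanA,sdA,nA mean, standard deviation (>= 0) and size (>= 2) of
#'   group A.
#' @param meanB,sdB,nB the same for group B.
#' @return An object of class \code{"htest"}.
#' @examples
#' # body-weight gain, 41 +/- 20 (n = 6) vs 7 +/- 5 (n = 6)
#' welchTTestSummary(41, 20, 6, 7, 5, 6)$p.value
#' @export
welchTTestSummary <- function(meanA, sdA, nA, meanB, sdB, nB) {
    stopifnot(is.finite(meanA), is.finite(meanB),
              sdA >= 0, sdB >= 0, nA >= 2, nB >= 2)
    w <- welchFromMoments(meanA, sdA, nA, meanB, sdB, nB)
    asHtest(w, c(`mean of A` = meanA, `mean of B` = meanB),
            "Welch two-sample t-test (summary statistics)",
            "group summaries")
}

#' Signed linear fold change from a log2 ratio
#'
#' Maps a log2 expression ratio L to the signed linear fold change
#' sign(L) * 2^|L|, the convention under which down-regulation is
#' reported as a negative multiple (e.g. L = -2.85 -> -7.21) and L = 0
#' maps to +1 (no change).
#'
#' @param log2Ratio numeric vector of finite log2 ratios.
#' @return Numeric vector of signed fold changes.
#' @examples
#' signedFoldChange(c(-2.85, 0, 1, 3.81))
#' @export
signedFoldChange <- function(log2Ratio) {
    log2Ratio <- as.numeric(log2Ratio)
    if (any(!is.finite(log2Ratio)))
        stop("log2Ratio must be finite")
    ifelse(log2Ratio == 0, 1, sign(log2Ratio) * 2^abs(log2Ratio))
}
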