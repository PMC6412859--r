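## Normexp background model: observed intensity X = B + S with
## B ~ Normal(mu, sigma^2) background and S ~ Exponential(mean alpha)
## signal.  Correction replaces X by E[S | X] + offset.

#' Fit normexp background-model parameters
#'
#' Estimates (mu, sigma, alpha) of the normal + exponential convolution
#' from a vector of foreground intensities.  The default estimator is the
#' method of moments: the exponential component carries all the skewness,
#' so alpha = (max(m3, 0)/2)^(1/3) from the third central moment, then
#' sigma^2 = var - alpha^2 and mu = mean - alpha, clamped to positivity.
#' \code{method = "mle"} refines the moment estimates by direct
#' maximization of the exact normexp log-likelihood.
#'
#' @param x numeric vector of foreground intensities (>= 50 values,
#'   non-negative).
#' @param method \code{"moments"} (default) or \code{"mle"}.
#' @return A list with components \code{mu}, \code{sigma}, \code{alpha}
#'   and \code{method}.
#' @examples
#' x <- rnorm(5000, 100, 15) + rexp(5000, 1/500)
#' normexpFit(x)
#' @export
normexpFit <- function(x, method = c("moments", "mle")) {
    method <- match.arg(method)
    x <- as.numeric(x)
    if (length(x) < 50L) stop("need at least 50 intensity values")
    if (any(!is.finite(x)) || any(x < 0))
        stop("intensities must be finite and non-negative")
    m <- mean(x)
    v <- var(x)
    if (v == 0) {
        warning("constant intensities; degenerate normexp fit")
        eps <- max(abs(m), 1) * 1e-6
        return(list(mu = m, sigma = eps, alpha = eps, method = method))
    }
    m3 <- mean((x - m)^3)
    if (m3 <= 0) {
        warning("non-positive skewness; falling back to minimal signal fraction")
        alpha <- sqrt(v) / 10
    } else {
        alpha <- (m3 / 2)^(1/3)
    }
    s2 <- v - alpha^2
    if (s2 <= 0) {
        ## exponential-dominated boundary: the signal carries essentially
        ## all the variance; warn only if the moments are inconsistent
        ## beyond what that regime explains
        if (alpha^2 > 2 * v)
            warning("inconsistent normexp moments; background clamped")
        s2 <- v * 1e-2
        alpha <- sqrt(v - s2)
    }
    fit <- list(mu = m - alpha, sigma = sqrt(s2), alpha = alpha,
                method = "moments")
    if (method == "mle") {
        nll <- function(par) {
            -sum(normexpLogDensity(x, par[1], exp(par[2]), exp(par[3])))
        }
        opt <- try(optim(c(fit$mu, log(fit$sigma), log(fit$alpha)), nll,
                         method = "Nelder-Mead",
                         control = list(maxit = 500)), silent = TRUE)
        if (!inherits(opt, "try-error") && is.finite(opt$value)) {
            fit <- list(mu = opt$par[1], sigma = exp(opt$par[2]),
                        alpha = exp(opt$par[3]), method = "mle")
        } else {
            warning("MLE refinement failed; returning moment estimates")
        }
    }
    fit
}

## log density of X = Normal(mu, sigma^2) + Exponential(mean alpha),
## computed in log space for numerical stability
normexpLogDensity <- function(x, mu, sigma, alpha) {
    z <- (x - mu - sigma^2 / alpha) / sigma
    -log(alpha) + (mu - x) / alpha + sigma^2 / (2 * alpha^2) +
        pnorm(z, log.p = TRUE)
}

#' Normexp background correction
#'
#' Replaces an observed intensity x by the posterior mean of the signal,
#' E[S | X = x] = mu.s + sigma * phi(mu.s/sigma) / Phi(mu.s/sigma) with
#' mu.s = x - mu - sigma^2/alpha, plus a positive offset that stabilizes
#' log ratios of weak spots (default 10).  The log-space Mills-ratio
#' evaluation keeps the result positive and monotone even for x far below
#' the background mean.
#'
#' @param x numeric vector of observed intensities.
#' @param params list with \code{mu}, \code{sigma}, \code{alpha}, as from
#'   [normexpFit()].
#' @param offset non-negative constant added to the corrected signal.
#' @return Numeric vector of corrected intensities, strictly greater than
#'   \code{offset}.
#' @examples
#' p <- list(mu = 50, sigma = 10, alpha = 200)
#' normexpSignal(70, p, offset = 10)
#' @export
normexpSignal <- function(x, params, offset = 10) {
    stopifnot(is.numeric(x), all(is.finite(x)), offset >= 0,
              params$sigma > 0, params$alpha > 0)
    mu.s <- x - params$mu - params$sigma^2 / params$alpha
    z <- mu.s / params$sigma
    ## phi(z)/Phi(z) via logs: stable for z << 0 (ratio ~ -z there)
    mills <- exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
    signal <- mu.s + params$sigma * mills
    pmax(signal, .Machine$double.xmin) + offset
}
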