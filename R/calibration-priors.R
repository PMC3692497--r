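#' Soft fossil-calibration prior density
#'
#' Log-density of a soft min/max calibration: uniform on (lower, upper)
#' carrying probability 1 - 2 * tailProb, a power-decay tail below the
#' minimum and a shifted-exponential tail above the maximum, each carrying
#' tailProb, with the density continuous at both bounds and integrating
#' to 1. With \code{lower = NULL} the bound is upper-only: a plateau on
#' (0, upper) carrying 1 - tailProb plus the exponential upper tail.
#'
#' @param t age(s) at which to evaluate (same units as the bounds).
#' @param lower,upper calibration bounds (lower < upper); \code{lower =
#'   NULL} for an upper-only bound.
#' @param tailProb probability mass in each tail (default 0.025).
#' @return log-density values; \code{-Inf} for \code{t <= 0}.
#' @examples
#' softBoundLogPrior(300, 250, 400)  # log(0.95 / 150)
#' @export
softBoundLogPrior <- function(t, lower = NULL, upper, tailProb = 0.025) {
  out <- rep(-Inf, length(t))
  pos <- t > 0
  if (is.null(lower)) {
    d <- (1 - tailProb) / upper
    lam <- d / tailProb
    below <- pos & t <= upper
    above <- pos & t > upper
    out[below] <- log(d)
    out[above] <- log(d) - lam * (t[above] - upper)
    return(out)
  }
  stopifnot(lower > 0, lower < upper)
  d <- (1 - 2 * tailProb) / (upper - lower)
  p <- d * lower / tailProb - 1          # power so the lower tail holds tailProb
  lam <- d / tailProb                    # exponential rate for the upper tail
  lo <- pos & t < lower
  mid <- t >= lower & t <= upper
  hi <- t > upper
  out[lo] <- log(d) + p * (log(t[lo]) - log(lower))
  out[mid] <- log(d)
  out[hi] <- log(d) - lam * (t[hi] - upper)
  out
}

#' Soft-bound cumulative distribution
#'
#' CDF matching [softBoundLogPrior()]; used to validate that prior-only
#' MCMC sampling reproduces the calibration density.
#'
#' @inheritParams softBoundLogPrior
#' @return probabilities in [0, 1].
#' @export
softBoundCDF <- function(t, lower = NULL, upper, tailProb = 0.025) {
  if (is.null(lower)) {
    d <- (1 - tailProb) / upper
    lam <- d / tailProb
    ifelse(t <= 0, 0,
           ifelse(t <= upper, d * t,
                  1 - tailProb * exp(-lam * (t - upper))))
  } else {
    d <- (1 - 2 * tailProb) / (upper - lower)
    p <- d * lower / tailProb - 1
    lam <- d / tailProb
    ifelse(t <= 0, 0,
           ifelse(t < lower, tailProb * (t / lower)^(p + 1),
                  ifelse(t <= upper, tailProb + d * (t - lower),
                         1 - tailProb * exp(-lam * (t - upper)))))
  }
}

#' Hard lower-bound calibration
#'
#' Log-density contribution of a hard minimum age: \code{-Inf} below the
#' bound, 0 above it. The flat part is proper only in combination with the
#' conditional node-age prior (all non-root ages uniform given the root
#' age), which is how the sampler embeds it.
#'
#' @param t age(s).
#' @param lower the hard minimum (> 0).
#' @return 0 or \code{-Inf} per element.
#' @export
hardLowerLogPrior <- function(t, lower) {
  stopifnot(lower > 0)
  ifelse(t >= lower, 0, -Inf)
}

#' Priors for the relaxed clock
#'
#' Gamma priors on the overall substitution rate per time unit (rgene) and
#' on the log-rate drift variance sigma^2, in the shape/rate
#' parameterization. Defaults are G(1, 5.2) and G(1, 5.6), matched to a
#' 2973-site amino-acid dataset with a 100-My time unit.
#'
#' @param rgeneShape,rgeneRate gamma prior on the mean rate mu.
#' @param sigma2Shape,sigma2Rate gamma prior on sigma^2.
#' @return list of the four (positive) hyperparameters.
#' @export
clockPriors <- function(rgeneShape = 1, rgeneRate = 5.2,
                        sigma2Shape = 1, sigma2Rate = 5.6) {
  stopifnot(rgeneShape > 0, rgeneRate > 0, sigma2Shape > 0, sigma2Rate > 0)
  list(rgeneShape = rgeneShape, rgeneRate = rgeneRate,
       sigma2Shape = sigma2Shape, sigma2Rate = sigma2Rate)
}

#' MCMC chain settings
#'
#' The full-scale schedule mirrors the production configuration (50,000
#' burn-in cycles, 200,000 samples taken every 20 cycles); the defaults
#' here are the desk-scale testing chain.
#'
#' @param burnIn burn-in sweeps (default 5000).
#' @param thin record every \code{thin}-th sweep after burn-in (default 2).
#' @param nSamples number of retained samples (default 20000).
#' @param seed RNG seed for the chain.
#' @param tailProb soft-calibration tail probability (default 0.025).
#' @return list of settings.
#' @export
chainSettings <- function(burnIn = 5000, thin = 2, nSamples = 20000,
                          seed = 1, tailProb = 0.025) {
  stopifnot(burnIn > 0, thin > 0, nSamples > 0)
  list(burnIn = as.integer(burnIn), thin = as.integer(thin),
       nSamples = as.integer(nSamples), seed = as.integer(seed),
       tailProb = tailProb)
}
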