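# Canonical JTT (Jones-Taylor-Thornton 1992) amino-acid exchangeabilities,
# as distributed with PAML (jones.dat): lower triangle, column-wise, state
# order A R N D C Q E G H I L K M F P S T W Y V.
.JTT_LOWER <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9,
  11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101,
  64, 126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15,
  503, 232, 8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59,
  38, 4, 46, 31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209,
  62, 323, 26, 597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26,
  12, 9, 181, 18, 5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201,
  33, 55, 8, 47, 16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21,
  479, 89, 10, 40, 245, 9, 32, 961, 14, 388, 248, 102, 59, 25, 52, 24,
  180, 65, 4, 21, 47, 103, 10, 8, 14, 43, 16, 29, 226, 24, 18, 323, 17,
  92, 12, 53, 536, 62, 285, 118, 6, 10, 23, 477, 35, 63, 38, 12, 21, 112,
  71, 25, 16)

# JTT equilibrium amino-acid frequencies (same source), renormalized to
# sum exactly to 1.
.JTT_FREQS <- local({
  f <- c(0.076748, 0.051691, 0.042645, 0.051544, 0.019803, 0.040752,
         0.061830, 0.073152, 0.022944, 0.053761, 0.091904, 0.058676,
         0.023826, 0.040126, 0.050901, 0.068765, 0.058565, 0.014261,
         0.032102, 0.066005)
  f / sum(f)
})

.jttExchangeabilities <- function() {
  m <- matrix(0, 20, 20, dimnames = list(.AA_STATES, .AA_STATES))
  m[lower.tri(m)] <- .JTT_LOWER
  m + t(m)
}

#' Discretize a gamma rate distribution into equal-probability categories
#'
#' Splits the Gamma(alpha, alpha) distribution (mean 1) into \code{k}
#' equal-probability bins and returns each bin's conditional mean as the
#' category rate (the CODEML/PHYML mean-rate convention, not medians).
#'
#' @param alpha gamma shape parameter (> 0).
#' @param k number of categories (>= 1).
#' @return list with \code{rates} (increasing, mean 1) and \code{weights}
#'   (all 1/k).
#' @examples
#' discretizeGamma(0.5, 4)$rates
#' @export
discretizeGamma <- function(alpha, k) {
  stopifnot(alpha > 0, k >= 1)
  if (k == 1) return(list(rates = 1, weights = 1))
  breaks <- stats::qgamma(seq(0, 1, length.out = k + 1),
                          shape = alpha, rate = alpha)
  # E[X; a < X < b] for Gamma(alpha, alpha) is the shape+1 CDF increment
  inc <- diff(stats::pgamma(breaks, shape = alpha + 1, rate = alpha))
  rates <- k * inc
  rates <- rates / sum(rates / k)  # exact mean 1
  list(rates = rates, weights = rep(1 / k, k))
}

#' Build a JTT(+I)+Gamma substitution model
#'
#' Assembles the JTT amino-acid model: generator Q with q_ij proportional
#' to s_ij pi_j, normalized so the expected substitution rate at
#' equilibrium is 1 per site per unit branch length across the rate-class
#' mixture. Among-site rate heterogeneity uses \code{nCategories}
#' equal-probability discrete-gamma classes (shape \code{alpha}) and an
#' optional invariant class of probability \code{pInv}; the variable-class
#' rates are rescaled by 1/(1 - pInv) so the overall mean rate stays 1.
#'
#' @param alpha gamma shape parameter (> 0).
#' @param nCategories number of gamma categories (default 4).
#' @param pInv proportion of invariant sites in [0, 1) (default 0).
#' @param freqs equilibrium frequencies; defaults to JTT's own. Supplying
#'   observed frequencies gives the +F variant.
#' @return a [SubstitutionModel-class].
#' @examples
#' m <- buildJTT(alpha = 0.5)
#' @export
buildJTT <- function(alpha = 1, nCategories = 4L, pInv = 0,
                     freqs = .JTT_FREQS) {
  if (alpha <= 0) stop("alpha must be > 0")
  stopifnot(length(freqs) == 20, all(freqs > 0))
  freqs <- freqs / sum(freqs)
  S <- .jttExchangeabilities()
  Q <- S * rep(freqs, each = 20)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q <- Q / scale
  g <- discretizeGamma(alpha, nCategories)
  catRates <- g$rates
  catWeights <- g$weights * (1 - pInv)
  if (pInv > 0) catRates <- catRates / (1 - pInv)
  # eigendecomposition of the pi-symmetrized generator, cached for P(t)
  sq <- sqrt(freqs)
  B <- Q * (sq / rep(sq, each = 20))  # diag(sq) Q diag(1/sq), elementwise
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  eig <- list(values = e$values,
              left = e$vectors / sq,              # diag(1/sq) U
              right = t(e$vectors * sq))          # t(U) diag(sq)
  new("SubstitutionModel", rates = S, freqs = freqs, alpha = alpha,
      nCategories = as.integer(nCategories), pInv = pInv, Q = Q,
      eig = eig, catRates = catRates, catWeights = catWeights)
}

#' Transition probability matrix P(t) = exp(Q t r)
#'
#' @param model a [SubstitutionModel-class].
#' @param t branch length (expected substitutions/site at rate 1).
#' @param rate rate multiplier (e.g. a gamma category rate).
#' @return 20x20 stochastic matrix.
#' @export
transitionProb <- function(model, t, rate = 1) {
  if (t < 0) stop("negative branch length")
  e <- model@eig
  P <- (e$left * rep(exp(e$values * t * rate), each = 20)) %*% e$right
  P[P < 0] <- 0
  P
}
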