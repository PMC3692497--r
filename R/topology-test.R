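#' Kishino-Hasegawa comparison of two topologies
#'
#' Compares the maximum-likelihood tree against a constrained topology
#' (typically the accepted species phylogeny): branch lengths are
#' re-optimized independently for each topology, per-site log-likelihoods
#' are computed, and the difference is summarized as
#' delta logL = logL(ML tree) - logL(constrained tree) with the KH normal
#' approximation SE = sqrt(n * var(per-site differences)). A gene is
#' accepted for dating when delta logL / SE < 1.
#'
#' @inheritParams siteLogLikelihoods
#' @param treeML the maximum-likelihood topology.
#' @param treeConstrained the constrained (species-phylogeny) topology.
#' @param rell if \code{TRUE}, also report a RELL bootstrap SE
#'   (\code{rellReplicates} site resamples of the fixed per-site
#'   differences) as a cross-check.
#' @param rellReplicates bootstrap replicates (default 1000).
#' @return list with \code{deltaLogL}, \code{se}, \code{ratio},
#'   \code{accepted}, per-site difference vector \code{siteDeltas}, and
#'   optionally \code{seRell}.
#' @export
khCompare <- function(alignment, treeML, treeConstrained, model,
                      rell = FALSE, rellReplicates = 1000) {
  if (identicalTopology(treeML, treeConstrained))
    return(list(deltaLogL = 0, se = 0, ratio = 0, accepted = TRUE,
                siteDeltas = numeric(nSites(alignment))))
  fitA <- optimizeBranchLengths(alignment, treeML, model)
  fitB <- optimizeBranchLengths(alignment, treeConstrained, model)
  sA <- siteLogLikelihoods(alignment, fitA$tree, model)$values
  sB <- siteLogLikelihoods(alignment, fitB$tree, model)$values
  d <- sA - sB
  n <- length(d)
  delta <- sum(d)
  se <- sqrt(n * stats::var(d))
  out <- list(deltaLogL = delta, se = se,
              ratio = if (se > 0) abs(delta) / se else
                if (delta == 0) 0 else Inf,
              accepted = acceptanceRule(delta, se), siteDeltas = d)
  if (rell) {
    sums <- replicate(rellReplicates,
                      sum(d[sample.int(n, n, replace = TRUE)]))
    out$seRell <- stats::sd(sums)
  }
  out
}

#' Gene-acceptance rule on a log-likelihood difference
#'
#' A gene whose ML tree conflicts with the accepted species phylogeny is
#' retained for divergence-time estimation when the conflict is within one
#' standard error: accepted iff |delta logL| / SE < 1. A ratio of exactly 1
#' (including the degenerate SE = 0 with a nonzero difference) is rejected.
#'
#' @param deltaLogL log-likelihood difference between the two topologies.
#' @param se its standard error (>= 0).
#' @return logical.
#' @examples
#' acceptanceRule(1.23, 2.35)  # TRUE
#' acceptanceRule(3.0, 1.0)    # FALSE
#' @export
acceptanceRule <- function(deltaLogL, se) {
  stopifnot(se >= 0)
  d <- abs(deltaLogL)
  if (se == 0) return(d == 0)
  d / se < 1
}

#' Test whether two trees share the same unrooted topology
#'
#' @param a,b ape \code{phylo} objects over the same tips.
#' @return logical.
#' @export
identicalTopology <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) return(FALSE)
  ua <- ape::unroot(a); ub <- ape::unroot(b)
  ua$edge.length <- NULL; ub$edge.length <- NULL
  isTRUE(.sameUnrootedTopology(ua, ub))
}

# topology-only comparison via ape's topological distance
.sameUnrootedTopology <- function(a, b) {
  d <- tryCatch(ape::dist.topo(a, b), error = function(e) NA)
  if (is.na(d)) return(FALSE)
  d == 0
}
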