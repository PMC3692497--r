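# Internal machinery: state encoding, site-pattern compression, the pruning
# recursion, and per-edge "flank" vectors used for fast branch-length work.

.encodeStates <- function(alignment) {
  states <- if (seqAlphabet(alignment) == "AA") .AA_STATES else .DNA_STATES
  m <- seqMatrix(alignment)
  enc <- match(m, states)          # NA for gap/unknown
  dim(enc) <- dim(m)
  rownames(enc) <- rownames(m)
  enc
}

.sitePatterns <- function(enc) {
  key <- apply(enc, 2, paste, collapse = ".")
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(pat = enc[, u, drop = FALSE], weights = tabulate(idx, sum(u)),
       index = idx)
}

# probability of a pattern under the zero-rate (invariant) class
.invariantProbs <- function(pat, freqs) {
  ns <- length(freqs)
  apply(pat, 2, function(col) {
    obs <- unique(col[!is.na(col)])
    if (length(obs) == 0) 1
    else if (length(obs) == 1) freqs[obs]
    else 0
  })
}

.tipCLV <- function(col, nStates) {
  npat <- length(col)
  v <- matrix(0, nStates, npat)
  isna <- is.na(col)
  v[, isna] <- 1
  v[cbind(col[!isna], which(!isna))] <- 1
  v
}

.checkTreeAlignment <- function(tree, alignment) {
  if (!setequal(tree$tip.label, taxonNames(alignment)))
    stop("tree tips and alignment taxa differ: ",
         paste(c(setdiff(tree$tip.label, taxonNames(alignment)),
                 setdiff(taxonNames(alignment), tree$tip.label)),
               collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
}

# Conditional likelihood vectors for all nodes, one [nStates x npat] matrix
# per node per rate category; also keeps each edge's contribution
# (P_e %*% clv_child) so sibling products can be reassembled.
.downPass <- function(tree, pat, model) {
  ns <- 20
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  el <- po$edge.length
  nnode <- max(E)
  ntip <- length(tree$tip.label)
  k <- length(model@catRates)
  npat <- ncol(pat)
  tipIdx <- match(tree$tip.label, rownames(pat))
  clv <- vector("list", k)
  contrib <- vector("list", k)
  for (c in seq_len(k)) {
    cl <- vector("list", nnode)
    for (tp in seq_len(ntip)) cl[[tp]] <- .tipCLV(pat[tipIdx[tp], ], ns)
    co <- vector("list", nrow(E))
    for (i in seq_len(nrow(E))) {
      ch <- E[i, 2]; pa <- E[i, 1]
      P <- transitionProb(model, el[i], model@catRates[c])
      co[[i]] <- P %*% cl[[ch]]
      cl[[pa]] <- if (is.null(cl[[pa]])) co[[i]] else cl[[pa]] * co[[i]]
    }
    clv[[c]] <- cl
    contrib[[c]] <- co
  }
  list(clv = clv, contrib = contrib, edge = E, edgeLength = el,
       root = E[nrow(E), 1], nTip = ntip)
}

.patternLogLik <- function(down, model, invP) {
  k <- length(model@catRates)
  L <- 0
  for (c in seq_len(k))
    L <- L + model@catWeights[c] *
      colSums(model@freqs * down$clv[[c]][[down$root]])
  if (model@pInv > 0) L <- L + model@pInv * invP
  log(L)
}

# Per-edge flank vectors: for edge i (parent -> child), U[[c]][[i]] is the
# likelihood of everything on the parent side (root prior included) and
# D = clv of the child, so that the total pattern likelihood is
# sum_ij U_i P_ij(t_i) D_j for every edge.
.edgeFlanks <- function(down, model) {
  E <- down$edge
  k <- length(model@catRates)
  nnode <- max(E)
  edgesOf <- split(seq_len(nrow(E)), E[, 1])  # parent -> edge rows
  childEdge <- integer(nnode)                 # node -> its parent edge row
  childEdge[E[, 2]] <- seq_len(nrow(E))
  U <- vector("list", k)
  for (c in seq_len(k)) {
    uv <- vector("list", nnode)
    uv[[down$root]] <- matrix(model@freqs, 20, ncol(down$clv[[c]][[1]]))
    Uc <- vector("list", nrow(E))
    for (i in rev(seq_len(nrow(E)))) {       # preorder
      pa <- E[i, 1]; ch <- E[i, 2]
      sib <- setdiff(edgesOf[[as.character(pa)]], i)
      u <- uv[[pa]]
      for (j in sib) u <- u * down$contrib[[c]][[j]]
      Uc[[i]] <- u
      if (ch > down$nTip) {
        P <- transitionProb(model, down$edgeLength[i], model@catRates[c])
        uv[[ch]] <- crossprod(P, u)
      }
    }
    U[[c]] <- Uc
  }
  U
}

.edgeLogLik <- function(t, i, down, flanks, model, invP) {
  k <- length(model@catRates)
  L <- 0
  for (c in seq_len(k)) {
    P <- transitionProb(model, t, model@catRates[c])
    D <- down$clv[[c]][[down$edge[i, 2]]]
    L <- L + model@catWeights[c] * colSums(flanks[[c]][[i]] * (P %*% D))
  }
  if (model@pInv > 0) L <- L + model@pInv * invP
  log(pmax(L, .Machine$double.xmin))
}

#' Per-site log-likelihoods by the pruning algorithm
#'
#' Computes the log-likelihood of an amino-acid alignment on a tree with
#' branch lengths under a [SubstitutionModel-class], via Felsenstein's
#' pruning recursion with discrete-gamma rate mixing. Gaps and unknown
#' residues are fully ambiguous (partial likelihood 1 for every state).
#'
#' @param alignment a [GeneAlignment-class] (amino-acid).
#' @param tree ape \code{phylo} with branch lengths in substitutions/site;
#'   tips must match the alignment taxa. Rooted or unrooted.
#' @param model a [SubstitutionModel-class].
#' @return list with \code{values} (per-site log-likelihoods) and
#'   \code{total} (their sum).
#' @export
siteLogLikelihoods <- function(alignment, tree, model) {
  .checkTreeAlignment(tree, alignment)
  enc <- .encodeStates(alignment)
  sp <- .sitePatterns(enc)
  down <- .downPass(tree, sp$pat, model)
  invP <- if (model@pInv > 0) .invariantProbs(sp$pat, model@freqs) else NULL
  ll <- .patternLogLik(down, model, invP)
  values <- ll[sp$index]
  list(values = values, total = sum(values))
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Optimizes each branch length in turn by bounded one-dimensional search
#' (Brent), using cached flank vectors so each branch's profile likelihood
#' is cheap, and cycles until the total log-likelihood improves by less
#' than \code{tol}.
#'
#' @inheritParams siteLogLikelihoods
#' @param tol convergence tolerance in log-likelihood units (default 1e-6).
#' @param maxCycles maximum optimization sweeps (default 30).
#' @param bounds branch-length search interval (default [1e-8, 20]).
#' @return list with \code{tree} (branch lengths replaced by their ML
#'   values) and \code{logL}.
#' @export
optimizeBranchLengths <- function(alignment, tree, model, tol = 1e-6,
                                  maxCycles = 30, bounds = c(1e-8, 20)) {
  .checkTreeAlignment(tree, alignment)
  # under a reversible model the two root branches are confounded (only
  # their sum is identifiable); optimize the unrooted tree instead
  if (ape::is.rooted(tree) && length(tree$tip.label) > 2)
    tree <- ape::unroot(tree)
  enc <- .encodeStates(alignment)
  sp <- .sitePatterns(enc)
  invP <- if (model@pInv > 0) .invariantProbs(sp$pat, model@freqs) else NULL
  wt <- sp$weights
  po <- ape::reorder.phylo(tree, "postorder")
  po$edge.length <- pmax(po$edge.length, bounds[1])
  down <- .downPass(po, sp$pat, model)
  cur <- sum(wt * .patternLogLik(down, model, invP))
  best <- list(tree = po, logL = cur)
  for (cycle in seq_len(maxCycles)) {
    flanks <- .edgeFlanks(down, model)
    el <- po$edge.length
    for (i in seq_along(el)) {
      f <- function(t) sum(wt * .edgeLogLik(t, i, down, flanks, model, invP))
      opt <- stats::optimize(f, bounds, maximum = TRUE, tol = 1e-8)
      if (opt$objective >= f(el[i])) el[i] <- opt$maximum
    }
    po$edge.length <- el
    down <- .downPass(po, sp$pat, model)
    new <- sum(wt * .patternLogLik(down, model, invP))
    if (new >= best$logL) best <- list(tree = po, logL = new)
    if (abs(new - cur) < tol) return(best)
    cur <- new
  }
  warning("branch-length optimization did not converge in ", maxCycles,
          " cycles; returning best so far")
  best
}

#' Estimate the gamma shape parameter alpha
#'
#' Maximizes the log-likelihood over alpha by bounded one-dimensional
#' search on [0.02, 100] (on a log scale), optionally alternating with
#' branch-length re-optimization.
#'
#' @inheritParams siteLogLikelihoods
#' @param nCategories,pInv model settings passed to [buildJTT()].
#' @param interval search bounds for alpha.
#' @param optimizeBranches if \code{TRUE}, alternate two rounds of alpha
#'   and branch-length optimization.
#' @return list with \code{alpha}, \code{logL}, and \code{tree}.
#' @export
estimateAlpha <- function(alignment, tree, nCategories = 4L, pInv = 0,
                          interval = c(0.02, 100),
                          optimizeBranches = FALSE) {
  if (nSites(alignment) < 2) stop("need at least 2 sites")
  fit <- function(tr) {
    opt <- stats::optimize(function(la) {
      m <- buildJTT(exp(la), nCategories, pInv)
      siteLogLikelihoods(alignment, tr, m)$total
    }, log(interval), maximum = TRUE, tol = 1e-4)
    list(alpha = exp(opt$maximum), logL = opt$objective)
  }
  res <- fit(tree)
  rounds <- if (optimizeBranches) 2 else 0
  for (r in seq_len(rounds)) {
    m <- buildJTT(res$alpha, nCategories, pInv)
    bl <- optimizeBranchLengths(alignment, tree, m)
    tree <- bl$tree
    res <- fit(tree)
  }
  if (res$alpha > 0.99 * interval[2] || res$alpha < 1.01 * interval[1])
    warning("alpha estimate at search boundary (", signif(res$alpha, 3),
            "); data may be rate-homogeneous or saturated")
  list(alpha = res$alpha, logL = res$logL, tree = tree)
}

#' Pairwise maximum-likelihood distance between two sequences
#'
#' Maximizes the two-sequence likelihood over a single divergence
#' parameter (expected substitutions/site) under the given model. Columns
#' with a gap or unknown in either sequence are ignored.
#'
#' @param seqA,seqB amino-acid sequences (single strings).
#' @param model a [SubstitutionModel-class].
#' @param bounds search interval (default [0, 20]).
#' @return the ML distance (numeric). A warning is issued for saturated
#'   pairs whose likelihood surface is flat up to the upper bound.
#' @examples
#' m <- buildJTT(alpha = 1)
#' pairwiseMLDistance("MKVLH", "MKVLH", m)  # ~0
#' @export
pairwiseMLDistance <- function(seqA, seqB, model, bounds = c(0, 20)) {
  a <- strsplit(toupper(seqA), "")[[1]]
  b <- strsplit(toupper(seqB), "")[[1]]
  if (length(a) != length(b)) stop("sequences must have equal length")
  ai <- match(a, .AA_STATES); bi <- match(b, .AA_STATES)
  ok <- !is.na(ai) & !is.na(bi)
  if (!any(ok)) stop("no comparable columns")
  counts <- matrix(0, 20, 20)
  tab <- table(factor(ai[ok], levels = 1:20), factor(bi[ok], levels = 1:20))
  counts[] <- as.numeric(tab)
  k <- length(model@catRates)
  f <- function(d) {
    L <- matrix(0, 20, 20)
    for (c in seq_len(k))
      L <- L + model@catWeights[c] *
        (model@freqs * transitionProb(model, d, model@catRates[c]))
    if (model@pInv > 0) diag(L) <- diag(L) + model@pInv * model@freqs
    sum(counts * log(pmax(L, .Machine$double.xmin)))
  }
  opt <- stats::optimize(f, bounds, maximum = TRUE, tol = 1e-8)
  d <- opt$maximum
  if (f(0) >= opt$objective) d <- 0
  if (d > 0.95 * bounds[2])
    warning("saturated pair: distance at upper bound ", signif(d, 4))
  d
}

#' Proportion of differing sites (p-distance)
#'
#' The fraction of columns at which two equal-length sequences differ.
#' Intended for use after complete deletion of gapped/missing columns.
#'
#' @param seqA,seqB sequences (single strings) of equal, positive length.
#' @return numeric in [0, 1].
#' @examples
#' pDistance("ACGT", "ACGA")  # 0.25
#' @export
pDistance <- function(seqA, seqB) {
  a <- strsplit(toupper(seqA), "")[[1]]
  b <- strsplit(toupper(seqB), "")[[1]]
  if (length(a) != length(b)) stop("sequences must have equal length")
  if (length(a) == 0) stop("zero columns")
  mean(a != b)
}
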