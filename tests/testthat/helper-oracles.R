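# Independent oracles used across the suite. Each reimplements the quantity
# being tested by a different route (enumeration, quadrature, closed form)
# and stays independent of the package's own algorithms.

# Optimal local-alignment raw score by exhaustive enumeration over aligned
# residue-pair subsets (no dynamic programming). A gap of length L costs
# gapOpen + L * gapExtend. Only feasible for short peptides.
oracleLocalScore <- function(a, b, mat, gapOpen = 11, gapExtend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- 0   # the empty local alignment
  gapCost <- function(len) if (len > 0) gapOpen + len * gapExtend else 0
  subsets <- function(n, k) utils::combn(n, k, simplify = FALSE)
  for (k in seq_len(min(na, nb))) {
    sa <- subsets(na, k); sb <- subsets(nb, k)
    for (ia in sa) for (ib in sb) {
      sc <- sum(mat[cbind(av[ia], bv[ib])])
      if (k > 1) {
        da <- diff(ia) - 1L
        db <- diff(ib) - 1L
        sc <- sc - sum(vapply(da, gapCost, numeric(1))) -
          sum(vapply(db, gapCost, numeric(1)))
      }
      if (sc > best) best <- sc
    }
  }
  best
}

# Per-site likelihood by summing over every assignment of states to the
# internal nodes (brute-force pruning oracle); handles discrete-gamma
# categories and the invariant class.
oracleSiteLogLik <- function(alignment, tree, model) {
  enc <- chondroclock:::.encodeStates(alignment)
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge; el <- po$edge.length
  ntip <- length(po$tip.label)
  nnode <- max(E)
  internal <- (ntip + 1):nnode
  tipRow <- match(po$tip.label, rownames(enc))
  k <- length(model@catRates)
  Ps <- lapply(seq_len(k), function(c)
    lapply(seq_len(nrow(E)), function(i)
      transitionProb(model, el[i], model@catRates[c])))
  root <- E[nrow(E), 1]
  nSites <- ncol(enc)
  out <- numeric(nSites)
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
  for (s in seq_len(nSites)) {
    Lsite <- 0
    for (c in seq_len(k)) {
      tot <- 0
      for (g in seq_len(nrow(grid))) {
        st <- integer(nnode)
        st[internal] <- grid[g, ]
        prob <- model@freqs[st[root]]
        ok <- TRUE
        for (i in seq_len(nrow(E))) {
          pa <- st[E[i, 1]]
          ch <- E[i, 2]
          chState <- if (ch <= ntip) enc[tipRow[ch], s] else st[ch]
          if (is.na(chState)) next      # missing tip: sums to 1
          prob <- prob * Ps[[c]][[i]][pa, chState]
          if (prob == 0) { ok <- FALSE; break }
        }
        if (ok) tot <- tot + prob
      }
      Lsite <- Lsite + model@catWeights[c] * tot
    }
    if (model@pInv > 0) {
      obs <- unique(stats::na.omit(enc[, s]))
      Lsite <- Lsite + model@pInv *
        (if (length(obs) == 0) 1
         else if (length(obs) == 1) model@freqs[obs] else 0)
    }
    out[s] <- log(Lsite)
  }
  out
}

# Gamma category means by adaptive quadrature over the equal-probability
# bins of Gamma(alpha, alpha).
oracleGammaRates <- function(alpha, k) {
  breaks <- stats::qgamma(seq(0, 1, length.out = k + 1),
                          shape = alpha, rate = alpha)
  vapply(seq_len(k), function(i) {
    lo <- breaks[i]
    hi <- if (is.finite(breaks[i + 1])) breaks[i + 1] else
      stats::qgamma(1 - 1e-12, alpha, alpha) * 4
    stats::integrate(function(x) x * stats::dgamma(x, alpha, alpha),
                     lo, hi, rel.tol = 1e-10)$value * k
  }, numeric(1))
}

# Reference end-trimming by a direct column scan.
oracleTrim <- function(mat, refRows, window, minOcc, missingChars) {
  occ <- 1 - colSums(matrix(mat[refRows, , drop = FALSE] %in% missingChars,
                            length(refRows))) / length(refRows)
  dense <- occ >= minOcc
  n <- length(dense)
  firstRun <- function(d) {
    for (i in seq_len(length(d) - window + 1))
      if (all(d[i:(i + window - 1)])) return(i)
    NA_integer_
  }
  from <- firstRun(dense)
  to <- firstRun(rev(dense))
  if (is.na(from) || is.na(to)) return(NULL)
  mat[, from:(n - to + 1), drop = FALSE]
}

# Random rooted tree with branch lengths, for round-trip and likelihood
# property tests.
randomTree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- round(stats::runif(nrow(tr$edge), 0.02, 0.5), 6)
  tr
}

aaString <- function(n, seed) {
  set.seed(seed)
  paste(sample(chondroclock:::.AA_STATES, n, replace = TRUE), collapse = "")
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
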