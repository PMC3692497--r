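#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining with a deterministic tie-break:
#' when several pairs minimize the Q-criterion equally (within 1e-12
#' relative), the pair whose sorted cluster labels are lexicographically
#' smallest is joined (a cluster is labelled by its smallest tip). On
#' additive distance matrices the generating topology and branch lengths
#' are recovered exactly.
#'
#' @param D symmetric, non-negative distance matrix with zero diagonal.
#' @param labels taxon labels (defaults to \code{rownames(D)}).
#' @return an unrooted ape \code{phylo}.
#' @export
njTree <- function(D, labels = rownames(D)) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  stopifnot(ncol(D) == n, length(labels) == n)
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix not symmetric")
  if (any(D < 0)) stop("negative distances")
  if (any(diag(D) != 0)) stop("nonzero diagonal")
  fmt <- function(x) sprintf("%.10g", x)
  if (n == 1) return(readNewick(paste0("(", labels, ");")))
  if (n == 2)
    return(readNewick(sprintf("(%s:%s,%s:%s);", labels[1], fmt(D[1, 2] / 2),
                              labels[2], fmt(D[1, 2] / 2))))
  frag <- labels
  lab <- labels
  repeat {
    m <- nrow(D)
    if (m == 3) break
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-12 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      p <- sort(c(lab[ij[1]], lab[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    newFrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    newLab <- min(lab[i], lab[j])
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    frag <- c(frag[keep], newFrag)
    lab <- c(lab[keep], newLab)
  }
  x1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  x2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  x3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(x1), frag[2], fmt(x2),
                 frag[3], fmt(x3))
  readNewick(txt)
}

#' Maximum-likelihood tree search by nearest-neighbor interchange
#'
#' Greedy hill climbing: starting from a given topology, branch lengths are
#' optimized, all NNI rearrangements are scored (each with its own
#' branch-length optimization), and the best neighbor is accepted while it
#' improves the log-likelihood. Returns a topology none of whose NNI
#' neighbors improves on it.
#'
#' @inheritParams siteLogLikelihoods
#' @param startTree starting topology over the alignment taxa (rooted
#'   trees are unrooted first).
#' @param maxRounds cap on accepted moves (default 20).
#' @param tol improvement needed to accept a move (default 1e-4 logL).
#' @return list with \code{tree} (ML branch lengths) and \code{logL}.
#' @export
mlSearchNNI <- function(alignment, startTree, model, maxRounds = 20,
                        tol = 1e-4) {
  tr <- startTree
  if (ape::is.rooted(tr)) tr <- ape::unroot(tr)
  if (is.null(tr$edge.length))
    tr$edge.length <- rep(0.1, nrow(tr$edge))
  cur <- optimizeBranchLengths(alignment, tr, model)
  for (round in seq_len(maxRounds)) {
    nbs <- phangorn::nni(cur$tree)
    scores <- lapply(seq_along(nbs), function(j) {
      nb <- nbs[[j]]    # [[ decompresses multiPhylo tip labels
      nb$edge.length <- rep(0.1, nrow(nb$edge))
      optimizeBranchLengths(alignment, nb, model)
    })
    lls <- vapply(scores, `[[`, numeric(1), "logL")
    if (max(lls) > cur$logL + tol) cur <- scores[[which.max(lls)]]
    else return(cur)
  }
  cur
}

#' Build a timetree from a topology and node ages
#'
#' Assigns each internal node an age (Ma) and sets branch lengths to
#' parent-minus-child age differences (tips at age 0), giving an
#' ultrametric chronogram.
#'
#' @param topology rooted ape \code{phylo}.
#' @param ages named numeric vector of internal-node ages in Ma; names are
#'   node labels (\code{topology$node.label}) or internal node numbers.
#' @return \code{phylo} with branch lengths in My and ages recoverable via
#'   [nodeAgesFromTree()].
#' @export
treeWithAges <- function(topology, ages) {
  ntip <- length(topology$tip.label)
  nnode <- topology$Nnode
  full <- numeric(ntip + nnode)
  if (!is.null(names(ages)) && !is.null(topology$node.label) &&
      all(names(ages) %in% topology$node.label)) {
    idx <- ntip + match(names(ages), topology$node.label)
  } else {
    idx <- as.integer(names(ages))
    if (anyNA(idx)) stop("ages must be named by node labels or numbers")
  }
  full[idx] <- ages
  if (length(idx) != nnode) stop("need an age for every internal node")
  el <- full[topology$edge[, 1]] - full[topology$edge[, 2]]
  if (any(el <= 0)) stop("ages must strictly decrease from root to tips")
  topology$edge.length <- el
  topology
}

#' Recover internal-node ages from an ultrametric tree
#'
#' @param tree rooted ultrametric \code{phylo} with branch lengths in My.
#' @return numeric vector of ages (Ma) for internal nodes, in ape node
#'   order (named by node labels when present).
#' @export
nodeAgesFromTree <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth) - depth
  out <- ages[(length(tree$tip.label) + 1):length(ages)]
  if (!is.null(tree$node.label)) names(out) <- tree$node.label
  out
}

#' Find the node calibrated by a set of tips
#'
#' @param tree rooted \code{phylo}.
#' @param tips character vector of tip labels; their most recent common
#'   ancestor is returned.
#' @return internal node number.
#' @export
cladeNode <- function(tree, tips) {
  miss <- setdiff(tips, tree$tip.label)
  if (length(miss))
    stop("calibration tips absent from topology: ",
         paste(miss, collapse = ", "))
  if (length(tips) == 1) stop("a calibrated clade needs at least two tips")
  ape::getMRCA(tree, tips)
}
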