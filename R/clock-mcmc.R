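# Bayesian relaxed-clock node dating.
#
# Model: fixed rooted topology; internal-node ages t (time unit 100 My);
# independent log-normal branch rates, log r_e ~ N(log mu, sigma2) (mu is
# the median rate, no mean correction); gamma hyperpriors on mu and sigma2;
# soft min/max or hard-lower fossil calibrations; uncalibrated node ages
# uniform conditional on the root age. Expected substitutions on a branch
# are r_e * (t_parent - t_child).
#
# Likelihood modes: "exact" (full pruning likelihood, small trees),
# "approx" (Gaussian approximation in unrooted branch lengths around their
# ML values, with per-branch curvatures), "prior" (likelihood off, for
# validating that the sampler targets the stated prior).

.cladeTipSets <- function(tree) {
  ntip <- length(tree$tip.label)
  E <- ape::reorder.phylo(tree, "postorder")$edge
  sets <- vector("list", max(E))
  for (tp in seq_len(ntip)) sets[[tp]] <- tree$tip.label[tp]
  for (i in seq_len(nrow(E))) {
    pa <- E[i, 1]; ch <- E[i, 2]
    sets[[pa]] <- c(sets[[pa]], sets[[ch]])
  }
  lapply(sets, sort)
}

.bipartitionKey <- function(tips, allTips) {
  comp <- sort(setdiff(allTips, tips))
  a <- paste(sort(tips), collapse = "|")
  b <- paste(comp, collapse = "|")
  if (a < b) paste(a, b, sep = "##") else paste(b, a, sep = "##")
}

# ML branch lengths and per-branch curvatures on the unrooted topology,
# keyed by bipartition so rooted edges can be mapped onto them.
.approxFit <- function(alignment, tree, model) {
  utr <- ape::unroot(tree)
  utr$edge.length <- rep(0.1, nrow(utr$edge))  # neutral starting lengths
  fit <- optimizeBranchLengths(alignment, utr, model, tol = 1e-4)
  ft <- fit$tree
  enc <- .encodeStates(alignment)
  sp <- .sitePatterns(enc)
  invP <- if (model@pInv > 0) .invariantProbs(sp$pat, model@freqs) else NULL
  wt <- sp$weights
  down <- .downPass(ft, sp$pat, model)
  flanks <- .edgeFlanks(down, model)
  bhat <- down$edgeLength
  H <- numeric(length(bhat))
  for (i in seq_along(bhat)) {
    f <- function(t) sum(wt * .edgeLogLik(t, i, down, flanks, model, invP))
    h <- max(1e-3 * bhat[i], 1e-5)
    b <- max(bhat[i], h + 1e-9)
    H[i] <- max(-(f(b + h) - 2 * f(b) + f(b - h)) / h^2, 1e-6)
  }
  allTips <- sort(tree$tip.label)
  sets <- .cladeTipSets(ft)
  keys <- vapply(seq_len(nrow(down$edge)), function(i)
    .bipartitionKey(sets[[down$edge[i, 2]]], allTips), character(1))
  list(bhat = bhat, H = H, keys = keys, logL = fit$logL)
}

.mapRootedEdges <- function(tree, keys) {
  allTips <- sort(tree$tip.label)
  sets <- .cladeTipSets(tree)
  E <- tree$edge
  vapply(seq_len(nrow(E)), function(i) {
    k <- .bipartitionKey(sets[[E[i, 2]]], allTips)
    m <- match(k, keys)
    if (is.na(m)) stop("internal error: unmatched bipartition")
    m
  }, integer(1))
}

.setupCalibrations <- function(tree, calibrations, rootUpper, tailProb) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  type <- integer(nnode)   # 0 none, 1 soft both, 2 soft upper-only, 3 hard lower
  lo <- rep(NA_real_, nnode); up <- rep(NA_real_, nnode)
  for (i in seq_len(nrow(calibrations))) {
    nd <- cladeNode(tree, calibrations$clade_tips[[i]])
    l <- calibrations$lower_Ma[i] / 100
    u <- calibrations$upper_Ma[i] / 100
    if (calibrations$style[i] == "hard-lower") {
      type[nd] <- 3L; lo[nd] <- l
    } else {
      if (is.na(l)) { type[nd] <- 2L; up[nd] <- u }
      else { type[nd] <- 1L; lo[nd] <- l; up[nd] <- u }
    }
  }
  if (type[root] %in% c(0L, 3L)) {
    impUp <- if (!is.null(rootUpper)) rootUpper / 100
             else max(up, lo, na.rm = TRUE) * 1.5
    message("root age upper bound not calibrated; using ",
            format(impUp * 100), " Ma",
            if (is.null(rootUpper)) " (1.5x the oldest calibration bound)")
    if (type[root] == 3L) { type[root] <- 1L; up[root] <- impUp }
    else { type[root] <- 2L; up[root] <- impUp }
  }
  list(type = type, lower = lo, upper = up, tailProb = tailProb)
}

.calibLogDensity <- function(cal, node, t) {
  switch(cal$type[node] + 1L,
         0,
         softBoundLogPrior(t, cal$lower[node], cal$upper[node],
                           cal$tailProb),
         softBoundLogPrior(t, NULL, cal$upper[node], cal$tailProb),
         hardLowerLogPrior(t, cal$lower[node]))
}

.initAges <- function(tree, cal) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  E <- tree$edge
  nnode <- ntip + tree$Nnode
  h <- integer(nnode)              # max edge count to a tip below
  for (i in seq_len(nrow(E)))      # postorder
    h[E[i, 1]] <- max(h[E[i, 1]], h[E[i, 2]] + 1L)
  ages <- numeric(nnode)
  ages[root] <- if (cal$type[root] == 1L)
    (cal$lower[root] + cal$upper[root]) / 2 else 0.8 * cal$upper[root]
  for (i in rev(seq_len(nrow(E)))) {   # preorder
    pa <- E[i, 1]; ch <- E[i, 2]
    if (ch <= ntip) next
    a <- ages[pa] * h[ch] / h[pa]
    if (cal$type[ch] %in% c(1L, 3L) && !is.na(cal$lower[ch]))
      a <- max(a, min(cal$lower[ch] * 1.02,
                      (cal$lower[ch] + ages[pa]) / 2))
    if (!is.na(cal$upper[ch])) a <- min(a, cal$upper[ch] * 0.98)
    ages[ch] <- min(a, ages[pa] * 0.99)
  }
  for (i in seq_len(nrow(E))) {        # repair any ordering violations
    pa <- E[i, 1]; ch <- E[i, 2]
    if (ch > ntip && ages[pa] <= ages[ch]) ages[pa] <- ages[ch] * 1.01
  }
  ages
}

#' Relaxed-clock MCMC over node ages and branch rates
#'
#' Metropolis-within-Gibbs sampling of internal-node ages, per-branch
#' log-normal rates, the mean rate mu and the drift variance sigma2 on a
#' fixed rooted topology under fossil calibrations. Proposal windows are
#' auto-tuned towards 20-40\% acceptance during burn-in and frozen
#' afterwards. Deterministic given the seed in \code{settings}.
#'
#' @param tree rooted binary ape \code{phylo}; tips must match the
#'   alignment when a likelihood mode is used.
#' @param calibrations calibration table as from [readCalibrations()]:
#'   columns \code{clade_tips} (list of tip-label vectors), \code{lower_Ma},
#'   \code{upper_Ma}, \code{style} (\code{soft} / \code{hard-lower}).
#' @param alignment a [GeneAlignment-class]; required unless
#'   \code{mode = "prior"}.
#' @param model a [SubstitutionModel-class]; required with a likelihood.
#' @param priors a [clockPriors()] list.
#' @param settings a [chainSettings()] list.
#' @param mode \code{"approx"} (Gaussian approximation around ML branch
#'   lengths; default), \code{"exact"} (full pruning likelihood; small
#'   trees), or \code{"prior"} (likelihood off).
#' @param rootUpper optional root upper bound in Ma when the root carries
#'   no upper calibration (otherwise 1.5x the oldest calibration is used,
#'   with a message).
#' @return a [ClockTrace-class]. Age columns \code{t_*} are in 100-My time
#'   units; [summarizeTrace()] converts to Ma.
#' @export
runClockMCMC <- function(tree, calibrations, alignment = NULL,
                         model = NULL, priors = clockPriors(),
                         settings = chainSettings(),
                         mode = c("approx", "exact", "prior"),
                         rootUpper = NULL) {
  mode <- match.arg(mode)
  if (!ape::is.rooted(tree) || !ape::is.binary(tree))
    stop("tree must be rooted and binary")
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  m <- tree$Nnode
  root <- ntip + 1L
  E <- tree$edge
  nE <- nrow(E)
  cal <- .setupCalibrations(tree, calibrations, rootUpper,
                            settings$tailProb)
  internal <- (ntip + 1L):(ntip + m)
  childEdges <- lapply(seq_len(ntip + m), function(nd) which(E[, 1] == nd))
  parentEdge <- integer(ntip + m)
  parentEdge[E[, 2]] <- seq_len(nE)
  adjEdges <- lapply(internal, function(nd)
    c(if (nd != root) parentEdge[nd], childEdges[[nd]]))
  names(adjEdges) <- internal
  rootEdges <- childEdges[[root]]
  nonRootEdges <- setdiff(seq_len(nE), rootEdges)

  if (mode != "prior" && (is.null(alignment) || is.null(model)))
    stop("alignment and model are required unless mode = 'prior'")
  if (mode != "prior") .checkTreeAlignment(tree, alignment)

  coordOf <- NULL; bhat <- NULL; Hc <- NULL; exactFn <- NULL
  if (mode == "approx") {
    ap <- .approxFit(alignment, tree, model)
    coordOf <- .mapRootedEdges(tree, ap$keys)
    bhat <- ap$bhat; Hc <- ap$H
  } else if (mode == "exact") {
    enc <- .encodeStates(alignment)
    sp <- .sitePatterns(enc)
    invP <- if (model@pInv > 0) .invariantProbs(sp$pat, model@freqs)
            else NULL
    template <- tree
    exactFn <- function(len) {
      template$edge.length <- len
      down <- .downPass(template, sp$pat, model)
      sum(sp$weights * .patternLogLik(down, model, invP))
    }
  }

  set.seed(settings$seed)
  ages <- .initAges(tree, cal)
  mu <- priors$rgeneShape / priors$rgeneRate
  s2 <- priors$sigma2Shape / priors$sigma2Rate
  x <- rep(log(mu), nE)                       # log branch rates
  y <- log(mu); z <- log(s2)
  dt <- ages[E[, 1]] - ages[E[, 2]]
  len <- exp(x) * dt

  uFromLen <- function(len) {
    u <- numeric(max(coordOf))
    u[coordOf[nonRootEdges]] <- len[nonRootEdges]
    u[coordOf[rootEdges[1]]] <- len[rootEdges[1]] + len[rootEdges[2]]
    u
  }
  llOfU <- function(u) -0.5 * Hc * (u - bhat)^2
  if (mode == "approx") { u <- uFromLen(len); llc <- llOfU(u) }
  if (mode == "exact") curLL <- exactFn(len)

  nodePriorDelta <- function(nd, tNew, tOld) {
    d <- .calibLogDensity(cal, nd, tNew) - .calibLogDensity(cal, nd, tOld)
    if (nd == root) d <- d - (m - 1) * (log(tNew) - log(tOld))
    d
  }

  wAge <- rep(0.1, m); names(wAge) <- internal
  wRate <- 0.3; wRootRate <- 0.3; wMu <- 0.4; wSigma <- 0.6
  accAge <- numeric(m); tryAge <- numeric(m)
  accRate <- 0; tryRate <- 0; accRR <- 0; tryRR <- 0
  accMu <- 0; tryMu <- 0; accSig <- 0; trySig <- 0

  totalSweeps <- settings$burnIn + settings$thin * settings$nSamples
  out <- matrix(NA_real_, settings$nSamples, m + nE + 2)
  nodeLabs <- if (!is.null(tree$node.label)) tree$node.label
              else as.character(internal)
  colnames(out) <- c(paste0("t_", nodeLabs), paste0("r_", seq_len(nE)),
                     "mu", "sigma2")
  rec <- 0L

  for (sweep in seq_len(totalSweeps)) {
    ## --- node ages ---
    for (k in seq_len(m)) {
      nd <- internal[k]
      t0 <- ages[nd]
      prop <- t0 + wAge[k] * (stats::runif(1) - 0.5)
      tryAge[k] <- tryAge[k] + 1
      kids <- E[childEdges[[nd]], 2]
      loB <- max(ages[kids], 0)
      upB <- if (nd == root) Inf else ages[E[parentEdge[nd], 1]]
      if (prop <= loB || prop >= upB) next
      dP <- nodePriorDelta(nd, prop, t0)
      if (dP == -Inf) next
      adj <- adjEdges[[k]]
      agesNew <- ages; agesNew[nd] <- prop
      lenAdj <- exp(x[adj]) * (agesNew[E[adj, 1]] - agesNew[E[adj, 2]])
      if (mode == "approx") {
        lenNew <- len; lenNew[adj] <- lenAdj
        cc <- unique(coordOf[adj])
        uNew <- u
        for (c2 in cc) {
          es <- which(coordOf == c2)
          uNew[c2] <- sum(lenNew[es])
        }
        dL <- sum(llOfU(uNew)[cc] - llc[cc])
      } else if (mode == "exact") {
        lenNew <- len; lenNew[adj] <- lenAdj
        newLL <- exactFn(lenNew)
        dL <- newLL - curLL
      } else dL <- 0
      if (log(stats::runif(1)) < dP + dL) {
        ages <- agesNew; len[adj] <- lenAdj
        if (mode == "approx") { u <- uNew; llc[cc] <- llOfU(uNew)[cc] }
        if (mode == "exact") curLL <- newLL
        accAge[k] <- accAge[k] + 1
      }
    }
    ## --- branch rates ---
    sdr <- sqrt(exp(z))
    if (mode %in% c("approx", "prior")) {
      e <- nonRootEdges
      xp <- x[e] + wRate * (stats::runif(length(e)) - 0.5)
      dP <- stats::dnorm(xp, y, sdr, log = TRUE) -
            stats::dnorm(x[e], y, sdr, log = TRUE)
      if (mode == "approx") {
        lenNew <- exp(xp) * dt2(ages, E, e)
        cc <- coordOf[e]
        dL <- -0.5 * Hc[cc] * ((lenNew - bhat[cc])^2) - llc[cc]
      } else { lenNew <- exp(xp) * dt2(ages, E, e); dL <- 0 }
      acc <- log(stats::runif(length(e))) < dP + dL
      tryRate <- tryRate + length(e); accRate <- accRate + sum(acc)
      if (any(acc)) {
        ea <- e[acc]
        x[ea] <- xp[acc]; len[ea] <- lenNew[acc]
        if (mode == "approx") {
          cca <- coordOf[ea]
          u[cca] <- len[ea]
          llc[cca] <- -0.5 * Hc[cca] * (u[cca] - bhat[cca])^2
        }
      }
      for (e1 in rootEdges) {      # the two root branches share a coordinate
        xp1 <- x[e1] + wRootRate * (stats::runif(1) - 0.5)
        tryRR <- tryRR + 1
        dP1 <- stats::dnorm(xp1, y, sdr, log = TRUE) -
               stats::dnorm(x[e1], y, sdr, log = TRUE)
        l1 <- exp(xp1) * (ages[E[e1, 1]] - ages[E[e1, 2]])
        if (mode == "approx") {
          c1 <- coordOf[e1]
          u1 <- u[c1] - len[e1] + l1
          dL1 <- (-0.5 * Hc[c1] * (u1 - bhat[c1])^2) - llc[c1]
        } else dL1 <- 0
        if (log(stats::runif(1)) < dP1 + dL1) {
          x[e1] <- xp1; len[e1] <- l1
          if (mode == "approx") {
            u[c1] <- u1; llc[c1] <- -0.5 * Hc[c1] * (u1 - bhat[c1])^2
          }
          accRR <- accRR + 1
        }
      }
    } else {                       # exact: scalar updates, full recompute
      for (e1 in seq_len(nE)) {
        xp1 <- x[e1] + wRate * (stats::runif(1) - 0.5)
        tryRate <- tryRate + 1
        dP1 <- stats::dnorm(xp1, y, sdr, log = TRUE) -
               stats::dnorm(x[e1], y, sdr, log = TRUE)
        lenNew <- len
        lenNew[e1] <- exp(xp1) * (ages[E[e1, 1]] - ages[E[e1, 2]])
        newLL <- exactFn(lenNew)
        if (log(stats::runif(1)) < dP1 + newLL - curLL) {
          x[e1] <- xp1; len <- lenNew; curLL <- newLL
          accRate <- accRate + 1
        }
      }
    }
    ## --- mu ---
    yp <- y + wMu * (stats::runif(1) - 0.5)
    tryMu <- tryMu + 1
    dP <- priors$rgeneShape * (yp - y) -
      priors$rgeneRate * (exp(yp) - exp(y)) +
      sum(stats::dnorm(x, yp, sdr, log = TRUE) -
          stats::dnorm(x, y, sdr, log = TRUE))
    if (log(stats::runif(1)) < dP) { y <- yp; accMu <- accMu + 1 }
    ## --- sigma2 ---
    zp <- z + wSigma * (stats::runif(1) - 0.5)
    trySig <- trySig + 1
    sdp <- sqrt(exp(zp))
    dP <- priors$sigma2Shape * (zp - z) -
      priors$sigma2Rate * (exp(zp) - exp(z)) +
      sum(stats::dnorm(x, y, sdp, log = TRUE) -
          stats::dnorm(x, y, sdr, log = TRUE))
    if (log(stats::runif(1)) < dP) { z <- zp; accSig <- accSig + 1 }

    ## --- burn-in window tuning ---
    if (sweep <= settings$burnIn && sweep %% 100 == 0) {
      adj <- function(w, a, t) {
        r <- if (t > 0) a / t else 0.3
        min(max(w * exp(1.5 * (r - 0.3)), 1e-4), 20)
      }
      for (k in seq_len(m)) wAge[k] <- adj(wAge[k], accAge[k], tryAge[k])
      wRate <- adj(wRate, accRate, tryRate)
      wRootRate <- adj(wRootRate, accRR, tryRR)
      wMu <- adj(wMu, accMu, tryMu)
      wSigma <- adj(wSigma, accSig, trySig)
      accAge[] <- 0; tryAge[] <- 0
      accRate <- tryRate <- accRR <- tryRR <- 0
      accMu <- tryMu <- accSig <- trySig <- 0
      dt <- ages[E[, 1]] - ages[E[, 2]]
    }
    ## --- record ---
    if (sweep > settings$burnIn &&
        (sweep - settings$burnIn) %% settings$thin == 0 &&
        rec < settings$nSamples) {
      rec <- rec + 1L
      out[rec, ] <- c(ages[internal], exp(x), exp(y), exp(z))
    }
  }
  accv <- c(age = mean(accAge / pmax(tryAge, 1)),
            rate = if (tryRate > 0) accRate / tryRate else NA,
            mu = if (tryMu > 0) accMu / tryMu else NA,
            sigma2 = if (trySig > 0) accSig / trySig else NA)
  new("ClockTrace", samples = out[seq_len(rec), , drop = FALSE],
      tree = tree, nodeLabels = nodeLabs,
      settings = c(settings, list(mode = mode)), acceptance = accv)
}

# branch durations for a subset of edges (helper kept tiny for the sampler)
dt2 <- function(ages, E, e) ages[E[e, 1]] - ages[E[e, 2]]

#' Posterior summaries of a dating trace
#'
#' Per-node posterior mean, median and equal-tail 95\% interval of the
#' divergence times, converted to Ma, plus a kernel density estimate on a
#' 512-point grid per node and the posterior mean rate per branch.
#'
#' @param trace a [ClockTrace-class].
#' @param prob interval mass (default 0.95, equal tails).
#' @return list with \code{nodes} (data.frame: node, mean_Ma, median_Ma,
#'   ci_lower_Ma, ci_upper_Ma), \code{rates} (posterior mean per branch)
#'   and \code{densities} (named list of \code{density} objects, Ma scale).
#' @export
summarizeTrace <- function(trace, prob = 0.95) {
  s <- trace@samples
  tcols <- grep("^t_", colnames(s), value = TRUE)
  a <- (1 - prob) / 2
  nodes <- do.call(rbind, lapply(tcols, function(cn) {
    v <- s[, cn] * 100
    q <- unname(stats::quantile(v, c(a, 0.5, 1 - a), type = 7))
    data.frame(node = sub("^t_", "", cn), mean_Ma = mean(v),
               median_Ma = q[2], ci_lower_Ma = q[1], ci_upper_Ma = q[3])
  }))
  stopifnot(all(nodes$ci_lower_Ma <= nodes$median_Ma + 1e-9),
            all(nodes$median_Ma <= nodes$ci_upper_Ma + 1e-9))
  dens <- lapply(tcols, function(cn) {
    v <- s[, cn] * 100
    if (stats::sd(v) == 0)
      return(list(x = rep(v[1], 512), y = rep(Inf, 512)))
    stats::density(v, n = 512)
  })
  names(dens) <- sub("^t_", "", tcols)
  rcols <- grep("^r_", colnames(s), value = TRUE)
  rates <- colMeans(s[, rcols, drop = FALSE])
  list(nodes = nodes, rates = rates, densities = dens)
}

#' Effective sample size of an MCMC trace
#'
#' ESS from the autocorrelation function using Geyer's initial positive
#' sequence truncation: n / (1 + 2 * sum of leading autocorrelations).
#'
#' @param x numeric vector of sequential samples.
#' @return effective sample size (capped at \code{length(x)}).
#' @export
effectiveSize <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  maxLag <- min(n - 1, 2000)
  rho <- stats::acf(x, lag.max = maxLag, plot = FALSE)$acf[-1]
  ssum <- 0
  k <- 1
  while (k <= length(rho) - 1) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    ssum <- ssum + pair
    k <- k + 2
  }
  min(n, n / (1 + 2 * ssum))
}

#' Agreement check between replicate chains
#'
#' Flags parameters whose posterior means differ between two replicate
#' chains by more than a relative tolerance, and reports effective sample
#' sizes, mirroring the practice of running replicate chains with
#' different seeds to detect convergence failure.
#'
#' @param traceA,traceB [ClockTrace-class] objects with identical
#'   parameterizations.
#' @param relTol relative tolerance on posterior means (default 0.02).
#' @return list with \code{table} (parameter, means, relative difference,
#'   ESS per chain, flag) and \code{pass} (no age parameter flagged).
#' @export
convergenceCheck <- function(traceA, traceB, relTol = 0.02) {
  sA <- traceA@samples; sB <- traceB@samples
  if (!identical(colnames(sA), colnames(sB)))
    stop("traces have different parameterizations")
  mA <- colMeans(sA); mB <- colMeans(sB)
  rel <- abs(mA - mB) / pmax(abs((mA + mB) / 2), .Machine$double.eps)
  tab <- data.frame(parameter = colnames(sA), mean_a = mA, mean_b = mB,
                    rel_diff = rel,
                    ess_a = vapply(colnames(sA), function(cn)
                      effectiveSize(sA[, cn]), numeric(1)),
                    ess_b = vapply(colnames(sB), function(cn)
                      effectiveSize(sB[, cn]), numeric(1)),
                    flagged = rel > relTol, row.names = NULL)
  ageRows <- grepl("^t_", tab$parameter)
  list(table = tab, pass = !any(tab$flagged[ageRows]))
}
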