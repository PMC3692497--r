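# Synthetic-data generators: sequence evolution along trees, paralog-bearing
# gene families for the orthology screen, and the 12-taxon vertebrate
# calibration scenario used for validating the dating machinery.

#' Derive a child seed from a master seed
#'
#' Counter-based seed splitting so that each module of a simulation can be
#' regenerated independently yet reproducibly from one master seed. Always
#' returns a positive integer below 2^31.
#'
#' @param seed master seed (integer).
#' @param index counter (integer >= 0).
#' @return derived integer seed.
#' @export
splitSeed <- function(seed, index) {
  v <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 1103
  as.integer(v %% 2147483646) + 1L
}

#' Simulate an alignment along a tree with branch lengths
#'
#' Evolves amino-acid sequences down a tree whose branch lengths are in
#' expected substitutions/site (at rate 1): root states are drawn from the
#' model's equilibrium frequencies, each site draws one rate class
#' (a discrete-gamma category, or the invariant class with probability
#' pInv), and states evolve along each branch with transition
#' probabilities exp(Q * length * classRate). Deterministic given the seed.
#'
#' @param tree ape \code{phylo} (rooted or unrooted) with branch lengths
#'   in substitutions/site.
#' @param model a [SubstitutionModel-class].
#' @param nSites number of sites.
#' @param seed RNG seed.
#' @return a [GeneAlignment-class] over the tree's tips.
#' @export
simulateAlignment <- function(tree, model, nSites, seed = 1) {
  set.seed(seed)
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  el <- po$edge.length
  ntip <- length(po$tip.label)
  nnode <- max(E)
  root <- E[nrow(E), 1]
  k <- length(model@catRates)
  classRate <- c(model@catRates, 0)                # last class = invariant
  classProb <- c(model@catWeights, model@pInv)
  siteClass <- sample.int(k + 1, nSites, replace = TRUE, prob = classProb)
  states <- matrix(NA_integer_, nnode, nSites)
  states[root, ] <- sample.int(20, nSites, replace = TRUE,
                               prob = model@freqs)
  for (i in rev(seq_len(nrow(E)))) {               # preorder
    pa <- E[i, 1]; ch <- E[i, 2]
    st <- states[pa, ]
    out <- integer(nSites)
    for (cl in unique(siteClass)) {
      idx <- which(siteClass == cl)
      if (classRate[cl] == 0) { out[idx] <- st[idx]; next }
      P <- transitionProb(model, el[i], classRate[cl])
      for (s in unique(st[idx])) {
        j <- idx[st[idx] == s]
        out[j] <- sample.int(20, length(j), replace = TRUE, prob = P[s, ])
      }
    }
    states[ch, ] <- out
  }
  m <- matrix(.AA_STATES[states[seq_len(ntip), , drop = FALSE]], ntip,
              nSites, dimnames = list(po$tip.label, NULL))
  GeneAlignment(m, alphabet = "AA")
}

#' Define a simulation scenario on a calibrated timetree
#'
#' Bundles a timetree (node ages in Ma), a substitution model, per-branch
#' rates and a seed into a reproducible scenario. Rates are either
#' explicit per-edge multipliers (substitutions/site per 100 My) or drawn
#' log-normally, log r ~ N(log rateMean, rateSigma2), emulating
#' independent-rates clock variation across lineages.
#'
#' @param timetree rooted ultrametric \code{phylo} with branch lengths in
#'   My (e.g. from [treeWithAges()]).
#' @param model a [SubstitutionModel-class].
#' @param nSites sites to simulate.
#' @param seed master seed; branch-rate draws and sequence evolution use
#'   split sub-seeds.
#' @param rateMean median branch rate in substitutions/site per 100 My
#'   (default 0.2).
#' @param rateSigma2 log-rate drift variance (default 0.1).
#' @param branchRates optional explicit per-edge rates (postorder edge
#'   order), overriding the log-normal draws.
#' @return list of class \code{"simulationScenario"}.
#' @export
simulationScenario <- function(timetree, model, nSites, seed = 1,
                               rateMean = 0.2, rateSigma2 = 0.1,
                               branchRates = NULL) {
  stopifnot(ape::is.rooted(timetree), !is.null(timetree$edge.length))
  structure(list(timetree = timetree, model = model, nSites = nSites,
                 seed = seed, rateMean = rateMean,
                 rateSigma2 = rateSigma2, branchRates = branchRates),
            class = "simulationScenario")
}

#' Simulate an alignment from a scenario
#'
#' Converts the scenario's timetree (My) and branch rates into expected
#' substitutions/site per branch and evolves sequences along it.
#'
#' @param scenario a [simulationScenario()].
#' @return list with \code{alignment}, \code{tree} (branch lengths in
#'   substitutions/site — the simulation truth), and \code{rates} (per
#'   edge, substitutions/site per 100 My).
#' @export
simulateScenario <- function(scenario) {
  st <- scenario
  po <- ape::reorder.phylo(st$timetree, "postorder")
  nE <- nrow(po$edge)
  rates <- st$branchRates
  if (is.null(rates)) {
    set.seed(splitSeed(st$seed, 1))
    rates <- exp(stats::rnorm(nE, log(st$rateMean), sqrt(st$rateSigma2)))
  }
  if (length(rates) != nE) stop("need one rate per edge")
  tr <- po
  tr$edge.length <- rates * po$edge.length / 100   # My -> 100-My units
  aln <- simulateAlignment(tr, st$model, st$nSites,
                           seed = splitSeed(st$seed, 2))
  list(alignment = aln, tree = tr, rates = rates)
}

#' Simulate a gene family for the orthology screen
#'
#' Builds the databases the preliminary screen consumes — a chimaera query
#' plus outgroup (human), shark and ray/skate peptide collections — from a
#' gene family evolved on a calibrated gnathostome tree (gnathostome split
#' 460 Ma, chimaera-elasmobranch 421 Ma, shark-ray 306 Ma), optionally
#' with an out-paralog duplicated before the gnathostome split.
#'
#' Loss patterns: \code{"none"} keeps orthologs everywhere (the screen
#' should pass the gene); \code{"hidden-paralogy"} deletes the ortholog in
#' the chimaera and the outgroup, so the query and the outgroup sequence
#' are both out-paralogs while sharks and rays keep orthologs — the
#' classic trap in which paralogs masquerade as orthologs, which the
#' bit-score rule should fail because the query then scores higher
#' against the outgroup than against the elasmobranch orthologs.
#'
#' @param seed RNG seed.
#' @param includeOutparalog simulate a duplicate copy originating at
#'   \code{duplicationAge}.
#' @param duplicationAge duplication age in Ma; must predate the
#'   gnathostome split (460 Ma) when a paralog is included.
#' @param lossPattern \code{"none"} or \code{"hidden-paralogy"} (the
#'   latter requires \code{includeOutparalog}).
#' @param nSites peptide length (default 1200, a long multi-domain
#'   vertebrate protein of the kind that dominated the screened candidate
#'   set).
#' @param rate substitution rate per 100 My (default 0.1, i.e. 1e-9
#'   substitutions/site/year, a typical vertebrate nuclear protein rate).
#' @param alpha gamma shape for among-site variation (default 1.5).
#' @return list with \code{query}, \code{outgroupDb}, \code{sharkDb},
#'   \code{rayDb} (named character vectors) and \code{truth}
#'   (\code{orthologous}: whether the query/database configuration is a
#'   genuine ortholog set).
#' @export
makeGeneFamily <- function(seed = 1, includeOutparalog = FALSE,
                           duplicationAge = 550,
                           lossPattern = c("none", "hidden-paralogy"),
                           nSites = 1200, rate = 0.1, alpha = 1.5) {
  lossPattern <- match.arg(lossPattern)
  if (lossPattern == "hidden-paralogy" && !includeOutparalog)
    stop("hidden-paralogy requires includeOutparalog = TRUE")
  speciesNwk <- function(suf)
    sprintf(paste0("(Hs%s:460,(Cm%s:421,((S1%s:150,S2%s:150):156,",
                   "(R1%s:150,R2%s:150):156):115):39)"),
            suf, suf, suf, suf, suf, suf)
  if (includeOutparalog) {
    if (duplicationAge <= 460)
      stop("duplication must predate the gnathostome split (460 Ma)")
    d <- duplicationAge - 460
    nwk <- sprintf("(%s:%g,%s:%g);", speciesNwk("_o"), d,
                   speciesNwk("_p"), d)
  } else {
    nwk <- paste0(speciesNwk("_o"), ";")
  }
  tt <- readNewick(nwk)
  model <- buildJTT(alpha = alpha, nCategories = 4L)
  tr <- tt
  tr$edge.length <- tt$edge.length * rate / 100
  aln <- simulateAlignment(tr, model, nSites, seed = seed)
  seqs <- apply(seqMatrix(aln), 1, paste, collapse = "")
  pick <- function(who) seqs[paste0(who, "_o")]
  if (lossPattern == "none") {
    out <- list(query = unname(pick("Cm")),
                outgroupDb = c(Hs = unname(pick("Hs"))),
                sharkDb = c(S1 = unname(pick("S1")),
                            S2 = unname(pick("S2"))),
                rayDb = c(R1 = unname(pick("R1")),
                          R2 = unname(pick("R2"))),
                truth = list(orthologous = TRUE))
  } else {
    out <- list(query = unname(seqs["Cm_p"]),
                outgroupDb = c(Hs = unname(seqs["Hs_p"])),
                sharkDb = c(S1 = unname(seqs["S1_o"]),
                            S2 = unname(seqs["S2_o"])),
                rayDb = c(R1 = unname(seqs["R1_o"]),
                          R2 = unname(seqs["R2_o"])),
                truth = list(orthologous = FALSE))
  }
  out
}

.FIG4_NEWICK <- paste0(
  "(((((((Hs,Md)n7,Gg)n6,Xt)n5,((Ol,Fr)n9,Dr)n8)n4,",
  "((Sh,Ry)n11,Cm)n10)n3,Ci)n2,Dm)n1;")

.FIG4_AGES <- list(
  I  = c(n1 = 566, n2 = 547, n3 = 454, n4 = 418, n5 = 343, n6 = 319,
         n7 = 148, n8 = 157, n9 = 112, n10 = 421, n11 = 306),
  II = c(n1 = 566, n2 = 547, n3 = 454, n4 = 418, n5 = 343, n6 = 319,
         n7 = 148, n8 = 157, n9 = 112, n10 = 420, n11 = 261))

.fig4Calibrations <- function(constraintSet) {
  node11lower <- if (constraintSet == "I") 250 else 190
  data.frame(
    clade_tips = I(list(c("Hs", "Dm"), c("Hs", "Ci"), c("Hs", "Cm"),
                        c("Hs", "Dr"), c("Hs", "Xt"), c("Hs", "Gg"),
                        c("Hs", "Md"), c("Ol", "Dr"), c("Ol", "Fr"),
                        c("Cm", "Sh"), c("Sh", "Ry"))),
    lower_Ma = c(550, NA, 422, 416, 330, 312, 125, 150, 97,
                 410, node11lower),
    upper_Ma = c(581, 581, 463, 422, 350, 330, 171, 165, 151, NA, NA),
    style = c(rep("soft", 9), "hard-lower", "hard-lower"),
    stringsAsFactors = FALSE)
}

#' The 12-taxon vertebrate calibration scenario
#'
#' A reproducible stand-in for the inputs of a nuclear-gene dating
#' analysis of vertebrates: the accepted 12-species topology (4
#' tetrapods, 3 teleosts, 3 chondrichthyans, 2 outgroups; internal nodes
#' labelled n1-n11), node ages set to representative published
#' divergence-time estimates as simulation truth, a
#' 19-constraint calibration table (8 soft min/max nodes, one soft
#' upper-only node, hard lower bounds of 410 Ma at the
#' chimaera-elasmobranch node n10 and 250 Ma — constraint set I — or
#' 190 Ma — set II — at the shark-ray node n11; the soft bounds are
#' synthetic reconstructions bracketing the truth ages, not published
#' values), and a JTT+Gamma alignment simulated under independent
#' log-normal branch rates.
#'
#' @param constraintSet \code{"I"} (shark-ray lower bound 250 Ma) or
#'   \code{"II"} (190 Ma).
#' @param nSites alignment length (default 2000).
#' @param seed master seed.
#' @param alpha gamma shape used for simulation (default 0.6, mid-range
#'   of per-gene estimates for vertebrate nuclear proteins).
#' @param rateMean,rateSigma2 clock-variation parameters passed to
#'   [simulationScenario()].
#' @return list with \code{timetree} (ages in My on branches, labels
#'   n1-n11), \code{trueAges} (named, Ma), \code{calibrations},
#'   \code{alignment}, \code{tree} (true substitutions/site branch
#'   lengths), \code{rates} and \code{model}.
#' @export
makeFig4Scenario <- function(constraintSet = c("I", "II"), nSites = 2000,
                             seed = 1, alpha = 0.6, rateMean = 0.2,
                             rateSigma2 = 0.1) {
  constraintSet <- match.arg(constraintSet)
  topo <- readNewick(.FIG4_NEWICK)
  ages <- .FIG4_AGES[[constraintSet]]
  tt <- treeWithAges(topo, ages)
  model <- buildJTT(alpha = alpha, nCategories = 4L)
  sc <- simulationScenario(tt, model, nSites, seed = seed,
                           rateMean = rateMean, rateSigma2 = rateSigma2)
  sim <- simulateScenario(sc)
  list(timetree = tt, trueAges = ages,
       calibrations = .fig4Calibrations(constraintSet),
       alignment = sim$alignment, tree = sim$tree, rates = sim$rates,
       model = model)
}

#' Write a calibration table to TSV
#'
#' @param calibrations calibration data.frame (list-column
#'   \code{clade_tips} collapsed with commas).
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
writeCalibrations <- function(calibrations, path) {
  out <- calibrations
  out$clade_tips <- vapply(calibrations$clade_tips, paste,
                           character(1), collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
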