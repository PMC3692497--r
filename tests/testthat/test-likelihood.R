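test_that("zero-branch likelihood reduces to the stationary frequency", {
  m <- buildJTT(alpha = 1, nCategories = 1L)
  aln <- GeneAlignment(c(a = "M", b = "M"))
  tr <- readNewick("(a:0,b:0);")
  ll <- siteLogLikelihoods(aln, tr, m)
  expect_equal(ll$total, log(m@freqs[match("M", chondroclock:::.AA_STATES)]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("pruning equals brute-force ancestral-state enumeration", {
  m3 <- buildJTT(alpha = 0.6)
  aln3 <- GeneAlignment(c(a = "MK", b = "MR", c = "LK"))
  tr3 <- readNewick("(a:0.2,b:0.4,c:0.3);")
  got <- siteLogLikelihoods(aln3, tr3, m3)
  expect_lt(max(abs(got$values - oracleSiteLogLik(aln3, tr3, m3))), 1e-8)

  m4 <- buildJTT(alpha = 1.2, pInv = 0.15)
  aln4 <- GeneAlignment(c(a = "MKV", b = "MRV", c = "LK-", d = "MKX"))
  tr4 <- readNewick("((a:0.1,b:0.3):0.2,(c:0.25,d:0.15):0.1);")
  got4 <- siteLogLikelihoods(aln4, tr4, m4)
  expect_lt(max(abs(got4$values - oracleSiteLogLik(aln4, tr4, m4))), 1e-8)
  expect_equal(got4$total, sum(got4$values))
})

test_that("likelihood is invariant to root placement and tip order", {
  m <- buildJTT(alpha = 0.9)
  tr <- randomTree(4, 77)
  aln <- simulateAlignment(tr, m, 50, seed = 78)
  base <- siteLogLikelihoods(aln, tr, m)$total
  utr <- ape::unroot(tr)
  expect_equal(siteLogLikelihoods(aln, utr, m)$total, base,
               tolerance = 1e-8)
  for (node in utr$edge[, 2][utr$edge[, 2] > 4][1]) {
    rr <- ape::root(utr, node = node, resolve.root = TRUE)
    expect_equal(siteLogLikelihoods(aln, rr, m)$total, base,
                 tolerance = 1e-8)
  }
  perm <- seqMatrix(aln)[c(3, 1, 4, 2), ]
  expect_equal(siteLogLikelihoods(GeneAlignment(perm), tr, m)$total, base,
               tolerance = 1e-10)
})

test_that("likelihood engine agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  m <- buildJTT(alpha = 0.5)
  tr <- randomTree(6, 123)
  aln <- simulateAlignment(tr, m, 300, seed = 124)
  mine <- siteLogLikelihoods(aln, tr, m)$total
  pd <- phangorn::phyDat(seqMatrix(aln), type = "AA")
  ref <- phangorn::pml(ape::unroot(tr), pd, model = "JTT", k = 4,
                       shape = 0.5)$logLik
  expect_equal(mine, ref, tolerance = 1e-6)
})

test_that("branch-length optimization recovers simulated lengths", {
  m <- buildJTT(alpha = 1, nCategories = 1L)
  tr <- readNewick("((a:0.12,b:0.22):0.08,(c:0.3,d:0.06):0.1);")
  aln <- simulateAlignment(tr, m, 30000, seed = 5)
  fit <- optimizeBranchLengths(aln, tr, m)
  utr <- ape::reorder.phylo(ape::unroot(tr), "postorder")
  expect_equal(fit$tree$edge.length, utr$edge.length, tolerance = 0.05)
})

test_that("optimization is an ascent and stable at its fixed point", {
  m <- buildJTT(alpha = 0.8)
  tr <- randomTree(5, 200)
  aln <- simulateAlignment(tr, m, 400, seed = 201)
  fit <- optimizeBranchLengths(aln, tr, m)
  for (i in 1:8) {
    start <- ape::unroot(tr)
    set.seed(300 + i)
    start$edge.length <- stats::runif(nrow(start$edge), 0.01, 1)
    before <- siteLogLikelihoods(aln, start, m)$total
    after <- optimizeBranchLengths(aln, start, m)
    expect_gte(after$logL, before)
    expect_equal(after$logL, fit$logL, tolerance = 1e-3)
  }
  again <- optimizeBranchLengths(aln, fit$tree, m)
  expect_lt(max(abs(again$tree$edge.length - fit$tree$edge.length)), 1e-3)
})

test_that("alpha estimation recovers the simulating value", {
  m <- buildJTT(alpha = 0.5)
  tr <- randomTree(5, 9)
  aln <- simulateAlignment(tr, m, 10000, seed = 10)
  est <- estimateAlpha(aln, tr)
  expect_equal(est$alpha, 0.5, tolerance = 0.1)

  grid <- exp(seq(log(0.05), log(20), length.out = 50))
  gl <- vapply(grid, function(a)
    siteLogLikelihoods(aln, tr, buildJTT(alpha = a))$total, numeric(1))
  expect_gte(est$logL, max(gl) - 1e-4)
})

test_that("rate-homogeneous data drive alpha towards the upper bound", {
  m <- buildJTT(alpha = 1e6, nCategories = 1L)
  tr <- randomTree(4, 31)
  aln <- simulateAlignment(tr, m, 2000, seed = 32)
  est <- suppressWarnings(estimateAlpha(aln, tr))
  # far above any realistic heterogeneity, and the profile is flat up to
  # the search bound (the boundary itself is hit only in the infinite-data
  # limit)
  expect_gt(est$alpha, 10)
  atBound <- siteLogLikelihoods(aln, tr, buildJTT(alpha = 100))$total
  expect_lt(est$logL - atBound, 2)
})

test_that("pairwise ML distance recovers truth and matches a grid search", {
  m <- buildJTT(alpha = 1)
  expect_equal(pairwiseMLDistance("MKVLH", "MKVLH", m), 0, tolerance = 1e-6)

  tr <- readNewick("(a:0.1,b:0.1);")
  aln <- simulateAlignment(tr, m, 10000, seed = 44)
  s <- apply(seqMatrix(aln), 1, paste, collapse = "")
  d <- pairwiseMLDistance(s["a"], s["b"], m)
  expect_equal(d, 0.2, tolerance = 0.02)

  grid <- seq(0.05, 0.5, by = 1e-4)
  nll <- function(dd) {
    k <- length(m@catRates)
    L <- Reduce(`+`, lapply(seq_len(k), function(c)
      m@catWeights[c] * (m@freqs * transitionProb(m, dd, m@catRates[c]))))
    ai <- match(strsplit(s["a"], "")[[1]], chondroclock:::.AA_STATES)
    bi <- match(strsplit(s["b"], "")[[1]], chondroclock:::.AA_STATES)
    sum(log(L[cbind(ai, bi)]))
  }
  gBest <- grid[which.max(vapply(grid, nll, numeric(1)))]
  expect_equal(d, gBest, tolerance = 1e-3)
})

test_that("p-distance counts mismatching columns", {
  expect_equal(pDistance("ACGT", "ACGA"), 0.25)
  expect_equal(pDistance("MKVL", "MKVL"), 0)
  expect_error(pDistance("", ""), "zero columns")
  set.seed(55)
  for (i in 1:10) {
    a <- aaString(60, 900 + i); b <- aaString(60, 950 + i)
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    expect_equal(pDistance(a, b), sum(av != bv) / 60)
  }
})
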