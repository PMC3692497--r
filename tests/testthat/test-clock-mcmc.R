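# Shorter chains than the package defaults are used here; the
# full-scale schedule is exercised through configuration only.

test_that("prior-only sampling reproduces an isolated calibration density", {
  sc <- makeFig4Scenario("I", nSites = 10, seed = 2)
  tr <- runClockMCMC(sc$timetree, sc$calibrations, mode = "prior",
                     settings = chainSettings(burnIn = 1000, thin = 1,
                                              nSamples = 5000, seed = 21))
  # n7 (therian split, soft 125-171 Ma) is far from its neighbours, so its
  # marginal should match the calibration density itself
  v <- sort(tr@samples[, "t_n7"] * 100)
  ks <- max(abs(seq_along(v) / length(v) - softBoundCDF(v, 125, 171)))
  expect_lt(ks, 0.05)
})

test_that("hard lower bounds are never crossed in the chain", {
  sc <- makeFig4Scenario("I", nSites = 10, seed = 3)
  tr <- runClockMCMC(sc$timetree, sc$calibrations, mode = "prior",
                     settings = chainSettings(burnIn = 500, thin = 1,
                                              nSamples = 3000, seed = 5))
  expect_true(all(tr@samples[, "t_n10"] >= 4.10))
  expect_true(all(tr@samples[, "t_n11"] >= 2.50))
  # and ages always respect the topology ordering
  expect_true(all(tr@samples[, "t_n10"] < tr@samples[, "t_n3"]))
  expect_true(all(tr@samples[, "t_n11"] < tr@samples[, "t_n10"]))
})

test_that("the sampler is deterministic given the seed", {
  sc <- makeFig4Scenario("I", nSites = 10, seed = 4)
  st <- chainSettings(burnIn = 200, thin = 1, nSamples = 500, seed = 99)
  a <- runClockMCMC(sc$timetree, sc$calibrations, mode = "prior",
                    settings = st)
  b <- runClockMCMC(sc$timetree, sc$calibrations, mode = "prior",
                    settings = st)
  expect_identical(a@samples, b@samples)
})

test_that("missing calibration tips fail before sampling", {
  sc <- makeFig4Scenario("I", nSites = 10, seed = 6)
  bad <- sc$calibrations
  bad$clade_tips[[1]] <- c("Hs", "nosuchtaxon")
  expect_error(runClockMCMC(sc$timetree, bad, mode = "prior"),
               "absent")
})

test_that("exact and approximate likelihood modes agree on a small tree", {
  topo <- readNewick("(((a,b)x1,c)x2,d)x3;")
  tt <- treeWithAges(topo, c(x1 = 100, x2 = 200, x3 = 300))
  model <- buildJTT(alpha = 1, nCategories = 2L)
  sim <- simulateScenario(simulationScenario(tt, model, 300, seed = 12,
                                             rateMean = 0.2,
                                             rateSigma2 = 0.05))
  cal <- data.frame(clade_tips = I(list(c("a", "b"), c("a", "d"))),
                    lower_Ma = c(80, 250), upper_Ma = c(120, 350),
                    style = c("soft", "soft"))
  st <- chainSettings(burnIn = 400, thin = 1, nSamples = 1200, seed = 8)
  ex <- runClockMCMC(tt, cal, alignment = sim$alignment, model = model,
                     mode = "exact", settings = st)
  ap <- runClockMCMC(tt, cal, alignment = sim$alignment, model = model,
                     mode = "approx", settings = st)
  se <- summarizeTrace(ex)$nodes
  sa <- summarizeTrace(ap)$nodes
  expect_equal(se$mean_Ma, sa$mean_Ma, tolerance = 0.08)
  # both recover the simulation truth inside their intervals
  truth <- c(x3 = 300, x2 = 200, x1 = 100)
  for (i in seq_len(nrow(se))) {
    tv <- truth[se$node[i]]
    expect_gte(tv, se$ci_lower_Ma[i] - 1e-9)
    expect_lte(tv, se$ci_upper_Ma[i] + 1e-9)
  }
})

test_that("trace summaries compute means, quantiles and densities", {
  mk <- function(v) new("ClockTrace",
                        samples = cbind(t_x = v, r_1 = rep(1, length(v)),
                                        mu = rep(1, length(v)),
                                        sigma2 = rep(1, length(v))),
                        tree = NULL, nodeLabels = "x",
                        settings = list(burnIn = 0L, thin = 1L, seed = 1L,
                                        mode = "prior"),
                        acceptance = c(age = 0.3))
  cons <- summarizeTrace(mk(rep(2, 100)))
  expect_equal(cons$nodes$mean_Ma, 200)
  expect_equal(cons$nodes$median_Ma, 200)
  expect_equal(cons$nodes$ci_lower_Ma, 200)
  expect_equal(cons$nodes$ci_upper_Ma, 200)

  set.seed(1)
  z <- stats::rnorm(1e5)
  s <- summarizeTrace(mk(z + 100))   # keep ages positive
  expect_equal(s$nodes$ci_lower_Ma / 100 - 100, -1.96, tolerance = 0.02)
  expect_equal(s$nodes$ci_upper_Ma / 100 - 100, 1.96, tolerance = 0.02)

  set.seed(2)
  skew <- exp(stats::rnorm(2e4, 0, 0.8))
  ssk <- summarizeTrace(mk(skew))
  expect_lte(ssk$nodes$median_Ma, ssk$nodes$mean_Ma)
})

test_that("effective sample size matches the AR(1) closed form", {
  set.seed(14)
  n <- 20000
  for (rho in c(0.3, 0.7)) {
    x <- numeric(n)
    for (i in 2:n) x[i] <- rho * x[i - 1] + stats::rnorm(1)
    expect_equal(effectiveSize(x), n * (1 - rho) / (1 + rho),
                 tolerance = 0.2)
  }
})

test_that("convergence check flags diverged means", {
  mk <- function(v) new("ClockTrace",
                        samples = cbind(t_x = v, mu = rep(1, length(v))),
                        tree = NULL, nodeLabels = "x",
                        settings = list(mode = "prior"),
                        acceptance = c(age = 0.3))
  set.seed(3)
  v <- stats::runif(500, 4, 5)
  same <- convergenceCheck(mk(v), mk(v))
  expect_true(same$pass)
  off <- convergenceCheck(mk(v), mk(v * 1.1), relTol = 0.02)
  expect_false(off$pass)
  expect_true(off$table$flagged[off$table$parameter == "t_x"])
})
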