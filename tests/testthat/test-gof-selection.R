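test_that("gof reports have the advertised shape and determinism", {
  set.seed(14)
  net <- randomNetwork(15, 0.3)
  fit <- mcmcMLE(net, ergmModel("edges"), ergmControl(seed = 2))
  r1 <- gofSimulate(net, fit, nSim = 1, seed = 5)
  expect_s4_class(r1, "GofReport")
  expect_equal(r1@nSim, 1L)
  expect_equal(nrow(r1@simulated$degree), 1L)
  r2 <- gofSimulate(net, fit, nSim = 8, seed = 5)
  r3 <- gofSimulate(net, fit, nSim = 8, seed = 5)
  expect_identical(r2@simulated, r3@simulated)
  # refusing a non-converged fit
  bad <- fit
  bad@converged <- FALSE
  expect_error(gofSimulate(net, bad, nSim = 2, seed = 1), "converged")
})

test_that("self-fitted model envelopes its own degree distribution", {
  set.seed(15)
  net <- randomNetwork(20, 0.25)
  fit <- mcmcMLE(net, ergmModel("edges"), ergmControl(seed = 7))
  rep <- gofSimulate(net, fit, nSim = 100, seed = 21)
  obs <- rep@observed$degree
  sims <- rep@simulated$degree
  nz <- which(obs > 0)
  inside <- vapply(nz, function(b)
    obs[b] >= min(sims[, b]) && obs[b] <= max(sims[, b]), logical(1))
  expect_gte(mean(inside), 0.9)
})

test_that("gof score is zero on perfect agreement and median-invariant", {
  set.seed(16)
  net <- randomNetwork(12, 0.4)
  v <- brainERGM:::.gofVectors(net)
  rep <- new("GofReport", observed = v,
             simulated = lapply(v, function(x)
               matrix(rep(x, 5), nrow = 5, byrow = TRUE)),
             nSim = 5L, seed = 1L)
  expect_equal(gofScore(rep), 0)
  # duplicating every simulated network leaves the score unchanged
  net2 <- randomNetwork(12, 0.5)
  v2 <- brainERGM:::.gofVectors(net2)
  sims <- lapply(names(v), function(f)
    rbind(v[[f]], v2[[f]], v[[f]]))
  names(sims) <- names(v)
  repA <- new("GofReport", observed = v2, simulated = sims,
              nSim = 3L, seed = 1L)
  simsDup <- lapply(sims, function(m) rbind(m, m))
  repB <- new("GofReport", observed = v2, simulated = simsDup,
              nSim = 6L, seed = 1L)
  expect_equal(gofScore(repA), gofScore(repB))
})

test_that("the better-fitting of two nested models scores lower", {
  # plant data from edges+gwesp, compare that model's score with edges-only
  gen <- ergmModel("edges", ergmTerm("gwesp", tau = 0.75))
  net <- simulateNetworks(gen, c(-3.3, 0.9), 40, 1,
                          samplerControl(seed = 33,
                                         thin = 3 * choose(40, 2)))[[1]]
  ctl <- ergmControl(sampleSize = 400, maxIter = 10, bridgeSteps = 5,
                     bridgeSampleSize = 60, seed = 8)
  fitFull <- mcmcMLE(net, gen, ctl)
  fitEdges <- mcmcMLE(net, ergmModel("edges"), ctl)
  sFull <- gofScore(gofSimulate(net, fitFull, nSim = 60, seed = 3))
  sEdges <- gofScore(gofSimulate(net, fitEdges, nSim = 60, seed = 3))
  expect_lt(sFull, sEdges)
})

test_that("backward selection drops a noise term and keeps edges", {
  set.seed(18)
  # data generated from an edges-only law; nodematch on random labels is noise
  nd <- data.frame(lobe = sample(c("A", "B"), 30, replace = TRUE))
  net0 <- simulateNetworks(ergmModel("edges"), stats::qlogis(0.2), 30, 1,
                           samplerControl(seed = 41))[[1]]
  net <- brainNetwork(30, edgeMatrix(net0), nodeData = nd)
  full <- ergmModel("edges", ergmTerm("nodematch", attribute = "lobe"))
  drops <- vapply(1:10, function(k) {
    ctl <- ergmControl(sampleSize = 300, maxIter = 8, bridgeSteps = 4,
                       bridgeSampleSize = 50, seed = 100 + k)
    netk <- simulateNetworks(ergmModel("edges"), stats::qlogis(0.2), 30, 1,
                             samplerControl(seed = 500 + k))[[1]]
    netk <- brainNetwork(30, edgeMatrix(netk), nodeData = nd)
    sel <- backwardPValueSelect(netk, full, fitter = mcmcFitter(ctl))
    !"nodematch.lobe" %in% termNames(sel@model)
  }, logical(1))
  expect_gte(mean(drops), 0.9)
})

test_that("selection bookkeeping: trails, stopping and single candidates", {
  set.seed(19)
  net <- randomNetwork(25, 0.25)
  ctl <- ergmControl(sampleSize = 300, maxIter = 8, bridgeSteps = 4,
                     bridgeSampleSize = 50, seed = 3)
  fitter <- mcmcFitter(ctl)
  # single candidate subset lattice: edges and edges+gwesp only
  sel <- aicSelect(net, list(ergmTerm("gwesp", tau = 0.75)), fitter = fitter)
  expect_equal(nrow(sel@trail), 2L)
  expect_true(.hasName <- sel@trail$model[which.min(sel@trail$value)] ==
                brainERGM:::.modelLabel(sel@model))
  # graphical selection is deterministic under fixed seeds and its chosen
  # score is the trail minimum
  g1 <- graphicalSelect(net, list(ergmTerm("gwesp", tau = 0.75)),
                        fitter = fitter, nSim = 20, seed = 9)
  g2 <- graphicalSelect(net, list(ergmTerm("gwesp", tau = 0.75)),
                        fitter = fitter, nSim = 20, seed = 9)
  expect_identical(g1@trail, g2@trail)
  expect_equal(min(g1@trail$value),
               g1@trail$value[g1@trail$model ==
                                brainERGM:::.modelLabel(g1@model)])
  # backward selection returns the full model when everything is significant
  net2 <- simulateNetworks(ergmModel("edges"), stats::qlogis(0.15), 30, 1,
                           samplerControl(seed = 77))[[1]]
  selB <- backwardPValueSelect(net2, ergmModel("edges"), fitter = fitter)
  expect_equal(termNames(selB@model), "edges")
  expect_equal(nrow(selB@trail), 1L)
})
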