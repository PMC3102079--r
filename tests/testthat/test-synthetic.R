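test_that("the six-node worked example satisfies the shared-partner identities", {
  ex <- sharedPartnerExample()
  expect_equal(nNodes(ex$network), 6L)
  expect_equal(edgeCount(ex$network), 7L)
  s <- ex$spd
  expect_equal(dsp(s), esp(s) + nsp(s))
  expect_equal(sum(dsp(s)), 15)  # C(6,2) dyads
  expect_equal(sum((seq_along(esp(s)) - 1) * esp(s)) %% 3, 0)
})

test_that("cohort generation is seed-deterministic with controllable spread", {
  spec0 <- cohortSpec(nSubjects = 3, nNodes = 24,
                      theta = c(-1.8, 0.4, -0.1), sd = c(0, 0, 0), seed = 4)
  coh <- generateCohort(spec0)
  expect_length(coh, 3L)
  # sd = 0: all subjects share the generating parameters
  for (s in coh) expect_equal(s$theta, c(-1.8, 0.4, -0.1))
  coh2 <- generateCohort(spec0)
  expect_identical(lapply(coh, function(s) edgeMatrix(s$network)),
                   lapply(coh2, function(s) edgeMatrix(s$network)))
  specSd <- cohortSpec(nSubjects = 4, nNodes = 24,
                       theta = c(-1.8, 0.4, -0.1), sd = c(0.3, 0.1, 0.02),
                       seed = 9)
  cohSd <- generateCohort(specSd)
  th <- t(vapply(cohSd, `[[`, numeric(3), "theta"))
  expect_gt(stats::sd(th[, 1]), 0)
  expect_error(cohortSpec(sd = c(-0.1, 0, 0)), ">= 0")
})

test_that("default cohort conditions give brain-like sparse networks", {
  spec <- cohortSpec(nSubjects = 5, seed = 11)
  coh <- generateCohort(spec)
  K <- vapply(coh, function(s) 2 * edgeCount(s$network) / 90, numeric(1))
  expect_true(all(K >= 3 & K <= 9))
  expect_false(any(vapply(coh, `[[`, logical(1), "degenerate")))
})

test_that("block correlation matrices have the planted structure", {
  noiseless <- generateCorrMatrices(1, nNodes = 12, nModules = 2,
                                    withinR = 0.5, betweenR = 0.1,
                                    noiseSd = 0, seed = 2)[[1]]
  mods <- attr(noiseless, "modules")
  same <- outer(mods, mods, `==`) & upper.tri(noiseless)
  expect_true(all(noiseless[same] == 0.5))
  expect_true(all(noiseless[!same & upper.tri(noiseless)] == 0.1))
  m <- generateCorrMatrices(1, nNodes = 30, nModules = 3, seed = 5)[[1]]
  expect_lt(max(abs(m - t(m))), 1e-12)
  expect_true(all(diag(m) == 1))
  expect_true(all(abs(m) <= 1))
  expect_error(generateCorrMatrices(1, withinR = 0.2, betweenR = 0.3),
               "betweenR")
})

test_that("thresholded modular matrices are more clustered than degree-matched noise", {
  set.seed(33)
  m <- generateCorrMatrices(1, nNodes = 90, nModules = 6, seed = 7)[[1]]
  net <- thresholdByS(m, s = 2.5)
  cObs <- descriptiveMetrics(net)$C
  # degree-matched uniform random comparison: same n and edge count
  cNull <- mean(vapply(1:20, function(k) {
    e <- which(upper.tri(diag(90)), arr.ind = TRUE)
    pick <- sample(nrow(e), edgeCount(net))
    descriptiveMetrics(brainNetwork(90, e[pick, , drop = FALSE]))$C
  }, numeric(1)))
  expect_gt(cObs, cNull)
})
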