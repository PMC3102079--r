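test_that("edges-only sampling matches the independent-dyad law", {
  M <- choose(10, 2)
  nets <- simulateNetworks(ergmModel("edges"), 0, 10, 500,
                           samplerControl(seed = 17))
  dens <- vapply(nets, edgeDensity, numeric(1))
  mcse <- stats::sd(dens) / sqrt(length(dens))
  expect_lt(abs(mean(dens) - 0.5), 3 * mcse + 1e-12)

  nets2 <- simulateNetworks(ergmModel("edges"), stats::qlogis(0.1), 10, 500,
                            samplerControl(seed = 18))
  dens2 <- vapply(nets2, edgeDensity, numeric(1))
  mcse2 <- stats::sd(dens2) / sqrt(length(dens2))
  expect_lt(abs(mean(dens2) - 0.1), 3 * mcse2 + 1e-12)
})

test_that("sampled statistic means match the enumeration expectation", {
  mod <- ergmModel("edges", ergmTerm("gwesp", tau = 0.75))
  theta <- c(-0.4, 0.3)
  m <- brainERGM:::.exactMoments(mod, theta, 5)
  nets <- simulateNetworks(mod, theta, 5, 800,
                           samplerControl(seed = 9, thin = 100))
  st <- attr(nets, "stats")
  for (k in 1:2) {
    mcse <- stats::sd(st[, k]) / sqrt(nrow(st))
    expect_lt(abs(mean(st[, k]) - m$mean[k]), 3 * mcse + 1e-12)
  }
})

test_that("incremental statistics tracked by the chain match the full computation", {
  mod <- allSevenTermModel()
  nd <- lobeData(9)
  nets <- simulateNetworks(mod, c(-1, 0.1, 0.2, 0.3, -0.1, 0.05, 0.4), 9, 20,
                           samplerControl(seed = 4), nodeData = nd)
  st <- attr(nets, "stats")
  for (k in seq_along(nets)) {
    expect_equal(unname(st[k, ]),
                 unname(statisticVector(nets[[k]], mod)), tolerance = 1e-9)
  }
})

test_that("fixed seeds reproduce draws and thinning reduces autocorrelation", {
  a <- simulateNetworks(ergmModel("edges"), -1, 12, 30,
                        samplerControl(seed = 5))
  b <- simulateNetworks(ergmModel("edges"), -1, 12, 30,
                        samplerControl(seed = 5))
  expect_identical(lapply(a, edgeMatrix), lapply(b, edgeMatrix))

  ac1 <- function(x) stats::cor(x[-1], x[-length(x)])
  thin1 <- simulateNetworks(ergmModel("edges"), 0, 12, 400,
                            samplerControl(seed = 6, thin = 1))
  thinBig <- simulateNetworks(ergmModel("edges"), 0, 12, 400,
                              samplerControl(seed = 6, thin = 200))
  expect_gt(ac1(attr(thin1, "stats")[, 1]),
            ac1(attr(thinBig, "stats")[, 1]))
})

test_that("degenerate parameters warn rather than fail", {
  expect_warning(simulateNetworks(ergmModel("edges"), -8, 12, 10,
                                  samplerControl(seed = 2)), "empty")
  expect_warning(simulateNetworks(ergmModel("edges"), 8, 12, 10,
                                  samplerControl(seed = 2)), "complete")
})

test_that("chain initialization options are honoured", {
  set.seed(44)
  net <- randomNetwork(8, 0.4)
  ctl <- samplerControl(burnin = 0, thin = 0, seed = 1, init = "observed",
                        initNetwork = net)
  out <- simulateNetworks(ergmModel("edges"), 0, 8, 1, control = ctl)
  expect_identical(edgeMatrix(out[[1]]), edgeMatrix(net))
  expect_error(samplerControl(burnin = -1), "burnin")
})
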