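test_that("shared-partner distributions match hand-derived fixed cases", {
  tri <- sharedPartnerDist(completeNetwork(3))
  expect_equal(unname(esp(tri)), c(0, 3))
  expect_equal(unname(nsp(tri)), c(0, 0))
  # 4-cycle: every edge has 0 shared partners, both diagonals have 2
  cyc <- brainNetwork(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
  s <- sharedPartnerDist(cyc)
  expect_equal(unname(esp(s)), c(4, 0, 0))
  expect_equal(unname(nsp(s)), c(0, 0, 2))
  expect_equal(unname(dsp(s)), c(4, 0, 2))
  empty <- sharedPartnerDist(brainNetwork(4))
  expect_equal(unname(nsp(empty)), c(6, 0, 0))
  expect_true(all(esp(empty) == 0))
})

test_that("shared-partner identities hold against brute force on random graphs", {
  set.seed(71)
  for (rep in 1:60) {
    n <- sample(4:11, 1)
    net <- randomNetwork(n, stats::runif(1, 0.1, 0.9))
    s <- sharedPartnerDist(net)
    b <- bruteSharedPartners(net)
    expect_equal(unname(esp(s)), b$esp)
    expect_equal(unname(nsp(s)), b$nsp)
    expect_equal(dsp(s), esp(s) + nsp(s))
    expect_equal(sum(esp(s)), edgeCount(net))
    expect_equal(sum(dsp(s)), choose(n, 2))
    # triangle incidence: sum_i i * esp_i = 3 * triangles
    tri <- unname(triadCensus(net)[4])
    expect_equal(sum((seq_along(esp(s)) - 1) * esp(s)), 3 * tri)
  }
})

test_that("ESP + NSP = DSP elementwise, including the printed worked example", {
  expect_equal(sumEspNsp(c(1, 5, 1, 0, 0), c(1, 4, 3, 0, 0)),
               c(2, 9, 4, 0, 0))
  expect_equal(sumEspNsp(numeric(4), numeric(4)), numeric(4))
  expect_equal(sumEspNsp(c(0, 3), c(0, 0)), c(0, 3))
  expect_error(sumEspNsp(1:3, 1:4), "equal length")
})

test_that("geometric weighting has its analytic values and bounds", {
  # triangle ESP: only the weight at one shared partner matters and the
  # exp(tau) prefactor cancels it
  for (tau in c(0, 0.3, 0.75, 2)) {
    expect_equal(gwStatistic(c(0, 3), tau), 3)
  }
  expect_equal(gwStatistic(numeric(6), 1.2), 0)
  # tau = 0: counts of entities with >= 1 shared partner
  expect_equal(gwStatistic(c(4, 2, 5, 1), 0), 8)
  expect_error(gwStatistic(c(1, 2), -0.1), "nonnegative")
  set.seed(5)
  for (rep in 1:20) {
    counts <- rpois(6, 3)
    tau <- runif(1, 0, 2)
    g0 <- gwStatistic(counts, tau)
    expect_equal(g0, bruteGw(counts, tau))
    # monotone in every entry, bounded by exp(tau) * sum_{i>=1} counts
    bump <- counts + c(0, 1, rep(0, 4))
    expect_gte(gwStatistic(bump, tau), g0)
    expect_lte(g0, exp(tau) * sum(counts[-1]))
  }
})

test_that("count statistics match hand values", {
  tri <- completeNetwork(3)
  expect_equal(countEdges(tri), 3)
  expect_equal(countTwoPaths(tri), 3)
  star <- brainNetwork(4, rbind(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(countTwoPaths(star), 3)
  nd <- data.frame(grp = c("A", "A", "B"))
  net <- brainNetwork(3, rbind(c(1, 2), c(2, 3)), nodeData = nd)
  expect_equal(countNodematch(net, "grp"), 1)
  expect_error(countNodematch(net, "missing"), "not found")
})

test_that("statistic vector evaluates terms in model order", {
  tri <- completeNetwork(3)
  expect_equal(unname(statisticVector(tri, ergmModel("edges"))), 3)
  g <- statisticVector(tri, ergmModel("edges", ergmTerm("gwesp", tau = 0.75)))
  expect_equal(unname(g), c(3, 3))
  empty <- brainNetwork(5)
  g0 <- statisticVector(empty, ergmModel("edges", "two_path",
                                         ergmTerm("gwdsp", tau = 0.75)))
  expect_equal(unname(g0), c(0, 0, 0))
  expect_error(statisticVector(tri, ergmModel(
    ergmTerm("nodematch", attribute = "lobe"))), "lobe")
})

test_that("statistic vector agrees with the naive loop oracle on random graphs", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(5:9, 1)
    net <- randomNetwork(n, stats::runif(1, 0.2, 0.8), nodeData = lobeData(n))
    mod <- allSevenTermModel()
    expect_equal(unname(statisticVector(net, mod)),
                 unname(bruteStatVector(net, mod)), tolerance = 1e-12)
  }
})

test_that("change statistics equal the statistic-vector difference for all terms", {
  set.seed(123)
  mod <- allSevenTermModel()
  for (rep in 1:100) {
    n <- sample(5:10, 1)
    net <- randomNetwork(n, stats::runif(1, 0.1, 0.9), nodeData = lobeData(n))
    dyad <- sample(n, 2)
    delta <- changeStatistics(net, dyad, mod)
    i <- min(dyad); j <- max(dyad)
    e <- edgeMatrix(net)
    keep <- !(e[, 1] == i & e[, 2] == j)
    netMinus <- brainNetwork(n, e[keep, , drop = FALSE],
                             nodeData = lobeData(n))
    netPlus <- brainNetwork(n, rbind(e[keep, , drop = FALSE], c(i, j)),
                            nodeData = lobeData(n))
    diffOracle <- bruteStatVector(netPlus, mod) - bruteStatVector(netMinus, mod)
    expect_equal(unname(delta), unname(diffOracle), tolerance = 1e-10)
  }
  # edges delta is always one; gwesp delta on an empty graph is zero
  net <- brainNetwork(3)
  expect_equal(unname(changeStatistics(net, c(1, 2), ergmModel("edges"))), 1)
  expect_equal(unname(changeStatistics(net, c(1, 2),
    ergmModel(ergmTerm("gwesp", tau = 0.75)))), 0)
  expect_error(changeStatistics(net, c(2, 2), ergmModel("edges")),
               "distinct")
})

test_that("model specification validity is enforced", {
  expect_error(ergmModel(ergmTerm("gwesp", tau = 0.75),
                         ergmTerm("gwesp", tau = 0.75)), "duplicate")
  expect_error(new("ErgmModel", terms = list(list(kind = "gwesp"))), "tau")
  expect_error(ergmModel(list(kind = "edges", tau = 1, name = "edges")),
               "must not carry")
  m <- bestAssessmentModel(tau = 0.33)
  expect_equal(termNames(m), c("edges", "gwesp", "gwnsp"))
  expect_equal(m@terms[[2]]$tau, 0.33)
})
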