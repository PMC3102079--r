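test_that("exact log partition matches closed form and naive enumeration", {
  # edges-only closed form: C(n,2) log(1 + e^theta)
  for (th in c(-1.3, 0, 0.8)) {
    expect_equal(exactLogPartition(ergmModel("edges"), th, 6),
                 choose(6, 2) * log(1 + exp(th)))
  }
  # theta = 0: log of the number of graphs
  mod <- ergmModel("edges", ergmTerm("gwesp", tau = 0.75))
  expect_equal(exactLogPartition(mod, c(0, 0), 4), 6 * log(2))
  # independent naive enumeration oracle at n = 4 and 5
  set.seed(31)
  for (n in 4:5) {
    theta <- c(stats::runif(1, -1, 0.2), stats::runif(1, 0, 0.6))
    b <- bruteEnumeration(mod, theta, n)
    expect_equal(exactLogPartition(mod, theta, n), b$log_kappa,
                 tolerance = 1e-10)
  }
  expect_error(exactLogPartition(ergmModel("edges"), 0, 12), "refused")
})

test_that("exact MLE has the closed form for edges-only models", {
  set.seed(8)
  net <- randomNetwork(6, 0.4)
  f <- exactMLE(net, ergmModel("edges"))
  expect_equal(unname(coef(f)), stats::qlogis(edgeDensity(net)),
               tolerance = 1e-8)
  # density one half: theta = 0 exactly
  half <- brainNetwork(4, rbind(c(1, 2), c(2, 3), c(3, 4)))
  f2 <- exactMLE(half, ergmModel("edges"))
  expect_equal(unname(coef(f2)), 0, tolerance = 1e-8)
  expect_error(exactMLE(brainNetwork(5), ergmModel("edges")), "boundary")
})

test_that("exact MLE satisfies the exponential-family moment match", {
  set.seed(12)
  mod <- ergmModel("edges", ergmTerm("gwesp", tau = 0.75))
  for (rep in 1:3) {
    net <- randomNetwork(5, stats::runif(1, 0.35, 0.65))
    f <- exactMLE(net, mod)
    m <- brainERGM:::.exactMoments(mod, coef(f), 5, nodeData(net))
    expect_lt(max(abs(m$mean - statisticVector(net, mod))), 1e-6)
    expect_equal(f@aic, 2 * 2 - 2 * f@loglik)
  }
})

test_that("MPLE is exact for edges-only and dyad-independent models", {
  set.seed(21)
  net <- randomNetwork(8, 0.45)
  f <- mple(net, ergmModel("edges"))
  expect_equal(unname(coef(f)), stats::qlogis(edgeDensity(net)),
               tolerance = 1e-9)
  # edges + nodematch is dyad independent: MPLE = exact MLE (draw until
  # neither route hits separation / the hull boundary)
  nd <- data.frame(lobe = rep(c("A", "B"), length.out = 7))
  mod <- ergmModel("edges", ergmTerm("nodematch", attribute = "lobe"))
  repeat {
    net2 <- randomNetwork(7, 0.5, nodeData = nd)
    fits <- tryCatch(list(mple(net2, mod), exactMLE(net2, mod)),
                     error = function(e) NULL)
    if (!is.null(fits)) break
  }
  fp <- fits[[1]]
  fx <- fits[[2]]
  expect_equal(coef(fp), coef(fx), tolerance = 1e-6)
  expect_error(mple(brainNetwork(5), ergmModel("edges")), "converge")
})

test_that("MCMC MLE recovers closed forms and the enumeration oracle", {
  set.seed(55)
  net <- randomNetwork(10, 0.35)
  fm <- mcmcMLE(net, ergmModel("edges"), ergmControl(seed = 2, sampleSize = 4000))
  expect_true(isConverged(fm))
  expect_lt(abs(unname(coef(fm)) - stats::qlogis(edgeDensity(net))), 0.02)
  mod <- ergmModel("edges", ergmTerm("gwesp", tau = 0.75))
  net6 <- interiorNetwork(6, 0.5, mod)
  fe <- exactMLE(net6, mod)
  fm6 <- mcmcMLE(net6, mod, ergmControl(seed = 3, sampleSize = 10000))
  expect_lt(max(abs(coef(fm6) - coef(fe))), 0.05)
  # absolute log-likelihood from the bridge is close to the exact one
  expect_equal(fm6@loglik, fe@loglik, tolerance = 0.2)
  # seed determinism
  fm6b <- mcmcMLE(net6, mod, ergmControl(seed = 3, sampleSize = 10000))
  expect_identical(coef(fm6), coef(fm6b))
  expect_identical(fm6@loglik, fm6b@loglik)
})

test_that("MCMC MLE log-likelihood at the estimate is at least the MPLE one", {
  set.seed(77)
  mod <- ergmModel("edges", ergmTerm("gwesp", tau = 0.75))
  net <- interiorNetwork(6, 0.5, mod)
  fm <- mcmcMLE(net, mod, ergmControl(seed = 4, sampleSize = 4000))
  llAt <- function(th) sum(th * statisticVector(net, mod)) -
    exactLogPartition(mod, th, 6)
  expect_gte(llAt(coef(fm)) + 0.02, llAt(coef(mple(net, mod))))
})

test_that("Wald p-values follow the Gaussian reference", {
  mod <- ergmModel("edges", ergmTerm("gwesp", tau = 0.75))
  f <- brainERGM:::.newFit(mod, c(0, 1.959964), c(1, 1), diag(2),
                           NA_real_, NA_real_, "mple", TRUE)
  p <- waldPvalues(f)
  expect_equal(unname(p[1]), 1)
  expect_equal(unname(p[2]), 0.05, tolerance = 1e-6)
  f3 <- brainERGM:::.newFit(ergmModel("edges"), 3, 1, diag(1),
                            NA_real_, NA_real_, "mple", TRUE)
  expect_equal(unname(waldPvalues(f3)), 0.0026998, tolerance = 1e-4)
  fz <- brainERGM:::.newFit(ergmModel("edges"), 1, 0, diag(1),
                            NA_real_, NA_real_, "mple", TRUE)
  expect_warning(pz <- waldPvalues(fz), "zero standard error")
  expect_true(is.na(pz))
})

test_that("AIC is 2p - 2 loglik and penalizes unhelpful terms", {
  expect_equal(aicOf(-10, 3), 26)
  expect_equal(aicOf(0, 1), 2)
  expect_gt(aicOf(-9.5, 3), aicOf(-10, 2))
  expect_error(aicOf(-1, 0), ">= 1")
})

test_that("fit results serialize to JSON and back", {
  set.seed(3)
  nd <- lobeData(6)
  net <- randomNetwork(6, 0.5, nodeData = nd)
  mod <- ergmModel("edges", ergmTerm("gwesp", tau = 0.75),
                   ergmTerm("nodematch", attribute = "lobe"))
  f <- mple(net, mod)
  path <- tempfile(fileext = ".json")
  writeFitResult(f, path)
  f2 <- readFitResult(path)
  expect_equal(coef(f2), coef(f))
  expect_equal(stdErrors(f2), stdErrors(f))
  expect_equal(termNames(f2@model), termNames(f@model))
})
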