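makeFit <- function(theta, model = bestAssessmentModel()) {
  p <- length(theta)
  brainERGM:::.newFit(model, theta, rep(0.1, p), diag(p), NA_real_,
                      NA_real_, "mcmc_mle", TRUE)
}

test_that("cohort containers enforce a shared converged model", {
  f1 <- makeFit(c(-2.5, 0.6, -0.1))
  f2 <- makeFit(c(-2.7, 0.5, -0.2))
  ch <- cohortFits(list(f1, f2))
  expect_equal(dim(thetaMatrix(ch)), c(2L, 3L))
  bad <- makeFit(c(-1, 0.2), ergmModel("edges", ergmTerm("gwesp")))
  expect_error(cohortFits(list(f1, bad)), "identical term list")
  nc <- f2
  nc@converged <- FALSE
  expect_error(cohortFits(list(f1, nc)), "converged")
})

test_that("identical cohorts give a null comparison", {
  a <- cohortFits(list(makeFit(c(-2, 1.0, -0.1)), makeFit(c(-2, 1.2, -0.2))))
  r <- compareTerm(a, a, "gwesp")
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(r$mean_a - r$mean_b, 0)
})

test_that("welch t matches an independent hand computation", {
  set.seed(92)
  # cohorts with a true GWNSP gap of half the between-subject noise
  sdB <- 0.2
  va <- rnorm(5, -0.1, sdB)
  vb <- rnorm(5, -0.1 + 0.5 * sdB, sdB)
  a <- cohortFits(lapply(va, function(v) makeFit(c(-2, 0.5, v))))
  b <- cohortFits(lapply(vb, function(v) makeFit(c(-2, 0.5, v))))
  r <- compareTerm(a, b, "gwnsp")
  # Welch statistic and Satterthwaite df from first principles
  s2a <- var(va) / 5
  s2b <- var(vb) / 5
  tHand <- (mean(va) - mean(vb)) / sqrt(s2a + s2b)
  dfHand <- (s2a + s2b)^2 / (s2a^2 / 4 + s2b^2 / 4)
  pHand <- 2 * stats::pt(-abs(tHand), dfHand)
  expect_equal(r$t, tHand, tolerance = 1e-10)
  expect_equal(r$df, dfHand, tolerance = 1e-10)
  expect_equal(r$p, pHand, tolerance = 1e-10)
  expect_equal(r$se_a, sd(va) / sqrt(5), tolerance = 1e-12)
  # antisymmetry in the cohorts
  r2 <- compareTerm(b, a, "gwnsp")
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  expect_error(compareTerm(a, b, "gwdsp"), "not in the cohort model")
})

test_that("average profiles are elementwise means", {
  single <- cohortFits(list(makeFit(c(-2.2, 0.7, -0.15))))
  expect_equal(unname(averageProfile(single)), c(-2.2, 0.7, -0.15))
  two <- cohortFits(list(makeFit(c(-3, 1, 0)), makeFit(c(-1, 0, 1))),
                    subjects = c("a", "b"))
  expect_equal(unname(averageProfile(two)), c(-2, 0.5, 0.5))
})

test_that("representative networks from an averaged profile sit between cohorts", {
  # two cohorts differing in the edges parameter: representative draws from
  # the averaged profile have densities between the cohort typical values
  mod <- ergmModel("edges")
  thA <- stats::qlogis(0.15)
  thB <- stats::qlogis(0.45)
  avg <- (thA + thB) / 2
  densOf <- function(th, seed) mean(vapply(
    simulateNetworks(mod, th, 30, 30, samplerControl(seed = seed)),
    edgeDensity, numeric(1)))
  dA <- densOf(thA, 1)
  dB <- densOf(thB, 2)
  dAvg <- densOf(avg, 3)
  expect_gt(dAvg, dA)
  expect_lt(dAvg, dB)
})
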