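# Monte Carlo maximum likelihood (Geyer-Thompson importance sampling),
# initialized at the MPLE. Each outer iteration simulates networks at the
# current parameter, maximizes the importance-sampling approximation of the
# log-likelihood ratio, and updates; short steps are taken when the
# importance weights degenerate. The absolute log-likelihood is recovered by
# bridge sampling along the path from the null model theta = 0, where
# log kappa = C(n,2) log 2 is known, so AIC values are comparable across
# models.

#' Control settings for MCMC maximum likelihood
#'
#' @param sampleSize networks simulated per outer iteration (default 1000).
#' @param burnin,thin sampler settings; defaults \code{10 choose(n,2)} and
#'   \code{choose(n,2)} toggles.
#' @param maxIter maximum outer iterations (default 20).
#' @param tol convergence tolerance on the parameter change (default 1e-3).
#' @param bridgeSteps path steps for the bridge estimate of the normalizing
#'   constant (default 8).
#' @param bridgeSampleSize networks per bridge step (default 125).
#' @param essFrac minimum effective importance sample size, as a fraction of
#'   \code{sampleSize}, below which the update step is halved (default 0.05).
#' @param seed integer root seed; every chain seed is derived from it.
#' @return a list of class \code{"ergmControl"}.
#' @export
ergmControl <- function(sampleSize = 1000, burnin = NULL, thin = NULL,
                        maxIter = 20, tol = 1e-3, bridgeSteps = 8,
                        bridgeSampleSize = 125, essFrac = 0.05, seed = 1L) {
  structure(list(sampleSize = sampleSize, burnin = burnin, thin = thin,
                 maxIter = maxIter, tol = tol, bridgeSteps = bridgeSteps,
                 bridgeSampleSize = bridgeSampleSize, essFrac = essFrac,
                 seed = as.integer(seed)),
            class = "ergmControl")
}

.lme <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Markov chain Monte Carlo maximum likelihood estimation
#'
#' Fits the ERGM by iterated importance sampling: starting from the MPLE,
#' each iteration simulates \code{sampleSize} networks at the current
#' parameter, maximizes the sampled approximation of the likelihood ratio,
#' and repeats until the parameter change falls below \code{tol}. Standard
#' errors use the inverse of the sampled-statistic covariance (the estimated
#' Fisher information) at the final estimate. If an observed statistic sits
#' at or beyond the extremes of the simulated statistics for two consecutive
#' iterations the fit aborts with a degeneracy diagnostic.
#'
#' @param net a \code{BrainNetwork}.
#' @param model an \code{ErgmModel}.
#' @param control an \code{\link{ergmControl}}.
#' @return an \code{\link[=ErgmFit-class]{ErgmFit}} with
#'   \code{method = "mcmc_mle"}; \code{loglik} is absolute (bridge
#'   estimate), so \code{aic} values are comparable across models.
#' @export
mcmcMLE <- function(net, model, control = ergmControl()) {
  validObject(model)
  n <- nNodes(net)
  p <- nTerms(model)
  nd <- nodeData(net)
  gObs <- statisticVector(net, model)
  m <- control$sampleSize

  theta <- tryCatch(unname(coef(mple(net, model))), error = function(e) {
    th <- rep(0, p)
    kinds <- vapply(model@terms, `[[`, character(1), "kind")
    d <- max(min(edgeDensity(net), 1 - 1e-6), 1e-6)
    th[kinds == "edges"] <- stats::qlogis(d)
    th
  })

  seeds <- .withSeed(control$seed,
                     sample.int(.Machine$integer.max - 1L,
                                control$maxIter + control$bridgeSteps + 2L))
  sctl <- function(seed) samplerControl(burnin = control$burnin,
                                        thin = control$thin, seed = seed,
                                        init = "observed", initNetwork = net)

  converged <- FALSE
  boundaryRuns <- 0L
  essHist <- numeric(0)
  gammaHist <- numeric(0)
  iter <- 0L
  for (t in seq_len(control$maxIter)) {
    iter <- t
    G <- .sampleStats(model, theta, n, m, sctl(seeds[t]), nd)$stats
    cmin <- apply(G, 2, min)
    cmax <- apply(G, 2, max)

    # degeneracy screen: an observed statistic EQUAL to the extreme of the
    # importance sample sits on the edge of the attainable support (the MLE
    # coordinate diverges); a near-constant sampled statistic that misses
    # the observed value means the chain has collapsed onto a degenerate
    # region. Two consecutive such iterations abort.
    nearConst <- (cmax - cmin) <= 1e-9 * pmax(1, abs(cmax))
    atBoundary <- any(gObs == cmin | gObs == cmax) ||
      any(nearConst & abs(gObs - colMeans(G)) > 1e-6)
    boundaryRuns <- if (atBoundary) boundaryRuns + 1L else 0L
    if (boundaryRuns >= 2L)
      stop("MCMC MLE aborted: an observed statistic equals its extreme ",
           "over the importance sample for two consecutive iterations; ",
           "the model is likely degenerate for this network")

    # partial stepping: pull the target inside the simulated convex hull
    # (coordinate-wise, with a 5% margin) so the update stays finite even
    # when the observed statistics lie outside the sampled range
    cmean <- colMeans(G)
    lo <- cmin + 0.05 * (cmax - cmin)
    hi <- cmax - 0.05 * (cmax - cmin)
    gammaK <- vapply(seq_len(p), function(k) {
      if (cmax[k] == cmin[k]) return(1)
      if (gObs[k] > hi[k]) return((hi[k] - cmean[k]) / (gObs[k] - cmean[k]))
      if (gObs[k] < lo[k]) return((lo[k] - cmean[k]) / (gObs[k] - cmean[k]))
      1
    }, numeric(1))
    gamma <- max(0.01, min(1, gammaK))
    gammaHist <- c(gammaHist, gamma)
    gHat <- gamma * gObs + (1 - gamma) * cmean

    thetaT <- theta
    negobj <- function(th) {
      d <- th - thetaT
      -(sum(d * gHat) - .lme(as.vector(G %*% d)))
    }
    neggrad <- function(th) {
      s <- as.vector(G %*% (th - thetaT))
      w <- exp(s - max(s))
      w <- w / sum(w)
      -(gHat - as.vector(crossprod(G, w)))
    }
    opt <- stats::optim(thetaT, negobj, neggrad, method = "BFGS",
                        control = list(maxit = 200))
    thetaStar <- opt$par
    # trust region: cap the step so one noisy sample cannot launch the
    # iteration into a degenerate region
    step <- thetaStar - thetaT
    if (max(abs(step)) > 2)
      thetaStar <- thetaT + step * (2 / max(abs(step)))

    s <- as.vector(G %*% (thetaStar - thetaT))
    w <- exp(s - max(s))
    w <- w / sum(w)
    ess <- 1 / sum(w^2)
    essHist <- c(essHist, ess)
    if (ess < control$essFrac * m) {
      theta <- thetaT + 0.5 * (thetaStar - thetaT)  # weights degenerate
    } else {
      theta <- thetaStar
      # converged when a full step (gamma = 1) is below tol or within the
      # Monte Carlo noise of the update (mcse ~ sqrt(diag(I^-1) / m))
      mcse <- tryCatch(sqrt(pmax(diag(solve(stats::cov(G))), 0) / m),
                       error = function(e) rep(0, p))
      if (gamma == 1 &&
          all(abs(theta - thetaT) < pmax(control$tol, 2 * mcse))) {
        converged <- TRUE
        break
      }
    }
  }

  # final inference sample at the estimate; one more scoring step from it
  # averages away part of the Monte Carlo noise of the last update
  Gf <- .sampleStats(model, theta, n, m,
                     sctl(seeds[control$maxIter + 1L]), nd)$stats
  thetaT <- theta
  fmin <- apply(Gf, 2, min)
  fmax <- apply(Gf, 2, max)
  interior <- all(gObs > fmin + 0.02 * (fmax - fmin) &
                  gObs < fmax - 0.02 * (fmax - fmin))
  w <- rep(1 / m, m)
  if (interior) {
    negobj <- function(th) {
      d <- th - thetaT
      -(sum(d * gObs) - .lme(as.vector(Gf %*% d)))
    }
    neggrad <- function(th) {
      s <- as.vector(Gf %*% (th - thetaT))
      w <- exp(s - max(s))
      w <- w / sum(w)
      -(gObs - as.vector(crossprod(Gf, w)))
    }
    opt <- stats::optim(thetaT, negobj, neggrad, method = "BFGS",
                        control = list(maxit = 200))
    s <- as.vector(Gf %*% (opt$par - thetaT))
    wStar <- exp(s - max(s))
    wStar <- wStar / sum(wStar)
    if (1 / sum(wStar^2) >= control$essFrac * m) {
      theta <- opt$par
      w <- wStar
    }
  }
  # Fisher information = Cov_theta[g], importance-reweighted to theta
  mu <- as.vector(crossprod(Gf, w))
  info <- crossprod(Gf * sqrt(w), Gf * sqrt(w)) - tcrossprod(mu)
  covTheta <- tryCatch(solve(info), error = function(e) {
    warning("singular Fisher information estimate; ",
            "standard errors unavailable")
    matrix(NA_real_, p, p)
  })

  # absolute log-likelihood: bridge from theta = 0 along a linear path
  K <- control$bridgeSteps
  delta <- theta / K
  logKappa <- choose(n, 2) * log(2)
  for (k in seq_len(K)) {
    thk <- (k - 1) * delta
    Gk <- .sampleStats(model, thk, n, control$bridgeSampleSize,
                       sctl(seeds[control$maxIter + 1L + k]), nd)$stats
    logKappa <- logKappa + .lme(as.vector(Gk %*% delta))
  }
  loglik <- sum(theta * gObs) - logKappa

  .newFit(model, theta, sqrt(pmax(diag(covTheta), 0)), covTheta,
          loglik, aicOf(loglik, p), "mcmc_mle", converged,
          diagnostics = list(iterations = iter, sample_size = m,
                             seed = control$seed, ess = essHist,
                             step_gamma = gammaHist,
                             loglik_type = "bridge",
                             observed_stats = gObs,
                             final_sample_mean = colMeans(Gf)))
}

#' Fitter factories for the selection procedures
#'
#' Model-selection procedures accept any \code{fitter(net, model)} function
#' returning an \code{ErgmFit}; these helpers bind the control settings.
#'
#' @param control settings for \code{\link{mcmcMLE}}.
#' @return a function of \code{(net, model)}.
#' @export
mcmcFitter <- function(control = ergmControl()) {
  function(net, model) mcmcMLE(net, model, control = control)
}

#' @rdname mcmcFitter
#' @param enumLimit enumeration limit for \code{\link{exactMLE}}.
#' @export
exactFitter <- function(enumLimit = 7L) {
  function(net, model) exactMLE(net, model, enumLimit = enumLimit)
}
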