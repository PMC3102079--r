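# Simulation-based goodness of fit: compare the observed network's degree,
# edgewise shared-partner, geodesic and triad-census distributions with those
# of networks simulated from the fitted model.

.GOF_FAMILIES <- c("degree", "esp", "geodesic", "triad_census")

.gofVectors <- function(net) {
  n <- nNodes(net)
  geo <- geodesicDistribution(net)
  list(
    degree = as.numeric(degreeDistribution(net)),
    esp = as.numeric(esp(sharedPartnerDist(net))),
    geodesic = c(as.numeric(geo$counts), geo$unreachable),
    triad_census = as.numeric(triadCensus(net))
  )
}

#' Simulate the goodness-of-fit distributions for a fitted model
#'
#' Simulates \code{nSim} networks at the fitted parameters (chains start
#' from independent edges at the observed density) and extracts, for the
#' observed network and every simulated one, the four comparison
#' distributions: degree, edgewise shared partners, minimum geodesic
#' distance (unreachable dyads as a separate final bin) and triad census.
#'
#' @param net the observed \code{BrainNetwork}.
#' @param fit a converged \code{ErgmFit} for \code{net}.
#' @param nSim number of simulated networks (default 100).
#' @param seed integer seed for the simulations.
#' @param control optional \code{\link{samplerControl}} overriding the
#'   default chain settings (its seed/init are still set here).
#' @return a \code{\link[=GofReport-class]{GofReport}}.
#' @export
gofSimulate <- function(net, fit, nSim = 100L, seed = 1L, control = NULL) {
  if (!isTRUE(fit@converged))
    stop("goodness of fit requires a converged fit")
  n <- nNodes(net)
  ctl <- samplerControl(burnin = control$burnin, thin = control$thin,
                        seed = seed, init = "bernoulli",
                        initProb = edgeDensity(net))
  sims <- suppressWarnings(
    simulateNetworks(fit@model, fit@theta, n, nSim, control = ctl,
                     nodeData = nodeData(net)))
  obs <- .gofVectors(net)
  simmats <- lapply(.GOF_FAMILIES, function(fam) {
    do.call(rbind, lapply(sims, function(x) .gofVectors(x)[[fam]]))
  })
  names(simmats) <- .GOF_FAMILIES
  new("GofReport", observed = obs, simulated = simmats,
      nSim = as.integer(nSim), seed = as.integer(seed))
}

setMethod("show", "GofReport", function(object) {
  cat("GofReport:", object@nSim, "simulated networks, families:",
      paste(names(object@observed), collapse = ", "), "\n")
  cat("  score:", format(gofScore(object), digits = 4), "\n")
})

.logitSmooth <- function(count, total) {
  p <- (count + 0.5) / (total + 1)
  log(p / (1 - p))
}

#' Scalar goodness-of-fit score (lower is better)
#'
#' Quantifies the visual GOF comparison: for every family and bin with any
#' nonzero frequency, the absolute difference between the logit relative
#' frequency of the observed network and the median over simulations
#' (frequencies smoothed as \code{(count + 0.5) / (total + 1)}); the score
#' averages these distances over bins, then equally over the four families.
#'
#' @param report a \code{\link[=GofReport-class]{GofReport}}.
#' @return nonnegative scalar; 0 when every simulated distribution equals
#'   the observed one.
#' @export
gofScore <- function(report) {
  famScores <- vapply(names(report@observed), function(fam) {
    obs <- report@observed[[fam]]
    sims <- report@simulated[[fam]]
    tObs <- sum(obs)
    tSim <- rowSums(sims)
    used <- which(obs > 0 | colSums(sims) > 0)
    if (length(used) == 0L) return(0)
    d <- vapply(used, function(b) {
      lObs <- .logitSmooth(obs[b], tObs)
      lSim <- stats::median(.logitSmooth(sims[, b], tSim))
      abs(lObs - lSim)
    }, numeric(1))
    mean(d)
  }, numeric(1))
  mean(famScores)
}

#' Plot a goodness-of-fit report
#'
#' One panel per family: logit of relative frequency per bin, boxplots over
#' the simulated networks, the observed network as a solid line.
#'
#' @param report a \code{\link[=GofReport-class]{GofReport}}.
#' @param families which families to draw (default all four).
#' @return invisibly, the report.
#' @export
plotGof <- function(report, families = names(report@observed)) {
  op <- graphics::par(mfrow = c(1, length(families)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (fam in families) {
    obs <- report@observed[[fam]]
    sims <- report@simulated[[fam]]
    tSim <- rowSums(sims)
    used <- which(obs > 0 | colSums(sims) > 0)
    lObs <- .logitSmooth(obs[used], sum(obs))
    lSim <- sapply(used, function(b) .logitSmooth(sims[, b], tSim))
    if (is.null(dim(lSim))) lSim <- matrix(lSim, nrow = 1)
    graphics::boxplot(lSim, names = used - 1L, outline = FALSE,
                      xlab = fam, ylab = "logit relative frequency",
                      main = fam, col = "grey90")
    graphics::lines(seq_along(used), lObs, lwd = 2)
  }
  invisible(report)
}

#' Per-bin GOF summary table
#'
#' @param report a \code{\link[=GofReport-class]{GofReport}}.
#' @return data.frame with one row per (family, bin): observed count,
#'   observed logit relative frequency, and quartiles of the simulated
#'   logit relative frequencies.
#' @export
gofTable <- function(report) {
  do.call(rbind, lapply(names(report@observed), function(fam) {
    obs <- report@observed[[fam]]
    sims <- report@simulated[[fam]]
    tSim <- rowSums(sims)
    bins <- seq_along(obs) - 1L
    lSim <- sapply(seq_along(obs), function(b) .logitSmooth(sims[, b], tSim))
    if (is.null(dim(lSim))) lSim <- matrix(lSim, nrow = 1)
    q <- apply(lSim, 2, stats::quantile, c(0.25, 0.5, 0.75))
    data.frame(family = fam, bin = bins, observed = obs,
               logit_obs = .logitSmooth(obs, sum(obs)),
               sim_q25 = q[1, ], sim_median = q[2, ], sim_q75 = q[3, ])
  }))
}
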