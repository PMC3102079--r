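# Synthetic-data module: every input the pipeline needs can be generated
# in code — a small worked example for the shared-partner statistics, ERGM
# cohorts with known generating parameters, and block-structured correlation
# matrices emulating partial-correlation inputs from resting-state fMRI.

#' Six-node worked example for the shared-partner distributions
#'
#' A small synthetic six-node, seven-edge network (a four-node diamond —
#' a cycle with one chord — carrying a two-edge tail) whose dyads populate
#' the 0-, 1- and 2-shared-partner bins of all three distributions. The
#' distributions are computed from the graph, never transcribed, so the
#' identities dsp = esp + nsp, sum(dsp) = C(6,2) and the triangle-incidence
#' identity hold by construction.
#'
#' @return list with \code{network} (the \code{BrainNetwork}) and
#'   \code{spd} (its \code{\link[=SharedPartnerDist-class]{SharedPartnerDist}}).
#' @examples
#' ex <- sharedPartnerExample()
#' esp(ex$spd) + nsp(ex$spd)  # equals dsp(ex$spd)
#' @export
sharedPartnerExample <- function() {
  edges <- rbind(c(1, 2), c(1, 3), c(2, 3), c(2, 4), c(3, 4),
                 c(4, 5), c(5, 6))
  net <- brainNetwork(6, edges)
  list(network = net, spd = sharedPartnerDist(net))
}

#' Describe a synthetic cohort of ERGM networks
#'
#' Study conditions emulating a resting-state cohort: 90-node networks drawn
#' from the best-assessment model (edges + GWESP + GWNSP, tau = 0.75) with a
#' sparse-graph parameter profile (negative edges, positive GWESP, negative
#' GWNSP — the sign pattern of fitted whole-brain networks) and mean degree
#' in the 5-6 range. Per-subject parameters are the generating profile plus
#' independent Gaussian between-subject noise; the default spreads are kept
#' small enough that subjects stay in the sparse small-world regime (the
#' GWESP term sits near a phase boundary beyond which draws turn dense).
#'
#' @param nSubjects number of subjects (default 10).
#' @param nNodes nodes per network (default 90).
#' @param theta generating parameter profile (one entry per model term).
#' @param sd per-term between-subject standard deviations.
#' @param model the generating \code{ErgmModel}.
#' @param seed integer seed.
#' @return a list of class \code{"cohortSpec"}.
#' @export
cohortSpec <- function(nSubjects = 10L, nNodes = 90L,
                       theta = c(-2.8, 0.6, -0.1),
                       sd = c(0.15, 0.04, 0.02),
                       model = bestAssessmentModel(), seed = 1L) {
  if (nSubjects < 1L) stop("nSubjects must be >= 1")
  if (any(sd < 0)) stop("between-subject sds must be >= 0")
  if (length(theta) != nTerms(model) || length(sd) != length(theta))
    stop("theta and sd must have one entry per model term")
  structure(list(nSubjects = as.integer(nSubjects),
                 nNodes = as.integer(nNodes),
                 theta = theta, sd = sd, model = model,
                 seed = as.integer(seed)),
            class = "cohortSpec")
}

#' Generate a synthetic cohort with known truth
#'
#' For each subject draws \code{theta_s = theta + N(0, sd)} per term and
#' simulates one network from the model at \code{theta_s}. Deterministic
#' under the spec's seed. Subjects whose draws leave the sparse regime the
#' cohort emulates (density outside [0.01, 0.25], i.e. mean degree roughly
#' 1-22 at n = 90) are flagged in the \code{degenerate} field: the
#' geometrically weighted terms sit near a phase boundary, and an unlucky
#' parameter draw can tip a subject into a dense state.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param control optional \code{\link{samplerControl}} template (burnin and
#'   thin are taken from it; seeds are derived from \code{spec$seed}).
#' @return list with one entry per subject, each a list of \code{network},
#'   \code{theta} (the subject's true parameters) and \code{degenerate}
#'   (logical flag).
#' @export
generateCohort <- function(spec, control = NULL) {
  stopifnot(inherits(spec, "cohortSpec"))
  p <- nTerms(spec$model)
  draws <- .withSeed(spec$seed, {
    list(thetas = matrix(stats::rnorm(spec$nSubjects * p,
                                      mean = rep(spec$theta, each = spec$nSubjects),
                                      sd = rep(spec$sd, each = spec$nSubjects)),
                         ncol = p),
         seeds = sample.int(.Machine$integer.max - 1L, spec$nSubjects))
  })
  lapply(seq_len(spec$nSubjects), function(s) {
    ctl <- samplerControl(burnin = control$burnin, thin = control$thin,
                          seed = draws$seeds[s], init = "empty")
    net <- withCallingHandlers(
      simulateNetworks(spec$model, draws$thetas[s, ], spec$nNodes, 1L,
                       control = ctl)[[1]],
      warning = function(w) invokeRestart("muffleWarning"))
    dens <- edgeDensity(net)
    list(network = net, theta = draws$thetas[s, ],
         degenerate = dens < 0.01 || dens > 0.25)
  })
}

#' Generate block-structured synthetic correlation matrices
#'
#' Emulates partial-correlation matrices derived from resting-state fMRI:
#' nodes fall into modules (communities), correlations are \code{withinR}
#' inside a module and \code{betweenR} across modules, plus symmetric
#' Gaussian noise; the result is forced to unit diagonal and clipped to
#' \code{[-1, 1]}. Thresholding such a matrix with
#' \code{\link{thresholdByS}} yields clustered, small-world-like networks.
#'
#' @param nMatrices how many matrices to generate.
#' @param nNodes nodes per matrix (default 90).
#' @param nModules number of equally sized modules (default 6).
#' @param withinR within-module correlation, in \code{(betweenR, 1]}.
#' @param betweenR between-module correlation, in \code{[0, withinR)}.
#' @param noiseSd standard deviation of the symmetric noise.
#' @param seed integer seed.
#' @return list of correlation matrices (with module membership in
#'   \code{attr(, "modules")}).
#' @export
generateCorrMatrices <- function(nMatrices, nNodes = 90L, nModules = 6L,
                                 withinR = 0.4, betweenR = 0.1,
                                 noiseSd = 0.05, seed = 1L) {
  if (!(betweenR >= 0 && betweenR < withinR && withinR <= 1))
    stop("need 0 <= betweenR < withinR <= 1")
  modules <- rep_len(seq_len(nModules), nNodes)
  base <- matrix(betweenR, nNodes, nNodes)
  same <- outer(modules, modules, `==`)
  base[same] <- withinR
  diag(base) <- 1
  .withSeed(seed, {
    lapply(seq_len(nMatrices), function(k) {
      noise <- matrix(stats::rnorm(nNodes^2, sd = noiseSd), nNodes)
      noise <- (noise + t(noise)) / 2
      m <- base + noise
      diag(m) <- 1
      m[m > 1] <- 1
      m[m < -1] <- -1
      attr(m, "modules") <- modules
      m
    })
  })
}
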