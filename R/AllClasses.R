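#' @import methods
NULL

#' Undirected simple graph on labeled nodes
#'
#' \code{BrainNetwork} stores an unweighted, undirected simple graph: the
#' binary adjacency structure that results from thresholding a functional
#' connectivity matrix. Edges are kept as a two-column integer matrix of
#' 1-based node indices with \code{i < j}, each unordered pair stored once.
#' Node labels (e.g. anatomical region names) and a per-node table of
#' categorical attributes (e.g. lobe membership) ride along.
#'
#' @slot nNodes integer, number of nodes.
#' @slot edges integer matrix with two columns; each row an edge \code{i < j}.
#' @slot nodeLabels character vector of length \code{nNodes}.
#' @slot nodeData data.frame of categorical node attributes, one row per node.
#'
#' @seealso \code{\link{brainNetwork}}, \code{\link{edgeDensity}},
#'   \code{\link{sharedPartnerDist}}
#' @export
setClass("BrainNetwork",
  representation(
    nNodes = "integer",
    edges = "matrix",
    nodeLabels = "character",
    nodeData = "data.frame"
  )
)

setValidity("BrainNetwork", function(object) {
  n <- object@nNodes
  e <- object@edges
  if (length(n) != 1L || is.na(n) || n < 1L)
    return("nNodes must be a single positive integer")
  if (!is.numeric(e) || ncol(e) != 2L)
    return("edges must be a two-column matrix")
  if (nrow(e) > 0L) {
    if (any(e < 1L) || any(e > n))
      return("edge endpoints must be node indices in 1..nNodes")
    if (any(e[, 1L] >= e[, 2L]))
      return("edges must satisfy i < j (no self-loops, stored once)")
    key <- (e[, 1L] - 1) * n + (e[, 2L] - 1)
    if (anyDuplicated(key))
      return("duplicate edges are not allowed")
  }
  if (nrow(e) > n * (n - 1) / 2)
    return("edge count exceeds the number of dyads")
  if (length(object@nodeLabels) != n)
    return("nodeLabels must have one entry per node")
  if (nrow(object@nodeData) != n && ncol(object@nodeData) > 0L)
    return("nodeData must have one row per node")
  TRUE
})

#' ERGM model specification
#'
#' An ordered list of sufficient-statistic definitions g(y). Supported term
#' kinds are \code{edges}, \code{two_path}, \code{gwd}, \code{gwesp},
#' \code{gwnsp}, \code{gwdsp} and \code{nodematch}. Geometrically weighted
#' terms carry a fixed, known decay parameter \code{tau}; \code{nodematch}
#' names a categorical node attribute.
#'
#' @slot terms list of term definitions created by \code{\link{ergmTerm}}.
#' @seealso \code{\link{ergmModel}}, \code{\link{statisticVector}}
#' @export
setClass("ErgmModel", representation(terms = "list"))

.TERM_KINDS <- c(edges = 1L, two_path = 2L, gwd = 3L, gwesp = 4L,
                 gwnsp = 5L, gwdsp = 6L, nodematch = 7L)
.GW_KINDS <- c("gwd", "gwesp", "gwnsp", "gwdsp")

setValidity("ErgmModel", function(object) {
  if (length(object@terms) < 1L)
    return("a model needs at least one term")
  for (tm in object@terms) {
    if (!is.list(tm) || is.null(tm$kind))
      return("each term must be a list with a 'kind' field")
    if (!tm$kind %in% names(.TERM_KINDS))
      return(paste0("unknown term kind '", tm$kind, "'"))
    if (tm$kind %in% .GW_KINDS) {
      if (is.null(tm$tau) || !is.numeric(tm$tau) || tm$tau < 0)
        return(paste0("term '", tm$kind, "' needs a nonnegative tau"))
    } else if (!is.null(tm$tau)) {
      return(paste0("term '", tm$kind, "' must not carry a tau"))
    }
    if (tm$kind == "nodematch") {
      if (is.null(tm$attribute) || !nzchar(tm$attribute))
        return("nodematch needs an attribute name")
    } else if (!is.null(tm$attribute)) {
      return(paste0("term '", tm$kind, "' must not carry an attribute"))
    }
  }
  keys <- vapply(object@terms, function(tm)
    paste(tm$kind, tm$attribute %||% "", sep = ":"), character(1))
  if (anyDuplicated(keys))
    return("duplicate (kind, attribute) terms are not allowed")
  TRUE
})

#' Fitted ERGM
#'
#' Parameter estimates and inference for one network under one model. The
#' log-likelihood is on the absolute scale (the normalizing constant is
#' evaluated by enumeration or estimated by bridge sampling from the null
#' model) unless \code{diagnostics$loglik_type} says otherwise; MPLE fits
#' carry the maximized pseudo-likelihood there and leave \code{loglik} NA.
#'
#' @slot theta named numeric vector of estimates.
#' @slot se named numeric vector of standard errors.
#' @slot cov estimated covariance matrix of \code{theta}.
#' @slot loglik numeric log-likelihood (NA when only a pseudo-likelihood
#'   is available).
#' @slot aic numeric Akaike information criterion, \code{2p - 2 loglik}.
#' @slot method one of \code{"mple"}, \code{"mcmc_mle"}, \code{"exact"}.
#' @slot converged logical convergence flag.
#' @slot model the \code{ErgmModel} that was fitted.
#' @slot diagnostics list of fitting details (sample sizes, iterations, seed).
#' @export
setClass("ErgmFit",
  representation(
    theta = "numeric", se = "numeric", cov = "matrix",
    loglik = "numeric", aic = "numeric", method = "character",
    converged = "logical", model = "ErgmModel", diagnostics = "list"
  )
)

setValidity("ErgmFit", function(object) {
  p <- length(object@model@terms)
  if (length(object@theta) != p || length(object@se) != p)
    return("theta and se must have one entry per model term")
  if (!all(dim(object@cov) == c(p, p)))
    return("cov must be p x p")
  TRUE
})

#' Shared-partner distributions of a graph
#'
#' For every unordered dyad (i, j) the shared-partner count is the number of
#' common neighbours of i and j. Dyads joined by an edge are tallied into the
#' edgewise distribution (ESP), the rest into the non-edgewise one (NSP); the
#' dyadwise distribution (DSP) tallies all dyads and equals ESP + NSP
#' elementwise. Index k of each vector counts dyads with exactly k - 1 shared
#' partners (i.e. counts start at zero shared partners).
#'
#' @slot esp,nsp,dsp numeric count vectors of length \code{nNodes - 1}.
#' @export
setClass("SharedPartnerDist",
  representation(esp = "numeric", nsp = "numeric", dsp = "numeric"))

setValidity("SharedPartnerDist", function(object) {
  if (length(object@esp) != length(object@nsp) ||
      length(object@esp) != length(object@dsp))
    return("esp, nsp, dsp must have equal length")
  if (any(object@esp < 0) || any(object@nsp < 0))
    return("counts must be nonnegative")
  if (max(abs(object@dsp - object@esp - object@nsp)) > 1e-8)
    return("dsp must equal esp + nsp elementwise")
  TRUE
})

#' Simulation-based goodness-of-fit report
#'
#' Holds the observed and simulated count vectors of the four comparison
#' families used for graphical GOF assessment: degree, edgewise shared
#' partners, minimum geodesic distance (with unreachable dyads as a separate
#' final bin) and triad census.
#'
#' @slot observed named list of observed count vectors, one per family.
#' @slot simulated named list of matrices (one row per simulated network).
#' @slot nSim integer number of simulated networks.
#' @slot seed integer seed used for the simulations.
#' @export
setClass("GofReport",
  representation(observed = "list", simulated = "list",
                 nSim = "integer", seed = "integer"))

setValidity("GofReport", function(object) {
  if (object@nSim < 1L) return("nSim must be >= 1")
  if (!setequal(names(object@observed), names(object@simulated)))
    return("observed and simulated families must match")
  for (fam in names(object@observed)) {
    if (ncol(object@simulated[[fam]]) != length(object@observed[[fam]]))
      return("bin counts must agree between observed and simulated")
    if (nrow(object@simulated[[fam]]) != object@nSim)
      return("each simulated matrix needs nSim rows")
  }
  TRUE
})

#' Model-selection result
#'
#' The chosen model, its fit, and the ordered trail of candidate models with
#' their criterion values (largest Wald p-value, AIC, or GOF score depending
#' on the procedure).
#'
#' @slot model the chosen \code{ErgmModel}.
#' @slot fit the chosen model's \code{ErgmFit}.
#' @slot trail data.frame recording every candidate considered.
#' @slot method character, which procedure produced the result.
#' @slot details list of per-candidate extras (e.g. GOF reports).
#' @export
setClass("SelectionResult",
  representation(model = "ErgmModel", fit = "ErgmFit",
                 trail = "data.frame", method = "character",
                 details = "list"))

setValidity("SelectionResult", function(object) {
  if (!.modelLabel(object@model) %in% object@trail$model)
    return("chosen model must appear in the trail")
  TRUE
})

#' Cohort of fitted ERGMs sharing one model
#'
#' @slot fits list of \code{ErgmFit}, one per subject.
#' @slot subjects character vector of subject identifiers.
#' @export
setClass("CohortFits",
  representation(fits = "list", subjects = "character"))

setValidity("CohortFits", function(object) {
  if (length(object@fits) < 1L) return("at least one fit required")
  if (length(object@subjects) != length(object@fits))
    return("one subject id per fit")
  nm <- lapply(object@fits, function(f) names(f@theta))
  if (!all(vapply(nm, identical, logical(1), nm[[1]])))
    return("all fits must share an identical term list")
  if (!all(vapply(object@fits, function(f) isTRUE(f@converged), logical(1))))
    return("all fits must have converged")
  TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a
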