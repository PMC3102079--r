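# Exact likelihood machinery by enumeration of all 2^C(n,2) labeled graphs.
# Affordable up to the enumeration limit (default n = 7, ~2 million graphs);
# the enumeration runs in Gray-code order in compiled code so each graph is
# one dyad toggle away from its predecessor.

#' Exact log normalizing constant of an ERGM
#'
#' \code{log kappa(theta) = log sum_y exp(theta' g(y))} over all labeled
#' simple graphs on \code{nNodes} nodes.
#'
#' @param model an \code{ErgmModel}.
#' @param theta parameter vector, one entry per term.
#' @param nNodes number of nodes, at most \code{enumLimit}.
#' @param nodeData data.frame of node attributes (needed for nodematch).
#' @param enumLimit refuse enumeration beyond this many nodes (default 7).
#' @return the log partition value (a real scalar).
#' @examples
#' # edges-only: closed form C(n,2) * log(1 + exp(theta))
#' exactLogPartition(ergmModel("edges"), -1, 5)
#' choose(5, 2) * log(1 + exp(-1))
#' @export
exactLogPartition <- function(model, theta, nNodes, nodeData = NULL,
                              enumLimit = 7L) {
  .exactMoments(model, theta, nNodes, nodeData, enumLimit)$log_kappa
}

.exactMoments <- function(model, theta, nNodes, nodeData = NULL,
                          enumLimit = 7L) {
  validObject(model)
  if (nNodes > enumLimit)
    stop("exact enumeration refused for n = ", nNodes,
         " (limit ", enumLimit, "); use mcmcMLE instead")
  if (length(theta) != nTerms(model))
    stop("theta must have one entry per model term")
  A <- .termAttrMatrix(model, nNodes = as.integer(nNodes),
                       nodeData = nodeData)
  cpp_exact(as.integer(nNodes), .termKinds(model), .termTaus(model), A,
            as.numeric(theta))
}

#' Exact maximum likelihood fit for small networks
#'
#' Maximizes \code{theta' g(y_obs) - log kappa(theta)} by quasi-Newton
#' optimization with the exact gradient \code{g(y_obs) - E_theta[g]}. At the
#' optimum the expected statistics match the observed ones (the
#' exponential-family moment condition), which is verified and reported.
#' Standard errors come from the inverse of the exact Fisher information
#' \code{Cov_theta[g]}.
#'
#' @param net a \code{BrainNetwork} with at most \code{enumLimit} nodes.
#' @param model an \code{ErgmModel}.
#' @param enumLimit enumeration limit (default 7 nodes).
#' @param gradTol convergence tolerance on the gradient norm.
#' @return an \code{\link[=ErgmFit-class]{ErgmFit}} with
#'   \code{method = "exact"}.
#' @export
exactMLE <- function(net, model, enumLimit = 7L, gradTol = 1e-6) {
  validObject(model)
  n <- nNodes(net)
  gObs <- statisticVector(net, model)
  nd <- nodeData(net)
  p <- nTerms(model)

  negll <- function(th) {
    m <- .exactMoments(model, th, n, nd, enumLimit)
    m$log_kappa - sum(th * gObs)
  }
  grad <- function(th) {
    m <- .exactMoments(model, th, n, nd, enumLimit)
    m$mean - gObs
  }
  opt <- stats::optim(rep(0, p), negll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  theta <- opt$par
  m <- .exactMoments(model, theta, n, nd, enumLimit)
  gnorm <- sqrt(sum((gObs - m$mean)^2))
  if (gnorm > max(gradTol, 1e-6) || any(abs(theta) > 15)) {
    worst <- termNames(model)[which.max(abs(gObs - m$mean))]
    stop("exact MLE did not converge (observed statistic '", worst,
         "' appears to lie on the boundary of the convex hull)")
  }
  covTheta <- tryCatch(solve(m$cov), error = function(e)
    matrix(NA_real_, p, p))
  loglik <- sum(theta * gObs) - m$log_kappa
  .newFit(model, theta, sqrt(pmax(diag(covTheta), 0)), covTheta,
          loglik, aicOf(loglik, p), "exact", TRUE,
          diagnostics = list(gradient_norm = gnorm,
                             expected_stats = m$mean,
                             observed_stats = gObs))
}
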