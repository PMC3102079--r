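#' Sampler settings
#'
#' Settings for the Metropolis dyad-toggle sampler. The chain proposes a
#' uniformly random dyad and accepts the toggle with probability
#' \code{min(1, exp(+-theta' delta))}, where \code{delta} is the dyad's
#' change-statistic vector. Defaults (chosen per chain length heuristics for
#' sparse brain-scale graphs): burn-in of \code{10 C(n,2)} toggles and
#' thinning of \code{C(n,2)} toggles between retained draws.
#'
#' @param burnin toggles discarded before the first draw (default
#'   \code{10 * choose(n, 2)}).
#' @param thin toggles between retained draws (default \code{choose(n, 2)}).
#' @param seed integer seed; fixed seed gives identical output.
#' @param init chain start: \code{"empty"}, \code{"observed"} (requires
#'   \code{initNetwork}) or \code{"bernoulli"} (independent edges with
#'   probability \code{initProb}).
#' @param initProb edge probability for \code{init = "bernoulli"}.
#' @param initNetwork a \code{BrainNetwork} to start from.
#' @return a list of class \code{"samplerControl"}.
#' @export
samplerControl <- function(burnin = NULL, thin = NULL, seed = 1L,
                           init = c("empty", "observed", "bernoulli"),
                           initProb = 0.5, initNetwork = NULL) {
  init <- match.arg(init)
  if (!is.null(burnin) && burnin < 0) stop("burnin must be >= 0")
  if (!is.null(thin) && thin < 0) stop("thin must be >= 0")
  structure(list(burnin = burnin, thin = thin, seed = as.integer(seed),
                 init = init, initProb = initProb,
                 initNetwork = initNetwork),
            class = "samplerControl")
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.initEdges <- function(n, control) {
  switch(control$init,
    empty = matrix(integer(0), ncol = 2L),
    observed = {
      if (is.null(control$initNetwork))
        stop("init = 'observed' needs initNetwork")
      edgeMatrix(control$initNetwork)
    },
    bernoulli = {
      p <- control$initProb
      .withSeed(control$seed + 1L, {
        up <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
        keep <- stats::runif(nrow(up)) < p
        matrix(as.integer(up[keep, , drop = FALSE]), ncol = 2L)
      })
    })
}

# stats-only sampling used by the fitting iterations
.sampleStats <- function(model, theta, n, count, control, nodeData = NULL,
                         returnEdges = FALSE) {
  A <- .termAttrMatrix(model, nNodes = n, nodeData = nodeData)
  burnin <- control$burnin %||% (10 * choose(n, 2))
  thin <- control$thin %||% choose(n, 2)
  init <- .initEdges(n, control)
  res <- cpp_sample(as.integer(n), .termKinds(model), .termTaus(model), A,
                    as.numeric(theta), init, burnin, thin,
                    as.integer(count), control$seed, returnEdges)
  colnames(res$stats) <- termNames(model)
  res
}

#' Simulate networks from an ERGM
#'
#' Draws networks from the model \code{exp(theta' g(y)) / kappa(theta)} by a
#' Metropolis chain over dyad toggles, returning \code{count} thinned draws.
#' A fixed seed yields identical output. Degenerate parameter vectors are not
#' an error, but a warning is issued when the draws are nearly empty or
#' nearly complete (mean density below 0.01 or above 0.99).
#'
#' @param model an \code{ErgmModel}.
#' @param theta parameter vector, one entry per term.
#' @param nNodes number of nodes.
#' @param count number of networks to return (>= 1).
#' @param control a \code{\link{samplerControl}}.
#' @param nodeData node attributes (required for nodematch terms).
#' @return list of \code{BrainNetwork} objects, with the retained draws'
#'   sufficient statistics in \code{attr(, "stats")} and the acceptance rate
#'   in \code{attr(, "acceptance_rate")}.
#' @examples
#' nets <- simulateNetworks(ergmModel("edges"), 0, nNodes = 10, count = 5,
#'                          control = samplerControl(seed = 42))
#' mean(vapply(nets, edgeDensity, numeric(1)))  # about 0.5
#' @export
simulateNetworks <- function(model, theta, nNodes, count,
                             control = samplerControl(), nodeData = NULL) {
  validObject(model)
  if (count < 1L) stop("count must be >= 1")
  if (any(!is.finite(theta))) stop("theta must be finite")
  if (length(theta) != nTerms(model))
    stop("theta must have one entry per model term")
  res <- .sampleStats(model, theta, nNodes, count, control,
                      nodeData = nodeData, returnEdges = TRUE)
  dens <- mean(res$n_edges) / choose(nNodes, 2)
  if (dens < 0.01 || dens > 0.99)
    warning("sampled networks are nearly ",
            if (dens < 0.01) "empty" else "complete",
            " (mean density ", format(dens, digits = 3),
            "): the parameter vector may be degenerate")
  nets <- lapply(res$edges, function(e)
    brainNetwork(nNodes, e, nodeData = nodeData))
  attr(nets, "stats") <- res$stats
  attr(nets, "acceptance_rate") <- res$acceptance_rate
  nets
}
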