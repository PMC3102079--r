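#' Shared-partner distributions (ESP, NSP, DSP)
#'
#' For each unordered dyad the number of shared partners (common neighbours)
#' is computed; dyads joined by an edge contribute to the edgewise
#' distribution (ESP), the others to the non-edgewise one (NSP), and every
#' dyad to the dyadwise one (DSP = ESP + NSP).
#'
#' @param net a \code{BrainNetwork} with at least two nodes.
#' @return a \code{\link[=SharedPartnerDist-class]{SharedPartnerDist}}; each
#'   count vector has length \code{nNodes - 1}, entry k counting dyads with
#'   exactly k - 1 shared partners.
#' @examples
#' tri <- brainNetwork(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
#' esp(sharedPartnerDist(tri))
#' @export
sharedPartnerDist <- function(net) {
  n <- nNodes(net)
  if (n < 2L) stop("need at least two nodes")
  A <- adjacencyMatrix(net)
  CN <- A %*% A                       # common-neighbour counts off-diagonal
  up <- upper.tri(A)
  sp <- CN[up]
  isEdge <- A[up] == 1L
  nb <- n - 1L
  espv <- tabulate(sp[isEdge] + 1L, nbins = nb)
  nspv <- tabulate(sp[!isEdge] + 1L, nbins = nb)
  names(espv) <- names(nspv) <- 0:(nb - 1L)
  new("SharedPartnerDist", esp = espv, nsp = nspv, dsp = espv + nspv)
}

#' @rdname sharedPartnerDist
#' @param x a \code{SharedPartnerDist}.
#' @export
esp <- function(x) x@esp

#' @rdname sharedPartnerDist
#' @export
nsp <- function(x) x@nsp

#' @rdname sharedPartnerDist
#' @export
dsp <- function(x) x@dsp

setMethod("show", "SharedPartnerDist", function(object) {
  k <- max(1L, max(which(object@dsp > 0), 1L))
  cat("SharedPartnerDist (up to", k - 1L, "shared partners)\n")
  print(rbind(esp = object@esp[1:k], nsp = object@nsp[1:k],
              dsp = object@dsp[1:k]))
})

#' Elementwise sum of ESP and NSP count vectors
#'
#' The dyadwise shared-partner distribution is the elementwise sum of the
#' edgewise and non-edgewise ones.
#'
#' @param esp,nsp count vectors of equal length.
#' @return the DSP count vector.
#' @examples
#' sumEspNsp(c(1, 5, 1, 0, 0), c(1, 4, 3, 0, 0))
#' @export
sumEspNsp <- function(esp, nsp) {
  if (length(esp) != length(nsp))
    stop("esp and nsp must have equal length")
  esp + nsp
}

#' Geometrically weighted statistic of a count distribution
#'
#' Computes \code{exp(tau) * sum_{k >= 1} (1 - (1 - exp(-tau))^k) * counts_k}
#' (the statnet-compatible curved-ERGM parameterization of Hunter 2007).
#' Applied to the ESP/NSP/DSP distributions it yields GWESP/GWNSP/GWDSP; to
#' the degree distribution, GWD. Larger shared-partner (or degree) counts
#' receive geometrically diminishing incremental weight, which is what guards
#' these terms against model degeneracy.
#'
#' @param counts numeric vector; \code{counts[k + 1]} is the number of
#'   entities with exactly \code{k} shared partners (or degree \code{k}).
#' @param tau nonnegative decay parameter.
#' @return the weighted sum (a real scalar).
#' @examples
#' gwStatistic(c(0, 3), tau = 0.75)  # triangle ESP: always 3
#' @export
gwStatistic <- function(counts, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0)
    stop("tau must be a single nonnegative number")
  k <- seq_along(counts) - 1L
  w <- exp(tau) * (1 - (1 - exp(-tau))^k)
  sum(w[k >= 1] * counts[k >= 1])
}

#' Count statistics
#'
#' \code{countEdges} counts edges; \code{countTwoPaths} counts paths of
#' length two, \code{sum_v choose(deg(v), 2)}; \code{countNodematch} counts
#' edges whose endpoints share the value of a categorical node attribute.
#'
#' @param net a \code{BrainNetwork}.
#' @param attribute node-attribute name (for \code{countNodematch}).
#' @return integer count.
#' @export
countEdges <- function(net) edgeCount(net)

#' @rdname countEdges
#' @export
countTwoPaths <- function(net) sum(choose(.degrees(net), 2))

#' @rdname countEdges
#' @export
countNodematch <- function(net, attribute) {
  val <- nodeAttribute(net, attribute)
  e <- edgeMatrix(net)
  sum(val[e[, 1L]] == val[e[, 2L]])
}

#' Sufficient-statistic vector g(y)
#'
#' Evaluates every term of a model specification on a network, in model
#' order. This is the reference (vectorized, whole-graph) route; the
#' compiled incremental route used by the sampler is cross-checked against
#' it in the test suite.
#'
#' @param net a \code{BrainNetwork}.
#' @param model an \code{ErgmModel}.
#' @return named numeric vector of length \code{nTerms(model)}.
#' @examples
#' tri <- brainNetwork(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
#' statisticVector(tri, ergmModel("edges", ergmTerm("gwesp", tau = 0.75)))
#' @export
statisticVector <- function(net, model) {
  validObject(model)
  spd <- NULL
  needSP <- any(vapply(model@terms, `[[`, character(1), "kind") %in%
                c("gwesp", "gwnsp", "gwdsp"))
  if (needSP) spd <- sharedPartnerDist(net)
  g <- vapply(model@terms, function(tm) {
    switch(tm$kind,
      edges = as.numeric(countEdges(net)),
      two_path = as.numeric(countTwoPaths(net)),
      gwd = gwStatistic(degreeDistribution(net), tm$tau),
      gwesp = gwStatistic(esp(spd), tm$tau),
      gwnsp = gwStatistic(nsp(spd), tm$tau),
      gwdsp = gwStatistic(dsp(spd), tm$tau),
      nodematch = as.numeric(countNodematch(net, tm$attribute)))
  }, numeric(1))
  names(g) <- termNames(model)
  g
}

#' Change statistics of a dyad
#'
#' The vector \code{g(y + ij) - g(y - ij)}: the amount each model statistic
#' changes when the edge (i, j) is switched on, regardless of its current
#' state. The conditional log odds of that edge equal \code{theta} times this
#' vector. Computed incrementally in compiled code.
#'
#' @param net a \code{BrainNetwork}.
#' @param dyad integer vector \code{c(i, j)} of two distinct node indices.
#' @param model an \code{ErgmModel}.
#' @return named numeric vector of length \code{nTerms(model)}.
#' @export
changeStatistics <- function(net, dyad, model) {
  validObject(model)
  if (length(dyad) != 2L || dyad[1L] == dyad[2L])
    stop("dyad must be two distinct node indices")
  A <- .termAttrMatrix(model, net)
  out <- cpp_change_stats(nNodes(net), edgeMatrix(net),
                          as.integer(min(dyad)), as.integer(max(dyad)),
                          .termKinds(model), .termTaus(model), A)
  names(out) <- termNames(model)
  out
}
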