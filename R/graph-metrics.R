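#' Edge density of a network
#'
#' Fraction of the \code{n(n-1)/2} dyads joined by an edge; the edge
#' probability of the matching Erdos-Renyi null model.
#'
#' @param net a \code{BrainNetwork} with at least two nodes.
#' @return proportion in \code{[0, 1]}.
#' @examples
#' edgeDensity(brainNetwork(3, rbind(c(1, 2), c(2, 3), c(1, 3))))
#' @export
edgeDensity <- function(net) {
  n <- nNodes(net)
  if (n < 2L) stop("density needs at least two nodes")
  edgeCount(net) / (n * (n - 1) / 2)
}

#' Degree distribution
#'
#' @param net a \code{BrainNetwork}.
#' @return numeric vector \code{D} of length \code{nNodes(net)} where
#'   \code{D[k + 1]} is the number of nodes with degree \code{k}; named by
#'   degree.
#' @export
degreeDistribution <- function(net) {
  n <- nNodes(net)
  deg <- .degrees(net)
  D <- tabulate(deg + 1L, nbins = n)
  names(D) <- 0:(n - 1)
  D
}

#' Geodesic (shortest-path) distribution over dyads
#'
#' Counts unordered dyads by their shortest-path distance (breadth-first
#' search via igraph); dyads in different components are reported separately
#' as \code{unreachable}, never folded into a numeric bin.
#'
#' @param net a \code{BrainNetwork}.
#' @return list with \code{counts} (named numeric vector over distances
#'   \code{1..n-1}) and \code{unreachable} (dyad count).
#' @export
geodesicDistribution <- function(net) {
  n <- nNodes(net)
  d <- igraph::distances(asIgraph(net))
  du <- d[upper.tri(d)]
  finite <- du[is.finite(du)]
  counts <- tabulate(finite, nbins = n - 1L)
  names(counts) <- seq_len(n - 1L)
  list(counts = counts, unreachable = sum(!is.finite(du)))
}

#' Triad census of an undirected graph
#'
#' Counts node triples by their number of internal edges (0, 1, 2 or 3).
#' Computed in closed form from the edge count, two-path count and triangle
#' count.
#'
#' @param net a \code{BrainNetwork} with at least three nodes.
#' @return numeric vector of length 4, names \code{"0".."3"}; sums to
#'   \code{choose(n, 3)}.
#' @export
triadCensus <- function(net) {
  n <- nNodes(net)
  if (n < 3L) stop("triad census needs at least three nodes")
  m <- edgeCount(net)
  deg <- .degrees(net)
  p2 <- sum(choose(deg, 2))
  tri <- sum(igraph::count_triangles(asIgraph(net))) / 3
  n3 <- tri
  n2 <- p2 - 3 * n3
  n1 <- m * (n - 2) - 2 * n2 - 3 * n3
  n0 <- choose(n, 3) - n1 - n2 - n3
  out <- c(`0` = n0, `1` = n1, `2` = n2, `3` = n3)
  out
}
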