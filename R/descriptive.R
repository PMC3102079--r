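#' Descriptive small-world metrics of a network
#'
#' The standard neuroimaging summary metrics: clustering coefficient C (mean
#' local clustering, zero for nodes of degree < 2), characteristic path
#' length L (mean shortest-path length over reachable unordered pairs; the
#' number of unreachable pairs is reported alongside), local efficiency Eloc
#' (mean over nodes of the global efficiency of the subgraph induced by the
#' node's neighbours), global efficiency Eglob (mean of 1/distance over all
#' unordered pairs, zero for unreachable ones), and mean nodal degree
#' K = 2m/n.
#'
#' @param net a \code{BrainNetwork} with at least two nodes.
#' @return named list with entries \code{C}, \code{L}, \code{Eloc},
#'   \code{Eglob}, \code{K} and \code{unreachable_pairs}.
#' @examples
#' tri <- brainNetwork(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
#' descriptiveMetrics(tri)  # C = 1, L = 1, Eglob = 1, K = 2
#' @export
descriptiveMetrics <- function(net) {
  n <- nNodes(net)
  if (n < 2L) stop("need at least two nodes")
  g <- asIgraph(net)

  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  C <- mean(cl)

  d <- igraph::distances(g)
  du <- d[upper.tri(d)]
  reach <- is.finite(du) & du > 0
  L <- if (any(reach)) mean(du[reach]) else NA_real_
  inv <- ifelse(is.finite(du) & du > 0, 1 / du, 0)
  Eglob <- mean(inv)

  Eloc <- mean(vapply(seq_len(n), function(v) {
    nb <- igraph::neighbors(g, v)
    if (length(nb) < 2L) return(0)
    .globalEfficiency(igraph::induced_subgraph(g, nb))
  }, numeric(1)))

  list(C = C, L = L, Eloc = Eloc, Eglob = Eglob,
       K = 2 * edgeCount(net) / n, unreachable_pairs = sum(!reach))
}

.globalEfficiency <- function(g) {
  d <- igraph::distances(g)
  du <- d[upper.tri(d)]
  if (length(du) == 0L) return(0)
  mean(ifelse(is.finite(du) & du > 0, 1 / du, 0))
}

#' Mean and standard error of descriptive metrics over simulated networks
#'
#' @param nets a list of at least two \code{BrainNetwork} objects (e.g.
#'   draws from \code{\link{simulateNetworks}}).
#' @return data.frame with one row per metric (\code{C}, \code{L},
#'   \code{Eloc}, \code{Eglob}, \code{K}) and columns \code{mean} and
#'   \code{se} (standard error of the mean).
#' @export
summarizeSimulations <- function(nets) {
  if (length(nets) < 2L) stop("need at least two networks")
  mm <- t(vapply(nets, function(x) {
    m <- descriptiveMetrics(x)
    c(C = m$C, L = m$L, Eloc = m$Eloc, Eglob = m$Eglob, K = m$K)
  }, numeric(5)))
  data.frame(metric = colnames(mm),
             mean = colMeans(mm),
             se = apply(mm, 2, stats::sd) / sqrt(nrow(mm)),
             row.names = colnames(mm))
}
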