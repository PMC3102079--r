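#' Construct a BrainNetwork
#'
#' Builds an undirected simple graph from an edge matrix of node indices.
#' Edges are normalized (each pair stored once with \code{i < j}, sorted,
#' deduplicated); self-loops are an error. Node labels default to
#' \code{"v1" ... "vn"}.
#'
#' @param nNodes number of nodes (positive integer).
#' @param edges two-column matrix (or empty/NULL) of node indices in
#'   \code{1..nNodes}; each row one edge.
#' @param nodeLabels optional character vector of node labels.
#' @param nodeData optional data.frame of categorical node attributes, one
#'   row per node.
#' @return A \code{\link[=BrainNetwork-class]{BrainNetwork}} object.
#' @examples
#' net <- brainNetwork(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
#' edgeCount(net)
#' @export
brainNetwork <- function(nNodes, edges = NULL, nodeLabels = NULL,
                         nodeData = NULL) {
  nNodes <- as.integer(nNodes)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- matrix(as.integer(as.matrix(edges)), ncol = 2L)
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loops are not allowed")
    flip <- edges[, 1L] > edges[, 2L]
    edges[flip, ] <- edges[flip, 2:1]
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  colnames(edges) <- c("i", "j")
  if (is.null(nodeLabels)) nodeLabels <- paste0("v", seq_len(nNodes))
  if (is.null(nodeData)) {
    nodeData <- data.frame(row.names = seq_len(nNodes))
  } else {
    nodeData <- as.data.frame(nodeData)
  }
  new("BrainNetwork", nNodes = nNodes, edges = edges,
      nodeLabels = as.character(nodeLabels), nodeData = nodeData)
}

#' @rdname brainNetwork
#' @param object,net a \code{BrainNetwork}.
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))

#' @rdname brainNetwork
#' @export
setMethod("nNodes", "BrainNetwork", function(object) object@nNodes)

#' @rdname brainNetwork
#' @export
setGeneric("edgeCount", function(object) standardGeneric("edgeCount"))

#' @rdname brainNetwork
#' @export
setMethod("edgeCount", "BrainNetwork", function(object) nrow(object@edges))

#' @rdname brainNetwork
#' @export
setGeneric("edgeMatrix", function(object) standardGeneric("edgeMatrix"))

#' @rdname brainNetwork
#' @export
setMethod("edgeMatrix", "BrainNetwork", function(object) object@edges)

#' @rdname brainNetwork
#' @export
setGeneric("nodeLabels", function(object) standardGeneric("nodeLabels"))

#' @rdname brainNetwork
#' @export
setMethod("nodeLabels", "BrainNetwork", function(object) object@nodeLabels)

#' @rdname brainNetwork
#' @export
setGeneric("nodeData", function(object) standardGeneric("nodeData"))

#' @rdname brainNetwork
#' @export
setMethod("nodeData", "BrainNetwork", function(object) object@nodeData)

#' Fetch one categorical node attribute
#'
#' @param net a \code{BrainNetwork}.
#' @param name attribute (column) name in \code{nodeData(net)}.
#' @return character vector of length \code{nNodes(net)}.
#' @export
nodeAttribute <- function(net, name) {
  nd <- nodeData(net)
  if (!name %in% colnames(nd))
    stop("node attribute '", name, "' not found")
  val <- as.character(nd[[name]])
  if (length(val) != nNodes(net) || anyNA(val))
    stop("node attribute '", name, "' must label every node")
  val
}

setMethod("show", "BrainNetwork", function(object) {
  cat("BrainNetwork with", object@nNodes, "nodes and",
      nrow(object@edges), "edges\n")
  cat("  density:", format(edgeDensity(object), digits = 4), "\n")
  if (ncol(object@nodeData) > 0L)
    cat("  node attributes:", paste(colnames(object@nodeData),
                                    collapse = ", "), "\n")
})

#' Adjacency matrix of a network
#'
#' @param net a \code{BrainNetwork}.
#' @return symmetric 0/1 integer matrix with node labels as dimnames.
#' @export
adjacencyMatrix <- function(net) {
  n <- nNodes(net)
  A <- matrix(0L, n, n, dimnames = list(nodeLabels(net), nodeLabels(net)))
  e <- edgeMatrix(net)
  if (nrow(e) > 0L) {
    A[e] <- 1L
    A[e[, 2:1, drop = FALSE]] <- 1L
  }
  A
}

#' Convert to an igraph object
#'
#' @param net a \code{BrainNetwork}.
#' @return an \code{igraph} undirected graph with a \code{name} vertex
#'   attribute carrying the node labels.
#' @export
asIgraph <- function(net) {
  g <- igraph::make_empty_graph(n = nNodes(net), directed = FALSE)
  if (edgeCount(net) > 0L)
    g <- igraph::add_edges(g, t(edgeMatrix(net)))
  igraph::set_vertex_attr(g, "name", value = nodeLabels(net))
}

.degrees <- function(net) {
  n <- nNodes(net)
  e <- edgeMatrix(net)
  tabulate(c(e[, 1L], e[, 2L]), nbins = n)
}
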