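# File readers and writers. Node labels in input files may be arbitrary
# strings; they are mapped to contiguous indices and kept as the label table.

#' Read a network from a two-column edge list
#'
#' Whitespace- or tab-separated, two columns of node labels, optional header
#' line. Labels are mapped to contiguous node indices (sorted unique order,
#' unless \code{nodeLabels} fixes the node set and order).
#'
#' @param file path to the edge-list file.
#' @param nodeLabels optional character vector fixing the full node set
#'   (needed to represent isolated nodes).
#' @param header does the file start with a header line? Default: detected
#'   (a first line whose tokens repeat nowhere else is treated as data).
#' @return a \code{BrainNetwork}.
#' @export
readEdgeList <- function(file, nodeLabels = NULL, header = FALSE) {
  x <- utils::read.table(file, header = header, colClasses = "character")
  if (ncol(x) < 2L) stop("edge list needs two columns")
  a <- x[[1]]
  b <- x[[2]]
  if (is.null(nodeLabels)) nodeLabels <- sort(unique(c(a, b)))
  i <- match(a, nodeLabels)
  j <- match(b, nodeLabels)
  if (anyNA(i) || anyNA(j))
    stop("edge list contains labels outside the node set")
  brainNetwork(length(nodeLabels), cbind(i, j), nodeLabels = nodeLabels)
}

#' @rdname readEdgeList
#' @param net a \code{BrainNetwork} to write.
#' @export
writeEdgeList <- function(net, file) {
  e <- edgeMatrix(net)
  lab <- nodeLabels(net)
  utils::write.table(data.frame(from = lab[e[, 1L]], to = lab[e[, 2L]]),
                     file, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(file)
}

#' Read a network from a square 0/1 adjacency CSV
#'
#' Optional header row / leading label column; the diagonal is ignored; the
#' matrix must be symmetric.
#'
#' @param file path to the CSV file.
#' @return a \code{BrainNetwork}.
#' @export
readAdjacencyCSV <- function(file) {
  first <- readLines(file, n = 1L)
  hasHeader <- is.na(suppressWarnings(
    as.numeric(strsplit(first, ",")[[1]][2])))
  x <- utils::read.csv(file, header = hasHeader, check.names = FALSE)
  labels <- NULL
  if (!is.numeric(x[[1]])) {
    labels <- as.character(x[[1]])
    x <- x[, -1, drop = FALSE]
  } else if (hasHeader) {
    labels <- colnames(x)
  }
  A <- as.matrix(x)
  storage.mode(A) <- "double"
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
  diag(A) <- 0
  if (anyNA(A) || !all(A %in% c(0, 1)))
    stop("adjacency entries must be 0 or 1")
  if (any(A != t(A))) stop("adjacency matrix must be symmetric")
  e <- which(A == 1 & upper.tri(A), arr.ind = TRUE)
  brainNetwork(nrow(A), e, nodeLabels = labels)
}

#' Read node attributes from TSV
#'
#' Two or more columns: node label then one column per categorical
#' attribute. A header line names the attributes; without one the single
#' attribute column is called \code{"attr"}.
#'
#' @param file path to the TSV file.
#' @param net optional \code{BrainNetwork}; when given, rows are matched to
#'   its node labels (every node must be labeled) and the attributes are
#'   attached to a copy of the network which is returned.
#' @return a data.frame of attributes (rownames = node labels), or the
#'   network with attributes attached when \code{net} is supplied.
#' @export
readNodeAttributes <- function(file, net = NULL) {
  peek <- utils::read.table(file, header = FALSE, sep = "\t", nrows = 1L,
                            colClasses = "character")
  header <- tolower(peek[1, 1]) %in% c("node", "node_label", "label", "id")
  x <- utils::read.table(file, header = header, sep = "\t",
                         colClasses = "character", check.names = FALSE)
  if (!header) colnames(x) <- c("node_label",
                                paste0("attr", seq_len(ncol(x) - 1L)))
  labels <- x[[1]]
  attrs <- x[, -1, drop = FALSE]
  rownames(attrs) <- labels
  if (is.null(net)) return(attrs)
  idx <- match(nodeLabels(net), labels)
  if (anyNA(idx))
    stop("attribute file is missing nodes: ",
         paste(utils::head(nodeLabels(net)[is.na(idx)], 5), collapse = ", "))
  nd <- attrs[idx, , drop = FALSE]
  rownames(nd) <- NULL
  brainNetwork(nNodes(net), edgeMatrix(net), nodeLabels(net), nd)
}

#' Read / write GraphML
#'
#' Thin wrappers over igraph's GraphML support.
#'
#' @param file path to a GraphML file.
#' @return \code{readGraphML} returns a \code{BrainNetwork}.
#' @export
readGraphML <- function(file) {
  g <- igraph::read_graph(file, format = "graphml")
  labels <- igraph::vertex_attr(g, "name") %||%
    paste0("v", seq_len(igraph::vcount(g)))
  e <- igraph::as_edgelist(g, names = FALSE)
  brainNetwork(igraph::vcount(g), e, nodeLabels = labels)
}

#' @rdname readGraphML
#' @param net a \code{BrainNetwork}.
#' @export
writeGraphML <- function(net, file) {
  igraph::write_graph(asIgraph(net), file, format = "graphml")
  invisible(file)
}
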