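#' Build a network from a correlation matrix by the size-matching rule
#'
#' Thresholds a (partial) correlation matrix so that the relation between the
#' node count n and the mean degree K is the same across subjects:
#' \code{n = K^s}, i.e. the target mean degree is \code{K = n^(1/s)}. The
#' \code{E = round(n K / 2)} largest off-diagonal entries become edges, so
#' every subject's network has exactly the same edge count at a given n. The
#' relation comes from the path length of a random graph with n nodes and
#' mean degree K, the usual device for producing comparable sparse networks
#' across subjects.
#'
#' @param corr square symmetric numeric matrix with unit diagonal (entries in
#'   \code{[-1, 1]}); dimnames, if any, become node labels.
#' @param s exponent of the size-matching relation, \code{> 1}; default 2.5,
#'   which gives K of about 6 at n = 90.
#' @param absolute rank entries by absolute value instead of signed value
#'   (default FALSE: positive couplings are retained first).
#' @param nodeData optional node-attribute data.frame passed through to the
#'   network.
#' @return a \code{BrainNetwork} with exactly \code{round(n * n^(1/s) / 2)}
#'   edges. Ties are broken by (row, column) index order.
#' @examples
#' set.seed(1)
#' z <- matrix(rnorm(90 * 20), 20)
#' r <- cor(t(z))
#' net <- thresholdByS(r, s = 2.5)
#' edgeCount(net)  # round(20 * 20^(1/2.5) / 2)
#' @export
thresholdByS <- function(corr, s = 2.5, absolute = FALSE, nodeData = NULL) {
  corr <- as.matrix(corr)
  n <- nrow(corr)
  if (n < 3L || ncol(corr) != n) stop("corr must be square with n >= 3")
  if (s <= 1) stop("s must be > 1")
  if (max(abs(corr - t(corr))) > 1e-8)
    stop("corr must be symmetric (within 1e-8)")
  K <- n^(1 / s)
  E <- round(n * K / 2)
  if (E > choose(n, 2))
    stop("target edge count ", E, " exceeds the ", choose(n, 2), " dyads")
  idx <- which(upper.tri(corr), arr.ind = TRUE)
  val <- corr[upper.tri(corr)]
  if (absolute) val <- abs(val)
  ord <- order(-val, idx[, 1L], idx[, 2L])
  take <- idx[ord[seq_len(E)], , drop = FALSE]
  labels <- rownames(corr) %||% colnames(corr)
  brainNetwork(n, take, nodeLabels = labels, nodeData = nodeData)
}

#' Read a correlation matrix from CSV
#'
#' Accepts a plain numeric CSV, with or without a header row and a leading
#' label column. Validates symmetry, unit diagonal and the \code{[-1, 1]}
#' range.
#'
#' @param file path to the CSV file.
#' @return numeric matrix with node labels as dimnames when present.
#' @export
readCorrelationMatrix <- function(file) {
  first <- readLines(file, n = 1L)
  hasHeader <- is.na(suppressWarnings(
    as.numeric(strsplit(first, ",")[[1]][2])))
  x <- utils::read.csv(file, header = hasHeader, check.names = FALSE)
  if (!is.numeric(x[[1]])) {
    labels <- as.character(x[[1]])
    x <- x[, -1, drop = FALSE]
    rownames(x) <- labels
  }
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("correlation matrix must be square")
  if (anyNA(m)) stop("correlation matrix contains missing values")
  if (max(abs(m - t(m))) > 1e-8) stop("correlation matrix must be symmetric")
  if (any(abs(m) > 1 + 1e-8)) stop("correlations must lie in [-1, 1]")
  if (any(abs(diag(m) - 1) > 1e-8)) stop("diagonal must be 1")
  if (!is.null(colnames(m)) && is.null(rownames(m))) rownames(m) <- colnames(m)
  m
}
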