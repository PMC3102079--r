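#' Define one ERGM term
#'
#' @param kind one of \code{"edges"}, \code{"two_path"}, \code{"gwd"},
#'   \code{"gwesp"}, \code{"gwnsp"}, \code{"gwdsp"}, \code{"nodematch"}.
#' @param tau nonnegative decay parameter, required for (and only for) the
#'   geometrically weighted kinds. The decay is fixed and known, not
#'   estimated. Default 0.75.
#' @param attribute node-attribute name, required for (and only for)
#'   \code{nodematch}.
#' @param name optional display name; defaults to the kind (plus the
#'   attribute for nodematch).
#' @return a term definition list for \code{\link{ergmModel}}.
#' @export
ergmTerm <- function(kind, tau = NULL, attribute = NULL, name = NULL) {
  kind <- match.arg(kind, names(.TERM_KINDS))
  if (kind %in% .GW_KINDS && is.null(tau)) tau <- 0.75
  if (is.null(name))
    name <- if (kind == "nodematch" && !is.null(attribute))
      paste0("nodematch.", attribute) else kind
  list(kind = kind, tau = tau, attribute = attribute, name = name)
}

#' Assemble an ERGM model specification
#'
#' @param ... term definitions from \code{\link{ergmTerm}}, or character
#'   shorthand (a kind name, using default settings).
#' @return an \code{\link[=ErgmModel-class]{ErgmModel}}.
#' @examples
#' ergmModel("edges", ergmTerm("gwesp", tau = 0.75))
#' @export
ergmModel <- function(...) {
  terms <- lapply(list(...), function(x) {
    if (is.character(x)) ergmTerm(x) else x
  })
  new("ErgmModel", terms = terms)
}

#' The best-assessment model preset
#'
#' Edges + GWESP + GWNSP: a connectedness term, a local-efficiency term and a
#' global-efficiency term — the combination retained across the majority of
#' per-subject graphical GOF selections for whole-brain functional networks.
#'
#' @param tau decay parameter shared by the geometrically weighted terms.
#' @return an \code{ErgmModel}.
#' @export
bestAssessmentModel <- function(tau = 0.75) {
  ergmModel(ergmTerm("edges"), ergmTerm("gwesp", tau = tau),
            ergmTerm("gwnsp", tau = tau))
}

#' @rdname ergmModel
#' @param object an \code{ErgmModel}.
#' @export
setGeneric("termNames", function(object) standardGeneric("termNames"))

#' @rdname ergmModel
#' @export
setMethod("termNames", "ErgmModel", function(object)
  vapply(object@terms, `[[`, character(1), "name"))

#' @rdname ergmModel
#' @export
setGeneric("nTerms", function(object) standardGeneric("nTerms"))

#' @rdname ergmModel
#' @export
setMethod("nTerms", "ErgmModel", function(object) length(object@terms))

setMethod("show", "ErgmModel", function(object) {
  cat("ErgmModel with", nTerms(object), "terms:\n")
  for (tm in object@terms) {
    extra <- if (!is.null(tm$tau)) paste0(" (tau = ", tm$tau, ")")
             else if (!is.null(tm$attribute)) paste0(" (", tm$attribute, ")")
             else ""
    cat("  -", tm$name, extra, "\n")
  }
})

.modelLabel <- function(model) paste(termNames(model), collapse = "+")

# --- internal encodings handed to the compiled core ---

.termKinds <- function(model)
  unname(.TERM_KINDS[vapply(model@terms, `[[`, character(1), "kind")])

.termTaus <- function(model)
  vapply(model@terms, function(tm) tm$tau %||% 0, numeric(1))

# n x p matrix of integer attribute codes; only nodematch columns are used
.termAttrMatrix <- function(model, net = NULL, nNodes = NULL,
                            nodeData = NULL) {
  if (!is.null(net)) {
    nNodes <- nNodes(net)
    nodeData <- nodeData(net)
  }
  p <- nTerms(model)
  A <- matrix(0L, nNodes, p)
  for (t in seq_len(p)) {
    tm <- model@terms[[t]]
    if (tm$kind == "nodematch") {
      if (is.null(nodeData) || !tm$attribute %in% colnames(nodeData))
        stop("nodematch term needs node attribute '", tm$attribute,
             "' but it is missing")
      val <- as.character(nodeData[[tm$attribute]])
      if (length(val) != nNodes || anyNA(val))
        stop("node attribute '", tm$attribute, "' must label every node")
      A[, t] <- as.integer(factor(val))
    }
  }
  A
}

# Serialize / deserialize a model as plain lists (for JSON/YAML configs)
.modelToList <- function(model) {
  lapply(model@terms, function(tm)
    Filter(Negate(is.null),
           list(kind = tm$kind, tau = tm$tau, attribute = tm$attribute)))
}

.modelFromList <- function(x) {
  clean <- function(v)
    if (is.null(v) || length(v) != 1L || is.na(v)) NULL else v
  new("ErgmModel", terms = unname(lapply(x, function(tm) {
    tm <- as.list(tm)
    ergmTerm(tm$kind, tau = clean(tm$tau), attribute = clean(tm$attribute))
  })))
}
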