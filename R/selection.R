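# The three model-selection procedures: backward p-value elimination, AIC
# over the subset lattice, and graphical GOF over the same lattice. The edges
# term is forced into every candidate (dropping it leaves the density
# unidentified, and every credible model of a thresholded network keeps it).

.subsetModels <- function(candidates) {
  p <- length(candidates)
  if (p > 12L) stop("at most 12 candidate terms are supported")
  idx <- 0:(2^p - 1)
  lapply(idx, function(mask) {
    keep <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    do.call(ergmModel, c(list(ergmTerm("edges")), candidates[keep]))
  })
}

.asTerms <- function(candidates) {
  lapply(candidates, function(x) if (is.character(x)) ergmTerm(x) else x)
}

#' Backward selection by Wald p-values
#'
#' Starting from the full model, iteratively refits and drops the term with
#' the largest Wald p-value above \code{alpha} (the edges term is never
#' dropped), stopping when all remaining terms are significant. If a refit
#' fails the previous model is kept and the procedure stops.
#'
#' @param net a \code{BrainNetwork}.
#' @param fullModel the full \code{ErgmModel} (must contain an edges term).
#' @param alpha significance level (default 0.05).
#' @param fitter function \code{(net, model) -> ErgmFit}; default MCMC MLE
#'   with default control.
#' @return a \code{\link[=SelectionResult-class]{SelectionResult}}; the
#'   trail records one row per fit performed.
#' @export
backwardPValueSelect <- function(net, fullModel, alpha = 0.05,
                                 fitter = mcmcFitter()) {
  model <- fullModel
  fit <- fitter(net, model)
  trail <- data.frame(model = .modelLabel(model),
                      criterion = "max_p_droppable",
                      value = NA_real_, stringsAsFactors = FALSE)
  repeat {
    pv <- suppressWarnings(waldPvalues(fit))
    kinds <- vapply(model@terms, `[[`, character(1), "kind")
    droppable <- which(kinds != "edges")
    trail$value[nrow(trail)] <-
      if (length(droppable)) max(pv[droppable]) else NA_real_
    if (length(droppable) == 0L) break
    worst <- droppable[which.max(pv[droppable])]
    if (is.na(pv[worst]) || pv[worst] <= alpha) break
    reduced <- new("ErgmModel", terms = model@terms[-worst])
    newFit <- tryCatch(fitter(net, reduced), error = function(e) NULL)
    if (is.null(newFit)) break
    model <- reduced
    fit <- newFit
    trail <- rbind(trail, data.frame(model = .modelLabel(model),
                                     criterion = "max_p_droppable",
                                     value = NA_real_))
  }
  new("SelectionResult", model = model, fit = fit, trail = trail,
      method = "p_value", details = list(alpha = alpha))
}

#' Model selection by AIC over the subset lattice
#'
#' Fits every subset of the candidate terms (edges always included) and
#' returns the minimum-AIC model. AIC values must be on a common absolute
#' log-likelihood scale, which the MCMC MLE provides via its bridge estimate
#' of the normalizing constant. Failed fits are recorded with infinite AIC.
#'
#' @param net a \code{BrainNetwork}.
#' @param candidates list of candidate \code{\link{ergmTerm}}s (or kind
#'   names) beyond edges; at most 12.
#' @param fitter function \code{(net, model) -> ErgmFit}.
#' @return a \code{\link[=SelectionResult-class]{SelectionResult}} with one
#'   trail row per subset.
#' @export
aicSelect <- function(net, candidates, fitter = mcmcFitter()) {
  models <- .subsetModels(.asTerms(candidates))
  fits <- vector("list", length(models))
  aics <- rep(Inf, length(models))
  for (k in seq_along(models)) {
    fits[[k]] <- tryCatch(fitter(net, models[[k]]), error = function(e) NULL)
    if (!is.null(fits[[k]]) && is.finite(fits[[k]]@aic))
      aics[k] <- fits[[k]]@aic
  }
  if (all(!is.finite(aics))) stop("every candidate fit failed")
  best <- which.min(aics)
  trail <- data.frame(model = vapply(models, .modelLabel, character(1)),
                      criterion = "aic", value = aics,
                      stringsAsFactors = FALSE)
  new("SelectionResult", model = models[[best]], fit = fits[[best]],
      trail = trail, method = "aic", details = list())
}

#' Model selection by graphical goodness of fit
#'
#' Over the same subset lattice as \code{\link{aicSelect}}, each candidate is
#' fitted, \code{nSim} networks are simulated from the fit, and the
#' \code{\link{gofScore}} summarizing the four comparison distributions is
#' computed; the minimum-score model is returned. This quantifies the visual
#' judgment of the boxplot GOF comparison; the full reports are retained in
#' \code{details$reports}.
#'
#' @param net a \code{BrainNetwork}.
#' @param candidates list of candidate terms beyond edges; at most 12.
#' @param fitter function \code{(net, model) -> ErgmFit}.
#' @param nSim simulated networks per candidate (default 100).
#' @param seed integer seed for the GOF simulations.
#' @return a \code{\link[=SelectionResult-class]{SelectionResult}}.
#' @export
graphicalSelect <- function(net, candidates, fitter = mcmcFitter(),
                            nSim = 100L, seed = 1L) {
  models <- .subsetModels(.asTerms(candidates))
  fits <- vector("list", length(models))
  reports <- vector("list", length(models))
  scores <- rep(Inf, length(models))
  for (k in seq_along(models)) {
    fits[[k]] <- tryCatch(fitter(net, models[[k]]), error = function(e) NULL)
    if (is.null(fits[[k]]) || !isTRUE(fits[[k]]@converged)) next
    reports[[k]] <- gofSimulate(net, fits[[k]], nSim = nSim,
                                seed = seed + k)
    scores[k] <- gofScore(reports[[k]])
  }
  if (all(!is.finite(scores))) stop("every candidate fit failed")
  best <- which.min(scores)
  trail <- data.frame(model = vapply(models, .modelLabel, character(1)),
                      criterion = "gof_score", value = scores,
                      stringsAsFactors = FALSE)
  new("SelectionResult", model = models[[best]], fit = fits[[best]],
      trail = trail, method = "graphical",
      details = list(reports = reports, nSim = nSim, seed = seed))
}

#' Run all three selection procedures side by side
#'
#' The procedures can disagree; this harness records all three results for
#' one network so disparate final models are visible next to each other.
#'
#' @param net a \code{BrainNetwork}.
#' @param candidates candidate terms beyond edges.
#' @param fitter function \code{(net, model) -> ErgmFit}.
#' @param alpha backward-selection significance level.
#' @param nSim GOF simulations per candidate.
#' @param seed integer seed.
#' @return named list of three \code{SelectionResult}s (\code{p_value},
#'   \code{aic}, \code{graphical}) plus \code{chosen}, the character vector
#'   of the three chosen model labels.
#' @export
selectionHarness <- function(net, candidates, fitter = mcmcFitter(),
                             alpha = 0.05, nSim = 100L, seed = 1L) {
  candidates <- .asTerms(candidates)
  full <- do.call(ergmModel, c(list(ergmTerm("edges")), candidates))
  res <- list(
    p_value = backwardPValueSelect(net, full, alpha = alpha, fitter = fitter),
    aic = aicSelect(net, candidates, fitter = fitter),
    graphical = graphicalSelect(net, candidates, fitter = fitter,
                                nSim = nSim, seed = seed)
  )
  res$chosen <- vapply(res[1:3], function(r) .modelLabel(r@model),
                       character(1))
  res
}

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult (", object@method, "): chosen model ",
      .modelLabel(object@model), "\n", sep = "")
  print(object@trail)
})
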