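#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates the stages end to end: network construction from correlation
#' matrices (or reading prebuilt edge lists), per-subject model fitting,
#' optional three-way model selection, goodness-of-fit simulation,
#' descriptive metrics, and an optional two-group parameter comparison.
#' Every artifact is written under \code{output_dir} together with a
#' manifest echoing the configuration and seed, so a rerun with the same
#' configuration reproduces the same files.
#'
#' @param config path to a YAML file or an equivalent named list. Recognized
#'   fields: \code{seed}; \code{output_dir}; \code{s} (threshold exponent);
#'   \code{absolute} (rank by absolute correlation); \code{model} (list of
#'   term entries \code{kind}/\code{tau}/\code{attribute}); \code{fitter}
#'   (\code{method} \code{"mcmc"}, \code{"mple"} or \code{"exact"} plus
#'   \code{\link{ergmControl}} fields); \code{gof_nsim}; \code{alpha};
#'   \code{candidates} (term entries; enables the selection stage);
#'   \code{inputs} with either \code{correlation_matrices} or
#'   \code{edge_lists} (paths), optional \code{attributes} (TSV path) and
#'   optional \code{groups} (named list of two subject-index vectors).
#' @return invisibly, a list with the per-subject networks, fits, selection
#'   results, GOF reports, metric table and comparison table.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  outDir <- config$output_dir %||% "pipeline_out"
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  model <- if (!is.null(config$model)) .modelFromList(config$model)
           else bestAssessmentModel()
  fitter <- .configFitter(config$fitter, seed)

  # --- construct / read networks -------------------------------------
  ins <- config$inputs %||% list()
  attrTable <- if (!is.null(ins$attributes))
    readNodeAttributes(ins$attributes)
  loadNet <- function(path) {
    net <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
      thresholdByS(readCorrelationMatrix(path),
                   s = config$s %||% 2.5,
                   absolute = isTRUE(config$absolute))
    } else {
      readEdgeList(path)
    }
    if (!is.null(attrTable)) {
      idx <- match(nodeLabels(net), rownames(attrTable))
      if (anyNA(idx)) stop("attribute table is missing nodes for ", path)
      net <- brainNetwork(nNodes(net), edgeMatrix(net), nodeLabels(net),
                          attrTable[idx, , drop = FALSE])
    }
    net
  }
  paths <- ins$correlation_matrices %||% ins$edge_lists
  if (is.null(paths)) stop("config$inputs must list networks or matrices")
  nets <- lapply(paths, loadNet)
  names(nets) <- paste0("s", seq_along(nets))

  .checkModelInputs(model, nets[[1]])

  # --- fit -----------------------------------------------------------
  fits <- lapply(seq_along(nets), function(k) {
    fit <- fitter(nets[[k]], model)
    writeFitResult(fit, file.path(outDir, paste0("fit_", names(nets)[k],
                                                 ".json")))
    fit
  })
  names(fits) <- names(nets)

  # --- selection (optional) -----------------------------------------
  selections <- NULL
  if (!is.null(config$candidates)) {
    cand <- .modelFromList(config$candidates)@terms
    selections <- lapply(seq_along(nets), function(k) {
      h <- selectionHarness(nets[[k]], cand, fitter = fitter,
                            alpha = config$alpha %||% 0.05,
                            nSim = config$gof_nsim %||% 100L,
                            seed = seed + k)
      utils::write.table(
        do.call(rbind, lapply(c("p_value", "aic", "graphical"), function(m)
          cbind(method = m, h[[m]]@trail))),
        file.path(outDir, paste0("selection_", names(nets)[k], ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
      h
    })
    names(selections) <- names(nets)
  }

  # --- GOF + metrics -------------------------------------------------
  gofs <- lapply(seq_along(nets), function(k) {
    rep <- gofSimulate(nets[[k]], fits[[k]],
                       nSim = config$gof_nsim %||% 100L, seed = seed + k)
    utils::write.table(gofTable(rep),
                       file.path(outDir, paste0("gof_", names(nets)[k],
                                                ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    rep
  })
  metricTab <- do.call(rbind, lapply(seq_along(nets), function(k) {
    m <- descriptiveMetrics(nets[[k]])
    data.frame(subject = names(nets)[k], C = m$C, L = m$L, Eloc = m$Eloc,
               Eglob = m$Eglob, K = m$K)
  }))
  utils::write.table(metricTab, file.path(outDir, "metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # --- group comparison (optional) ----------------------------------
  comparison <- NULL
  if (!is.null(ins$groups)) {
    gidx <- ins$groups
    if (length(gidx) != 2L) stop("groups must name exactly two cohorts")
    ca <- cohortFits(fits[unlist(gidx[[1]])])
    cb <- cohortFits(fits[unlist(gidx[[2]])])
    comparison <- lapply(termNames(model), function(tm)
      c(term = tm, compareTerm(ca, cb, tm)))
    jsonlite::write_json(comparison, file.path(outDir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(config = config, seed = seed,
                   subjects = names(nets),
                   model = .modelToList(model))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(networks = nets, fits = fits, selections = selections,
                 gof = gofs, metrics = metricTab, comparison = comparison))
}

.configFitter <- function(fcfg, seed) {
  method <- fcfg$method %||% "mcmc"
  switch(method,
    mple = function(net, model) mple(net, model),
    exact = exactFitter(enumLimit = fcfg$enumLimit %||% 7L),
    mcmc = mcmcFitter(ergmControl(
      sampleSize = fcfg$sampleSize %||% 1000,
      burnin = fcfg$burnin,
      thin = fcfg$thin,
      maxIter = fcfg$maxIter %||% 20,
      tol = fcfg$tol %||% 1e-3,
      bridgeSteps = fcfg$bridgeSteps %||% 10,
      bridgeSampleSize = fcfg$bridgeSampleSize %||% 200,
      seed = fcfg$seed %||% seed)),
    stop("unknown fitter method '", method, "'"))
}

# fail early, by name, when a nodematch term lacks its attribute
.checkModelInputs <- function(model, net) {
  for (tm in model@terms)
    if (tm$kind == "nodematch" &&
        !tm$attribute %in% colnames(nodeData(net)))
      stop("model term nodematch needs node attribute '", tm$attribute,
           "' which is missing from the input networks")
  invisible(TRUE)
}
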