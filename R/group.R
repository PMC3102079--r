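#' Bundle per-subject fits sharing one model
#'
#' Group comparisons of parameter profiles require every subject to be
#' fitted with the same term list (and networks of the same size), since the
#' metrics depend on each other and on n.
#'
#' @param fits list of converged \code{ErgmFit}s with identical term lists.
#' @param subjects optional character vector of subject ids.
#' @return a \code{\link[=CohortFits-class]{CohortFits}}.
#' @export
cohortFits <- function(fits, subjects = NULL) {
  if (is.null(subjects)) subjects <- paste0("s", seq_along(fits))
  new("CohortFits", fits = fits, subjects = as.character(subjects))
}

#' Matrix of per-subject estimates
#'
#' @param cohort a \code{CohortFits}.
#' @return numeric matrix, one row per subject, one column per term.
#' @export
thetaMatrix <- function(cohort) {
  m <- do.call(rbind, lapply(cohort@fits, coef))
  rownames(m) <- cohort@subjects
  m
}

setMethod("show", "CohortFits", function(object) {
  cat("CohortFits:", length(object@fits), "subjects, model",
      .modelLabel(object@fits[[1]]@model), "\n")
  print(colMeans(thetaMatrix(object)))
})

#' Compare one parameter between two cohorts
#'
#' Welch two-sample t-test (Satterthwaite degrees of freedom) on the
#' per-subject estimates of the named term, treating the estimates as data.
#' The estimates' own standard errors are not propagated into the
#' between-subject comparison; with few subjects per group the
#' unequal-variance test is the safer default.
#'
#' @param a,b \code{CohortFits} with at least two subjects each, sharing the
#'   same model.
#' @param term term name (as in \code{termNames} of the shared model).
#' @return list with \code{mean_a}, \code{se_a}, \code{mean_b}, \code{se_b}
#'   (sample means and standard errors of the estimates), \code{t},
#'   \code{df} and \code{p}.
#' @export
compareTerm <- function(a, b, term) {
  xa <- thetaMatrix(a)
  xb <- thetaMatrix(b)
  if (!term %in% colnames(xa) || !term %in% colnames(xb))
    stop("term '", term, "' is not in the cohort model")
  if (nrow(xa) < 2L || nrow(xb) < 2L)
    stop("need at least two subjects per cohort")
  va <- xa[, term]
  vb <- xb[, term]
  if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
    # identical within-group values: zero variance, define t = 0 when the
    # means agree rather than erroring
    if (mean(va) == mean(vb)) {
      tt <- list(statistic = c(t = 0), parameter = c(df = NA_real_),
                 p.value = 1)
    } else {
      tt <- list(statistic = c(t = Inf * sign(mean(va) - mean(vb))),
                 parameter = c(df = NA_real_), p.value = 0)
    }
  } else {
    tt <- stats::t.test(va, vb, var.equal = FALSE)
  }
  list(mean_a = mean(va), se_a = stats::sd(va) / sqrt(length(va)),
       mean_b = mean(vb), se_b = stats::sd(vb) / sqrt(length(vb)),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Average parameter profile of a cohort
#'
#' Elementwise mean of the per-subject estimates: the profile from which
#' representative group networks can be simulated with
#' \code{\link{simulateNetworks}}.
#'
#' @param cohort a \code{CohortFits}.
#' @return named numeric vector.
#' @export
averageProfile <- function(cohort) {
  colMeans(thetaMatrix(cohort))
}
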