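.newFit <- function(model, theta, se, cov, loglik, aic, method, converged,
                    diagnostics = list()) {
  nm <- termNames(model)
  names(theta) <- nm
  names(se) <- nm
  dimnames(cov) <- list(nm, nm)
  new("ErgmFit", theta = theta, se = se, cov = cov,
      loglik = as.numeric(loglik), aic = as.numeric(aic), method = method,
      converged = converged, model = model, diagnostics = diagnostics)
}

#' Accessors for fitted ERGMs
#'
#' @param object,fit an \code{ErgmFit}.
#' @return \code{coef} returns the named estimate vector; \code{stdErrors}
#'   the standard errors; \code{vcov} the covariance matrix; \code{logLik}
#'   the log-likelihood and \code{AIC} the information criterion.
#' @export
setMethod("coef", "ErgmFit", function(object) object@theta)

#' @rdname coef-ErgmFit-method
#' @export
stdErrors <- function(fit) fit@se

#' @rdname coef-ErgmFit-method
#' @export
setMethod("vcov", "ErgmFit", function(object) object@cov)

#' @rdname coef-ErgmFit-method
#' @export
setMethod("logLik", "ErgmFit", function(object) object@loglik)

#' @rdname coef-ErgmFit-method
#' @export
isConverged <- function(fit) fit@converged

#' Two-sided Wald p-values for each model term
#'
#' The estimates are approximate MLEs and asymptotically Gaussian, so
#' \code{p_k = 2 (1 - Phi(|theta_k / se_k|))}.
#'
#' @param fit an \code{ErgmFit} with positive standard errors.
#' @return named numeric vector of p-values (NA, with a warning, for any
#'   zero standard error).
#' @export
waldPvalues <- function(fit) {
  se <- fit@se
  p <- 2 * stats::pnorm(-abs(fit@theta / se))
  if (any(se <= 0, na.rm = TRUE)) {
    warning("zero standard error: p-value undefined for ",
            paste(names(se)[se <= 0], collapse = ", "))
    p[se <= 0] <- NA_real_
  }
  p
}

#' Akaike information criterion
#'
#' @param loglik absolute log-likelihood at the MLE.
#' @param p number of model terms (>= 1).
#' @return \code{2 p - 2 loglik}.
#' @export
aicOf <- function(loglik, p) {
  if (p < 1) stop("p must be >= 1")
  2 * p - 2 * loglik
}

setMethod("show", "ErgmFit", function(object) {
  cat("ErgmFit (", object@method, ", ",
      if (object@converged) "converged" else "NOT converged", ")\n", sep = "")
  pv <- suppressWarnings(waldPvalues(object))
  tab <- data.frame(estimate = object@theta, se = object@se,
                    p.value = pv, row.names = names(object@theta))
  print(format(tab, digits = 4))
  if (is.finite(object@aic)) cat("AIC:", format(object@aic, digits = 6), "\n")
})

#' Write / read a fitted ERGM as JSON
#'
#' @param fit an \code{ErgmFit}.
#' @param file path to a JSON file.
#' @return \code{readFitResult} returns the \code{ErgmFit}.
#' @export
writeFitResult <- function(fit, file) {
  x <- list(
    terms = .modelToList(fit@model),
    term_names = names(fit@theta),
    theta = unname(fit@theta),
    se = unname(fit@se),
    cov = fit@cov,
    loglik = fit@loglik,
    aic = fit@aic,
    p_values = unname(suppressWarnings(waldPvalues(fit))),
    method = fit@method,
    converged = fit@converged,
    diagnostics = fit@diagnostics
  )
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(file)
}

#' @rdname writeFitResult
#' @export
readFitResult <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  model <- .modelFromList(
    if (is.data.frame(x$terms)) split(x$terms, seq_len(nrow(x$terms)))
    else x$terms)
  .newFit(model, as.numeric(x$theta), as.numeric(x$se),
          matrix(as.numeric(x$cov), length(x$theta)),
          x$loglik %||% NA_real_, x$aic %||% NA_real_, x$method,
          isTRUE(x$converged), as.list(x$diagnostics))
}
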