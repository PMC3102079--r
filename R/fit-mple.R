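#' Maximum pseudo-likelihood estimation
#'
#' Logistic regression of the dyad indicators \code{y_ij} on the change
#' statistics over all \code{C(n,2)} dyads, without intercept: the MPLE.
#' For dyad-independent models (e.g. edges + nodematch) the pseudo-likelihood
#' coincides with the true likelihood, so the MPLE equals the MLE; for
#' dyad-dependent terms it is the standard fast approximation used to seed
#' MCMC maximum likelihood. Standard errors come from the usual logistic
#' information matrix (they understate uncertainty under dyad dependence).
#'
#' @param net a \code{BrainNetwork}.
#' @param model an \code{ErgmModel}.
#' @return an \code{\link[=ErgmFit-class]{ErgmFit}} with
#'   \code{method = "mple"}. \code{loglik}/\code{aic} are NA; the maximized
#'   pseudo-log-likelihood is reported in
#'   \code{diagnostics$pseudo_loglik}.
#' @examples
#' net <- brainNetwork(6, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6)))
#' coef(mple(net, ergmModel("edges")))  # logit of density, exactly
#' @export
mple <- function(net, model) {
  validObject(model)
  A <- .termAttrMatrix(model, net)
  d <- cpp_change_stat_matrix(nNodes(net), edgeMatrix(net),
                              .termKinds(model), .termTaus(model), A)
  X <- d$X
  colnames(X) <- termNames(model)
  y <- d$y
  if (qr(X)$rank < ncol(X))
    stop("MPLE design matrix is rank deficient; drop redundant terms")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(), intercept = FALSE))
  theta <- fit$coefficients
  if (!fit$converged || any(!is.finite(theta)) || any(abs(theta) > 12))
    stop("MPLE did not converge (separation: an observed statistic is at ",
         "its extreme, e.g. an empty or complete graph)")
  # information matrix of the logistic regression
  w <- fit$weights
  info <- crossprod(X * sqrt(w))
  covTheta <- solve(info)
  mu <- fit$fitted.values
  pll <- sum(y * log(mu) + (1 - y) * log1p(-mu))
  .newFit(model, theta, sqrt(diag(covTheta)), covTheta,
          NA_real_, NA_real_, "mple", TRUE,
          diagnostics = list(pseudo_loglik = pll, loglik_type = "pseudo",
                             n_dyads = length(y)))
}
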