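#' Linear projection models for two-class metabolite panels
#'
#' All four projection-based classifiers (best-univariate, first principal
#' component, Fisher discriminant, logistic regression) share one model
#' object: a variable subset, one weight per subset variable, an intercept
#' (zero except for logistic regression), and the standardization fitted on
#' the training cohort. A sample's score is
#' \code{intercept + sum(weights * standardized values)}, and the sign
#' convention is always resolved at fit time so that the mean ASD score is
#' at least the mean TD score ("ASD high").
#'
#' @name projection_model
NULL

new_projection_model <- function(method, subset, weights, intercept,
                                 standardization, flipped = FALSE,
                                 converged = TRUE, extra = list()) {
  if (length(weights) != length(subset)) {
    stop("weights length must equal subset length")
  }
  if (all(weights == 0)) stop("projection model must have a nonzero weight")
  structure(list(method = method, subset = subset,
                 weights = stats::setNames(as.numeric(weights), subset),
                 intercept = as.numeric(intercept),
                 standardization = standardization,
                 flipped = flipped, converged = converged, extra = extra),
            class = "projection_model")
}

#' @export
print.projection_model <- function(x, ...) {
  cat(sprintf("projection_model [%s] on %d variable(s): %s\n", x$method,
              length(x$subset), paste(x$subset, collapse = ", ")))
  cat("weights:", paste(sprintf("%s=%.4g", x$subset, x$weights),
                        collapse = ", "), "\n")
  if (x$intercept != 0) cat("intercept:", format(x$intercept), "\n")
  if (!x$converged) cat("NOTE: fit did not converge\n")
  invisible(x)
}

# Standardized training submatrix + labels for a fit; shared preamble of all
# fitting routines.
prepare_fit <- function(panel, subset, require_labels = TRUE) {
  sub <- subset_panel(panel, variables = subset)
  if (require_labels && !all(c("ASD", "TD") %in% sub$labels)) {
    stop("fitting requires both ASD and TD samples")
  }
  std <- fit_standardization(sub)
  z <- apply_standardization(sub, std)
  list(z = z$values, labels = sub$labels, std = std)
}

# Flip weights/intercept if mean ASD score < mean TD score; ties keep +.
orient_asd_high <- function(weights, intercept, z, labels) {
  s <- drop(z %*% weights) + intercept
  flip <- mean(s[labels == "ASD"]) < mean(s[labels == "TD"])
  if (flip) {
    weights <- -weights
    intercept <- -intercept
  }
  list(weights = weights, intercept = intercept, flipped = flip)
}

#' Univariate classifier direction
#'
#' The simplest classifier: a single mean-centered, unit-variance variable,
#' with weight +1 or -1 so the ASD class scores high. Ties in class means
#' break to +1.
#'
#' @param panel A labeled \code{metabolite_panel}.
#' @param variable A single variable id present in the panel.
#' @return A \code{projection_model} with method \code{"UNIVARIATE"}.
#' @export
fit_univariate <- function(panel, variable) {
  stopifnot(length(variable) == 1)
  fit <- prepare_fit(panel, variable)
  o <- orient_asd_high(1, 0, fit$z, fit$labels)
  new_projection_model("UNIVARIATE", variable, o$weights, 0, fit$std,
                       flipped = o$flipped)
}

#' First-principal-component direction
#'
#' PCA is applied to the standardized panel with class membership ignored
#' (equivalently, PCA of the correlation matrix); only the first component is
#' retained. The unit-norm loading vector is then sign-oriented using the
#' labels so the ASD class scores high. With tied leading eigenvalues the
#' eigenvector reported by the symmetric eigensolver is made deterministic by
#' orienting it positive on its largest-magnitude loading of lowest variable
#' index before the label-based orientation.
#'
#' @param panel A labeled \code{metabolite_panel} with >= 3 samples.
#' @param subset Variable ids to use; defaults to all.
#' @return A \code{projection_model} with method \code{"PCA"}; the share of
#'   total variance on the first component is stored in
#'   \code{extra$variance_explained}.
#' @export
fit_pca_direction <- function(panel, subset = panel_variables(panel)) {
  if (n_samples(panel) < 3) stop("PCA requires at least 3 samples")
  fit <- prepare_fit(panel, subset)
  cm <- stats::cor(fit$z)
  if (!all(is.finite(cm))) stop("rank-deficient data: correlation undefined")
  eg <- eigen(cm, symmetric = TRUE)
  w <- eg$vectors[, 1]
  # deterministic sign before labels enter: positive on the dominant loading
  # with lowest index
  lead <- which(abs(w) == max(abs(w)))[1]
  if (w[lead] < 0) w <- -w
  o <- orient_asd_high(w, 0, fit$z, fit$labels)
  new_projection_model("PCA", subset, o$weights, 0, fit$std,
                       flipped = o$flipped,
                       extra = list(variance_explained =
                                      eg$values[1] / sum(eg$values)))
}

#' Fisher discriminant direction
#'
#' Maximizes the ratio of between-class to within-class scatter of the two
#' classes. For two classes the solution is the closed form
#' \eqn{w \propto S_w^{-1}(\bar x_{ASD} - \bar x_{TD})} on the standardized
#' variables, where \eqn{S_w} is the pooled within-class scatter matrix. A
#' ridge \eqn{\lambda I} with \eqn{\lambda = 10^{-6}\,\mathrm{tr}(S_w)/p} is
#' always added: subsets up to all 22 variables are fitted on cohorts of
#' under 200 children, where the raw scatter can be near-singular.
#'
#' @param panel A labeled \code{metabolite_panel} with >= 2 samples per class.
#' @param subset Variable ids to use; defaults to all.
#' @return A unit-norm, ASD-high \code{projection_model} with method
#'   \code{"FDA"}.
#' @export
fit_fda_direction <- function(panel, subset = panel_variables(panel)) {
  fit <- prepare_fit(panel, subset)
  z <- fit$z
  asd <- z[fit$labels == "ASD", , drop = FALSE]
  td <- z[fit$labels == "TD", , drop = FALSE]
  if (nrow(asd) < 2 || nrow(td) < 2) {
    stop("FDA requires at least 2 samples per class")
  }
  dmu <- colMeans(asd) - colMeans(td)
  sw <- crossprod(sweep(asd, 2, colMeans(asd))) +
    crossprod(sweep(td, 2, colMeans(td)))
  p <- ncol(z)
  lambda <- 1e-6 * sum(diag(sw)) / p
  sw_reg <- sw + diag(lambda, p)
  w <- tryCatch(solve(sw_reg, dmu), error = function(e) {
    stop(sprintf("within-class scatter singular after regularization (condition number %.3g)",
                 kappa(sw_reg)))
  })
  w <- w / sqrt(sum(w^2))
  o <- orient_asd_high(w, 0, z, fit$labels)
  new_projection_model("FDA", subset, o$weights, 0, fit$std,
                       flipped = o$flipped)
}

#' Logistic regression by penalized IRLS
#'
#' Models the log odds of ASD membership as a linear function of the
#' standardized variables, \eqn{L(x) = w_0 + w^T x}, and estimates
#' \eqn{(w_0, w)} by maximizing the Bernoulli log likelihood with an optional
#' ridge penalty on the slopes (intercept unpenalized) via iteratively
#' reweighted least squares. The small default ridge keeps the estimates
#' finite when the classes are linearly separable, where unpenalized maximum
#' likelihood diverges. Convergence is declared when every component of the
#' penalized score gradient is below \code{1e-8}; hitting the 100-iteration
#' cap flags the model as non-converged rather than failing.
#'
#' @param panel A labeled \code{metabolite_panel}.
#' @param subset Variable ids to use; defaults to all.
#' @param ridge Nonnegative ridge penalty on the slopes; default \code{1e-4}.
#' @return A \code{projection_model} with method \code{"LR"}; scores are the
#'   fitted log odds of ASD.
#' @export
fit_logistic <- function(panel, subset = panel_variables(panel),
                         ridge = 1e-4) {
  stopifnot(ridge >= 0)
  fit <- prepare_fit(panel, subset)
  z <- fit$z
  y <- as.numeric(fit$labels == "ASD")
  X <- cbind(1, z)
  p <- ncol(z)
  pen <- diag(c(0, rep(ridge, p)))  # intercept unpenalized
  beta <- rep(0, p + 1)
  converged <- FALSE
  for (iter in seq_len(100)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - mu) - pen %*% beta)
    if (max(abs(grad)) < 1e-8) {
      converged <- TRUE
      break
    }
    wts <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * wts, X) + pen
    step <- drop(solve(H, grad))
    # step-halving on the penalized log likelihood
    ll0 <- lr_penalized_ll(X, y, beta, pen)
    for (half in 0:20) {
      cand <- beta + step / 2^half
      if (lr_penalized_ll(X, y, cand, pen) >= ll0 - 1e-12) break
    }
    beta <- cand
  }
  # complete separation with no ridge: the MLE sits at infinity and the
  # gradient only vanishes through floating-point saturation of the
  # fitted probabilities — report that as non-convergence
  if (ridge == 0) {
    eta <- drop(X %*% beta)
    if (all(y == (eta > 0)) && max(abs(eta)) > 20) converged <- FALSE
  }
  o <- orient_asd_high(beta[-1], beta[1], z, fit$labels)
  new_projection_model("LR", subset, o$weights, o$intercept, fit$std,
                       flipped = o$flipped, converged = converged)
}

lr_penalized_ll <- function(X, y, beta, pen) {
  eta <- drop(X %*% beta)
  # log(1 + e^eta) computed stably
  sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta)))) -
    drop(beta %*% pen %*% beta) / 2
}

#' Score a panel with a projection model
#'
#' Applies the model's training-cohort standardization (never refit) and
#' returns \code{intercept + z %*% weights} per sample.
#'
#' @param panel A \code{metabolite_panel} containing all model variables.
#' @param model A \code{projection_model}.
#' @return Named numeric vector of scores, one per sample.
#' @export
project <- function(panel, model) {
  sub <- subset_panel(panel, variables = model$subset)
  z <- apply_standardization(sub, model$standardization)
  stats::setNames(drop(z$values %*% model$weights) + model$intercept,
                  rownames(panel$values))
}

#' TD-membership probability from logistic-regression scores
#'
#' For an ASD-high logistic model the score is the log odds of ASD, so
#' \eqn{p(TD \mid x) = 1/(1 + e^{score})}, computed with a numerically
#' stable sigmoid. This is the one classifier whose class membership comes
#' straight from the model, with no kernel density step.
#'
#' @param scores Scores from a method-\code{LR} projection model.
#' @return Vector of TD-membership probabilities; \code{p(ASD) = 1 - p(TD)}
#'   exactly.
#' @export
lr_membership <- function(scores) {
  stats::plogis(-scores)
}
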