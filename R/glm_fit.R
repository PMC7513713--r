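#' Small-sample corrected Akaike information criterion
#'
#' \eqn{AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)}, where `k` counts every
#' estimated parameter: intercept, slopes, and the random-intercept variance
#' when one is fitted.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @return the AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) .fail("AICc undefined: n (%d) must exceed k + 1 (%d)", n, k + 1)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit one breeding-success or offspring-count model
#'
#' Fits a generalized linear (mixed) model of the kinds used throughout the
#' analysis:
#' \describe{
#'   \item{`binomial`}{bred (0/1) with a logit link.}
#'   \item{`poisson`}{offspring count with a log link (males; counts are
#'     not biologically capped).}
#'   \item{`binomial_out_of_4`}{offspring count as successes out of 4 with a
#'     logit link (females, whose litters are capped at 4).}
#' }
#' Fixed-effects models use [stats::glm()] (iteratively reweighted least
#' squares); a single random intercept is fitted with [lme4::glmer()] by
#' adaptive Gauss--Hermite quadrature (`nAGQ` nodes, default 15), falling
#' back to the Laplace approximation (`nAGQ = 1`) with a message if the
#' quadrature fit fails.
#'
#' @param data model frame; must contain the response column (`bred` or
#'   `n_offspring`), the predictors, and the grouping column if `random` is
#'   given.
#' @param family `"binomial"`, `"poisson"` or `"binomial_out_of_4"`.
#' @param predictors character vector of predictor column names (possibly
#'   empty for an intercept-only model).
#' @param random optional name of a grouping column for a random intercept.
#' @param nAGQ quadrature nodes for the mixed fit.
#' @return an object of class `breeding_fit`: coefficients and standard
#'   errors, `loglik`, `k`, `n`, `aicc`, `ranef_var`, and the underlying
#'   fitted model (`fit`).
#' @export
fit_breeding_glm <- function(data, family = c("binomial", "poisson", "binomial_out_of_4"),
                             predictors = character(0), random = NULL, nAGQ = 15) {
  family <- match.arg(family)
  lhs <- switch(family,
                binomial = "bred",
                poisson = "n_offspring",
                binomial_out_of_4 = "cbind(n_offspring, 4L - n_offspring)")
  if (family == "binomial_out_of_4" && any(data$n_offspring > 4L))
    .fail("binomial_out_of_4: offspring counts exceed 4")
  glm_family <- if (family == "poisson") stats::poisson() else stats::binomial()
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  used <- c(intersect(c("bred", "n_offspring"), colnames(data)), predictors, random)
  cc <- stats::complete.cases(data[, used, drop = FALSE])
  data <- data[cc, , drop = FALSE]
  n <- nrow(data)

  if (is.null(random)) {
    fml <- stats::as.formula(paste(lhs, "~", rhs))
    fit <- stats::glm(fml, family = glm_family, data = data)
    if (!fit$converged) .fail("glm did not converge (%d iterations)", fit$iter)
    est <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    ll <- as.numeric(stats::logLik(fit))
    k <- length(est)
    rv <- NA_real_
  } else {
    fml <- stats::as.formula(paste(lhs, "~", rhs, "+ (1 |", random, ")"))
    fit <- tryCatch(
      suppressWarnings(lme4::glmer(fml, family = glm_family, data = data, nAGQ = nAGQ)),
      error = function(e) NULL)
    if (is.null(fit) && nAGQ != 1) {
      message(sprintf("glmer with nAGQ = %d failed; falling back to Laplace (nAGQ = 1)", nAGQ))
      fit <- suppressWarnings(lme4::glmer(fml, family = glm_family, data = data, nAGQ = 1))
    }
    if (is.null(fit)) .fail("mixed model failed to fit")
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    ll <- as.numeric(stats::logLik(fit))
    k <- length(est) + 1L  # + random-intercept variance
    rv <- unname(lme4::VarCorr(fit)[[random]][1L])
  }
  if (any(abs(est) > 15))
    warning("coefficient magnitude > 15 on the standardized scale: possible complete separation",
            call. = FALSE)
  names(se) <- names(est)
  structure(
    list(coefficients = est, se = se, loglik = ll, k = k, n = n,
         aicc = aicc(ll, k, n), ranef_var = rv, family = family,
         predictors = predictors, random = random, fit = fit),
    class = "breeding_fit")
}

#' @export
print.breeding_fit <- function(x, ...) {
  cat(sprintf("Breeding model (%s%s): n = %d, k = %d, logLik = %.3f, AICc = %.3f\n",
              x$family,
              if (is.null(x$random)) "" else paste0(", (1|", x$random, ")"),
              x$n, x$k, x$loglik, x$aicc))
  print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' @export
coef.breeding_fit <- function(object, ...) object$coefficients

#' @export
logLik.breeding_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}
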