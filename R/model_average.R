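#' All-subsets AICc model selection and full model averaging
#'
#' Fits every subset of the global predictor set (including the
#' intercept-only model), ranks the fits by AICc, retains the models within
#' `delta` AICc of the best, renormalizes their Akaike weights, and averages
#' coefficients over the retained set. With `method = "full"` (the default)
#' a predictor absent from a model contributes a coefficient of 0 to the
#' average, shrinking weakly supported effects toward zero;
#' `method = "conditional"` averages only over the models that contain the
#' predictor. Unconditional standard errors follow the model-averaging
#' variance formula
#' \deqn{SE_j = \sqrt{\sum_m w_m \left( var_m(\hat\beta_j) + (\hat\beta_{jm} - \bar\beta_j)^2 \right)}}
#' Two importance summaries are reported per predictor: `ri`, the sum of the
#' renormalized Akaike weights of the top-set models containing it, and
#' `ri_prop`, the unweighted proportion of top-set models containing it.
#' Both equal 1 for a predictor present in every top model.
#'
#' Predictors are 2-SD standardized (see [standardize_2sd()]) before
#' fitting unless `standardize = FALSE`; the standardization constants are
#' stored so [predict.averaged_model()] can accept raw covariate values.
#'
#' @inheritParams fit_breeding_glm
#' @param predictors the global predictor set (at most a handful; all
#'   `2^p` subsets are fitted).
#' @param delta AICc window defining the top model set (default 2).
#' @param method `"full"` (zero substitution) or `"conditional"`.
#' @param standardize 2-SD standardize predictors before fitting.
#' @return an object of class `averaged_model` with elements `table` (the
#'   per-predictor summary), `top_models` (list of `breeding_fit`s),
#'   `weights`, `selection` (AICc ranking of all subsets), `constants`
#'   (standardization constants), `family`, `random`.
#' @export
model_average <- function(data, family = c("binomial", "poisson", "binomial_out_of_4"),
                          predictors, random = NULL, delta = 2,
                          method = c("full", "conditional"),
                          standardize = TRUE, nAGQ = 15) {
  family <- match.arg(family)
  method <- match.arg(method)
  stopifnot(length(predictors) >= 1L)
  if (length(predictors) > 8L) .fail("all-subsets enumeration is limited to 8 predictors")

  constants <- NULL
  if (standardize) {
    constants <- list()
    for (v in predictors) {
      z <- standardize_2sd(data[[v]], name = v)
      constants[[v]] <- c(center = attr(z, "center"), scale = attr(z, "scale"))
      data[[v]] <- as.numeric(z)
    }
  }

  p <- length(predictors)
  subsets <- lapply(seq_len(2^p) - 1L,
                    function(m) predictors[bitwAnd(m, 2^(seq_len(p) - 1L)) > 0L])
  fits <- vector("list", length(subsets))
  failed <- logical(length(subsets))
  for (i in seq_along(subsets)) {
    fits[[i]] <- tryCatch(
      fit_breeding_glm(data, family, subsets[[i]], random, nAGQ),
      error = function(e) {
        warning(sprintf("subset {%s} failed to fit: %s",
                        paste(subsets[[i]], collapse = ", "),
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    failed[i] <- is.null(fits[[i]])
  }
  fits <- fits[!failed]
  subsets <- subsets[!failed]
  if (!length(fits)) .fail("no candidate model could be fitted")

  aiccs <- vapply(fits, function(f) f$aicc, numeric(1L))
  ord <- order(aiccs)
  fits <- fits[ord]; subsets <- subsets[ord]; aiccs <- aiccs[ord]
  delta_aicc <- aiccs - aiccs[1L]
  top <- delta_aicc <= delta
  w <- exp(-0.5 * delta_aicc[top])
  w <- w / sum(w)

  top_fits <- fits[top]
  terms <- c("(Intercept)", predictors)
  m <- length(top_fits)
  beta <- var_m <- matrix(0, m, length(terms), dimnames = list(NULL, terms))
  present <- matrix(FALSE, m, length(terms), dimnames = list(NULL, terms))
  for (i in seq_len(m)) {
    cf <- top_fits[[i]]$coefficients
    se <- top_fits[[i]]$se
    beta[i, names(cf)] <- cf
    var_m[i, names(cf)] <- se^2
    present[i, names(cf)] <- TRUE
  }

  if (method == "full") {
    est <- colSums(w * beta)
    se_unc <- sqrt(colSums(w * (var_m + sweep(beta, 2, est)^2)))
  } else {
    est <- se_unc <- setNames(numeric(length(terms)), terms)
    for (j in seq_along(terms)) {
      in_m <- present[, j]
      wj <- w[in_m] / sum(w[in_m])
      est[j] <- sum(wj * beta[in_m, j])
      se_unc[j] <- sqrt(sum(wj * (var_m[in_m, j] + (beta[in_m, j] - est[j])^2)))
    }
  }
  ri <- colSums(w * present)
  ri_prop <- colMeans(present)

  tab <- data.frame(term = terms, estimate = unname(est), se_unconditional = unname(se_unc),
                    ri = unname(ri), ri_prop = unname(ri_prop),
                    stringsAsFactors = FALSE)
  tab$ri[tab$term == "(Intercept)"] <- NA_real_
  tab$ri_prop[tab$term == "(Intercept)"] <- NA_real_

  selection <- data.frame(
    model = vapply(subsets, function(s) if (length(s)) paste(s, collapse = "+") else "(null)",
                   character(1L)),
    k = vapply(fits, function(f) f$k, numeric(1L)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1L)),
    aicc = aiccs, delta_aicc = delta_aicc,
    in_top_set = top, stringsAsFactors = FALSE)

  structure(
    list(table = tab, top_models = top_fits, weights = w, selection = selection,
         constants = constants, family = family, random = random,
         predictors = predictors, delta = delta, method = method),
    class = "averaged_model")
}

#' @export
print.averaged_model <- function(x, digits = 4, ...) {
  cat(sprintf("Model-averaged %s model (%s average, top set: %d of %d models, dAICc <= %g)\n",
              x$family, x$method, length(x$top_models), nrow(x$selection), x$delta))
  if (!is.null(x$random)) cat(sprintf("Random intercept: (1|%s)\n", x$random))
  tab <- x$table
  tab$estimate <- round(tab$estimate, digits)
  tab$se_unconditional <- round(tab$se_unconditional, digits)
  tab$ri <- round(tab$ri, 2)
  tab$ri_prop <- round(tab$ri_prop, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.averaged_model <- function(object, ...) {
  cat("Candidate model ranking (AICc):\n")
  print(transform(object$selection, aicc = round(aicc, 3),
                  delta_aicc = round(delta_aicc, 3),
                  loglik = round(loglik, 3)), row.names = FALSE)
  cat(sprintf("\nAkaike weights within top set: %s\n",
              paste(round(object$weights, 3), collapse = ", ")))
  print(object)
  invisible(object)
}

#' @export
coef.averaged_model <- function(object, ...) {
  setNames(object$table$estimate, object$table$term)
}

#' Fitted probabilities (or rates) from an averaged model
#'
#' Back-transforms the averaged coefficients to the response scale for a
#' profile of raw covariate values, applying the standardization constants
#' stored at fit time. Predictors whose relative importance is below 1 are
#' flagged (attribute `averaged_over_uncertain`): their contribution is an
#' average over models that disagree about their inclusion.
#'
#' @param object an [model_average()] fit.
#' @param newdata `data.frame` of raw covariate values (one column per
#'   predictor of the global model).
#' @param type `"response"` (inverse-link scale) or `"link"`.
#' @param ... unused.
#' @return numeric vector of fitted values, one per row of `newdata`.
#' @export
predict.averaged_model <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  cf <- coef(object)
  eta <- rep(cf[["(Intercept)"]], nrow(newdata))
  for (v in object$predictors) {
    if (!v %in% colnames(newdata)) .fail("newdata lacks predictor '%s'", v)
    x <- as.numeric(newdata[[v]])
    if (!is.null(object$constants)) {
      cst <- object$constants[[v]]
      lo <- cst[["center"]] - cst[["scale"]]  # roughly mean +- 2 SD of fit data
      hi <- cst[["center"]] + cst[["scale"]]
      if (any(x < lo - cst[["scale"]] | x > hi + cst[["scale"]], na.rm = TRUE))
        warning(sprintf("'%s' outside the range observed at fit time: extrapolating", v),
                call. = FALSE)
      x <- (x - cst[["center"]]) / cst[["scale"]]
    }
    eta <- eta + cf[[v]] * x
  }
  out <- if (type == "link") eta
         else if (object$family == "poisson") exp(eta)
         else stats::plogis(eta)
  uncertain <- object$table$term[!is.na(object$table$ri) & object$table$ri < 1]
  if (length(uncertain)) attr(out, "averaged_over_uncertain") <- uncertain
  out
}
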