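# Inverse-variance pooling of the survey-model and expert-model coefficient
# vectors — the pipeline's central computation. For each regression
# parameter, with survey estimate b_o (variance s_o^2) and expert estimate
# b_e (variance s_e^2):
#
#   beta_c = (b_o / s_o^2 + b_e / s_e^2) / (1 / s_o^2 + 1 / s_e^2)
#   s_c^2  = (1 / s_o^2 + 1 / s_e^2)^-1
#
# i.e. the minimum-variance convex combination. Confidence intervals use a
# t quantile with v_c = v_o + v_e degrees of freedom. Pooling is elementwise
# (per parameter); cross-coefficient covariance is not used. Both parents
# model a probability through a logit-linked mean on identically
# standardized covariates, which is what makes their coefficients
# commensurate — an assumption of the method, stated, not derived.

#' Combine survey and expert models by inverse-variance pooling
#'
#' @param mo Survey-side `sdm_fit` (weighted logistic; "observation" parent).
#' @param me Expert-side `sdm_fit` (weighted Beta mixed; "elicitation"
#'   parent).
#' @param alpha Significance level for reported intervals (default 0.05).
#' @return An object of class `sdm_combined` with elements `coef` (fused
#'   beta_c), `se` (fused s_c), `residual_df` (v_c = v_o + v_e), `alpha`,
#'   and `provenance`.
#' @export
#' @examples
#' study <- simulate_study(seed = 3, n_sites = 140, n_grid = 50)
#' ref <- reference_scaling(study$covariates)
#' gt <- fit_survey(study$observations, study$covariates, ref, model_id = "GT")
#' e <- fit_expert(study$elicitations, study$covariates, ref)
#' gte <- combine_models(gt, e)
#' print(gte)
combine_models <- function(mo, me, alpha = 0.05) {
  stopifnot(inherits(mo, "sdm_fit"), inherits(me, "sdm_fit"))
  if (!mo$converged || !me$converged) {
    stop("both parent models must have converged", call. = FALSE)
  }
  if (!identical(names(mo$coef), names(me$coef))) {
    stop("parent models have mismatched coefficient names/order", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  so <- mo$se
  se <- me$se
  if (any(!is.finite(so)) || any(so <= 0) || any(!is.finite(se)) || any(se <= 0)) {
    stop("parent standard errors must be positive and finite", call. = FALSE)
  }
  prec <- so^-2 + se^-2
  beta_c <- (mo$coef * so^-2 + me$coef * se^-2) / prec
  s_c <- sqrt(1 / prec)
  structure(
    list(
      coef = beta_c, se = s_c, residual_df = mo$residual_df + me$residual_df,
      alpha = alpha,
      provenance = c(
        observation = mo$model_id %||% "survey",
        elicitation = me$model_id %||% "expert"
      ),
      parents = list(observation = mo, elicitation = me),
      ref = mo$ref, vars = mo$vars,
      model_id = paste0(mo$model_id %||% "survey", "_", me$model_id %||% "E")
    ),
    class = "sdm_combined"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sdm_combined <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Combined model %s (inverse-variance pooled; v_c = %s)\n",
    x$model_id, format(x$residual_df, digits = digits)
  ))
  ci <- confint(x, level = 1 - x$alpha)
  tab <- cbind(Estimate = x$coef, `Std. Error` = x$se, ci)
  print(round(tab, digits))
  invisible(x)
}

#' @export
coef.sdm_combined <- function(object, ...) object$coef

#' @export
vcov.sdm_combined <- function(object, ...) {
  v <- diag(object$se^2)
  dimnames(v) <- list(names(object$coef), names(object$coef))
  v
}

#' Confidence intervals for a combined model
#'
#' beta_c +/- t_(alpha/2, v_c) * s_c, with v_c = v_o + v_e.
#'
#' @param object An `sdm_combined`.
#' @param parm Optional coefficient subset.
#' @param level Confidence level (default `1 - object$alpha`).
#' @param ... Unused.
#' @return Two-column matrix of lower/upper bounds.
#' @export
confint.sdm_combined <- function(object, parm, level = 1 - object$alpha, ...) {
  if (level <= 0 || level >= 1) stop("invalid confidence level", call. = FALSE)
  q <- stats::qt(1 - (1 - level) / 2, df = object$residual_df)
  out <- cbind(
    lower = object$coef - q * object$se,
    upper = object$coef + q * object$se
  )
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Predict presence probabilities from a combined model
#'
#' Inverse-logit of the fused linear predictor. Covariates are standardized
#' with the parents' shared reference scaling unless already standardized.
#'
#' @inheritParams predict.sdm_fit
#' @param object An `sdm_combined`.
#' @return Probabilities in (0, 1) (or linear predictors for
#'   `type = "link"`).
#' @export
predict.sdm_combined <- function(object, newdata = NULL,
                                 type = c("response", "link"),
                                 standardized = FALSE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    stop("newdata is required for combined-model predictions", call. = FALSE)
  }
  z <- if (standardized) newdata else standardize(newdata, object$ref)
  X <- sdm_design_matrix(z, object$vars)
  if (ncol(X) != length(object$coef)) {
    stop("covariate dimension mismatch", call. = FALSE)
  }
  eta <- drop(X %*% object$coef)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
plot.sdm_combined <- function(x, level = 1 - x$alpha, ...) {
  plot.sdm_fit(x, level = level, ...)
}
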