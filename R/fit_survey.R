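# Confidence-weighted logistic regression for the survey-based models (the
# ground-only "G" model and the ground + thermal "GT" model). Weights are
# prior case weights multiplying per-record log-likelihood contributions:
# the fit maximizes sum_i w_i [y_i log p_i + (1 - y_i) log(1 - p_i)] with
# p_i = plogis(x_i' beta), and standard errors come from the inverse of the
# weighted information X' diag(w p (1 - p)) X. This is exactly the
# behaviour of a binomial GLM given non-integer prior weights, so the IRLS
# engine is stats::glm.fit (deviance tolerance 1e-10, up to 100 iterations).

#' Fit a confidence-weighted logistic regression to survey observations
#'
#' @param observations Observation table (`site_id`, `source`, `y`,
#'   `weight`), e.g. from [load_observations()] or [simulate_surveys()].
#' @param covariates Covariate table containing every observed `site_id`.
#' @param ref Reference scaling ([reference_scaling()]) of the base dataset;
#'   covariates are standardized against it before fitting so every model in
#'   the pipeline shares a covariate scale.
#' @param weights Per-record confidence weights in (0, 1]; defaults to the
#'   table's `weight` column.
#' @param model_id Optional label ("G", "GT", ...) carried into reports.
#' @param vars Covariate names; defaults to [sdm_covariates()].
#' @return An object of class `sdm_fit` with, among others, elements `coef`,
#'   `se`, `vcov`, `residual_df` (n - p with p = 7), `n_obs`, `converged`.
#' @export
#' @examples
#' study <- simulate_study(seed = 42, n_sites = 120, n_grid = 50)
#' ref <- reference_scaling(study$covariates)
#' fit <- fit_survey(study$observations, study$covariates, ref, model_id = "GT")
#' summary(fit)
fit_survey <- function(observations, covariates, ref,
                       weights = observations$weight,
                       model_id = NULL, vars = sdm_covariates()) {
  validate_observation_table(observations)
  idx <- match(observations$site_id, covariates$site_id)
  if (anyNA(idx)) {
    stop("covariates missing for site(s): ",
      paste(utils::head(observations$site_id[is.na(idx)], 5L), collapse = ", "),
      call. = FALSE
    )
  }
  z <- standardize(covariates[idx, , drop = FALSE], ref)
  X <- sdm_design_matrix(z, vars)
  y <- as.numeric(observations$y)
  w <- as.numeric(weights)
  stopifnot(length(w) == length(y), all(w > 0), all(w <= 1))
  p <- ncol(X)
  if (sum(y == 1) < 1L || sum(y == 0) < 1L) {
    stop("need at least one presence and one absence", call. = FALSE)
  }
  if (length(y) <= p) {
    stop("need more observations (", length(y), ") than parameters (", p, ")",
      call. = FALSE
    )
  }
  qrx <- qr(X)
  if (qrx$rank < p) {
    stop("rank-deficient design; collinear column(s): ",
      paste(colnames(X)[qrx$pivot[(qrx$rank + 1L):p]], collapse = ", "),
      call. = FALSE
    )
  }

  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y,
      weights = w, family = stats::binomial(),
      control = stats::glm.control(epsilon = 1e-10, maxit = 100L)
    ),
    warning = function(cond) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(cond))) {
        separation <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  beta <- fit$coefficients
  mu <- fit$fitted.values
  info <- crossprod(X, X * (w * mu * (1 - mu)))
  vc <- tryCatch(solve(info), error = function(cond) matrix(NA_real_, p, p))
  dimnames(vc) <- list(colnames(X), colnames(X))
  converged <- isTRUE(fit$converged) && !separation && all(is.finite(vc))
  if (separation) {
    warning(
      "possible complete separation: fitted probabilities numerically 0 or 1; ",
      "coefficients may be diverging (max |coef| = ",
      format(max(abs(beta)), digits = 3), ")"
    )
  }

  new_sdm_fit(
    family = "binomial", coef = beta, vcov = vc,
    residual_df = length(y) - p, n_obs = length(y), converged = converged,
    aux = list(deviance = fit$deviance, separation = separation),
    ref = ref, vars = vars, X = X, y = y, w = w, model_id = model_id
  )
}

new_sdm_fit <- function(family, coef, vcov, residual_df, n_obs, converged,
                        aux, ref, vars, X, y, w, model_id = NULL,
                        expert = NULL, edf_random = 0) {
  se <- sqrt(diag(vcov))
  structure(
    list(
      family = family, coef = coef, se = se, vcov = vcov,
      residual_df = residual_df, edf_random = edf_random, link = "logit",
      n_obs = n_obs, converged = converged, aux = aux,
      ref = ref, vars = vars, X = X, y = y, w = w, expert = expert,
      model_id = model_id
    ),
    class = "sdm_fit"
  )
}

#' @export
print.sdm_fit <- function(x, digits = 4, ...) {
  label <- if (is.null(x$model_id)) "" else paste0(" [", x$model_id, "]")
  cat(sprintf(
    "Confidence-weighted %s regression%s (n = %d, residual df = %s)\n",
    if (x$family == "binomial") "logistic" else "Beta mixed",
    label, x$n_obs, format(x$residual_df, digits = digits)
  ))
  print(round(x$coef, digits))
  if (!x$converged) cat("** fit did not converge — diagnostics in $aux **\n")
  invisible(x)
}

#' @export
summary.sdm_fit <- function(object, ...) {
  tab <- cbind(
    Estimate = object$coef,
    `Std. Error` = object$se,
    `t value` = object$coef / object$se,
    `Pr(>|t|)` = 2 * stats::pt(
      -abs(object$coef / object$se), df = object$residual_df
    )
  )
  out <- list(
    fit = object, coefficients = tab,
    aux = object$aux, residual_df = object$residual_df
  )
  class(out) <- "summary.sdm_fit"
  out
}

#' @export
print.summary.sdm_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  if (x$fit$family == "beta") {
    cat(sprintf(
      "\nBeta precision phi = %.4g; expert random-intercept SD = %.4g (edf %.2f)\n",
      x$aux$phi, x$aux$sigma_expert, x$fit$edf_random
    ))
  }
  invisible(x)
}

#' @export
coef.sdm_fit <- function(object, ...) object$coef

#' @export
vcov.sdm_fit <- function(object, ...) object$vcov

#' Confidence intervals for a fitted model
#'
#' t-based Wald intervals at the model's residual degrees of freedom. For
#' the Beta mixed model the intercept does not vary within expert and is
#' confounded with the expert random effect, so its interval uses
#' containment degrees of freedom (number of experts minus one) — with few
#' experts the nominal residual df would understate its uncertainty.
#'
#' @param object An `sdm_fit`.
#' @param parm Optional coefficient subset.
#' @param level Confidence level.
#' @param ... Unused.
#' @return Two-column matrix of lower/upper bounds.
#' @export
confint.sdm_fit <- function(object, parm, level = 0.95, ...) {
  df <- rep(object$residual_df, length(object$coef))
  if (object$family == "beta" && !is.null(object$expert) &&
    isTRUE(object$aux$sigma_expert > 0)) {
    df[names(object$coef) == "(Intercept)"] <-
      max(nlevels(object$expert) - 1L, 1L)
  }
  q <- stats::qt(1 - (1 - level) / 2, df = df)
  out <- cbind(
    lower = object$coef - q * object$se,
    upper = object$coef + q * object$se
  )
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Predict presence/suitability probabilities from a fitted model
#'
#' Applies the inverse logit to the linear predictor at new sites. New
#' covariates are standardized with the model's stored reference scaling
#' unless `standardized = TRUE`.
#'
#' @param object An `sdm_fit`.
#' @param newdata Covariate data frame; if omitted, the training design is
#'   used.
#' @param type `"response"` (probability, default) or `"link"`.
#' @param standardized Set `TRUE` when `newdata` is already standardized.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1) (or linear predictors).
#' @export
predict.sdm_fit <- function(object, newdata = NULL, type = c("response", "link"),
                            standardized = FALSE, ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) {
    object$X
  } else {
    z <- if (standardized) newdata else standardize(newdata, object$ref)
    sdm_design_matrix(z, object$vars)
  }
  if (ncol(X) != length(object$coef)) {
    stop("covariate dimension mismatch: design has ", ncol(X),
      " columns, model has ", length(object$coef), " coefficients",
      call. = FALSE
    )
  }
  eta <- drop(X %*% object$coef)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
residuals.sdm_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- predict(object)
  r <- object$y - mu
  if (type == "response") {
    return(r)
  }
  v <- if (object$family == "binomial") {
    mu * (1 - mu)
  } else {
    mu * (1 - mu) / (1 + object$aux$phi)
  }
  r / sqrt(v / object$w)
}

#' Simulate responses from a fitted model
#'
#' Draws new response vectors at the training sites: Bernoulli draws for the
#' logistic family, Beta draws (with fresh expert intercepts when a random
#' effect was fitted) for the Beta family.
#'
#' @param object An `sdm_fit`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns.
#' @export
simulate.sdm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  eta_fix <- drop(object$X %*% object$coef)
  n <- length(eta_fix)
  out <- replicate(nsim, {
    if (object$family == "binomial") {
      stats::rbinom(n, 1L, stats::plogis(eta_fix))
    } else {
      sig <- object$aux$sigma_expert
      u <- stats::rnorm(length(unique(object$expert)), 0, sig)
      mu <- stats::plogis(eta_fix + u[as.integer(factor(object$expert))])
      stats::rbeta(n, mu * object$aux$phi, (1 - mu) * object$aux$phi)
    }
  })
  as.data.frame(out)
}

#' Coefficient plot for fitted and combined models
#'
#' Dot-and-whisker display of coefficient estimates with confidence
#' intervals, the standard way to compare the precision of the survey,
#' expert and fused models.
#'
#' @param x An `sdm_fit` or `sdm_combined` object (or a list of them).
#' @param level Confidence level.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.sdm_fit <- function(x, level = 0.95, ...) {
  ci <- confint(x, level = level)
  est <- coef(x)
  k <- length(est)
  graphics::plot(
    est, seq_len(k),
    xlim = range(ci), yaxt = "n",
    xlab = "coefficient (standardized scale)", ylab = "", pch = 19, ...
  )
  graphics::segments(ci[, 1L], seq_len(k), ci[, 2L], seq_len(k))
  graphics::axis(2, at = seq_len(k), labels = names(est), las = 1, cex.axis = 0.8)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
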