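# Confidence-weighted Beta regression with a Gaussian random intercept per
# expert (the "E" model). The response is the elicited habitat-suitability
# probability; confidence weights (0.50 / 0.75 / 1.00) multiply per-record
# log-density contributions. Estimation is marginal maximum likelihood: the
# expert intercept is integrated out by adaptive Gauss-Hermite quadrature,
# which yields clean fixed-effect standard errors for downstream pooling.
#
# Model: y_ij ~ Beta(mu_ij * phi, (1 - mu_ij) * phi),
#        logit(mu_ij) = x_i' beta + u_j,  u_j ~ N(0, sigma^2),
# weighted marginal likelihood
#   prod_j  integral  prod_i f(y_ij | u)^(w_ij)  dN(u; 0, sigma^2).

#' Squeeze probabilities off the boundary of (0, 1)
#'
#' Experts may state probabilities of exactly 0 or 1, where the Beta
#' likelihood is undefined. The standard remedy compresses the sample toward
#' 0.5: y' = (y (n - 1) + 0.5) / n.
#'
#' @param p Values in \[0, 1\].
#' @param n Sample size driving the amount of compression.
#' @return Values strictly inside (0, 1); 0.5 is a fixed point.
#' @export
#' @examples
#' squeeze_probabilities(c(0, 0.5, 1), n = 60)
squeeze_probabilities <- function(p, n) {
  stopifnot(all(p >= 0 & p <= 1), n >= 1)
  (p * (n - 1) + 0.5) / n
}

# log density contributions, weighted; y strictly inside (0,1)
beta_loglik_rows <- function(y, mu, phi, w) {
  w * stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)
}

# keep the mean safely inside (0,1) during optimization
clamp_mu <- function(mu) pmin(pmax(mu, 1e-10), 1 - 1e-10)

# Conditional mode of u_j given theta: vectorized ascent Newton (with
# backtracking) over experts. The warm start u0 comes from the previous
# outer-iteration evaluation; if the posterior value does not improve the
# step is halved, and a non-finite warm start falls back to zero, so the
# returned modes depend only on theta, not on the optimizer's path.
# Returns list(u, curv) where curv = -h''(u) > 0.
expert_modes <- function(u0, eta_fix, ystar, y, expert_idx, phi, w, sigma2,
                         n_experts, maxit = 15L, tol = 1e-8) {
  hval <- function(u) {
    mu <- clamp_mu(stats::plogis(eta_fix + u[expert_idx]))
    rowsum_by(beta_loglik_rows(y, mu, phi, w), expert_idx, n_experts) -
      u^2 / (2 * sigma2)
  }
  u <- u0
  u[!is.finite(u)] <- 0
  h <- hval(u)
  if (any(!is.finite(h))) {
    u <- rep(0, n_experts)
    h <- hval(u)
  }
  for (it in seq_len(maxit)) {
    mu <- clamp_mu(stats::plogis(eta_fix + u[expert_idx]))
    m <- mu * (1 - mu)
    delta <- digamma(mu * phi) - digamma((1 - mu) * phi)
    trig <- trigamma(mu * phi) + trigamma((1 - mu) * phi)
    g <- rowsum_by(w * phi * (ystar - delta) * m, expert_idx, n_experts) -
      u / sigma2
    hpp <- rowsum_by(
      w * phi * (-phi * trig * m^2 + (ystar - delta) * (1 - 2 * mu) * m),
      expert_idx, n_experts
    ) - 1 / sigma2
    g[!is.finite(g)] <- 0 # flat beyond numeric range: no step for that expert
    hpp[!is.finite(hpp)] <- -1
    if (max(abs(g)) < tol) break
    hpp <- pmin(hpp, -1e-8)
    step <- -g / hpp
    step <- sign(step) * pmin(abs(step), 4)
    # backtracking: halve any expert's step until its posterior improves
    h_new <- h
    for (bt in 1:12) {
      h_new <- hval(u + step)
      worse <- !is.finite(h_new) | h_new < h - 1e-12
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    keep <- is.finite(h_new) & h_new >= h - 1e-12
    u[keep] <- u[keep] + step[keep]
    h[keep] <- h_new[keep]
  }
  mu <- clamp_mu(stats::plogis(eta_fix + u[expert_idx]))
  m <- mu * (1 - mu)
  delta <- digamma(mu * phi) - digamma((1 - mu) * phi)
  trig <- trigamma(mu * phi) + trigamma((1 - mu) * phi)
  hpp_rows <- w * phi * (-phi * trig * m^2 + (ystar - delta) * (1 - 2 * mu) * m)
  curv <- -(rowsum_by(hpp_rows, expert_idx, n_experts) - 1 / sigma2)
  list(u = u, curv = pmax(curv, 1e-8))
}

rowsum_by <- function(x, idx, n_groups) {
  out <- numeric(n_groups)
  tmp <- rowsum(x, idx)
  out[as.integer(rownames(tmp))] <- tmp[, 1L]
  out
}

# Negative weighted marginal log-likelihood via adaptive Gauss-Hermite
# quadrature, with its analytic gradient (attribute "gradient"). The
# gradient holds the adaptive node positions fixed at the current
# conditional modes, the usual AGQ device; with converged inner modes and
# >= 15 nodes the neglected node-movement terms are far below the outer
# optimizer's tolerance. state caches conditional modes for warm starts.
expert_negloglik <- function(theta, X, y, ystar, expert_idx, w, nodes,
                             n_experts, state, sigma_fixed = NULL,
                             grad = FALSE) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  phi <- min(max(exp(theta[p + 1L]), 1e-6), 1e8)
  eta_fix <- drop(X %*% beta)
  if (!is.null(sigma_fixed) && sigma_fixed == 0) {
    mu <- clamp_mu(stats::plogis(eta_fix))
    ll <- sum(beta_loglik_rows(y, mu, phi, w))
    nll <- if (is.finite(ll)) -ll else 1e10
    if (grad && is.finite(ll)) {
      m <- mu * (1 - mu)
      delta <- digamma(mu * phi) - digamma((1 - mu) * phi)
      g_beta <- -crossprod(X, w * phi * (ystar - delta) * m)[, 1L]
      dl_dphi <- mu * ystar + log1p(-y) + digamma(phi) -
        mu * digamma(mu * phi) - (1 - mu) * digamma((1 - mu) * phi)
      g_logphi <- -sum(w * dl_dphi) * phi
      attr(nll, "gradient") <- c(g_beta, g_logphi)
    }
    return(nll)
  }
  sigma <- if (is.null(sigma_fixed)) exp(theta[p + 2L]) else sigma_fixed
  sigma2 <- sigma^2
  md <- expert_modes(
    state$u, eta_fix, ystar, y, expert_idx, phi, w, sigma2, n_experts
  )
  state$u <- md$u
  tau <- 1 / sqrt(md$curv)
  t_k <- nodes$x
  log_wk <- log(nodes$w) + t_k^2
  K <- length(t_k)
  # u-matrix of node positions per expert (experts indexed 1..E), expanded
  # to observation rows
  u_nodes <- outer(md$u, rep(1, K)) + sqrt(2) * outer(tau, t_k)
  eta_mat <- eta_fix + u_nodes[expert_idx, , drop = FALSE]
  mu_mat <- clamp_mu(stats::plogis(eta_mat))
  ll_rows <- w * stats::dbeta(y, mu_mat * phi, (1 - mu_mat) * phi, log = TRUE)
  S <- rowsum(ll_rows, expert_idx) # sorted by expert index = 1..E
  log_prior <- stats::dnorm(u_nodes, 0, sigma, log = TRUE)
  A <- sweep(S + log_prior, 2L, log_wk, "+")
  amax <- apply(A, 1L, max)
  logL_j <- log(sqrt(2) * tau) + amax + log(rowSums(exp(A - amax)))
  nll <- -sum(logL_j)
  if (!is.finite(nll)) {
    return(1e10)
  }
  if (grad) {
    r <- exp(A - amax)
    r <- r / rowSums(r) # posterior node weights per expert (E x K)
    r_rows <- r[expert_idx, , drop = FALSE]
    m_mat <- mu_mat * (1 - mu_mat)
    dg_a <- digamma(mu_mat * phi)
    dg_b <- digamma((1 - mu_mat) * phi)
    score_eta <- w * phi * (ystar - (dg_a - dg_b)) * m_mat # n x K
    q <- rowSums(r_rows * score_eta)
    g_beta <- -crossprod(X, q)[, 1L]
    dl_dphi <- mu_mat * ystar + log1p(-y) + digamma(phi) -
      mu_mat * dg_a - (1 - mu_mat) * dg_b
    g_logphi <- -sum(rowSums(r_rows * (w * dl_dphi))) * phi
    gr <- c(g_beta, g_logphi)
    if (is.null(sigma_fixed)) {
      g_logsigma <- -sum(rowSums(r * (u_nodes^2 / sigma2 - 1)))
      gr <- c(gr, g_logsigma)
    }
    attr(nll, "gradient") <- gr
  }
  nll
}

#' Fit the confidence-weighted Beta mixed model to elicitation data
#'
#' @param elicitations Elicitation table (see [load_elicitations()] /
#'   [simulate_elicitation()]).
#' @param covariates Covariate table covering every elicited `site_id`.
#' @param ref Reference scaling of the base dataset.
#' @param response Response column: `"p_suitability"` (default — the
#'   pipeline models the suitability answer, whose confidence is far higher
#'   than the presence answers') or `"p_mode"`.
#' @param weights Per-record confidence weights; defaults to the `weight`
#'   column.
#' @param nq Number of Gauss-Hermite quadrature nodes (>= 15 recommended).
#' @param sigma `NULL` to estimate the expert random-intercept SD by
#'   marginal ML, or a fixed non-negative value (0 drops the random effect).
#' @param df_method `"edf"` (default): residual df = n - p - edf_random,
#'   with edf_random the effective df absorbed by the random intercepts;
#'   `"nominal"`: residual df = n - p.
#' @param model_id Optional label; defaults to `"E"`.
#' @param vars Covariate names; defaults to [sdm_covariates()].
#' @return An `sdm_fit` with `family = "beta"`; `aux` holds `phi`,
#'   `sigma_expert`, `edf_random`, `logLik` and boundary diagnostics.
#' @export
#' @examples
#' study <- simulate_study(seed = 7, n_sites = 100, n_grid = 50)
#' ref <- reference_scaling(study$covariates)
#' efit <- fit_expert(study$elicitations, study$covariates, ref)
#' summary(efit)
fit_expert <- function(elicitations, covariates, ref,
                       response = c("p_suitability", "p_mode"),
                       weights = elicitations$weight, nq = 15L,
                       sigma = NULL, df_method = c("edf", "nominal"),
                       model_id = "E", vars = sdm_covariates()) {
  response <- match.arg(response)
  df_method <- match.arg(df_method)
  validate_elicitation_table(elicitations)
  idx <- match(elicitations$site_id, covariates$site_id)
  if (anyNA(idx)) {
    stop("covariates missing for elicited site(s): ",
      paste(utils::head(elicitations$site_id[is.na(idx)], 5L), collapse = ", "),
      call. = FALSE
    )
  }
  z <- standardize(covariates[idx, , drop = FALSE], ref)
  X <- sdm_design_matrix(z, vars)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 2L) stop("too few elicitation records for ", p, " parameters", call. = FALSE)
  w <- as.numeric(weights)
  stopifnot(length(w) == n, all(w > 0))
  expert <- factor(elicitations$expert_id)
  n_experts <- nlevels(expert)
  expert_idx <- as.integer(expert)
  if (n_experts < 2L && is.null(sigma)) {
    warning(
      "fewer than 2 experts: random intercept not identifiable; ",
      "falling back to a fixed-intercept-only fit (sigma = 0)"
    )
    sigma <- 0
  }
  y <- squeeze_probabilities(as.numeric(elicitations[[response]]), n)
  ystar <- stats::qlogis(y)

  # starting values from a weighted least-squares fit on the logit scale
  beta0 <- tryCatch(
    stats::lm.wfit(X, ystar, w)$coefficients,
    error = function(cond) c(mean(ystar), rep(0, p - 1L))
  )
  beta0[!is.finite(beta0)] <- 0
  mu0 <- stats::plogis(drop(X %*% beta0))
  phi0 <- max(1 / max(mean((y - mu0)^2 / (mu0 * (1 - mu0))), 1e-4) - 1, 2)
  resm <- tapply(ystar - drop(X %*% beta0), expert_idx, mean)
  sigma0 <- max(stats::sd(resm), 0.1)
  if (!is.finite(sigma0)) sigma0 <- 0.1

  nodes <- pracma::gaussHermite(nq)
  state <- new.env(parent = emptyenv())
  state$u <- rep(0, n_experts)

  est_sigma <- is.null(sigma)
  theta0 <- as.numeric(c(beta0, log(phi0), if (est_sigma) log(sigma0)))
  cache <- new.env(parent = emptyenv())
  eval_at <- function(th) {
    if (!identical(cache$theta, th)) {
      cache$val <- expert_negloglik(
        th, X, y, ystar, expert_idx, w, nodes, n_experts, state,
        sigma_fixed = if (est_sigma) NULL else sigma, grad = TRUE
      )
      cache$theta <- th
    }
    cache$val
  }
  obj <- function(th) as.numeric(eval_at(th))
  gr <- function(th) {
    g <- attr(eval_at(th), "gradient")
    if (is.null(g)) rep(0, length(th)) else g
  }
  opt <- stats::optim(theta0, obj, gr,
    method = "BFGS",
    control = list(maxit = 500L, reltol = 1e-12)
  )
  # BFGS can stall with a poor curvature estimate; restart from the stalled
  # point until the score is numerically zero or no further progress is made
  for (restart in 1:5) {
    if (max(abs(gr(opt$par))) < 1e-3) break
    opt2 <- stats::optim(opt$par, obj, gr,
      method = "BFGS",
      control = list(maxit = 500L, reltol = 1e-12)
    )
    if (opt2$value < opt$value - 1e-10) opt <- opt2 else break
  }
  score_norm <- max(abs(gr(opt$par)))
  # curvature at the optimum, by differencing the analytic gradient
  H <- stats::optimHess(opt$par, obj, gr)
  H <- (H + t(H)) / 2
  theta <- opt$par
  beta <- theta[seq_len(p)]
  names(beta) <- colnames(X)
  phi <- exp(theta[p + 1L])
  sigma_hat <- if (est_sigma) exp(theta[p + 2L]) else sigma

  vc_full <- tryCatch(solve(H), error = function(cond) matrix(NA_real_, length(theta), length(theta)))
  vc <- vc_full[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(vc) <- list(colnames(X), colnames(X))

  boundary <- (phi < 1e-3) || (est_sigma && (sigma_hat > 50 || sigma_hat < 1e-8))
  converged <- opt$convergence == 0L && !boundary && score_norm < 1e-2 &&
    all(is.finite(vc)) && all(diag(vc) > 0)
  if (boundary) {
    warning(sprintf(
      "boundary estimate: phi = %.3g, sigma = %.3g; model flagged",
      phi, sigma_hat
    ))
  }

  edf_random <- if (sigma_hat < 1e-8) {
    0
  } else {
    eta_fix <- drop(X %*% beta)
    md <- expert_modes(
      state$u, eta_fix, ystar, y, expert_idx, phi, w, sigma_hat^2, n_experts
    )
    expert_edf(X, eta_fix, md$u, expert_idx, phi, w, sigma_hat, n_experts)
  }
  residual_df <- if (df_method == "edf") n - p - edf_random else n - p

  fit <- new_sdm_fit(
    family = "beta", coef = beta, vcov = vc, residual_df = residual_df,
    n_obs = n, converged = converged,
    aux = list(
      phi = phi, sigma_expert = sigma_hat, logLik = -opt$value,
      score_norm = score_norm, boundary = boundary, df_method = df_method,
      u_modes = if (sigma_hat > 0) state$u else rep(0, n_experts),
      theta_vcov = vc_full
    ),
    ref = ref, vars = vars, X = X, y = y, w = w, model_id = model_id,
    expert = expert, edf_random = edf_random
  )
  fit
}

# Effective df absorbed by the random intercepts: trace of the ridge-type
# smoother for the joint (beta, u) problem, minus the p fixed-effect df.
# Uses the expected conditional information of the Beta likelihood at the
# conditional modes; collinearity of the intercept with the u-columns is
# what keeps the value below n_experts - 1 for large sigma.
expert_edf <- function(X, eta_fix, u, expert_idx, phi, w, sigma, n_experts) {
  mu <- stats::plogis(eta_fix + u[expert_idx])
  m <- mu * (1 - mu)
  info_rows <- w * phi^2 * (trigamma(mu * phi) + trigamma((1 - mu) * phi)) * m^2
  Z <- stats::model.matrix(~ 0 + factor(expert_idx, levels = seq_len(n_experts)))
  C <- cbind(X, Z)
  I_joint <- crossprod(C, C * info_rows)
  P <- diag(c(rep(0, ncol(X)), rep(1 / sigma^2, n_experts)))
  F <- tryCatch(solve(I_joint + P, I_joint), error = function(cond) NULL)
  if (is.null(F)) {
    return(NA_real_)
  }
  max(sum(diag(F)) - ncol(X), 0)
}

#' Residual degrees of freedom of the expert model
#'
#' v_e = n - p_fixed - edf_random by default (p_fixed = 7), where
#' edf_random is the effective number of parameters absorbed by the expert
#' random intercepts; with `method = "nominal"`, simply n - p_fixed.
#'
#' @param model An `sdm_fit` with `family = "beta"`.
#' @param method `"edf"` or `"nominal"`.
#' @return Residual degrees of freedom (possibly non-integer).
#' @export
residual_df_expert <- function(model, method = c("edf", "nominal")) {
  method <- match.arg(method)
  p <- length(model$coef)
  if (method == "nominal") {
    return(model$n_obs - p)
  }
  model$n_obs - p - model$edf_random
}
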