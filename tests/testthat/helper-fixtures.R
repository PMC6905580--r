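# Small deterministic fixtures built in code.

# covariate table with independent draws (no landscape structure)
small_covariates <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    site_id = sprintf("T%03d", seq_len(n)),
    longitude = runif(n, 153.19, 153.20),
    latitude = runif(n, -27.70, -27.69),
    fpc = runif(n, 5, 95),
    rev = rbinom(n, 1, 0.5),
    dist_path = runif(n, 0, 300),
    dist_water = runif(n, 0, 400),
    stringsAsFactors = FALSE
  )
}

# balanced observation table over small_covariates sites
small_observations <- function(cov, seed = 1) {
  set.seed(seed + 100)
  n <- nrow(cov)
  y <- rep(c(1L, 0L), length.out = n)
  src <- ifelse(y == 1, sample(c("ground", "thermal"), n, TRUE), "thermal")
  w <- ifelse(y == 0, 0.9, sample(c(0.5, 0.9, 1.0), n, TRUE))
  data.frame(
    site_id = cov$site_id, source = src, y = y, weight = w,
    stringsAsFactors = FALSE
  )
}

# direct numerical maximization of the weighted Bernoulli log-likelihood
# (independent of the package's IRLS route)
oracle_weighted_logistic <- function(X, y, w) {
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(w * (y * eta - log1p(exp(eta))))
  }
  gr <- function(beta) {
    p <- plogis(drop(X %*% beta))
    -drop(crossprod(X, w * (y - p)))
  }
  optim(rep(0, ncol(X)), nll, gr,
    method = "BFGS",
    control = list(maxit = 1000, reltol = 1e-15)
  )$par
}

# direct numerical maximization of the weighted Beta log-likelihood
# (fixed effects only)
oracle_weighted_beta <- function(X, y, w, start = NULL) {
  nll <- function(th) {
    beta <- th[seq_len(ncol(X))]
    phi <- exp(th[ncol(X) + 1])
    mu <- plogis(drop(X %*% beta))
    val <- -sum(w * dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
    if (is.finite(val)) val else 1e10
  }
  th0 <- if (is.null(start)) c(rep(0, ncol(X)), log(10)) else start
  o <- optim(th0, nll, method = "BFGS", control = list(maxit = 2000, reltol = 1e-15))
  o <- optim(o$par, nll, method = "Nelder-Mead", control = list(maxit = 5000, reltol = 1e-15))
  list(beta = o$par[seq_len(ncol(X))], phi = exp(o$par[ncol(X) + 1]))
}

expect_no_failure <- function(expr) expect_error(expr, NA)
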