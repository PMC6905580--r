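#' Model covariates
#'
#' The six habitat covariates entering every regression, in canonical order:
#' longitude, latitude, percent foliage projective cover, remnant-Eucalyptus
#' indicator, distance to nearest path (m), distance to fresh water (m).
#'
#' @return Character vector of covariate column names.
#' @export
sdm_covariates <- function() {
  c("longitude", "latitude", "fpc", "rev", "dist_path", "dist_water")
}

#' Reference scaling from a base covariate table
#'
#' Computes per-covariate means and sample standard deviations (n - 1
#' denominator) on a base set of sites. Every dataset in the pipeline —
#' training, elicitation, validation and prediction-grid tables — is centred
#' and scaled with the scaling of the ground-survey ("base") rows so that
#' coefficients from different models share a common covariate scale, a
#' prerequisite for pooling them. The binary remnant-vegetation indicator is
#' z-scored like every other covariate for the same reason.
#'
#' @param covariates Data frame of site covariates containing the columns in
#'   [sdm_covariates()].
#' @param vars Covariate columns to scale; defaults to [sdm_covariates()].
#' @return An object of class `sdm_scaling`: a data frame with columns
#'   `variable`, `mean`, `sd`.
#' @export
#' @examples
#' ref <- reference_scaling(data.frame(
#'   longitude = 1:3, latitude = 4:6, fpc = c(10, 20, 40),
#'   rev = c(0, 1, 1), dist_path = c(5, 10, 20), dist_water = c(100, 50, 10)
#' ))
#' ref
reference_scaling <- function(covariates, vars = sdm_covariates()) {
  missing_cols <- setdiff(vars, names(covariates))
  if (length(missing_cols) > 0L) {
    stop("missing covariate column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(covariates) < 2L) {
    stop("need at least 2 rows to compute a reference scaling", call. = FALSE)
  }
  m <- vapply(covariates[vars], function(x) mean(as.numeric(x)), numeric(1))
  s <- vapply(covariates[vars], function(x) stats::sd(as.numeric(x)), numeric(1))
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop(
      "constant covariate(s) (sd = 0): ",
      paste(vars[!is.finite(s) | s <= 0], collapse = ", "),
      call. = FALSE
    )
  }
  out <- data.frame(variable = vars, mean = unname(m), sd = unname(s))
  class(out) <- c("sdm_scaling", "data.frame")
  out
}

#' Standardize covariates against a reference scaling
#'
#' Applies z = (x - mean_ref) / sd_ref per covariate. The reference means and
#' standard deviations come from the base dataset (see
#' [reference_scaling()]), not from the table being standardized.
#'
#' @param covariates Data frame containing every variable in `ref`.
#' @param ref An `sdm_scaling` object.
#' @return Data frame with the scaled covariate columns (other columns are
#'   carried through unchanged).
#' @export
standardize <- function(covariates, ref) {
  stopifnot(inherits(ref, "sdm_scaling"))
  missing_cols <- setdiff(ref$variable, names(covariates))
  if (length(missing_cols) > 0L) {
    stop("covariate table lacks column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  out <- covariates
  for (i in seq_len(nrow(ref))) {
    v <- ref$variable[i]
    out[[v]] <- (as.numeric(covariates[[v]]) - ref$mean[i]) / ref$sd[i]
  }
  out
}

#' Invert a standardization
#'
#' Maps z-scores back to the original covariate scale, x = z * sd + mean.
#'
#' @inheritParams standardize
#' @return Data frame on the original scale.
#' @export
unstandardize <- function(covariates, ref) {
  stopifnot(inherits(ref, "sdm_scaling"))
  out <- covariates
  for (i in seq_len(nrow(ref))) {
    v <- ref$variable[i]
    out[[v]] <- as.numeric(covariates[[v]]) * ref$sd[i] + ref$mean[i]
  }
  out
}

#' @export
print.sdm_scaling <- function(x, ...) {
  cat("Reference scaling (base-model means and SDs):\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Design matrix for the distribution models
#'
#' Intercept plus the standardized covariates, in canonical order.
#'
#' @param covariates Data frame already standardized with [standardize()].
#' @param vars Covariate names; defaults to [sdm_covariates()].
#' @return Numeric matrix with columns `(Intercept)`, then `vars`.
#' @keywords internal
sdm_design_matrix <- function(covariates, vars = sdm_covariates()) {
  missing_cols <- setdiff(vars, names(covariates))
  if (length(missing_cols) > 0L) {
    stop("covariate table lacks column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  x <- cbind(
    "(Intercept)" = rep(1, nrow(covariates)),
    as.matrix(as.data.frame(lapply(covariates[vars], as.numeric)))
  )
  storage.mode(x) <- "double"
  x
}
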