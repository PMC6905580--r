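# Predictive-performance evaluation: a high-confidence validation set drawn
# from the thermal-imagery records, leave-one-out cross-validated
# predictions for the models whose training data contain the validation
# sites, classification at a presence-favouring 0.4 cutoff, and the
# accuracy / sensitivity / specificity / RMSPE report, plus
# prediction-surface export for the visualization grid.

#' Build the high-confidence validation set
#'
#' Thermal-survey-derived records (presences and the generated absences)
#' with confidence weight >= `min_weight`. High-confidence records keep the
#' validation labels representative of the truth on the ground.
#'
#' @param observations Observation table with `source` and `weight`.
#' @param min_weight Inclusive weight threshold (default 0.90).
#' @return The qualifying subset, row order preserved.
#' @export
build_validation_set <- function(observations, min_weight = 0.90) {
  keep <- observations$source == "thermal" & observations$weight >= min_weight
  out <- observations[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("validation set is empty")
  rownames(out) <- NULL
  out
}

#' Classify predicted probabilities at a cutoff
#'
#' Probabilities at or above the cutoff are classified as presence; the
#' default cutoff of 0.4 (rather than 0.5) favours detecting presences, the
#' conservation priority.
#'
#' @param p Probabilities in \[0, 1\].
#' @param cutoff Threshold; ties classify as presence (>=).
#' @return Integer vector of 0/1 labels.
#' @export
#' @examples
#' classify(c(0.39, 0.40, 0.41)) # 0 1 1
classify <- function(p, cutoff = 0.4) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  as.integer(p >= cutoff)
}

#' Confusion counts and classification metrics
#'
#' @param obs Binary observed labels.
#' @param pred Binary predicted labels (same length).
#' @return A one-row data frame: `tp`, `fp`, `tn`, `fn`, `accuracy`
#'   (correct / total), `sensitivity` (true positive rate), `specificity`
#'   (true negative rate), `n`. When a class is absent the corresponding
#'   rate is `NA` with a warning.
#' @export
#' @examples
#' confusion_metrics(c(1, 1, 1, 0), c(0, 1, 1, 0))
confusion_metrics <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) >= 1L)
  stopifnot(all(obs %in% c(0, 1)), all(pred %in% c(0, 1)))
  tp <- sum(obs == 1 & pred == 1)
  fp <- sum(obs == 0 & pred == 1)
  tn <- sum(obs == 0 & pred == 0)
  fn <- sum(obs == 1 & pred == 0)
  n <- length(obs)
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("no observed presences: sensitivity undefined")
    NA_real_
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    warning("no observed absences: specificity undefined")
    NA_real_
  }
  data.frame(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / n, sensitivity = sens, specificity = spec, n = n
  )
}

#' Root mean-square prediction error
#'
#' Computed on raw predicted probabilities against the binary outcomes (not
#' on classified labels): sqrt(mean((obs - p)^2)).
#'
#' @param obs Binary observed labels.
#' @param p Predicted probabilities.
#' @return RMSPE in \[0, 1\] for probabilities vs binary outcomes.
#' @export
#' @examples
#' rmspe(c(1, 1, 1, 0), c(0.39, 0.4, 0.7, 0.1))
rmspe <- function(obs, p) {
  stopifnot(length(obs) == length(p))
  if (length(obs) == 0L) stop("empty input", call. = FALSE)
  sqrt(mean((obs - p)^2))
}

#' Leave-one-out cross-validated predictions at validation sites
#'
#' For each validation site whose record is part of the survey training
#' data: drop that record, refit the survey model on the remainder, and (for
#' combined recipes) re-pool with the expert model before predicting at the
#' dropped site. The expert model is fit once — its records come from the
#' elicitation stream and contain no validation observations — so only the
#' survey parent is refit per fold.
#'
#' @param observations Survey observation table (the full training data).
#' @param covariates Covariate table covering all sites.
#' @param ref Reference scaling of the base dataset.
#' @param validation_ids Site ids to predict (each must be present in
#'   `observations`).
#' @param expert_fit Optional expert-model `sdm_fit`; when supplied each
#'   fold's refit is combined with it and the fused model predicts.
#' @param alpha Significance level passed to [combine_models()].
#' @return Named numeric vector of probabilities, one per validation id (in
#'   the order given). Folds whose refit fails to converge are flagged with
#'   a warning and return `NA`.
#' @export
loocv_predictions <- function(observations, covariates, ref, validation_ids,
                              expert_fit = NULL, alpha = 0.05) {
  if (length(validation_ids) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  miss <- setdiff(validation_ids, observations$site_id)
  if (length(miss) > 0L) {
    stop("validation id(s) not present in training data: ",
      paste(utils::head(miss, 5L), collapse = ", "),
      call. = FALSE
    )
  }
  out <- stats::setNames(rep(NA_real_, length(validation_ids)), validation_ids)
  for (id in validation_ids) {
    train <- observations[observations$site_id != id, , drop = FALSE]
    fold <- tryCatch(
      {
        refit <- fit_survey(train, covariates, ref)
        model <- if (is.null(expert_fit)) {
          refit
        } else {
          combine_models(refit, expert_fit, alpha = alpha)
        }
        site <- covariates[covariates$site_id == id, , drop = FALSE]
        predict(model, newdata = site)
      },
      error = function(cond) {
        warning("LOOCV fold for site ", id, " failed: ", conditionMessage(cond))
        NA_real_
      }
    )
    out[id] <- fold
  }
  out
}

#' Run the full multi-source distribution study
#'
#' Fits the ground-only (G) and ground + thermal (GT) weighted logistic
#' models and the expert Beta mixed model (E); pools G_E and GT_E by
#' inverse-variance weighting; evaluates all four models on the
#' high-confidence validation set (direct predictions for G and G_E, LOOCV
#' for GT and GT_E, whose training data contain the validation sites);
#' classifies at the cutoff; and predicts all four models across the
#' visualization grid.
#'
#' The G model uses the ground-survey presences plus an equal-count random
#' draw of the generated absences (seeded, reproducible), mirroring the
#' base-model bookkeeping of a balanced ground-only dataset; its covariate
#' scaling is the reference scaling for every other dataset. A draw whose
#' small design is completely separable is rejected and redrawn.
#'
#' @param observations Survey observation table.
#' @param covariates Covariate table covering observed sites.
#' @param elicitations Elicitation table.
#' @param grid Prediction-grid covariate table (optional; `NULL` skips
#'   surface prediction).
#' @param cutoff Classification cutoff (default 0.4).
#' @param alpha Significance level for combined intervals.
#' @param seed Seed for the G-model absence draw.
#' @param nq Quadrature nodes for the expert model.
#' @param df_method Residual-df convention for the expert model.
#' @return An object of class `sdm_study`: `fits` (G, GT, E), `combined`
#'   (G_E, GT_E), `reports` (one row per model: confusion counts, accuracy,
#'   sensitivity, specificity, RMSPE), `surfaces` (grid predictions per
#'   model), `validation`, `ref`, `config`.
#' @export
run_study <- function(observations, covariates, elicitations, grid = NULL,
                      cutoff = 0.4, alpha = 0.05, seed = 1L, nq = 15L,
                      df_method = c("edf", "nominal")) {
  df_method <- match.arg(df_method)
  validate_observation_table(observations)
  validate_covariate_table(covariates[c("site_id", sdm_covariates())])
  validate_elicitation_table(elicitations)

  # base (G) dataset: ground presences + an equal random draw of absences.
  # With ~16 presences against 7 parameters a particular draw can be
  # completely separable; the draw is redrawn (deterministically, from the
  # seed) until the base fit converges.
  ground_pres <- which(observations$source == "ground" & observations$y == 1)
  abs_rows <- which(observations$y == 0)
  n_abs <- min(length(ground_pres), length(abs_rows))
  fit_g <- NULL
  for (attempt in seq_len(25L)) {
    g_abs <- with_seed(
      derive_seed(seed, paste0("g-absences", attempt)),
      sort(sample(abs_rows, n_abs))
    )
    g_obs <- observations[sort(c(ground_pres, g_abs)), , drop = FALSE]
    ref <- reference_scaling(
      covariates[match(g_obs$site_id, covariates$site_id), , drop = FALSE]
    )
    cand <- tryCatch(
      suppressWarnings(fit_survey(g_obs, covariates, ref, model_id = "G")),
      error = function(cond) NULL
    )
    if (!is.null(cand) && cand$converged) {
      fit_g <- cand
      break
    }
  }
  if (is.null(fit_g)) {
    stop(
      "base (G) model did not converge for any of 25 absence draws ",
      "(likely separation with too few ground presences)",
      call. = FALSE
    )
  }
  fit_gt <- fit_survey(observations, covariates, ref, model_id = "GT")
  fit_e <- fit_expert(elicitations, covariates, ref,
    nq = nq, df_method = df_method
  )
  g_e <- combine_models(fit_g, fit_e, alpha = alpha)
  gt_e <- combine_models(fit_gt, fit_e, alpha = alpha)

  validation <- build_validation_set(observations)
  vcov_sites <- covariates[match(validation$site_id, covariates$site_id), , drop = FALSE]

  preds <- list(
    G = predict(fit_g, newdata = vcov_sites),
    GT = loocv_predictions(observations, covariates, ref, validation$site_id),
    G_E = predict(g_e, newdata = vcov_sites),
    GT_E = loocv_predictions(
      observations, covariates, ref, validation$site_id,
      expert_fit = fit_e, alpha = alpha
    )
  )
  reports <- do.call(rbind, lapply(names(preds), function(mid) {
    p <- as.numeric(preds[[mid]])
    cm <- confusion_metrics(validation$y, classify(p, cutoff))
    cbind(
      data.frame(model = mid, cutoff = cutoff),
      cm[c("tp", "fp", "tn", "fn", "accuracy", "sensitivity", "specificity")],
      data.frame(rmspe = rmspe(validation$y, p), n_validation = cm$n)
    )
  }))
  rownames(reports) <- NULL

  surfaces <- NULL
  if (!is.null(grid)) {
    surfaces <- data.frame(
      site_id = grid$site_id,
      longitude = grid$longitude, latitude = grid$latitude,
      G = predict(fit_g, newdata = grid),
      GT = predict(fit_gt, newdata = grid),
      G_E = predict(g_e, newdata = grid),
      GT_E = predict(gt_e, newdata = grid)
    )
  }

  structure(
    list(
      fits = list(G = fit_g, GT = fit_gt, E = fit_e),
      combined = list(G_E = g_e, GT_E = gt_e),
      reports = reports, surfaces = surfaces,
      validation = validation, validation_predictions = preds, ref = ref,
      config = list(
        cutoff = cutoff, alpha = alpha, seed = seed, nq = nq,
        df_method = df_method
      )
    ),
    class = "sdm_study"
  )
}

#' @export
print.sdm_study <- function(x, digits = 3, ...) {
  cat("Multi-source species distribution study\n")
  cat(sprintf(
    "  G n = %d, GT n = %d, E n = %d; validation n = %d; cutoff = %.2f\n",
    x$fits$G$n_obs, x$fits$GT$n_obs, x$fits$E$n_obs,
    nrow(x$validation), x$config$cutoff
  ))
  cat("\nPredictive performance:\n")
  perf <- x$reports[c("model", "accuracy", "sensitivity", "specificity", "rmspe")]
  perf[-1L] <- round(perf[-1L], digits)
  print(perf, row.names = FALSE)
  invisible(x)
}

#' Write study outputs (performance report and prediction surfaces) to CSV
#'
#' @param study An `sdm_study`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study_outputs <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$reports, file.path(dir, "performance.csv"),
    row.names = FALSE
  )
  if (!is.null(study$surfaces)) {
    utils::write.csv(study$surfaces, file.path(dir, "prediction_surfaces.csv"),
      row.names = FALSE
    )
  }
  invisible(dir)
}
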