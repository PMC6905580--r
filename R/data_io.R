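# Delimited-table input/output for the three data streams: site-level
# observations (presence/absence with confidence weights), expert
# elicitations, and prediction-grid covariates. Files are comma-separated
# UTF-8 with a header row; header names are configurable through a
# column-mapping so external tables load without editing.

OBS_COLUMNS <- c(
  "site_id", "longitude", "latitude", "fpc", "rev",
  "dist_path", "dist_water", "y", "source", "weight"
)
ELIC_COLUMNS <- c(
  "expert_id", "site_id", "p_min", "p_mode", "p_max",
  "presence_confidence", "p_suitability", "suitability_confidence", "weight"
)
CONFIDENCE_LEVELS <- c("not_very_sure", "quite_sure", "very_sure")

#' Column mapping for external tables
#'
#' Builds a mapping from the package's canonical column names to the header
#' names used in an external file, so tables with different headers load
#' without editing. Unmentioned columns keep their canonical name.
#'
#' @param ... Named arguments, canonical = "file header name", e.g.
#'   `column_mapping(fpc = "FPC", dist_water = "Water")`.
#' @param file Optionally, a JSON or YAML file holding the same mapping.
#' @return Named character vector (canonical -> header).
#' @export
column_mapping <- function(..., file = NULL) {
  map <- c(...)
  if (!is.null(file)) {
    from_file <- if (grepl("\\.ya?ml$", file, ignore.case = TRUE)) {
      unlist(yaml_read_mapping(file))
    } else {
      unlist(jsonlite::read_json(file, simplifyVector = TRUE))
    }
    map <- c(from_file[setdiff(names(from_file), names(map))], map)
  }
  if (length(map) > 0L && (is.null(names(map)) || any(names(map) == ""))) {
    stop("column mapping entries must be named", call. = FALSE)
  }
  map
}

yaml_read_mapping <- function(file) {
  # very small "key: value" reader; avoids a hard yaml dependency
  lines <- readLines(file, warn = FALSE)
  lines <- lines[grepl(":", lines, fixed = TRUE)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  out <- lapply(kv, function(x) trimws(paste(x[-1L], collapse = ":")))
  names(out) <- vapply(kv, function(x) trimws(x[[1L]]), character(1))
  out
}

rename_with_mapping <- function(df, required, mapping, what) {
  header <- required
  if (length(mapping) > 0L) {
    idx <- match(names(mapping), required)
    header[idx[!is.na(idx)]] <- unname(mapping[!is.na(idx)])
  }
  missing_cols <- setdiff(header, names(df))
  if (length(missing_cols) > 0L) {
    stop(
      what, " table is missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  out <- df[header]
  names(out) <- required
  out
}

validate_range <- function(x, lo, hi, name, rows_are = "row") {
  bad <- which(!is.finite(x) | x < lo | x > hi)
  if (length(bad) > 0L) {
    stop(
      sprintf(
        "%s out of range [%g, %g] at %s %s",
        name, lo, hi, rows_are, paste(utils::head(bad, 5L), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  invisible(x)
}

validate_covariate_table <- function(cov) {
  if (nrow(cov) == 0L) {
    return(invisible(cov))
  }
  if (anyDuplicated(cov$site_id)) {
    stop("duplicate site_id values: ",
      paste(utils::head(unique(cov$site_id[duplicated(cov$site_id)]), 5L),
        collapse = ", "
      ),
      call. = FALSE
    )
  }
  validate_range(cov$fpc, 0, 100, "fpc")
  if (!all(cov$rev %in% c(0, 1))) {
    stop("rev must be 0 or 1 at row ",
      paste(utils::head(which(!cov$rev %in% c(0, 1)), 5L), collapse = ", "),
      call. = FALSE
    )
  }
  validate_range(cov$dist_path, 0, Inf, "dist_path")
  validate_range(cov$dist_water, 0, Inf, "dist_water")
  invisible(cov)
}

validate_observation_table <- function(obs) {
  if (nrow(obs) == 0L) {
    return(invisible(obs))
  }
  if (!all(obs$y %in% c(0, 1))) {
    stop("presence indicator y must be 0 or 1 at row ",
      paste(utils::head(which(!obs$y %in% c(0, 1)), 5L), collapse = ", "),
      call. = FALSE
    )
  }
  bad_w <- which(!is.finite(obs$weight) | obs$weight <= 0 | obs$weight > 1)
  if (length(bad_w) > 0L) {
    stop("weight must lie in (0, 1] at row ",
      paste(utils::head(bad_w, 5L), collapse = ", "),
      call. = FALSE
    )
  }
  invisible(obs)
}

validate_elicitation_table <- function(el) {
  if (nrow(el) == 0L) {
    return(invisible(el))
  }
  for (v in c("p_min", "p_mode", "p_max", "p_suitability")) {
    validate_range(el[[v]], 0, 1, v)
  }
  bad <- which(el$p_min > el$p_mode | el$p_mode > el$p_max)
  if (length(bad) > 0L) {
    stop("need p_min <= p_mode <= p_max at row ",
      paste(utils::head(bad, 5L), collapse = ", "),
      call. = FALSE
    )
  }
  for (v in c("presence_confidence", "suitability_confidence")) {
    if (!all(el[[v]] %in% CONFIDENCE_LEVELS)) {
      stop(v, " must be one of ", paste(CONFIDENCE_LEVELS, collapse = ", "),
        call. = FALSE
      )
    }
  }
  if (!all(el$weight %in% c(0.50, 0.75, 1.00))) {
    stop("elicitation weight must be one of 0.50, 0.75, 1.00", call. = FALSE)
  }
  invisible(el)
}

#' Load site-level observations and covariates from a CSV file
#'
#' Reads a table with one row per weighted presence/absence observation
#' (site id, coordinates, the six habitat covariates, presence indicator,
#' data source and confidence weight), validates it against the domain
#' invariants, and splits it into an observation table and a covariate
#' table. Row order is preserved.
#'
#' @param path CSV file with a header row.
#' @param mapping Optional [column_mapping()] translating canonical column
#'   names to the file's header names.
#' @return A list with elements `observations` (site_id, source, y, weight)
#'   and `covariates` (site_id plus the [sdm_covariates()] columns).
#' @export
load_observations <- function(path, mapping = column_mapping()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- rename_with_mapping(raw, OBS_COLUMNS, mapping, "observation")
  cov <- df[c("site_id", sdm_covariates())]
  obs <- df[c("site_id", "source", "y", "weight")]
  validate_covariate_table(cov)
  validate_observation_table(obs)
  list(observations = obs, covariates = cov)
}

#' Load an expert-elicitation table from a CSV file
#'
#' One row per expert x viewed site: the elicited minimum/mode/maximum
#' presence probabilities with their confidence category, the habitat
#' suitability probability with its confidence category, and the confidence
#' weight. If the `weight` column is absent it is derived from
#' `suitability_confidence` via [expert_weight()].
#'
#' @inheritParams load_observations
#' @return Validated data frame with the canonical elicitation columns.
#' @export
load_elicitations <- function(path, mapping = column_mapping()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  has_weight <- "weight" %in% c(names(raw), unname(mapping["weight"]))
  cols <- if (has_weight) ELIC_COLUMNS else setdiff(ELIC_COLUMNS, "weight")
  df <- rename_with_mapping(raw, cols, mapping, "elicitation")
  if (!has_weight) df$weight <- expert_weight(df$suitability_confidence)
  validate_elicitation_table(df)
  df[ELIC_COLUMNS]
}

#' Load a prediction-grid covariate table from a CSV file
#'
#' @inheritParams load_observations
#' @return Validated covariate data frame (site_id plus [sdm_covariates()]).
#' @export
load_grid <- function(path, mapping = column_mapping()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- rename_with_mapping(
    raw, c("site_id", sdm_covariates()), mapping, "grid"
  )
  validate_covariate_table(df)
  df
}

#' Write a joined observation + covariate table to CSV
#'
#' Inverse of [load_observations()]; the written file round-trips.
#'
#' @param observations Observation table (site_id, source, y, weight).
#' @param covariates Covariate table (site_id plus [sdm_covariates()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, covariates, path) {
  covariates <- covariates[c("site_id", sdm_covariates())]
  df <- merge(covariates, observations, by = "site_id", sort = FALSE)
  df <- df[match(observations$site_id, df$site_id), OBS_COLUMNS]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an elicitation table to CSV
#' @param elicitations Elicitation table with the canonical columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_elicitations <- function(elicitations, path) {
  utils::write.csv(elicitations[ELIC_COLUMNS], path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
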