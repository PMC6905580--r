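#' Default confidence-weight table
#'
#' The study design assigns every observation a confidence weight used as a
#' prior case weight in the likelihood. Ground-survey presences are certain
#' (1.00); thermal-imagery presences carry the detection algorithm's
#' confidence class (1.00 confirmed, 0.90 uncertain-but-confirmed, 0.50
#' unconfirmed); randomly generated absences carry 0.90 because false
#' negatives are unlikely but possible; expert probabilities carry 1.00,
#' 0.75 or 0.50 for "very sure", "quite sure" and "not very sure".
#'
#' @return A data frame with columns `source`, `category` and `weight`, one
#'   row per valid (source, category) pair.
#' @seealso [assign_weight()]
#' @export
#' @examples
#' weight_table()
weight_table <- function() {
  data.frame(
    source = c(
      "ground",
      "thermal", "thermal", "thermal",
      "absence",
      "expert", "expert", "expert"
    ),
    category = c(
      "presence",
      "high_confirmed", "uncertain_confirmed", "uncertain_unconfirmed",
      "generated",
      "very_sure", "quite_sure", "not_very_sure"
    ),
    weight = c(1.00, 1.00, 0.90, 0.50, 0.90, 1.00, 0.75, 0.50),
    stringsAsFactors = FALSE
  )
}

#' Map a data source and confidence category to its weight
#'
#' Pure lookup into the confidence-weight table. Vectorised over
#' `source`/`category`.
#'
#' @param source Data-source tag: `"ground"`, `"thermal"`, `"absence"` or
#'   `"expert"`.
#' @param category Detection/confidence class; see [weight_table()] for the
#'   valid pairs.
#' @param table Weight table to look up in; defaults to [weight_table()].
#'   Supplying a modified table overrides the default mapping.
#' @return Numeric weight(s) in (0, 1].
#' @export
#' @examples
#' assign_weight("ground", "presence")            # 1.00
#' assign_weight("thermal", "uncertain_unconfirmed")  # 0.50
#' assign_weight("expert", "quite_sure")          # 0.75
assign_weight <- function(source, category, table = weight_table()) {
  stopifnot(length(source) == length(category))
  key <- paste(source, category, sep = "\r")
  tab_key <- paste(table$source, table$category, sep = "\r")
  idx <- match(key, tab_key)
  if (anyNA(idx)) {
    bad <- paste0("(", source[is.na(idx)], ", ", category[is.na(idx)], ")")
    stop(
      "unknown (source, category) pair(s): ", paste(unique(bad), collapse = ", "),
      "; valid pairs are: ",
      paste0("(", tab_key[order(tab_key)], ")", collapse = ", ") |>
        gsub(pattern = "\r", replacement = ", "),
      call. = FALSE
    )
  }
  table$weight[idx]
}

#' Map expert confidence categories to weights
#'
#' Convenience wrapper around [assign_weight()] for the three elicitation
#' confidence categories.
#'
#' @param category Character vector with values among `"not_very_sure"`,
#'   `"quite_sure"`, `"very_sure"`.
#' @return Numeric weights in {0.50, 0.75, 1.00}.
#' @export
expert_weight <- function(category) {
  assign_weight(rep("expert", length(category)), category)
}
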