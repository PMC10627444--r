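# Ordinal management categories and recommendation lookup.

#' Ordinal High/Low management key
#'
#' Classifies each unit's category-score triple: condition High iff its
#' score >= 6, adaptive capacity High iff >= 6, vulnerability High iff its
#' (negative) score <= -6.  The key concatenates the three results in the
#' order Current Condition-Vulnerability-Adaptive Capacity, e.g.
#' `"High-Low-High"`.
#'
#' @param condition,vulnerability,adaptive integer category scores
#'   (vulnerability negative).
#' @param thresholds list with `high` (default 6) and `vuln_high`
#'   (default -6).
#' @return character keys; `NA` wherever any score is missing.
#' @examples
#' ordinal_classify(7, -3, 8)   # "High-Low-High"
#' ordinal_classify(6, -6, 6)   # "High-High-High"
#' @export
ordinal_classify <- function(condition, vulnerability, adaptive,
                             thresholds = list(high = 6, vuln_high = -6)) {
  hl <- function(x) ifelse(x, "High", "Low")
  key <- paste(hl(condition >= thresholds$high),
               hl(vulnerability <= thresholds$vuln_high),
               hl(adaptive >= thresholds$high), sep = "-")
  key[!is.finite(condition) | !is.finite(vulnerability) |
        !is.finite(adaptive)] <- NA_character_
  key
}

#' All eight management keys
#'
#' @return character vector of the 8 possible keys in a fixed order.
#' @export
management_keys <- function() {
  g <- expand.grid(a = c("High", "Low"), v = c("High", "Low"),
                   c = c("High", "Low"), stringsAsFactors = FALSE)
  paste(g$c, g$v, g$a, sep = "-")
}

#' Default recommendation table
#'
#' Maps each of the eight management keys to an ordered list of management
#' actions.  Two entries carry substantive defaults — High-Low-High
#' (conservation priority: maintain current marsh extent through
#' conservation actions) and Low-High-Low (limited protection value; major
#' restoration, removal of barriers to migration, experimental restoration
#' methods).  The remaining six ship as clearly labelled placeholders: the
#' full per-key action lists are expected to be supplied as data
#' (`recommendations.json`) by the user.
#'
#' @return named list: key -> character vector of actions.
#' @export
default_recommendations <- function() {
  rec <- stats::setNames(
    lapply(management_keys(), function(k) {
      sprintf("PLACEHOLDER: supply site-specific management actions for %s", k)
    }),
    management_keys())
  rec[["High-Low-High"]] <- c(
    "High priority for conservation",
    "Maintain current marsh extent through conservation actions",
    "Protect adjacent migration corridors")
  rec[["Low-High-Low"]] <- c(
    "Limited protection value in current state",
    "Major restoration required",
    "Removal of barriers to migration",
    "Consider experimental restoration methods")
  rec
}

#' Look up management recommendations for a key
#'
#' @param key a management key string (e.g. `"High-Low-High"`).
#' @param table recommendation table, a named list as
#'   [default_recommendations()]; must cover all 8 keys.
#' @return ordered character vector of actions.
#' @export
recommend <- function(key, table = default_recommendations()) {
  missing_keys <- setdiff(management_keys(), names(table))
  if (length(missing_keys)) {
    stop("recommendation table incomplete, missing: ",
         paste(missing_keys, collapse = ", "))
  }
  if (!key %in% management_keys()) stop("unknown management key: ", key)
  table[[key]]
}
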