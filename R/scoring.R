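# Decile-rank resilience scoring.
#
# Ranks are always relative to the analysis cohort: decile breaks (the
# 10th..90th percentiles under the linear-interpolation quantile convention)
# cut each metric into ten bins; a unit's rank is the bin holding its value.
# Negative-influence metrics are multiplied by -1 after ranking; weighted
# category sums are re-ranked into category scores (vulnerability on a
# negative -1..-10 scale); category scores sum to the total, which is ranked
# once more into the 1..10 total resilience score.

#' Metric directions and weights
#'
#' Per-metric sign (+1 positive influence on resilience, -1 negative) and
#' summation weight.  Defaults: negative for unvegetated edge ratio,
#' % impervious, % agricultural, soil erodibility, % below MHHW, % below MTL
#' and % hardened shoreline; positive for the rest; weight 1.5 on hardened
#' shoreline and 2 on the migration ratio, 1 elsewhere.
#'
#' @param sign named numeric vector (+1/-1) per metric.
#' @param weight named numeric vector per metric.
#' @return A `metric_directions` list with `sign` and `weight`.
#' @export
metric_directions <- function(sign = NULL, weight = NULL) {
  mc <- metric_columns()
  s <- stats::setNames(rep(1, length(mc$all)), mc$all)
  s[c("unveg_edge_ratio", "pct_impervious", "pct_agricultural",
      "soil_erodibility", "pct_below_mhhw", "pct_below_mtl",
      "pct_hardened")] <- -1
  w <- stats::setNames(rep(1, length(mc$all)), mc$all)
  w["pct_hardened"] <- 1.5
  w["migration_ratio"] <- 2.0
  if (!is.null(sign)) s[names(sign)] <- sign
  if (!is.null(weight)) w[names(weight)] <- weight
  if (!all(s %in% c(-1, 1))) stop("signs must be +1 or -1")
  structure(list(sign = s, weight = w), class = "metric_directions")
}

#' Decile breaks
#'
#' The nine cut points (10th..90th percentiles) defining ten equal-
#' probability bins over the cohort's values, using the linear-interpolation
#' quantile convention (R type 7).  Ties in the data legitimately produce
#' duplicated breaks.
#'
#' @param values numeric vector; `NA`s dropped.
#' @return numeric length-9, non-decreasing.
#' @export
decile_breaks <- function(values) {
  v <- values[is.finite(values)]
  if (!length(v)) stop("no finite values to compute decile breaks from")
  stats::quantile(v, probs = seq(0.1, 0.9, by = 0.1), names = FALSE, type = 7)
}

#' Rank a value against decile breaks
#'
#' rank = 1 + number of breaks strictly below the value; a value tied with a
#' break falls in the lower bin.
#'
#' @param v numeric vector of values (`NA` gives `NA` rank).
#' @param breaks length-9 non-decreasing break values.
#' @return integer ranks in 1..10.
#' @export
rank_value <- function(v, breaks) {
  vapply(v, function(x) {
    if (!is.finite(x)) return(NA_integer_)
    1L + sum(breaks < x)
  }, 1L)
}

#' Score all metrics of a cohort
#'
#' Per metric: decile breaks over the cohort, rank per unit, signed score =
#' sign x rank.  A unit missing a metric gets a missing rank/score for that
#' metric and does not enter that metric's break computation.
#'
#' @param metrics data.frame with `unit_id` and the 13 metric columns
#'   ([metric_columns()]); extra columns are carried through untouched.
#' @param dirs a [metric_directions()].
#' @return data.frame with `unit_id`, `metric_rank_<m>` and
#'   `metric_score_<m>` columns.
#' @export
score_metrics <- function(metrics, dirs = metric_directions()) {
  mc <- metric_columns()
  missing_cols <- setdiff(mc$all, names(metrics))
  if (length(missing_cols)) {
    stop("metric table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(metrics$unit_id)) stop("duplicate unit_id in metric table")
  if (nrow(metrics) < 2) stop("scoring needs a cohort of >= 2 units")
  out <- data.frame(unit_id = metrics$unit_id, stringsAsFactors = FALSE)
  for (m in mc$all) {
    v <- metrics[[m]]
    if (all(!is.finite(v))) {
      rk <- rep(NA_integer_, length(v))
    } else {
      br <- decile_breaks(v)
      rk <- rank_value(v, br)
    }
    out[[paste0("metric_rank_", m)]] <- rk
    out[[paste0("metric_score_", m)]] <- dirs$sign[[m]] * rk
  }
  out
}

#' Weighted category sum for each unit
#'
#' Sum of weight x signed metric score over the category's metrics.  A unit
#' missing any metric in the category gets a missing sum.
#'
#' @param scored output of [score_metrics()].
#' @param dirs a [metric_directions()].
#' @param category `"condition"`, `"vulnerability"` or `"adaptive"`.
#' @return numeric vector of sums, one per unit.
#' @export
category_sum <- function(scored, dirs = metric_directions(),
                         category = c("condition", "vulnerability", "adaptive")) {
  category <- match.arg(category)
  mets <- metric_columns()[[category]]
  s <- rep(0, nrow(scored))
  for (m in mets) {
    s <- s + dirs$weight[[m]] * scored[[paste0("metric_score_", m)]]
  }
  s
}

#' Category resilience scores from category sums
#'
#' Condition and adaptive capacity: decile rank of the sums, 1..10 (higher
#' sum = higher score).  Vulnerability: the sums are negated before ranking
#' so the most vulnerable unit ranks 10, then the rank is multiplied by -1,
#' giving the -1 (low) .. -10 (high vulnerability) scale.  Units with a
#' missing sum are excluded from the break computation and get `NA`.
#'
#' @param sums numeric vector of category sums.
#' @param category `"condition"`, `"vulnerability"` or `"adaptive"`.
#' @return integer scores (1..10, or -10..-1 for vulnerability).
#' @export
category_score <- function(sums,
                           category = c("condition", "vulnerability", "adaptive")) {
  category <- match.arg(category)
  v <- if (category == "vulnerability") -sums else sums
  if (all(!is.finite(v))) return(rep(NA_integer_, length(sums)))
  rk <- rank_value(v, decile_breaks(v))
  if (category == "vulnerability") -rk else rk
}

#' Full score table for a metric-table cohort
#'
#' Runs the complete scoring calculus: metric ranks and signed scores,
#' weighted category sums, category scores, total sum and total score, the
#' ordinal High/Low triple and the concatenated management key.
#'
#' @inheritParams score_metrics
#' @param thresholds ordinal cut points, see [ordinal_classify()].
#' @return data.frame (`score_table`): `unit_id`, carried-through group
#'   columns, per-metric ranks/scores, `sum_condition`, `sum_vulnerability`,
#'   `sum_adaptive`, `score_condition`, `score_vulnerability`,
#'   `score_adaptive`, `total_sum`, `total_score`, `management_key`.
#' @examples
#' tab <- generate_metric_table(seed = 1, n_units = 20)
#' st <- score_table(tab)
#' head(st[, c("unit_id", "score_condition", "score_vulnerability",
#'             "score_adaptive", "total_score", "management_key")])
#' @export
score_table <- function(metrics, dirs = metric_directions(),
                        thresholds = list(high = 6, vuln_high = -6)) {
  scored <- score_metrics(metrics, dirs)
  scored$sum_condition <- category_sum(scored, dirs, "condition")
  scored$sum_vulnerability <- category_sum(scored, dirs, "vulnerability")
  scored$sum_adaptive <- category_sum(scored, dirs, "adaptive")
  scored$score_condition <- category_score(scored$sum_condition, "condition")
  scored$score_vulnerability <- category_score(scored$sum_vulnerability,
                                               "vulnerability")
  scored$score_adaptive <- category_score(scored$sum_adaptive, "adaptive")
  scored$total_sum <- scored$score_condition + scored$score_vulnerability +
    scored$score_adaptive
  ok <- is.finite(scored$total_sum)
  scored$total_score <- NA_integer_
  if (any(ok)) {
    br <- decile_breaks(scored$total_sum[ok])
    scored$total_score[ok] <- rank_value(scored$total_sum[ok], br)
  }
  scored$management_key <- ordinal_classify(scored$score_condition,
                                            scored$score_vulnerability,
                                            scored$score_adaptive,
                                            thresholds = thresholds)
  # carry grouping columns through
  extra <- setdiff(names(metrics), c("unit_id", metric_columns()$all))
  for (cn in extra) scored[[cn]] <- metrics[[cn]]
  class(scored) <- c("score_table", "data.frame")
  scored
}
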