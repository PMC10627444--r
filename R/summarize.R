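# Group-level summaries: mean +/- SD per category and total, management-key
# contingency tables, and the best/worst metric per group.

#' Summarize scores by a grouping label
#'
#' Per group: unit count, mean and sample SD (n-1 denominator) of each
#' category score and the total score, counts per management key, and the
#' top positive / top negative metric by group-mean signed metric score.
#' Units with missing values are excluded column-wise.
#'
#' @param scores a [score_table()] data.frame.
#' @param by name of a grouping column in `scores`; `NULL` summarizes all
#'   units as one `"all"` group.
#' @param sd_denominator `"n-1"` (sample, default) or `"n"` (population).
#' @return data.frame, one row per group, with columns `group`, `n_units`,
#'   `mean_*`/`sd_*` for the three categories and total,
#'   `top_positive_metric`, `top_negative_metric`, and `n_<key>` counts.
#' @export
group_summary <- function(scores, by = NULL, sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  grp <- if (is.null(by)) rep("all", nrow(scores)) else {
    if (!by %in% names(scores)) stop("no grouping column '", by, "' in scores")
    as.character(scores[[by]])
  }
  sdev <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2) return(if (length(x) == 1) 0 else NA_real_)
    s2 <- stats::var(x)
    if (sd_denominator == "n") s2 <- s2 * (length(x) - 1) / length(x)
    sqrt(s2)
  }
  mn <- function(x) { x <- x[is.finite(x)]; if (!length(x)) NA_real_ else mean(x) }
  cols <- c(condition = "score_condition", vulnerability = "score_vulnerability",
            adaptive = "score_adaptive", total = "total_score")
  keys <- management_keys()
  groups <- unique(grp[!is.na(grp)])
  rows <- lapply(groups, function(gname) {
    gi <- which(grp == gname)
    if (!length(gi)) return(NULL)
    row <- data.frame(group = gname, n_units = length(gi),
                      stringsAsFactors = FALSE)
    for (nm in names(cols)) {
      row[[paste0("mean_", nm)]] <- mn(scores[[cols[nm]]][gi])
      row[[paste0("sd_", nm)]] <- sdev(scores[[cols[nm]]][gi])
    }
    ex <- extreme_metrics(scores[gi, , drop = FALSE])
    row$top_positive_metric <- ex[["top_positive_metric"]]
    row$top_negative_metric <- ex[["top_negative_metric"]]
    for (k in keys) {
      row[[paste0("n_", gsub("-", "_", k))]] <-
        sum(scores$management_key[gi] == k, na.rm = TRUE)
    }
    row
  })
  do.call(rbind, rows)
}

#' Best and worst metric of a group
#'
#' Metrics ranked by group-mean signed metric score; returns the argmax
#' ("the most beneficial factor") and argmin ("the biggest challenge").
#' Ties break by the canonical metric order of [metric_columns()].
#'
#' @param scores a [score_table()] subset (rows of one group).
#' @return named character length-2: `top_positive_metric`,
#'   `top_negative_metric`.
#' @export
extreme_metrics <- function(scores) {
  mets <- metric_columns()$all
  means <- vapply(mets, function(m) {
    v <- scores[[paste0("metric_score_", m)]]
    v <- v[is.finite(v)]
    if (!length(v)) NA_real_ else mean(v)
  }, 0)
  if (all(is.na(means))) {
    return(c(top_positive_metric = NA_character_,
             top_negative_metric = NA_character_))
  }
  c(top_positive_metric = mets[which.max(means)],
    top_negative_metric = mets[which.min(means)])
}

#' Management-key contingency table
#'
#' Counts of units per (management key x group), with row and column totals,
#' mirroring a wide summary-table layout (keys as rows, groups as columns,
#' `Total` margins).
#'
#' @param scores a [score_table()] data.frame with `management_key`.
#' @param by grouping column name; `NULL` = single `"all"` group.
#' @return data.frame: `management_key` rows (8 keys + `"Total"`), one
#'   column per group plus `Total`.
#' @export
category_count_table <- function(scores, by = NULL) {
  grp <- if (is.null(by)) rep("all", nrow(scores)) else as.character(scores[[by]])
  keys <- management_keys()
  ok <- !is.na(scores$management_key) & !is.na(grp)
  groups <- sort(unique(grp[ok]))
  out <- data.frame(management_key = c(keys, "Total"),
                    stringsAsFactors = FALSE)
  for (gname in groups) {
    cnt <- vapply(keys, function(k) {
      sum(ok & scores$management_key == k & grp == gname)
    }, 0L)
    out[[gname]] <- c(cnt, sum(cnt))
  }
  gcols <- setdiff(names(out), "management_key")
  out$Total <- if (length(gcols) == 1) out[[gcols]] else
    rowSums(as.matrix(out[, gcols, drop = FALSE]))
  out
}
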