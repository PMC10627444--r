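#' Bundled example summary tables from a national application
#'
#' Two small tables transcribed from a published contiguous-US application
#' of the framework, shipped as worked-example inputs:
#'
#' * `national_example_counts()` — counts of marsh units per management key
#'   and coastal region (1,984 units total) in the wide layout produced by
#'   [category_count_table()], without the margin rows.
#' * `gulf_islands_example()` — subgroup summary for an eight-unit national
#'   seashore: unit counts, mean and SD of the total resilience score for
#'   its western (n = 5) and eastern (n = 3) island groups.
#'
#' @return data.frames (see above).
#' @examples
#' counts <- national_example_counts()
#' colSums(counts[, -1])
#' @export
national_example_counts <- function() {
  utils::read.csv(system.file("extdata", "national_counts.csv",
                              package = "marshres"),
                  check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname national_example_counts
#' @export
gulf_islands_example <- function() {
  utils::read.csv(system.file("extdata", "gulf_islands_groups.csv",
                              package = "marshres"),
                  stringsAsFactors = FALSE)
}

#' Margin arithmetic over a wide management-key count table
#'
#' Adds the row (`Total` column) and column (`Total` row) margins to a wide
#' counts table such as [national_example_counts()], and computes the share
#' of units per key.
#'
#' @param counts data.frame: `management_key` plus one numeric column per
#'   group.
#' @return list with `table` (margins added) and `key_percent` (named
#'   percentage of the grand total per management key).
#' @export
count_table_margins <- function(counts) {
  gcols <- setdiff(names(counts), "management_key")
  mat <- as.matrix(counts[, gcols, drop = FALSE])
  row_tot <- rowSums(mat)
  col_tot <- colSums(mat)
  grand <- sum(mat)
  out <- counts
  out$Total <- row_tot
  total_row <- c(list(management_key = "Total"), as.list(col_tot),
                 list(Total = grand))
  out <- rbind(out, as.data.frame(total_row, check.names = FALSE))
  list(table = out,
       key_percent = stats::setNames(100 * row_tot / grand,
                                     counts$management_key))
}

#' Size-weighted pooled mean of subgroup means
#'
#' The overall mean of a score equals the unit-count-weighted mean of its
#' subgroup means (the pooled-mean identity used to check printed subgroup
#' summaries against a printed overall mean).
#'
#' @param n unit counts per subgroup.
#' @param means subgroup means.
#' @return pooled mean.
#' @export
pooled_mean <- function(n, means) {
  if (length(n) != length(means)) stop("n and means must match in length")
  sum(n * means) / sum(n)
}
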