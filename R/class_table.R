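#' Land-cover class attribute table
#'
#' A `class_table` maps integer land-cover class codes to the semantic flags
#' the resilience metrics need: whether a class is tidal marsh, vegetated,
#' open water, natural, agricultural, or available as marsh migration space,
#' plus a per-class impervious fraction used to weight development intensity.
#'
#' The default table mirrors the semantics of 30 m coastal land-cover
#' products (open water, estuarine emergent marsh, unvegetated flat,
#' natural upland, agriculture, and three developed intensities with
#' impervious fractions 0.25 / 0.60 / 0.90), but every field is
#' user-configurable because class-to-flag mappings differ between products.
#'
#' @param codes integer vector of class codes (unique).
#' @param label character labels, one per code.
#' @param is_marsh,is_vegetated,is_water,is_natural,is_agricultural,is_migratable
#'   logical flags, one per code.
#' @param impervious_fraction numeric in \[0, 1\], one per code.
#' @return A `class_table`: a data.frame with one row per class code.
#' @examples
#' ct <- default_class_table()
#' ct[ct$is_marsh, ]
#' @export
class_table <- function(codes, label, is_marsh, is_vegetated, is_water,
                        is_natural, is_agricultural, is_migratable,
                        impervious_fraction) {
  codes <- as.integer(codes)
  if (anyDuplicated(codes)) {
    stop("class codes must be unique, duplicated: ",
         paste(codes[duplicated(codes)], collapse = ", "))
  }
  tab <- data.frame(
    code = codes,
    label = as.character(label),
    is_marsh = as.logical(is_marsh),
    is_vegetated = as.logical(is_vegetated),
    is_water = as.logical(is_water),
    is_natural = as.logical(is_natural),
    is_agricultural = as.logical(is_agricultural),
    is_migratable = as.logical(is_migratable),
    impervious_fraction = as.numeric(impervious_fraction),
    stringsAsFactors = FALSE
  )
  if (any(tab$impervious_fraction < 0 | tab$impervious_fraction > 1)) {
    stop("impervious_fraction must lie in [0, 1]")
  }
  if (any(tab$is_marsh & tab$is_water)) {
    stop("a class cannot be both marsh and open water")
  }
  bad <- tab$impervious_fraction > 0 & (tab$is_natural | tab$is_marsh)
  if (any(bad)) {
    stop("impervious classes cannot be flagged natural or marsh: codes ",
         paste(tab$code[bad], collapse = ", "))
  }
  class(tab) <- c("class_table", "data.frame")
  tab
}

#' @rdname class_table
#' @export
default_class_table <- function() {
  class_table(
    codes = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L),
    label = c("open_water", "estuarine_marsh", "unvegetated_flat",
              "natural_upland", "agriculture",
              "developed_low", "developed_medium", "developed_high"),
    is_marsh        = c(FALSE, TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    is_vegetated    = c(FALSE, TRUE,  FALSE, TRUE,  TRUE,  FALSE, FALSE, FALSE),
    is_water        = c(TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    is_natural      = c(FALSE, FALSE, FALSE, TRUE,  FALSE, FALSE, FALSE, FALSE),
    is_agricultural = c(FALSE, FALSE, FALSE, FALSE, TRUE,  FALSE, FALSE, FALSE),
    # migration space: low-lying natural upland or agriculture; developed and
    # impervious surfaces are barriers and never convert to marsh
    is_migratable   = c(FALSE, FALSE, FALSE, TRUE,  TRUE,  FALSE, FALSE, FALSE),
    impervious_fraction = c(0, 0, 0, 0, 0, 0.25, 0.60, 0.90)
  )
}

# flag lookup: named logical/numeric vector indexed by class code as character
ct_flag <- function(ct, field) {
  stats::setNames(ct[[field]], as.character(ct$code))
}

# map a code matrix to one flag; NA (nodata) stays NA
codes_to_flag <- function(codes, ct, field) {
  v <- ct_flag(ct, field)[as.character(codes)]
  out <- matrix(v, nrow = nrow(codes), ncol = ncol(codes))
  out
}
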