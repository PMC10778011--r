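#' Breslow thickness categories
#'
#' The three clinically relevant Breslow thickness groups used for melanoma
#' staging: thinner than 1 mm, between 1 and 2 mm (both boundaries
#' inclusive), and thicker than 2 mm. The ordering reflects increasing
#' tumour depth.
#'
#' @return Character vector of the three ordered category labels.
#' @export
#' @examples
#' breslow_levels()
breslow_levels <- function() {
  c("<1mm", "1-2mm", ">2mm")
}

#' Bin a continuous Breslow thickness into its clinical category
#'
#' Thickness below 1 mm maps to `<1mm`, between 1 and 2 mm (inclusive on
#' both ends) to `1-2mm`, and above 2 mm to `>2mm`. The middle interval is
#' closed so that the three groups are exhaustive and boundary cases fall
#' into the intermediate-risk group.
#'
#' @param thickness_mm Numeric vector of Breslow thicknesses in millimetres;
#'   all values must be strictly positive.
#' @return An ordered factor with levels [breslow_levels()].
#' @export
#' @examples
#' categorize_thickness(c(0.5, 1, 1.5, 2, 3.2))
categorize_thickness <- function(thickness_mm) {
  if (!is.numeric(thickness_mm)) {
    abort("`thickness_mm` must be numeric.")
  }
  if (any(!is.finite(thickness_mm)) || any(thickness_mm <= 0)) {
    abort("All thickness values must be finite and > 0 mm.")
  }
  lab <- ifelse(thickness_mm < 1, "<1mm",
    ifelse(thickness_mm <= 2, "1-2mm", ">2mm")
  )
  breslow_factor(lab)
}

#' Coerce labels to the Breslow category factor
#'
#' @param x Character vector or factor of category labels.
#' @return Ordered factor with levels [breslow_levels()].
#' @export
breslow_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), breslow_levels())
  if (length(bad)) {
    abort(paste0(
      "Unknown Breslow category label(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  factor(x, levels = breslow_levels(), ordered = TRUE)
}
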