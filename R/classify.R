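#' Stage lesions with the multispectral threshold decision tree
#'
#' Implements the three-threshold staging tree. Circularity splits first:
#' irregular lesions (circularity below the threshold) are staged by their
#' mean G intensity — bright G (at or above threshold) means `<1mm`, dark G
#' means `1-2mm`. Regular lesions (circularity at or above the threshold)
#' are staged by mean IR intensity — dark IR (below threshold) means
#' `>2mm`, bright IR means `1-2mm`. "Over" branches are closed (`>=`),
#' "under" branches open (`<`), so every feature vector maps to exactly one
#' category. Solidity, roundness and the R channel are measured by the
#' feature extractor but deliberately unused here.
#'
#' @param features Data frame with columns `circularity`, `mean_G`,
#'   `mean_IR` (one row per lesion), e.g. from [extract_cohort_features()].
#' @param config A [threshold_config()] object.
#' @return `features` as a tibble with an `msi_category` factor column
#'   appended.
#' @export
#' @examples
#' classify_msi(tibble::tibble(
#'   circularity = c(0.5, 0.5, 0.9, 0.9),
#'   mean_G = c(120, 5, 120, 120),
#'   mean_IR = c(150, 150, 100, 150)
#' ))
classify_msi <- function(features, config = threshold_config()) {
  if (!inherits(config, "threshold_config")) {
    abort("`config` must be created by threshold_config().",
      class = "breslowmsi_config_error"
    )
  }
  need <- c("circularity", "mean_G", "mean_IR")
  missing_cols <- setdiff(need, names(features))
  if (length(missing_cols)) {
    abort(paste0(
      "`features` is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "breslowmsi_input_error")
  }
  for (col in need) {
    if (any(!is.finite(features[[col]]))) {
      abort(paste0("`", col, "` contains non-finite values."),
        class = "breslowmsi_input_error"
      )
    }
  }
  lab <- ifelse(
    features$circularity < config$circularity_threshold,
    ifelse(features$mean_G >= config$g_threshold, "<1mm", "1-2mm"),
    ifelse(features$mean_IR < config$ir_threshold, ">2mm", "1-2mm")
  )
  mutate(as_tibble(features), msi_category = breslow_factor(lab))
}
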