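#' Reconstruct a confusion matrix's diagonal and marginals from per-class rows
#'
#' Published accuracy tables usually print, per category, the stratum size
#' `n` and the one-vs-rest sensitivity and specificity. Those rows pin down
#' the confusion matrix's diagonal and marginal totals: the diagonal is
#' `round(sens_k * n_k)`, the false positives of category k are
#' `(N - n_k) - round(spec_k * (N - n_k))`, and the predicted-column total
#' is their sum. The result is accepted only if the rounding is globally
#' consistent, i.e. total false positives equal total false negatives.
#'
#' @param n Integer vector of per-category stratum sizes (true counts).
#' @param sensitivity,specificity Numeric vectors of per-category
#'   proportions in `[0, 1]`.
#' @return A list of class `breslow_confusion_recon` with `diagonal`,
#'   `row_totals`, `col_totals`, `fp`, `fn` and `n_total`.
#' @export
#' @examples
#' confusion_from_class_metrics(
#'   n = c(56, 15, 27),
#'   sensitivity = c(0.982, 0.800, 0.852),
#'   specificity = c(0.952, 0.940, 0.986)
#' )
confusion_from_class_metrics <- function(n, sensitivity, specificity) {
  if (length(n) != length(sensitivity) || length(n) != length(specificity)) {
    abort("Input lengths differ.", class = "breslowmsi_input_error")
  }
  if (any(n <= 0)) {
    abort("All stratum sizes must be positive.",
      class = "breslowmsi_input_error"
    )
  }
  if (any(sensitivity < 0 | sensitivity > 1) ||
    any(specificity < 0 | specificity > 1)) {
    abort("Proportions must be in [0, 1].", class = "breslowmsi_input_error")
  }
  n_total <- sum(n)
  diagonal <- round(sensitivity * n)
  fn <- n - diagonal
  neg <- n_total - n
  tn <- round(specificity * neg)
  fp <- neg - tn
  if (abs(sum(fp) - sum(fn)) > 1e-9) {
    abort(
      sprintf(
        "Inconsistent rows after rounding: total FP = %d but total FN = %d.",
        sum(fp), sum(fn)
      ),
      class = "breslowmsi_reconciliation_error"
    )
  }
  structure(
    list(
      diagonal = diagonal,
      row_totals = n,
      col_totals = diagonal + fp,
      fp = fp,
      fn = fn,
      n_total = n_total
    ),
    class = "breslow_confusion_recon"
  )
}

#' @export
print.breslow_confusion_recon <- function(x, ...) {
  cat("Reconstructed confusion structure\n")
  print(tibble(
    category = breslow_levels()[seq_along(x$diagonal)],
    diagonal = x$diagonal, row_total = x$row_totals,
    col_total = x$col_totals, fp = x$fp, fn = x$fn
  ))
  invisible(x)
}

#' Totals implied by per-class accuracy rows
#'
#' From a reconstruction (see [confusion_from_class_metrics()]) computes
#' the micro-averaged sensitivity/specificity/PPV/NPV and the overall
#' multi-class kappa — everything a published "Total" row displays that is
#' a function of the diagonal and the marginals.
#'
#' @param recon A `breslow_confusion_recon` object, or a data frame with
#'   columns `n`, `sensitivity`, `specificity` to reconstruct from.
#' @return One-row tibble with `n`, micro `sensitivity`, `specificity`,
#'   `ppv`, `npv`, and `kappa`.
#' @export
#' @examples
#' reported_accuracy("hfus") |> reconstruct_totals()
reconstruct_totals <- function(recon) {
  if (is.data.frame(recon)) {
    recon <- confusion_from_class_metrics(
      recon$n, recon$sensitivity, recon$specificity
    )
  }
  if (!inherits(recon, "breslow_confusion_recon")) {
    abort("Expected a reconstruction or a per-class data frame.",
      class = "breslowmsi_input_error"
    )
  }
  tp <- sum(recon$diagonal)
  fn <- sum(recon$fn)
  fp <- sum(recon$fp)
  tn <- length(recon$diagonal) * recon$n_total - tp - fn - fp
  tibble(
    n = recon$n_total,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = tp / (tp + fp),
    npv = tn / (tn + fn),
    kappa = kappa_from_marginals(
      recon$diagonal, recon$row_totals, recon$col_totals
    )
  )
}

#' Published per-class diagnostic accuracy of the two staging methods
#'
#' The per-class rows reported by the clinical validation study for
#' optically guided high-frequency ultrasound (98 lesions) and for the
#' multispectral-imaging classifier (99 lesions): stratum size, MSE of the
#' continuous estimate, one-vs-rest sensitivity/specificity/PPV/NPV,
#' binary kappa and its 95% CI. These rows are inputs for the
#' reconstruction utilities — the printed totals can be re-derived from
#' them with [confusion_from_class_metrics()] and [reconstruct_totals()].
#'
#' @param method `"hfus"` or `"msi"`.
#' @return A tibble with one row per Breslow category.
#' @export
#' @examples
#' reported_accuracy("msi")
reported_accuracy <- function(method = c("hfus", "msi")) {
  method <- match.arg(method)
  if (method == "hfus") {
    tibble(
      category = breslow_levels(),
      n = c(56L, 15L, 27L),
      mse = c(0.034, 0.080, 1.02),
      sensitivity = c(0.982, 0.800, 0.852),
      specificity = c(0.952, 0.940, 0.986),
      ppv = c(0.965, 0.706, 0.958),
      npv = c(0.976, 0.963, 0.946),
      kappa = c(0.937, 0.701, 0.868),
      kappa_low = c(0.867, 0.503, 0.755),
      kappa_high = c(1.000, 0.900, 0.980)
    )
  } else {
    tibble(
      category = breslow_levels(),
      n = c(56L, 15L, 28L),
      mse = c(0.64, 0.61, 3.36),
      sensitivity = c(0.554, 0.600, 0.786),
      specificity = c(0.930, 0.679, 0.901),
      ppv = c(0.912, 0.250, 0.759),
      npv = c(0.615, 0.905, 0.914),
      kappa = c(0.457, 0.177, 0.680),
      kappa_low = c(0.286, -0.052, 0.517),
      kappa_high = c(0.627, 0.406, 0.842)
    )
  }
}
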