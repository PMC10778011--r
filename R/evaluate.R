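#' Build a 3x3 confusion matrix of Breslow categories
#'
#' Rows are the true (histological) category, columns the predicted one,
#' both in the fixed order `<1mm`, `1-2mm`, `>2mm`.
#'
#' @param truth,estimate Vectors of category labels (character or factor)
#'   of equal length.
#' @return An integer matrix of class `breslow_confusion`.
#' @export
#' @examples
#' build_confusion(c("<1mm", ">2mm"), c("<1mm", "1-2mm"))
build_confusion <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have equal length.",
      class = "breslowmsi_input_error"
    )
  }
  if (length(truth) < 1) {
    abort("Need at least one observation.", class = "breslowmsi_input_error")
  }
  cm <- table(
    true = breslow_factor(truth),
    predicted = breslow_factor(estimate)
  )
  structure(
    matrix(as.integer(cm), 3, 3, dimnames = dimnames(cm)),
    class = "breslow_confusion"
  )
}

as_confusion <- function(cm) {
  m <- unclass(cm)
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort("Expected a square confusion matrix.",
      class = "breslowmsi_input_error"
    )
  }
  if (any(m < 0) || sum(m) <= 0) {
    abort("Confusion matrix entries must be >= 0 with positive total.",
      class = "breslowmsi_input_error"
    )
  }
  m
}

#' Collapse a multi-class confusion matrix one-vs-rest
#'
#' For category `k`, TP is the diagonal cell, FN the rest of row `k`, FP
#' the rest of column `k`, and TN everything else; the four counts always
#' sum to the grand total.
#'
#' @param cm A confusion matrix (e.g. from [build_confusion()]).
#' @param k Category index (1-3) or label.
#' @return Named numeric vector `c(tp, fn, fp, tn)`.
#' @export
one_vs_rest <- function(cm, k) {
  m <- as_confusion(cm)
  if (is.character(k)) k <- match(k, rownames(m))
  if (is.na(k) || k < 1 || k > nrow(m)) {
    abort("Unknown category index.", class = "breslowmsi_input_error")
  }
  tp <- m[k, k]
  fn <- sum(m[k, ]) - tp
  fp <- sum(m[, k]) - tp
  tn <- sum(m) - tp - fn - fp
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Binary diagnostic metrics from 2x2 counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive and
#' negative predictive values, and the chance-corrected agreement (Cohen's
#' kappa) of the corresponding 2x2 table.
#'
#' @param tp,fn,fp,tn Non-negative counts; both the positive (`tp + fn`)
#'   and the negative (`fp + tn`) stratum must be non-empty.
#' @return One-row tibble with `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `kappa` (proportions in `[0, 1]`, kappa in `[-1, 1]`).
#' @export
#' @examples
#' class_metrics(55, 1, 2, 40)
class_metrics <- function(tp, fn, fp, tn) {
  tp <- unname(tp)
  fn <- unname(fn)
  fp <- unname(fp)
  tn <- unname(tn)
  counts <- c(tp, fn, fp, tn)
  if (any(counts < 0) || any(!is.finite(counts))) {
    abort("Counts must be finite and >= 0.", class = "breslowmsi_input_error")
  }
  if (tp + fn == 0 || fp + tn == 0) {
    abort("Undefined metrics: empty positive or negative stratum.",
      class = "breslowmsi_domain_error"
    )
  }
  m2 <- matrix(c(tp, fn, fp, tn), 2, 2, byrow = TRUE)
  tibble(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    kappa = cohen_kappa(m2)
  )
}

#' Micro-averaged diagnostic metrics
#'
#' Pools TP/FN/FP/TN over the one-vs-rest collapses of all categories and
#' applies the binary formulas to the pooled counts. For single-label
#' multi-class data the pooled collapses are symmetric, so micro
#' sensitivity equals micro PPV (both equal overall accuracy) and micro
#' specificity equals micro NPV.
#'
#' @param cm A confusion matrix.
#' @return One-row tibble with `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
micro_average <- function(cm) {
  m <- as_confusion(cm)
  pooled <- rowSums(vapply(
    seq_len(nrow(m)), function(k) one_vs_rest(m, k), numeric(4)
  ))
  pooled <- unname(pooled)
  names(pooled) <- c("tp", "fn", "fp", "tn")
  tibble(
    sensitivity = unname(pooled["tp"] / (pooled["tp"] + pooled["fn"])),
    specificity = unname(pooled["tn"] / (pooled["tn"] + pooled["fp"])),
    ppv = unname(pooled["tp"] / (pooled["tp"] + pooled["fp"])),
    npv = unname(pooled["tn"] / (pooled["tn"] + pooled["fn"]))
  )
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, where `p_o` is
#' the observed agreement (trace over total) and `p_e` the agreement
#' expected from the marginals. Depends only on the diagonal and the row
#' and column totals.
#'
#' @param cm A square confusion matrix (any number of categories).
#' @return Kappa in `[-1, 1]`.
#' @export
#' @examples
#' cohen_kappa(diag(c(10, 10, 10))) # 1
cohen_kappa <- function(cm) {
  m <- as_confusion(cm)
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (1 - pe < .Machine$double.eps) {
    abort("Kappa undefined: degenerate single-category marginals.",
      class = "breslowmsi_domain_error"
    )
  }
  (po - pe) / (1 - pe)
}

#' Kappa from a diagonal and the marginal totals
#'
#' Kappa is a function of the diagonal and the marginals only, so it can be
#' computed for a matrix that is only partially known — as when a published
#' accuracy table is reconstructed from its per-class rows.
#'
#' @param diagonal Vector of diagonal counts.
#' @param row_totals,col_totals Marginal totals (same length as
#'   `diagonal`; both must sum to the same grand total).
#' @return Kappa in `[-1, 1]`.
#' @export
#' @examples
#' kappa_from_marginals(c(55, 12, 23), c(56, 15, 27), c(57, 17, 24))
kappa_from_marginals <- function(diagonal, row_totals, col_totals) {
  if (length(diagonal) != length(row_totals) ||
    length(diagonal) != length(col_totals)) {
    abort("Lengths differ.", class = "breslowmsi_input_error")
  }
  if (abs(sum(row_totals) - sum(col_totals)) > 1e-9) {
    abort("Row and column totals disagree.", class = "breslowmsi_input_error")
  }
  n <- sum(row_totals)
  po <- sum(diagonal) / n
  pe <- sum(row_totals * col_totals) / n^2
  if (1 - pe < .Machine$double.eps) {
    abort("Kappa undefined: degenerate single-category marginals.",
      class = "breslowmsi_domain_error"
    )
  }
  (po - pe) / (1 - pe)
}

#' Asymptotic confidence interval for Cohen's kappa
#'
#' Large-sample standard error of the kappa estimator (the
#' Fleiss-Cohen-Everitt variance, which uses the full cell proportions)
#' with a normal quantile, clipped to `[-1, 1]`.
#'
#' @param cm A square confusion matrix with total >= 10.
#' @param alpha Two-sided error level (default 0.05 for a 95% interval).
#' @return One-row tibble with `kappa`, `se`, `low`, `high`.
#' @export
kappa_ci <- function(cm, alpha = 0.05) {
  m <- as_confusion(cm)
  n <- sum(m)
  if (n < 10) {
    abort("Need a total of at least 10 for the asymptotic interval.",
      class = "breslowmsi_input_error"
    )
  }
  p <- m / n
  pi_row <- rowSums(p)
  pi_col <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(pi_row * pi_col)
  k <- cohen_kappa(m)

  term1 <- sum(diag(p) * ((1 - pe) - (pi_col + pi_row) * (1 - po))^2)
  off <- !diag(nrow(m))
  sum_mat <- outer(pi_col, pi_row, `+`) # [i, j] = p_.i + p_j.
  term2 <- (1 - po)^2 * sum(p[off] * (sum_mat[off])^2)
  term3 <- (po * pe - 2 * pe + po)^2
  v <- (term1 + term2 - term3) / (n * (1 - pe)^4)
  se <- sqrt(max(v, 0))
  z <- qnorm(1 - alpha / 2)
  tibble(
    kappa = k,
    se = se,
    low = max(k - z * se, -1),
    high = min(k + z * se, 1)
  )
}

#' Mean squared error of continuous thickness estimates per category
#'
#' Averages the squared difference between estimated and true thickness
#' within each true clinical category and overall. Categories with no
#' lesions are simply absent from the output.
#'
#' @param true_mm,est_mm Numeric vectors (mm) of equal length.
#' @param true_cats Category labels of the same length.
#' @return A tibble with `category` (including `"overall"`), `n`, and
#'   `mse` (mm^2).
#' @export
mse_by_category <- function(true_mm, est_mm, true_cats) {
  if (length(true_mm) != length(est_mm) ||
    length(true_mm) != length(true_cats)) {
    abort("Input lengths differ.", class = "breslowmsi_input_error")
  }
  df <- tibble(
    category = as.character(breslow_factor(true_cats)),
    sq = (est_mm - true_mm)^2
  )
  per <- df |>
    group_by(category) |>
    summarise(n = dplyr::n(), mse = mean(sq), .groups = "drop") |>
    arrange(match(category, breslow_levels()))
  bind_rows(per, tibble(category = "overall", n = nrow(df), mse = mean(df$sq)))
}

#' Full diagnostic-accuracy report for a categorical staging method
#'
#' Builds the 3x3 confusion matrix and derives, per category, the
#' one-vs-rest sensitivity, specificity, PPV, NPV and binary kappa with its
#' asymptotic CI, plus (optionally) the per-category MSE of a continuous
#' thickness estimate; the totals row carries the micro-averaged metrics,
#' the overall multi-class kappa and its CI.
#'
#' @param data Data frame with one row per lesion.
#' @param truth,estimate Columns holding the true and predicted category
#'   (tidy evaluation).
#' @param true_mm,est_mm Optional columns with the true and estimated
#'   continuous thickness for the MSE column.
#' @param alpha Error level for kappa intervals.
#' @return An object of class `breslow_eval` with components `confusion`,
#'   `per_class`, `totals`, `kappa`, `kappa_low`, `kappa_high`, `n`.
#'   `tidy()` returns the per-class table, `glance()` the totals row.
#' @export
#' @examples
#' df <- tibble::tibble(
#'   truth = c("<1mm", "<1mm", "1-2mm", ">2mm"),
#'   pred = c("<1mm", "1-2mm", "1-2mm", ">2mm")
#' )
#' evaluate_classification(df, truth, pred)
evaluate_classification <- function(data, truth, estimate,
                                    true_mm = NULL, est_mm = NULL,
                                    alpha = 0.05) {
  truth_v <- dplyr::pull(data, {{ truth }})
  est_v <- dplyr::pull(data, {{ estimate }})
  cm <- build_confusion(truth_v, est_v)

  mm_true <- if (!rlang::quo_is_null(enquo(true_mm))) {
    dplyr::pull(data, {{ true_mm }})
  }
  mm_est <- if (!rlang::quo_is_null(enquo(est_mm))) {
    dplyr::pull(data, {{ est_mm }})
  }
  mse_tbl <- if (!is.null(mm_true) && !is.null(mm_est)) {
    mse_by_category(mm_true, mm_est, truth_v)
  }

  per_class <- purrr::map_dfr(seq_len(3), function(k) {
    counts <- one_vs_rest(cm, k)
    if (counts["tp"] + counts["fn"] == 0) {
      return(tibble(
        category = breslow_levels()[k], n = 0L, mse = NA_real_,
        sensitivity = NA_real_, specificity = NA_real_,
        ppv = NA_real_, npv = NA_real_,
        kappa = NA_real_, kappa_low = NA_real_, kappa_high = NA_real_
      ))
    }
    cmet <- class_metrics(counts["tp"], counts["fn"], counts["fp"], counts["tn"])
    m2 <- matrix(counts[c("tp", "fn", "fp", "tn")], 2, 2, byrow = TRUE)
    ci <- kappa_ci(m2, alpha)
    mse_k <- if (!is.null(mse_tbl)) {
      v <- mse_tbl$mse[mse_tbl$category == breslow_levels()[k]]
      if (length(v)) v else NA_real_
    } else {
      NA_real_
    }
    dplyr::bind_cols(
      tibble(
        category = breslow_levels()[k],
        n = as.integer(counts["tp"] + counts["fn"]),
        mse = mse_k
      ),
      cmet,
      tibble(kappa_low = ci$low, kappa_high = ci$high)
    )
  })
  per_class <- per_class[, c(
    "category", "n", "mse", "sensitivity", "specificity",
    "ppv", "npv", "kappa", "kappa_low", "kappa_high"
  )]

  overall_ci <- kappa_ci(cm, alpha)
  totals <- dplyr::bind_cols(
    tibble(
      category = "total",
      n = sum(cm),
      mse = if (!is.null(mse_tbl)) {
        mse_tbl$mse[mse_tbl$category == "overall"]
      } else {
        NA_real_
      }
    ),
    micro_average(cm),
    tibble(
      kappa = overall_ci$kappa,
      kappa_low = overall_ci$low,
      kappa_high = overall_ci$high
    )
  )

  structure(
    list(
      confusion = cm,
      per_class = per_class,
      totals = totals,
      kappa = overall_ci$kappa,
      kappa_low = overall_ci$low,
      kappa_high = overall_ci$high,
      n = sum(cm)
    ),
    class = "breslow_eval"
  )
}

#' @export
print.breslow_eval <- function(x, ...) {
  cat(sprintf(
    "Breslow staging accuracy (n = %d)\n", x$n
  ))
  cat("Confusion matrix (rows = truth, cols = predicted):\n")
  print(unclass(x$confusion))
  fmt <- x$per_class
  for (col in c("sensitivity", "specificity", "ppv", "npv")) {
    fmt[[col]] <- sprintf("%.1f%%", 100 * fmt[[col]])
  }
  fmt$kappa <- sprintf("%.3f", x$per_class$kappa)
  fmt$ci_95 <- sprintf("%.3f-%.3f", x$per_class$kappa_low, x$per_class$kappa_high)
  print(as.data.frame(fmt[, c(
    "category", "n", "sensitivity", "specificity", "ppv", "npv",
    "kappa", "ci_95"
  )]), row.names = FALSE)
  cat(sprintf(
    "Micro: sens %.1f%%, spec %.1f%% | kappa %.3f (%.3f-%.3f)\n",
    100 * x$totals$sensitivity, 100 * x$totals$specificity,
    x$kappa, x$kappa_low, x$kappa_high
  ))
  invisible(x)
}

#' @rdname evaluate_classification
#' @param x A `breslow_eval` object.
#' @param ... Unused.
#' @method tidy breslow_eval
#' @export
tidy.breslow_eval <- function(x, ...) {
  x$per_class
}

#' @rdname evaluate_classification
#' @method glance breslow_eval
#' @export
glance.breslow_eval <- function(x, ...) {
  x$totals
}
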