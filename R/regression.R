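#' Pearson product-moment correlation with a two-sided test
#'
#' Thin, validated wrapper around [stats::cor.test()] returning the
#' correlation coefficient and its two-sided t-test p-value as a tidy row.
#'
#' @param x,y Numeric vectors of equal length (>= 3) with non-zero
#'   variance.
#' @return A one-row tibble with columns `r`, `p_value`, `n`.
#' @export
#' @examples
#' pearson_r(1:10, (1:10)^2)
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.",
      class = "breslowmsi_input_error"
    )
  }
  if (length(x) < 3) {
    abort("Need at least 3 paired observations.",
      class = "breslowmsi_input_error"
    )
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined: zero variance.",
      class = "breslowmsi_domain_error"
    )
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Multivariate linear model of Breslow thickness on spectral features
#'
#' Ordinary least squares of true thickness on mean G, R and IR intensity
#' plus circularity, with an intercept. The model's headline summary is the
#' Pearson correlation between fitted and observed thickness (equal to the
#' square root of R^2), with overall significance from the regression
#' F-test.
#'
#' @param data Data frame with columns `mean_G`, `mean_R`, `mean_IR`,
#'   `circularity` and the response.
#' @param response Column holding the observed Breslow thickness in mm
#'   (default `true_breslow_mm`); tidy evaluation is supported.
#' @return An object of class `breslow_lm` with components `fit` (the
#'   underlying `lm`), `r` (multivariate correlation), `f_statistic`,
#'   `p_value`, `fitted` and `coefficients`. `tidy()`, `glance()`,
#'   `augment()`, `predict()` and `autoplot()` methods are provided.
#' @export
#' @examples
#' p <- sim_params(n = 30, seed = 5)
#' cohort <- sample_cohort(p)
#' feats <- dplyr::bind_cols(cohort, extract_cohort_features(cohort, p)[-1])
#' fit <- fit_breslow_lm(feats)
#' glance(fit)
fit_breslow_lm <- function(data, response = true_breslow_mm) {
  predictors <- c("mean_G", "mean_R", "mean_IR", "circularity")
  missing_cols <- setdiff(predictors, names(data))
  if (length(missing_cols)) {
    abort(paste0(
      "`data` is missing predictor(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "breslowmsi_input_error")
  }
  y <- dplyr::pull(data, {{ response }})
  if (length(y) < 6) {
    abort("Need at least 6 lesions to fit 5 parameters.",
      class = "breslowmsi_input_error"
    )
  }
  df <- data.frame(
    .breslow = y,
    data[, predictors, drop = FALSE]
  )
  fit <- lm(.breslow ~ mean_G + mean_R + mean_IR + circularity, data = df)

  alias <- is.na(coef(fit))
  if (any(alias)) {
    abort(paste0(
      "Design is rank deficient; collinear predictor(s): ",
      paste(names(coef(fit))[alias], collapse = ", ")
    ), class = "breslowmsi_fit_error")
  }

  sm <- summary(fit)
  fstat <- unname(sm$fstatistic)
  p_overall <- pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(
    list(
      fit = fit,
      coefficients = coef(fit),
      fitted = unname(stats::fitted(fit)),
      observed = y,
      r = sqrt(max(sm$r.squared, 0)),
      f_statistic = fstat[1],
      p_value = p_overall
    ),
    class = "breslow_lm"
  )
}

#' @export
print.breslow_lm <- function(x, ...) {
  cat("Multivariate Breslow thickness model (OLS)\n")
  cat(sprintf(
    "  n = %d, r = %.3f, F = %.2f, p = %.3g\n",
    length(x$fitted), x$r, x$f_statistic, x$p_value
  ))
  cat("  Coefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @rdname fit_breslow_lm
#' @param x A `breslow_lm` object.
#' @param ... Unused.
#' @method tidy breslow_lm
#' @export
tidy.breslow_lm <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p_value = sm[, "Pr(>|t|)"]
  )
}

#' @rdname fit_breslow_lm
#' @method glance breslow_lm
#' @export
glance.breslow_lm <- function(x, ...) {
  tibble(
    r = x$r,
    r_squared = x$r^2,
    f_statistic = x$f_statistic,
    p_value = x$p_value,
    n = length(x$fitted)
  )
}

#' @rdname fit_breslow_lm
#' @method augment breslow_lm
#' @export
augment.breslow_lm <- function(x, ...) {
  tibble(
    observed_mm = x$observed,
    fitted_mm = x$fitted,
    residual_mm = x$observed - x$fitted
  )
}

#' @export
predict.breslow_lm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(object$fitted)
  }
  unname(stats::predict(object$fit, newdata = as.data.frame(newdata)))
}
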