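#' Render a synthetic multispectral lesion image and its ROI mask
#'
#' Draws a star-convex lesion outline (a disk whose radius is perturbed by
#' a small set of random-phase Fourier harmonics; the per-category
#' amplitude controls boundary irregularity and hence circularity) and
#' fills the four 8-bit channels. Mean channel intensities inside the
#' lesion follow the generator's intensity model: G depends on the Breslow
#' category, IR declines linearly with true thickness, R declines weakly
#' with thickness, AF is flat. Pixel-level Gaussian noise is added to every
#' channel before quantisation to 0-255.
#'
#' @param record A one-row data frame (or list) with at least
#'   `true_breslow_mm`; a cohort row from [sample_cohort()] works directly.
#' @param params A [sim_params()] object.
#' @param seed Integer seed for this lesion; shape, intensity and pixel
#'   noise each draw from a sub-stream derived from it.
#' @return A list with elements `channels` (named list of integer matrices
#'   `AF`, `G`, `R`, `IR`, values 0-255) and `mask` (0/1 integer matrix of
#'   the same dimensions).
#' @export
#' @examples
#' p <- sim_params(seed = 3)
#' rec <- sample_cohort(p)[1, ]
#' img <- render_lesion(rec, p, seed = 11)
#' dim(img$mask)
render_lesion <- function(record, params = sim_params(), seed = 1) {
  check_sim_params(params)
  t_mm <- record$true_breslow_mm
  if (is.null(t_mm) || !is.finite(t_mm) || t_mm <= 0) {
    abort("`record` must carry a positive `true_breslow_mm`.")
  }
  category <- as.character(categorize_thickness(t_mm))
  size <- params$image_size

  withr::with_seed(stream_seed(seed, "shapes"), {
    radius <- sample(seq(params$radius_range[1], params$radius_range[2]), 1)
    if (size < 3 * radius) {
      abort("Image grid too small to contain the lesion.",
        class = "breslowmsi_generation_error"
      )
    }
    amp <- params$irregularity_by_category[[category]]
    harmonics <- 2:8
    amps <- amp / sqrt(harmonics)
    phases <- runif(length(harmonics), 0, 2 * pi)
  })

  centre <- (size + 1) / 2
  xg <- matrix(rep(seq_len(size), size), nrow = size)
  yg <- t(xg)
  theta <- atan2(yg - centre, xg - centre)
  rr <- sqrt((xg - centre)^2 + (yg - centre)^2)
  wobble <- Reduce(
    `+`,
    lapply(seq_along(harmonics), function(i) {
      amps[i] * cos(harmonics[i] * theta + phases[i])
    })
  )
  r_bound <- pmin(radius * pmax(1 + wobble, 0.25), centre - 2)
  mask <- matrix(as.integer(rr <= r_bound), nrow = size)

  withr::with_seed(stream_seed(seed, "intensity"), {
    g_val <- params$g_mean_by_category[[category]] + rnorm(1, 0, params$g_scatter_sd)
    ir_val <- params$ir_intercept + params$ir_slope * t_mm +
      rnorm(1, 0, params$ir_scatter_sd)
    r_val <- params$r_intercept + params$r_slope * t_mm +
      rnorm(1, 0, params$r_scatter_sd)
  })
  lesion_means <- c(AF = params$af_mean, G = g_val, R = r_val, IR = ir_val)
  background <- c(AF = 15, G = 140, R = 160, IR = 175)

  withr::with_seed(stream_seed(seed, "pixel"), {
    channels <- lapply(names(lesion_means), function(ch) {
      base <- ifelse(mask == 1L, lesion_means[[ch]], background[[ch]])
      if (params$channel_noise_sd > 0) {
        base <- base + rnorm(length(base), 0, params$channel_noise_sd)
      }
      matrix(pmin(pmax(as.integer(round(base)), 0L), 255L), nrow = size)
    })
  })
  names(channels) <- names(lesion_means)
  list(channels = channels, mask = mask)
}

#' Render every lesion of a cohort
#'
#' @param cohort A cohort tibble from [sample_cohort()].
#' @param params A [sim_params()] object; per-lesion seeds are derived from
#'   `params$seed` so the whole set is reproducible.
#' @return A named list (by `lesion_id`) of [render_lesion()] results.
#' @export
render_cohort <- function(cohort, params = sim_params()) {
  base <- stream_seed(params$seed, "shapes")
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    render_lesion(cohort[i, ], params, seed = (base + 7919 * i) %% 2147483647)
  })
  names(out) <- cohort$lesion_id
  out
}
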