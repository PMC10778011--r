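#' Simulation parameters for the synthetic melanoma cohort
#'
#' Bundles every knob of the synthetic-data generator. The defaults encode
#' the study conditions the generator is meant to emulate: a right-skewed
#' thickness distribution with mean 1.61 mm and SD 1.69 mm clipped to the
#' observed range 0.135-8.12 mm, subtype and anatomical-site frequencies of
#' the clinical cohort, heteroscedastic ultrasound measurement noise
#' calibrated so that measured vs. true thickness correlates at r = 0.943,
#' and an infrared reflectance that declines linearly with tumour depth so
#' that mean IR intensity and thickness correlate at r = -0.659.
#'
#' @param n Number of lesions to simulate (default 101, the clinical cohort
#'   size).
#' @param seed Integer seed; every random stream of the generator is derived
#'   from it.
#' @param thickness_mean,thickness_sd Mean and SD (mm) to which the
#'   log-normal thickness law is moment-matched.
#' @param thickness_clip Length-2 numeric, the (low, high) clip range in mm.
#' @param hfus_noise_sd0 Baseline SD (mm) of the simulated ultrasound
#'   measurement error.
#' @param hfus_noise_prop Proportional term: the error SD for a lesion of
#'   true depth t is `hfus_noise_sd0 + hfus_noise_prop * t` (deeper tumours
#'   are measured less precisely).
#' @param ir_slope Slope of mean IR intensity against thickness
#'   (A.U. per mm, negative: deeper tumours reflect less infrared light).
#' @param ir_scatter_sd Lesion-level SD (A.U.) of mean IR intensity around
#'   the linear trend.
#' @param g_mean_by_category Named numeric, mean G-channel intensity (A.U.)
#'   for each Breslow category.
#' @param g_scatter_sd Lesion-level SD (A.U.) of mean G intensity.
#' @param r_slope,r_intercept,r_scatter_sd Linear model and scatter for the
#'   red channel (used by the regression module only).
#' @param af_mean Mean autofluorescence intensity (generated for format
#'   completeness; unused by any downstream analysis).
#' @param channel_noise_sd Pixel-level Gaussian noise SD added to every
#'   channel when rendering.
#' @param irregularity_by_category Named numeric, radial perturbation
#'   amplitude of the lesion boundary per category; larger values yield more
#'   irregular outlines and hence lower circularity.
#' @param image_size Side length (pixels) of the rendered image grid.
#' @param radius_range Length-2 integer range (pixels) from which the base
#'   lesion radius is drawn.
#'
#' @details The IR intercept is not free: it is pinned so that the
#'   noise-free, 8-bit-quantised IR value crosses the 113.7 A.U. classifier
#'   threshold exactly at 2 mm, which is what makes the decision tree
#'   recover the true category when all noise terms are zero. Because
#'   channels are stored as integers, the effective decision boundary on a
#'   noise-free channel sits at the rounding midpoint 113.5 (the largest
#'   value that rounds below the smallest integer passing the threshold),
#'   so the intercept is `113.5 - 2 * ir_slope`.
#'
#' @return A list of class `sim_params`.
#' @export
#' @examples
#' p <- sim_params(n = 50, seed = 7)
#' p$thickness_mean
sim_params <- function(n = 101,
                       seed = 1,
                       thickness_mean = 1.61,
                       thickness_sd = 1.69,
                       thickness_clip = c(0.135, 8.12),
                       hfus_noise_sd0 = 0.08,
                       hfus_noise_prop = 0.211,
                       ir_slope = -8,
                       ir_scatter_sd = 13.3,
                       g_mean_by_category = c("<1mm" = 10, "1-2mm" = 6, ">2mm" = 6),
                       g_scatter_sd = 4,
                       r_slope = -3,
                       r_intercept = 120,
                       r_scatter_sd = 10,
                       af_mean = 30,
                       channel_noise_sd = 6,
                       irregularity_by_category = c("<1mm" = 0.25, "1-2mm" = 0.18, ">2mm" = 0.02),
                       image_size = 96,
                       radius_range = c(14, 24)) {
  stopifnot_param(is.numeric(n) && length(n) == 1 && n >= 1, "`n` must be >= 1.")
  stopifnot_param(
    is.numeric(seed) && length(seed) == 1 && is.finite(seed),
    "`seed` must be a single integer."
  )
  stopifnot_param(
    length(thickness_clip) == 2 && thickness_clip[1] < thickness_clip[2] &&
      thickness_clip[1] > 0,
    "`thickness_clip` must be (low, high) with 0 < low < high."
  )
  stopifnot_param(
    thickness_mean > 0 && thickness_sd > 0,
    "`thickness_mean` and `thickness_sd` must be positive."
  )
  stopifnot_param(
    hfus_noise_sd0 >= 0 && hfus_noise_prop >= 0 &&
      ir_scatter_sd >= 0 && g_scatter_sd >= 0 &&
      r_scatter_sd >= 0 && channel_noise_sd >= 0,
    "Noise parameters must be >= 0."
  )
  stopifnot_param(ir_slope < 0, "`ir_slope` must be negative.")
  stopifnot_param(
    all(breslow_levels() %in% names(g_mean_by_category)) &&
      all(breslow_levels() %in% names(irregularity_by_category)),
    "Per-category parameters must name all three Breslow categories."
  )
  stopifnot_param(
    image_size >= 3 * radius_range[2],
    "`image_size` too small for the largest lesion radius."
  )

  # moment-matched log-normal: E = exp(mu + s2/2), V = E^2 (exp(s2) - 1)
  s2 <- log(1 + (thickness_sd / thickness_mean)^2)
  mu <- log(thickness_mean) - s2 / 2

  structure(
    list(
      n = as.integer(n), seed = as.integer(seed),
      thickness_mean = thickness_mean, thickness_sd = thickness_sd,
      thickness_meanlog = mu, thickness_sdlog = sqrt(s2),
      thickness_clip = thickness_clip,
      hfus_noise_sd0 = hfus_noise_sd0, hfus_noise_prop = hfus_noise_prop,
      ir_slope = ir_slope,
      # rounding midpoint below ceiling(113.7): quantised IR crosses the
      # classifier threshold exactly at t = 2 mm
      ir_intercept = (ceiling(113.7) - 0.5) - 2 * ir_slope,
      ir_scatter_sd = ir_scatter_sd,
      g_mean_by_category = g_mean_by_category, g_scatter_sd = g_scatter_sd,
      r_slope = r_slope, r_intercept = r_intercept, r_scatter_sd = r_scatter_sd,
      af_mean = af_mean,
      channel_noise_sd = channel_noise_sd,
      irregularity_by_category = irregularity_by_category,
      image_size = as.integer(image_size),
      radius_range = as.integer(radius_range)
    ),
    class = "sim_params"
  )
}

#' Noise-free variant of a parameter set
#'
#' Returns a copy of `params` with all stochastic measurement terms
#' (ultrasound noise, lesion-level intensity scatter, pixel noise) set to
#' zero. In this limit both the ultrasound and the image-based classifier
#' recover the true category exactly.
#'
#' @param params A [sim_params()] object.
#' @return A `sim_params` object.
#' @export
noiseless_params <- function(params = sim_params()) {
  params$hfus_noise_sd0 <- 0
  params$hfus_noise_prop <- 0
  params$ir_scatter_sd <- 0
  params$g_scatter_sd <- 0
  params$r_scatter_sd <- 0
  params$channel_noise_sd <- 0
  params
}

#' Decision-tree thresholds for the image-based classifier
#'
#' The classifier first splits on circularity, then on mean G intensity
#' (low-circularity branch) or mean IR intensity (high-circularity branch).
#' Defaults are the published operating points: circularity 0.75, G channel
#' 8.0 A.U., IR channel 113.7 A.U. Intensities are interpreted on the 8-bit
#' 0-255 scale.
#'
#' @param circularity_threshold Circularity split point, in (0, 1].
#' @param g_threshold G-channel mean intensity split point, in [0, 255].
#' @param ir_threshold IR-channel mean intensity split point, in [0, 255].
#' @return A list of class `threshold_config`.
#' @export
threshold_config <- function(circularity_threshold = 0.75,
                             g_threshold = 8.0,
                             ir_threshold = 113.7) {
  stopifnot_param(
    circularity_threshold > 0 && circularity_threshold <= 1,
    "`circularity_threshold` must be in (0, 1]."
  )
  stopifnot_param(
    g_threshold >= 0 && g_threshold <= 255 &&
      ir_threshold >= 0 && ir_threshold <= 255,
    "Intensity thresholds must be in [0, 255]."
  )
  structure(
    list(
      circularity_threshold = circularity_threshold,
      g_threshold = g_threshold,
      ir_threshold = ir_threshold
    ),
    class = "threshold_config"
  )
}

stopifnot_param <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg, class = "breslowmsi_config_error")
  invisible(TRUE)
}

# Named, reproducible random streams: every stage draws from its own seed
# derived from the single user-facing seed, so regenerating one stage never
# perturbs another.
stream_seed <- function(seed, stream) {
  offsets <- c(
    cohort = 101L, hfus = 211L, shapes = 307L,
    intensity = 401L, pixel = 503L
  )
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483647)
}
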