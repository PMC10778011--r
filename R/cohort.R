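#' Melanoma subtype and anatomical site frequencies of the reference cohort
#'
#' Relative frequencies used by the synthetic generator: eight melanoma
#' subtypes (superficial spreading melanoma dominating at 68.3%) and five
#' anatomical sites, as observed in the 101-lesion clinical validation
#' cohort.
#'
#' @return A tibble with columns `value`, `kind` (`"subtype"` or `"site"`)
#'   and `prob`.
#' @export
cohort_composition <- function() {
  subtype <- tibble(
    value = c(
      "SSM", "NM", "SSM sec. Nod.", "LMM sec. Nod.",
      "LMM", "ALM", "UC", "Naevoid"
    ),
    kind = "subtype",
    prob = c(69, 8, 10, 1, 6, 1, 4, 2) / 101
  )
  site <- tibble(
    value = c("trunk", "extremities", "cheek", "forehead", "neck"),
    kind = "site",
    prob = c(60, 32, 6, 2, 1) / 101
  )
  bind_rows(subtype, site)
}

#' Simulate a synthetic melanoma cohort
#'
#' Draws `params$n` lesions with a true Breslow thickness from a log-normal
#' law moment-matched to the configured mean and SD and clipped to the
#' configured range, a melanoma subtype and an anatomical site from the
#' reference cohort frequencies. The result is fully determined by
#' `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @return A tibble with columns `lesion_id`, `true_breslow_mm`, `subtype`,
#'   `site`, and `true_category` (the histological category, from
#'   [categorize_thickness()]).
#' @export
#' @examples
#' cohort <- sample_cohort(sim_params(n = 20, seed = 42))
#' dplyr::count(cohort, true_category)
sample_cohort <- function(params = sim_params()) {
  check_sim_params(params)
  comp <- cohort_composition()
  sub <- comp[comp$kind == "subtype", ]
  sit <- comp[comp$kind == "site", ]
  withr::with_seed(stream_seed(params$seed, "cohort"), {
    t_raw <- rlnorm(params$n, params$thickness_meanlog, params$thickness_sdlog)
    t_mm <- pmin(pmax(t_raw, params$thickness_clip[1]), params$thickness_clip[2])
    subtype <- sample(sub$value, params$n, replace = TRUE, prob = sub$prob)
    site <- sample(sit$value, params$n, replace = TRUE, prob = sit$prob)
  })
  tibble(
    lesion_id = sprintf("L%04d", seq_len(params$n)),
    true_breslow_mm = t_mm,
    subtype = subtype,
    site = site,
    true_category = categorize_thickness(t_mm)
  )
}

#' Simulate optically guided high-frequency ultrasound measurements
#'
#' Adds a simulated preoperative ultrasound thickness reading for every
#' lesion: the true depth plus heteroscedastic Gaussian error with SD
#' `hfus_noise_sd0 + hfus_noise_prop * depth`, floored at zero so that
#' measurements stay physical. With the default calibration the measured
#' and true thicknesses correlate at r = 0.943.
#'
#' @param cohort A cohort tibble from [sample_cohort()] (any data frame with
#'   a `true_breslow_mm` column works).
#' @param params A [sim_params()] object.
#' @param seed Optional integer overriding the ultrasound noise stream seed
#'   derived from `params$seed`.
#' @return `cohort` with columns `hfus_measured_mm` and `hfus_category`
#'   appended.
#' @export
#' @examples
#' sim_params(n = 10, seed = 1) |>
#'   sample_cohort() |>
#'   simulate_hfus(sim_params(n = 10, seed = 1))
simulate_hfus <- function(cohort, params = sim_params(), seed = NULL) {
  check_sim_params(params)
  if (!"true_breslow_mm" %in% names(cohort)) {
    abort("`cohort` must contain a `true_breslow_mm` column.")
  }
  t_mm <- cohort$true_breslow_mm
  if (any(!is.finite(t_mm)) || any(t_mm <= 0)) {
    abort("`true_breslow_mm` must be finite and positive.")
  }
  seed <- seed %||% stream_seed(params$seed, "hfus")
  withr::with_seed(as.integer(seed), {
    eps <- rnorm(
      length(t_mm),
      mean = 0,
      sd = params$hfus_noise_sd0 + params$hfus_noise_prop * t_mm
    )
  })
  measured <- pmax(t_mm + eps, 0)
  mutate(
    as_tibble(cohort),
    hfus_measured_mm = measured,
    # a floored-at-zero reading still belongs to the thinnest group
    hfus_category = categorize_thickness(pmax(measured, 1e-6))
  )
}

check_sim_params <- function(params) {
  if (!inherits(params, "sim_params")) {
    abort("`params` must be created by sim_params().",
      class = "breslowmsi_config_error"
    )
  }
  invisible(TRUE)
}
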