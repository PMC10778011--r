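#' Write a per-lesion table as CSV with a metadata header
#'
#' Writes comment lines (`#`) carrying the package version, a configuration
#' hash and the seed, followed by a standard comma-separated table with a
#' header row, UTF-8, `.` decimal separator.
#'
#' @param data Data frame to write.
#' @param path Output file path.
#' @param seed Seed to record in the header (may be `NULL`).
#' @param config Object whose [rlang::hash()] is recorded (may be `NULL`).
#' @return `path`, invisibly.
#' @export
write_lesion_table <- function(data, path, seed = NULL, config = NULL) {
  meta <- c(
    sprintf("# breslowmsi %s", as.character(utils::packageVersion("breslowmsi"))),
    sprintf("# seed: %s", if (is.null(seed)) "NA" else as.character(seed)),
    sprintf("# config: %s", if (is.null(config)) "NA" else rlang::hash(config))
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(as.data.frame(data), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-lesion CSV written by [write_lesion_table()]
#'
#' @param path File path; `#` comment lines are skipped.
#' @return A tibble. Category columns are restored as ordered factors.
#' @export
read_lesion_table <- function(path) {
  df <- as_tibble(utils::read.csv(path, comment.char = "#"))
  for (col in intersect(
    c("true_category", "hfus_category", "msi_category"), names(df)
  )) {
    df[[col]] <- breslow_factor(df[[col]])
  }
  df
}

#' Write a lesion's channels and mask as 8-bit grayscale PNGs
#'
#' One file per channel (`<id>_AF.png`, `_G`, `_R`, `_IR`) plus
#' `<id>_mask.png` with foreground 255.
#'
#' @param lesion A [render_lesion()] result.
#' @param dir Output directory (created if missing).
#' @param id Lesion identifier used as the filename stem.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_lesion_images <- function(lesion, dir, id) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  for (ch in names(lesion$channels)) {
    p <- file.path(dir, sprintf("%s_%s.png", id, ch))
    png::writePNG(t(lesion$channels[[ch]]) / 255, p)
    paths[ch] <- p
  }
  pm <- file.path(dir, sprintf("%s_mask.png", id))
  png::writePNG(t(lesion$mask) * 1.0, pm)
  paths["mask"] <- pm
  invisible(paths)
}

read_png_8bit <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  vals <- img * 255
  if (max(abs(vals - round(vals))) > 1e-6) {
    abort(
      sprintf("`%s` does not contain 8-bit data; refusing to truncate.", path),
      class = "breslowmsi_format_error"
    )
  }
  # undo the row/column transposition used when writing
  t(matrix(as.integer(round(vals)), nrow = nrow(img)))
}

#' Read a multispectral image set and its ROI mask
#'
#' Accepts either a directory of per-channel 8-bit grayscale PNGs (suffixes
#' `_AF`, `_G`, `_R`, `_IR` and `_mask`, as written by
#' [write_lesion_images()]) or a single multi-page 8-bit TIFF whose pages
#' are ordered AF, G, R, IR, mask. The mask is binarised at 128. All planes
#' must share dimensions; 16-bit data is rejected explicitly.
#'
#' @param path Directory (PNG layout) or `.tif`/`.tiff` file.
#' @param id Filename stem for the PNG layout.
#' @return A list with `channels` (named list of integer matrices) and
#'   `mask` (0/1 integer matrix).
#' @export
read_image_set <- function(path, id = NULL) {
  chan_names <- c("AF", "G", "R", "IR")
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!file.exists(path)) {
      abort(sprintf("File not found: %s", path), class = "breslowmsi_format_error")
    }
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (length(pages) < 5) {
      abort("Multi-page TIFF must hold AF, G, R, IR and mask pages.",
        class = "breslowmsi_format_error"
      )
    }
    bits <- attr(pages[[1]], "bits.per.sample")
    if (!is.null(bits) && bits > 8) {
      abort(
        sprintf("`%s` is %d-bit; only 8-bit data is supported.", path, bits),
        class = "breslowmsi_format_error"
      )
    }
    planes <- lapply(pages[1:5], function(pg) {
      if (length(dim(pg)) == 3) pg <- pg[, , 1]
      t(matrix(as.integer(round(pg * 255)), nrow = nrow(pg)))
    })
    names(planes) <- c(chan_names, "mask")
  } else {
    if (is.null(id)) {
      abort("`id` is required when reading a PNG directory.",
        class = "breslowmsi_format_error"
      )
    }
    files <- file.path(path, sprintf("%s_%s.png", id, c(chan_names, "mask")))
    missing_f <- files[!file.exists(files)]
    if (length(missing_f)) {
      abort(
        paste0("Missing channel file(s): ", paste(missing_f, collapse = ", ")),
        class = "breslowmsi_format_error"
      )
    }
    planes <- lapply(files, read_png_8bit)
    names(planes) <- c(chan_names, "mask")
  }
  dims <- vapply(planes, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("Channel and mask dimensions differ.",
      class = "breslowmsi_format_error"
    )
  }
  list(
    channels = planes[chan_names],
    mask = matrix(as.integer(planes$mask >= 128), nrow = nrow(planes$mask))
  )
}

#' Write an evaluation report as JSON
#'
#' Mirrors the `breslow_eval` structure field-for-field, plus a metadata
#' block with the package version, seed and configuration hash.
#'
#' @param report A `breslow_eval` object.
#' @param path Output `.json` path.
#' @param seed,config Recorded in the metadata block (may be `NULL`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, seed = NULL, config = NULL) {
  out <- list(
    metadata = list(
      tool = "breslowmsi",
      version = as.character(utils::packageVersion("breslowmsi")),
      seed = seed,
      config_hash = if (is.null(config)) NA else rlang::hash(config)
    ),
    confusion = unclass(report$confusion),
    per_class = report$per_class,
    totals = report$totals,
    overall_kappa = report$kappa,
    overall_kappa_ci = c(report$kappa_low, report$kappa_high)
  )
  jsonlite::write_json(out, path,
    auto_unbox = TRUE, digits = NA, dataframe = "rows", matrix = "rowmajor"
  )
  invisible(path)
}
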