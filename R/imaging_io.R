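#' Calibrated image container
#'
#' Bundles an 8-bit RGB pixel array with its spatial calibration. Pixels are
#' stored as an integer array `[row, column, channel]` with values in 0--255;
#' row 1 is the top of the image. The calibration `cm_per_pixel` converts
#' pixel counts to physical areas (`cm2 = pixels * cm_per_pixel^2`).
#'
#' @param pixels integer array `[rows, cols, 3]`, values in 0--255.
#' @param cm_per_pixel side length of one pixel in centimetres (> 0), or
#'   `NA` when no calibration is available (all areas then stay in pixel
#'   units and a warning is emitted downstream).
#' @param source_id free-text provenance label (sample id, replicate index).
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, cm_per_pixel, source_id = "") {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) {
    stop("pixels must be a [rows, cols, 3] array")
  }
  if (d[1] < 16L || d[2] < 16L) {
    stop("image must be at least 16x16 pixels, got ", d[1], "x", d[2])
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("channel values must lie in [0, 255]")
  }
  if (!is.na(cm_per_pixel) && cm_per_pixel <= 0) {
    stop("cm_per_pixel must be positive, got ", cm_per_pixel)
  }
  structure(
    list(
      pixels = array(as.integer(round(pixels)), d),
      cm_per_pixel = as.numeric(cm_per_pixel),
      source_id = as.character(source_id)
    ),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "calibrated_image '%s': %d x %d px, %s cm/px\n",
    x$source_id, d[1], d[2],
    if (is.na(x$cm_per_pixel)) "uncalibrated" else format(x$cm_per_pixel)
  ))
  invisible(x)
}

#' Read an image file with spatial calibration
#'
#' Reads PNG, TIFF or JPEG rasters. Grayscale images are promoted to RGB by
#' channel replication; higher bit depths are rescaled to 8 bits. Pixel
#' values are otherwise untouched.
#'
#' @param path path to a PNG/TIFF/JPEG file.
#' @param cm_per_pixel spatial calibration (cm per pixel side), must be > 0.
#' @param source_id provenance label; defaults to the file name without
#'   extension.
#' @return A [calibrated_image()].
#' @export
read_image <- function(path, cm_per_pixel, source_id = NULL) {
  if (!file.exists(path)) {
    stop("cannot read image: file not found: ", path)
  }
  if (is.na(cm_per_pixel) || cm_per_pixel <= 0) {
    stop("cm_per_pixel must be positive, got ", cm_per_pixel)
  }
  img <- tryCatch(
    EBImage::readImage(path),
    error = function(e) stop("cannot decode image '", path, "': ",
                             conditionMessage(e))
  )
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) {
    # grayscale: promote to RGB
    a <- array(rep(a, 3L), c(dim(a), 3L))
  } else if (dim(a)[3] > 3L) {
    a <- a[, , 1:3, drop = FALSE] # drop alpha
  }
  # EBImage stores (x = column, y = row); transpose to [row, col, channel]
  a <- aperm(a, c(2L, 1L, 3L))
  if (is.null(source_id)) {
    source_id <- sub("\\.[^.]*$", "", basename(path))
  }
  calibrated_image(round(a * 255), cm_per_pixel, source_id)
}

#' Write a calibrated image to disk
#'
#' Inverse of [read_image()]: writes the 8-bit RGB array as PNG/TIFF/JPEG
#' (format chosen from the file extension). PNG and TIFF round-trip
#' losslessly.
#'
#' @param image a [calibrated_image()].
#' @param path output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  a <- aperm(image$pixels / 255, c(2L, 1L, 3L))
  img <- EBImage::Image(a, colormode = "Color")
  EBImage::writeImage(img, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Holds every tunable parameter of the segmentation and measurement chain.
#' Defaults correspond to the standard protocol: (1, 99) percentile linear
#' contrast stretch, one 3x3 median filter, automatic between-class-variance
#' (Otsu) threshold restricted to slice-interior pixels, morphological
#' closing with a 3x3 square structuring element, per-particle hole filling,
#' and a 4 px minimum particle size to suppress single-pixel noise.
#'
#' @param contrast_percentiles ordered pair in \[0, 100): gray levels at these
#'   histogram percentiles are stretched to 0 and 255.
#' @param filter_window odd integer >= 1; side of the square median-filter
#'   window (1 disables filtering).
#' @param threshold_mode `"automatic"` (Otsu within the slice) or `"fixed"`.
#' @param fixed_threshold gray level 0--255 used when `threshold_mode` is
#'   `"fixed"`.
#' @param closing_radius half-width of the square structuring element used
#'   for closing (side `2*closing_radius + 1`); 0 disables closing.
#' @param min_particle_area_px connected components smaller than this pixel
#'   count are discarded.
#' @param area_class_edges strictly increasing lower class boundaries in cm2
#'   defining exactly ten particle-area classes; the last class is unbounded
#'   above. Default anchors: below 0.1 cm2 (intrinsic pork fat), 0.1--0.5 cm2
#'   (added lard), 5 cm2 and above.
#' @param fill_holes fill interior holes of each detected particle?
#' @param seed integer seed recorded with the configuration.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(contrast_percentiles = c(1, 99),
                            filter_window = 3L,
                            threshold_mode = c("automatic", "fixed"),
                            fixed_threshold = 128L,
                            closing_radius = 1L,
                            min_particle_area_px = 4L,
                            area_class_edges = c(0, 0.1, 0.5, 1, 1.5,
                                                 2, 2.5, 3, 4, 5),
                            fill_holes = TRUE,
                            seed = 1L) {
  threshold_mode <- match.arg(threshold_mode)
  if (length(contrast_percentiles) != 2L ||
      any(contrast_percentiles < 0) || any(contrast_percentiles >= 100) ||
      contrast_percentiles[1] >= contrast_percentiles[2]) {
    stop("contrast_percentiles must be an ordered pair in [0, 100)")
  }
  if (filter_window < 1L || filter_window %% 2L == 0L) {
    stop("filter_window must be an odd integer >= 1")
  }
  if (fixed_threshold < 0 || fixed_threshold > 255) {
    stop("fixed_threshold must be a gray level in [0, 255]")
  }
  if (closing_radius < 0L) stop("closing_radius must be >= 0")
  if (min_particle_area_px < 0L) stop("min_particle_area_px must be >= 0")
  if (length(area_class_edges) != 10L ||
      any(diff(area_class_edges) <= 0)) {
    stop("area_class_edges must be 10 strictly increasing boundaries ",
         "(ten classes, the last unbounded above)")
  }
  structure(
    list(
      contrast_percentiles = as.numeric(contrast_percentiles),
      filter_window = as.integer(filter_window),
      threshold_mode = threshold_mode,
      fixed_threshold = as.numeric(fixed_threshold),
      closing_radius = as.integer(closing_radius),
      min_particle_area_px = as.integer(min_particle_area_px),
      area_class_edges = as.numeric(area_class_edges),
      fill_holes = isTRUE(fill_holes),
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a key = value file
#'
#' Lines are `key = value`; blank lines and lines starting with `#` are
#' ignored. Vector values are comma-separated. Unknown keys are an error.
#'
#' @param path path to the configuration file.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    v <- vals[i]
    args[[k]] <- switch(k,
      contrast_percentiles = ,
      area_class_edges = as.numeric(strsplit(v, ",")[[1]]),
      threshold_mode = v,
      fill_holes = as.logical(v),
      filter_window = ,
      closing_radius = ,
      min_particle_area_px = ,
      seed = as.integer(v),
      fixed_threshold = as.numeric(v),
      stop("unknown config key: ", k)
    )
  }
  do.call(pipeline_config, args)
}

#' Write a pipeline configuration to a key = value file
#'
#' @param config a [pipeline_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  fmt <- function(v) {
    if (is.numeric(v)) paste(format(v, digits = 15, trim = TRUE),
                             collapse = ",")
    else as.character(v)
  }
  lines <- vapply(
    names(config),
    function(k) paste(k, "=", fmt(config[[k]])),
    ""
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write per-particle and per-image measurements to CSV
#'
#' Writes one CSV holding both a per-particle block (one row per detected
#' fat particle) and a per-image summary block, distinguished by the
#' `row_type` column. [read_measurements()] reconstructs both tables;
#' numbers round-trip to better than 6 significant digits.
#'
#' @param measurements non-empty list of slice measurements from
#'   [measure_slice()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  if (inherits(measurements, "slice_measurement")) {
    measurements <- list(measurements)
  }
  if (length(measurements) == 0L) {
    stop("measurements must be a non-empty list")
  }
  stopifnot(all(vapply(measurements, inherits, TRUE, "slice_measurement")))

  particle_rows <- do.call(rbind, lapply(measurements, function(m) {
    if (m$n == 0L) return(NULL)
    cbind(source_id = m$source_id, row_type = "particle", m$particles)
  }))
  image_rows <- do.call(rbind, lapply(measurements, function(m) {
    h <- m$histogram
    row <- data.frame(
      source_id = m$source_id, row_type = "image",
      n = m$n, A_s = m$A_s, n_per_area = m$n_per_area, vfc = m$vfc,
      af_mean = m$af_mean, af_max = m$af_max,
      rf_mean = m$rf_mean, rf_max = m$rf_max,
      stringsAsFactors = FALSE
    )
    counts <- as.data.frame(as.list(h$counts))
    names(counts) <- paste0("class", seq_along(h$counts))
    cbind(row, counts)
  }))

  all_cols <- union(names(image_rows), names(particle_rows))
  pad <- function(df) {
    if (is.null(df)) return(NULL)
    for (col in setdiff(all_cols, names(df))) df[[col]] <- NA
    df[all_cols]
  }
  out <- rbind(pad(particle_rows), pad(image_rows))
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE),
    error = function(e) stop("cannot write measurements to '", path, "': ",
                             conditionMessage(e))
  )
  invisible(path)
}

#' Read a measurement CSV written by [write_measurements()]
#'
#' @param path CSV path.
#' @return A list with data frames `particles` and `images`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"row_type" %in% names(df)) {
    stop("not a measurement CSV (missing row_type): ", path)
  }
  particles <- df[df$row_type == "particle",
                  intersect(c("source_id", "label", "area_cm2",
                              "perimeter_cm", "roundness", "centroid_row",
                              "centroid_col", "touches_border"), names(df))]
  images <- df[df$row_type == "image",
               setdiff(names(df), c("label", "area_cm2", "perimeter_cm",
                                    "roundness", "centroid_row",
                                    "centroid_col", "touches_border"))]
  images$row_type <- NULL
  rownames(particles) <- rownames(images) <- NULL
  list(particles = particles, images = images)
}

#' Read a published per-sample summary table
#'
#' Reads a long-format CSV of per-sample summary statistics as printed in
#' object-analysis reports: columns `sample`, `statistic`, `mean`, `sd`,
#' `letters` (Duncan grouping letters). Returns the table in wide form with
#' one row per sample and `<statistic>_mean` / `<statistic>_sd` /
#' `<statistic>_letters` columns.
#'
#' A transcription of the published 16-sample salami object-analysis table
#' ships with the package:
#' `system.file("extdata", "salami_object_analysis.csv", package = "fatmorph")`.
#' One evident misprint in the source table is corrected in the shipped
#' transcription: sample C's mean particle area prints as 0.174, which
#' contradicts both the stated column range (0.075--0.138) and its own
#' grouping letter ("e", among means of 0.112--0.123); it is transcribed
#' as 0.124 (a plausible 7/2 digit transposition consistent with both).
#'
#' @param path CSV path.
#' @return A data frame, one row per sample.
#' @export
read_summary_table <- function(path) {
  if (!file.exists(path)) stop("summary table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "statistic", "mean", "sd", "letters")
  if (!all(need %in% names(df))) {
    stop("summary table must have columns: ", paste(need, collapse = ", "))
  }
  samples <- unique(df$sample)
  stats <- unique(df$statistic)
  out <- data.frame(sample = samples, stringsAsFactors = FALSE)
  for (s in stats) {
    sub <- df[df$statistic == s, ]
    idx <- match(samples, sub$sample)
    out[[paste0(s, "_mean")]] <- sub$mean[idx]
    out[[paste0(s, "_sd")]] <- sub$sd[idx]
    out[[paste0(s, "_letters")]] <- sub$letters[idx]
  }
  out
}
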