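#' Measure a directory of slice images
#'
#' Runs [measure_slice()] on every readable PNG/TIFF/JPEG in `input_dir`.
#' The sample id is the file name up to the first underscore and the
#' replicate id the remainder (the naming used by [generate_study()]).
#' Images that fail to decode or segment are logged and skipped, not
#' fatal. Writes the combined per-particle / per-image measurement CSV
#' and a JSON run manifest (configuration snapshot, input checksums, tool
#' version, timestamps, warnings) that suffices to reproduce the run.
#'
#' @param input_dir directory containing >= 1 readable image.
#' @param cm_per_pixel spatial calibration applied to every image.
#' @param config a [pipeline_config()].
#' @param output_dir output directory (created if needed).
#' @return Invisibly, a list: `measurements` (list of
#'   `slice_measurement`), `csv`, `manifest` (paths), `warnings`.
#' @export
cmd_measure <- function(input_dir, cm_per_pixel = NA,
                        config = pipeline_config(),
                        output_dir = file.path(input_dir, "results")) {
  files <- list.files(input_dir,
                      pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L) {
    stop("no readable images found in ", input_dir)
  }
  if (is.na(cm_per_pixel)) {
    warning("no spatial calibration supplied: areas reported in pixel ",
            "units under cm2-labelled columns")
    cm_use <- 1
  } else {
    cm_use <- cm_per_pixel
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  measurements <- list()
  warns <- character()
  for (f in sort(files)) {
    m <- tryCatch(
      measure_slice(read_image(f, cm_use), config),
      error = function(e) {
        msg <- paste0("skipped '", basename(f), "': ",
                      conditionMessage(e))
        warns <<- c(warns, msg)
        message(msg)
        NULL
      }
    )
    if (!is.null(m)) measurements[[length(measurements) + 1L]] <- m
  }
  if (length(measurements) == 0L) {
    stop("no image could be measured in ", input_dir)
  }
  csv <- file.path(output_dir, "measurements.csv")
  write_measurements(measurements, csv)
  manifest <- write_manifest(
    file.path(output_dir, "manifest.json"),
    config = config, cm_per_pixel = cm_per_pixel,
    inputs = sort(files), outputs = csv, warnings = warns
  )
  invisible(list(measurements = measurements, csv = csv,
                 manifest = manifest, warnings = warns))
}

write_manifest <- function(path, config, cm_per_pixel, inputs, outputs,
                           warnings) {
  manifest <- list(
    tool = "fatmorph",
    version = as.character(utils::packageVersion("fatmorph")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    cm_per_pixel = cm_per_pixel,
    config = unclass(config),
    inputs = data.frame(
      path = inputs,
      md5 = unname(tools::md5sum(inputs)),
      stringsAsFactors = FALSE
    ),
    outputs = outputs,
    warnings = warnings
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

# split "A_01" style ids into sample ("A") and replicate ("01")
split_source_id <- function(source_id) {
  sample <- sub("_.*$", "", source_id)
  replicate <- sub("^[^_]*_?", "", source_id)
  data.frame(sample = sample, replicate = replicate,
             stringsAsFactors = FALSE)
}

#' Summarize a measurement CSV into per-sample tables and statistics
#'
#' Reads the measurement CSV written by [cmd_measure()], aggregates
#' replicate images into per-sample mean +- SD summaries, attaches
#' Duncan's multiple range letters per statistic (when >= 2 samples with
#' >= 2 replicates each), runs PCA on the correlation matrix of the six
#' per-sample image statistics (plus chemical fat when supplied), and,
#' when a chemical-fat table is supplied, fits the visible-vs-chemical
#' linear correlation. Also writes the per-sample area-class frequency
#' figure and, where applicable, scree, biplot and correlation figures.
#'
#' @param measurement_csv path to a measurement CSV.
#' @param chemical_csv optional CSV with columns `sample_id` (or `sample`)
#'   and `fat_pct`.
#' @param output_dir output directory (created if needed).
#' @param alpha significance level for the Duncan grouping.
#' @param edges ten area-class boundaries for the distribution figure.
#' @return Invisibly, a list: `summary` (per-sample data frame with
#'   letters), `groupings` (list of `duncan_grouping` per statistic),
#'   `pca` (`pca_result` or `NULL`), `correlation` (`fat_correlation` or
#'   `NULL`), `files` (paths written).
#' @export
cmd_summarize <- function(measurement_csv, chemical_csv = NULL,
                          output_dir = dirname(measurement_csv),
                          alpha = 0.05,
                          edges = pipeline_config()$area_class_edges) {
  dat <- read_measurements(measurement_csv)
  images <- dat$images
  if (nrow(images) == 0L) stop("measurement CSV holds no image rows")
  ids <- split_source_id(images$source_id)
  images$sample <- ids$sample
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  samples <- unique(images$sample)
  summary_df <- do.call(rbind, lapply(samples, function(s) {
    summarize_sample(images[images$sample == s, ], s)
  }))

  # Duncan letters per statistic
  groupings <- list()
  reps <- table(images$sample)
  if (length(samples) >= 2L && all(reps >= 2L)) {
    for (stat in summary_statistics) {
      vals <- split(images[[stat]], images$sample)[samples]
      g <- anova_duncan(vals, alpha = alpha)
      groupings[[stat]] <- g
      summary_df[[paste0(stat, "_letters")]] <-
        g$group_letters[match(summary_df$sample, g$sample_ids)]
    }
    grouping_csv <- file.path(output_dir, "duncan_groupings.csv")
    gdf <- do.call(rbind, lapply(names(groupings), function(stat) {
      g <- groupings[[stat]]
      data.frame(statistic = stat, sample = g$sample_ids,
                 mean = unname(g$means), letters = g$group_letters,
                 F_statistic = g$F_statistic, p_value = g$p_value,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(gdf, grouping_csv, row.names = FALSE)
    files <- c(files, grouping_csv)
  } else {
    warning("fewer than 2 samples (or a sample with a single ",
            "replicate): statistics skipped")
  }

  summary_csv <- file.path(output_dir, "sample_summary.csv")
  utils::write.csv(summary_df, summary_csv, row.names = FALSE)
  files <- c(files, summary_csv)

  # per-sample area-class frequency distribution figure
  hist_png <- file.path(output_dir, "area_class_distribution.png")
  p <- plot_area_distribution(dat$particles, edges)
  if (!is.null(p)) {
    ggplot2::ggsave(hist_png, p, width = 9, height = 6, dpi = 120)
    files <- c(files, hist_png)
  }

  # chemical fat table
  chemical <- NULL
  if (!is.null(chemical_csv)) {
    ch <- utils::read.csv(chemical_csv, stringsAsFactors = FALSE)
    idcol <- intersect(c("sample_id", "sample"), names(ch))[1]
    if (is.na(idcol) || !"fat_pct" %in% names(ch)) {
      stop("chemical CSV needs columns sample_id (or sample) and fat_pct")
    }
    chemical <- ch$fat_pct[match(summary_df$sample, ch[[idcol]])]
    if (anyNA(chemical)) {
      warning("missing chemical fat for sample(s): ",
              paste(summary_df$sample[is.na(chemical)], collapse = ", "),
              "; dropped from PCA/correlation")
    }
  }

  # PCA over the six per-sample statistics (+ chemical fat if present)
  pca <- NULL
  feat <- as.matrix(summary_df[, paste0(summary_statistics, "_mean")])
  colnames(feat) <- summary_statistics
  rownames(feat) <- summary_df$sample
  keep <- rep(TRUE, nrow(feat))
  if (!is.null(chemical)) {
    feat <- cbind(feat, chemical_fat = chemical)
    keep <- !is.na(chemical)
  }
  if (sum(keep) >= 3L) {
    pca <- tryCatch(pca_correlation(feat[keep, , drop = FALSE]),
                    error = function(e) {
                      warning("PCA skipped: ", conditionMessage(e))
                      NULL
                    })
  }
  if (!is.null(pca)) {
    load_csv <- file.path(output_dir, "pca_loadings.csv")
    utils::write.csv(as.data.frame(pca$loadings), load_csv)
    score_csv <- file.path(output_dir, "pca_scores.csv")
    utils::write.csv(as.data.frame(pca$scores), score_csv)
    scree_png <- file.path(output_dir, "pca_scree.png")
    ggplot2::ggsave(scree_png, plot_scree(pca), width = 6, height = 4,
                    dpi = 120)
    biplot_png <- file.path(output_dir, "pca_biplot.png")
    ggplot2::ggsave(biplot_png, plot_biplot(pca), width = 7, height = 6,
                    dpi = 120)
    files <- c(files, load_csv, score_csv, scree_png, biplot_png)
  }

  # visible vs chemical correlation
  correlation <- NULL
  if (!is.null(chemical) && sum(keep) >= 3L) {
    correlation <- correlate_vfc_chemical(summary_df$vfc_mean[keep],
                                          chemical[keep])
    corr_png <- file.path(output_dir, "vfc_vs_chemical.png")
    ggplot2::ggsave(
      corr_png,
      plot_fat_correlation(summary_df$vfc_mean[keep], chemical[keep],
                           correlation),
      width = 6, height = 5, dpi = 120
    )
    files <- c(files, corr_png)
  }

  invisible(list(summary = summary_df, groupings = groupings, pca = pca,
                 correlation = correlation, files = files))
}

#' Per-sample area-class frequency distribution plot
#'
#' Bar chart of the fraction of fat particles per area class, faceted by
#' sample.
#'
#' @param particles per-particle data frame with `source_id`, `area_cm2`.
#' @param edges ten area-class boundaries (cm2).
#' @return A ggplot object, or `NULL` when there are no particles.
#' @export
plot_area_distribution <- function(particles,
                                   edges =
                                     pipeline_config()$area_class_edges) {
  if (nrow(particles) == 0L) return(NULL)
  ids <- split_source_id(particles$source_id)
  labels <- c(
    sprintf("[%.2g,%.2g)", edges[-10], edges[-1]),
    sprintf(">=%.2g", edges[10])
  )
  df <- do.call(rbind, lapply(split(particles$area_cm2, ids$sample),
    function(a) {
      h <- area_class_histogram(a, edges)
      data.frame(class = factor(labels, levels = labels),
                 frequency = h$frequencies)
    }))
  df$sample <- sub("\\..*$", "", rownames(df))
  ggplot2::ggplot(df,
                  ggplot2::aes(x = .data$class, y = .data$frequency)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~sample) +
    ggplot2::labs(x = "fat particle area class (cm²)",
                  y = "frequency") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 60, hjust = 1))
}

#' Scree plot of a correlation-matrix PCA
#' @param pca a `pca_result`.
#' @return A ggplot object.
#' @export
plot_scree <- function(pca) {
  df <- data.frame(component = seq_along(pca$eigenvalues),
                   eigenvalue = pca$eigenvalues,
                   pct = pca$explained_variance_pct)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = df$component) +
    ggplot2::labs(x = "principal component",
                  y = "eigenvalue of the correlation matrix") +
    ggplot2::theme_bw()
}

#' Loading/score biplot of the first two principal components
#' @param pca a `pca_result`.
#' @return A ggplot object.
#' @export
plot_biplot <- function(pca) {
  sc <- as.data.frame(pca$scores[, 1:2, drop = FALSE])
  names(sc) <- c("PC1", "PC2")
  sc$sample <- rownames(pca$scores)
  ld <- as.data.frame(pca$loadings[, 1:2, drop = FALSE])
  names(ld) <- c("PC1", "PC2")
  ld$variable <- rownames(pca$loadings)
  r <- max(abs(sc$PC1), abs(sc$PC2))
  ld$PC1 <- ld$PC1 * r
  ld$PC2 <- ld$PC2 * r
  pct <- pca$explained_variance_pct
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1, yend = .data$PC2),
      arrow = grid::arrow(length = grid::unit(2, "mm")),
      colour = "firebrick"
    ) +
    ggplot2::geom_text(data = ld,
                       ggplot2::aes(label = .data$variable),
                       colour = "firebrick", vjust = -0.6, size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample), size = 3.2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", pct[1]),
      y = sprintf("PC2 (%.0f%%)", pct[2])
    ) +
    ggplot2::theme_bw()
}

#' Scatter plot of visible versus chemical fat with the fitted line
#' @param vfc,chemical paired per-sample percentages.
#' @param correlation a `fat_correlation` fit of the same data.
#' @return A ggplot object.
#' @export
plot_fat_correlation <- function(vfc, chemical, correlation) {
  df <- data.frame(vfc = vfc, chemical = chemical)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$vfc, y = .data$chemical)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = correlation$slope,
                         intercept = correlation$intercept) +
    ggplot2::annotate(
      "text", x = min(vfc), y = max(chemical), hjust = 0,
      label = sprintf("R² = %.2f", correlation$R2)
    ) +
    ggplot2::labs(x = "visible fat content (%)",
                  y = "chemical fat content (%)") +
    ggplot2::theme_bw()
}
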