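# end-to-end runs use a reduced study (small images, few replicates) so the
# whole file stays fast; the full layout is exercised in test-acceptance.R

test_that("cmd_measure measures a directory, skipping corrupt files", {
  dir <- withr::local_tempdir()
  specs <- study_specs(image_size = c(192L, 192L), slice_radius = 75L,
                       cm_per_pixel = 0.04, min_separation = 2)[1:2]
  generate_study(specs, replicates = 2L, seed = 3, dir = dir)
  writeLines("not an image", file.path(dir, "C_01.png")) # corrupt

  res <- suppressWarnings(
    cmd_measure(dir, cm_per_pixel = 0.04,
                output_dir = file.path(dir, "out"))
  )
  expect_length(res$measurements, 4L)
  expect_length(res$warnings, 1L)
  expect_match(res$warnings, "C_01")
  expect_true(file.exists(res$csv))
  expect_true(file.exists(res$manifest))

  back <- read_measurements(res$csv)
  expect_equal(nrow(back$images), 4L)

  # manifest lists config snapshot and input checksums
  man <- jsonlite::read_json(res$manifest)
  expect_equal(man$tool, "fatmorph")
  expect_equal(length(man$inputs), 5L)
  expect_true(!is.null(man$config$closing_radius))

  expect_error(cmd_measure(withr::local_tempdir()), "no readable images")
})

test_that("rerunning measurement yields identical CSVs", {
  dir <- withr::local_tempdir()
  specs <- study_specs(image_size = c(128L, 128L), slice_radius = 50L,
                       cm_per_pixel = 0.06, min_separation = 2)[1]
  generate_study(specs, replicates = 2L, seed = 11, dir = dir)
  r1 <- cmd_measure(dir, 0.06, output_dir = file.path(dir, "o1"))
  r2 <- cmd_measure(dir, 0.06, output_dir = file.path(dir, "o2"))
  expect_identical(readLines(r1$csv), readLines(r2$csv))
})

test_that("cmd_summarize builds per-sample tables, letters, PCA and correlation", {
  dir <- withr::local_tempdir()
  specs <- study_specs(image_size = c(192L, 192L), slice_radius = 75L,
                       cm_per_pixel = 0.04, min_separation = 2)[c(1, 6, 11, 16)]
  names(specs) <- c("A", "B", "C", "D")
  truth <- generate_study(specs, replicates = 3L, seed = 17, dir = dir)
  res <- cmd_measure(dir, 0.04, output_dir = file.path(dir, "out"))

  # chemical fat correlated with the generator's true coverage
  agg <- stats::aggregate(true_vfc ~ sample, truth, mean)
  chem_csv <- file.path(dir, "chemical.csv")
  utils::write.csv(
    data.frame(sample_id = agg$sample, fat_pct = 1.1 * agg$true_vfc + 2),
    chem_csv, row.names = FALSE
  )

  out <- cmd_summarize(res$csv, chem_csv,
                       output_dir = file.path(dir, "out"))
  expect_equal(nrow(out$summary), 4L)
  expect_true(all(paste0(c("n_per_area", "vfc"), "_letters") %in%
                    names(out$summary)))
  expect_length(out$groupings, 6L)
  expect_s3_class(out$pca, "pca_result")
  expect_equal(sum(out$pca$explained_variance_pct), 100,
               tolerance = 1e-6)
  expect_s3_class(out$correlation, "fat_correlation")
  expect_gt(out$correlation$R2, 0.9) # chemical built from true coverage
  expect_true(all(file.exists(out$files)))

  # every number in the summary equals a recomputation from the CSV
  back <- read_measurements(res$csv)
  ids <- sub("_.*$", "", back$images$source_id)
  for (s in unique(ids)) {
    redo <- summarize_sample(back$images[ids == s, ], s)
    for (col in names(redo)) {
      expect_equal(out$summary[out$summary$sample == s, col],
                   redo[[col]], info = paste(s, col))
    }
  }
})

test_that("cmd_summarize degrades gracefully without chemical data or replication", {
  dir <- withr::local_tempdir()
  specs <- study_specs(image_size = c(128L, 128L), slice_radius = 50L,
                       cm_per_pixel = 0.06, min_separation = 2)[1:3]
  generate_study(specs, replicates = 2L, seed = 29, dir = dir)
  res <- cmd_measure(dir, 0.06, output_dir = file.path(dir, "out"))

  out <- cmd_summarize(res$csv, output_dir = file.path(dir, "out"))
  expect_null(out$correlation)
  expect_s3_class(out$pca, "pca_result") # runs on image features alone

  # single sample: summary only, statistics skipped with a warning
  one <- read_measurements(res$csv)
  keep <- startsWith(one$images$source_id, "A_")
  m1 <- file.path(dir, "one.csv")
  df <- utils::read.csv(res$csv)
  utils::write.csv(df[startsWith(df$source_id, "A_"), ], m1,
                   row.names = FALSE)
  expect_warning(out1 <- cmd_summarize(m1, output_dir = dir), "skipped")
  expect_equal(nrow(out1$summary), 1L)
  expect_length(out1$groupings, 0L)
})
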