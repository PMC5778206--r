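test_that("grayscale conversion follows the 0.299/0.587/0.114 luma weights", {
  px <- array(0L, c(16, 16, 3))
  px[1, 1, ] <- c(255L, 255L, 255L)
  px[1, 2, ] <- c(200L, 30L, 30L)
  img <- calibrated_image(px, 0.01)
  g <- to_grayscale(img)
  expect_equal(g[1, 1], 255L)
  expect_equal(g[2, 2], 0L)
  # round(0.299*200 + 0.587*30 + 0.114*30) = round(80.83) = 81
  expect_equal(g[1, 2], 81L)
})

test_that("contrast stretch maps the percentile range onto [0, 255]", {
  g <- matrix(as.integer(seq(50, 150, length.out = 400)), 20, 20)
  e <- enhance_contrast(g, c(0, 100))
  expect_equal(min(e), 0L)
  expect_equal(max(e), 255L)
  # monotone non-decreasing in input level
  expect_true(all(diff(e[order(g)]) >= 0L))

  # already full-range image is unchanged up to rounding
  f <- matrix(as.integer(seq(0, 255, length.out = 256)), 16, 16)
  expect_true(all(abs(enhance_contrast(f, c(0, 100)) - f) <= 1L))

  # two-level image snaps to {0, 255}
  two <- matrix(c(60L, 160L), 16, 16)
  expect_setequal(unique(as.vector(enhance_contrast(two, c(0, 100)))),
                  c(0L, 255L))

  # constant image: degenerate histogram returned unchanged with a notice
  const <- matrix(42L, 16, 16)
  expect_message(out <- enhance_contrast(const, c(1, 99)), "degenerate")
  expect_identical(out, const)
})

test_that("median smoothing matches a brute-force oracle and its contracts", {
  set.seed(11)
  g <- matrix(sample(0:255, 30 * 25, TRUE), 30, 25)
  expect_identical(smooth_gray(g, 1L), g)
  expect_identical(smooth_gray(g, 3L), brute_median3(g))
  expect_error(smooth_gray(g, 2L), "odd")

  # isolated bright pixel in a flat field is removed
  flat <- matrix(10L, 21, 21)
  flat[11, 11] <- 250L
  expect_true(all(smooth_gray(flat, 3L) == 10L))

  # checkerboard: every interior 3x3 window has 5 pixels of the centre's
  # colour, so the majority (= median) is the centre value itself
  cb <- matrix(0L, 20, 20)
  cb[(row(cb) + col(cb)) %% 2 == 0] <- 255L
  sm <- smooth_gray(cb, 3L)
  expect_identical(sm[2:19, 2:19], cb[2:19, 2:19])
})

test_that("slice extraction finds the disk, fills holes, errors on empty", {
  # red disk radius 200 on black 512^2: area within 1% of pi * 200^2
  px <- array(10L, c(512, 512, 3))
  d <- disk_mask(200, 512)
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[d] <- c(150L, 40L, 45L)[ch]
    px[, , ch] <- plane
  }
  img <- calibrated_image(px, 0.01, "disk")
  slice <- extract_slice_mask(to_grayscale(img), img)
  expect_lt(abs(slice$area_pixels / (pi * 200^2) - 1), 0.01)
  expect_equal(slice$A_s, slice$area_pixels * 0.01^2)

  # interior dark hole gets filled into a single component
  px2 <- px
  hole <- disk_mask(30, 512)
  for (ch in 1:3) {
    plane <- px2[, , ch]
    plane[hole] <- 10L
    px2[, , ch] <- plane
  }
  img2 <- calibrated_image(px2, 0.01, "holed")
  slice2 <- extract_slice_mask(to_grayscale(img2), img2)
  expect_equal(slice2$area_pixels, slice$area_pixels)

  # all-black image has no slice
  black <- calibrated_image(array(0L, c(64, 64, 3)), 0.01)
  expect_error(extract_slice_mask(to_grayscale(black), black), "no slice")
})

test_that("fat segmentation recovers separated particles and edge cases", {
  # 10 well-separated ellipses on a uniform red disk
  ph <- generate_phantom(small_spec(n_particles = 10, noise_sd = 0,
                                    illumination_gradient = 0, seed = 21))
  m <- measure_slice(ph$image)
  expect_equal(m$n, 10L)

  # no white pixels inside the slice -> zero particles, not an error
  ph0 <- generate_phantom(small_spec(n_particles = 0, noise_sd = 0,
                                     illumination_gradient = 0, seed = 1))
  m0 <- measure_slice(ph0$image)
  expect_equal(m0$n, 0L)
  expect_equal(m0$vfc, 0)

  # bridged squares merge into one component whose size a brute-force
  # flood fill confirms
  mask <- matrix(FALSE, 40, 40)
  mask[5:14, 5:14] <- TRUE
  mask[5:14, 20:29] <- TRUE
  mask[9, 15:19] <- TRUE # 1-px bridge
  gray <- matrix(0L, 40, 40)
  gray[mask] <- 255L
  slice <- structure(list(mask = matrix(TRUE, 40, 40),
                          area_pixels = 1600L, A_s = 1600),
                     class = "slice_mask")
  fat <- segment_fat(gray, slice,
                     pipeline_config(closing_radius = 0L,
                                     fill_holes = FALSE))
  oracle <- brute_components(mask)
  expect_equal(fat$n_particles, oracle$n)
  expect_equal(sum(fat$mask), sum(mask))
})

test_that("component labeling is 8-connected and partitions the mask", {
  set.seed(42)
  for (i in 1:5) {
    mask <- matrix(stats::runif(60 * 60) > 0.7, 60, 60)
    gray <- matrix(0L, 60, 60)
    gray[mask] <- 255L
    slice <- structure(list(mask = matrix(TRUE, 60, 60),
                            area_pixels = 3600L, A_s = 3600),
                       class = "slice_mask")
    fat <- segment_fat(gray, slice,
                       pipeline_config(closing_radius = 0L,
                                       fill_holes = FALSE,
                                       min_particle_area_px = 0L))
    oracle <- brute_components(mask)
    expect_equal(fat$n_particles, oracle$n)
    # labels form a partition: nonzero exactly on the mask
    expect_true(all((fat$labels > 0L) == mask))
    expect_equal(sort(unique(as.vector(fat$labels[fat$labels > 0L]))),
                 seq_len(fat$n_particles))
  }
})

test_that("fat mask is a subset of the slice mask and the chain is deterministic", {
  sp <- small_spec(coverage = 0.15, seed = 9)
  ph <- generate_phantom(sp)
  img <- ph$image
  gray <- smooth_gray(enhance_contrast(to_grayscale(img)), 3L)
  slice <- extract_slice_mask(gray, img)
  fat <- segment_fat(gray, slice, pipeline_config())
  expect_true(all(slice$mask[fat$mask]))

  m1 <- measure_slice(img)
  m2 <- measure_slice(img)
  expect_identical(m1, m2)
})

test_that("closing with the square element never shrinks an isolated convex particle", {
  for (seed in 1:4) {
    set.seed(seed)
    mask <- matrix(FALSE, 60, 60)
    a <- stats::runif(1, 5, 12)
    b <- stats::runif(1, 3, a)
    th <- stats::runif(1, 0, pi)
    dr <- rep(seq_len(60) - 30, times = 60)
    dc <- rep(seq_len(60) - 30, each = 60)
    u <- (dr * cos(th) + dc * sin(th)) / a
    v <- (-dr * sin(th) + dc * cos(th)) / b
    mask <- matrix(u^2 + v^2 <= 1, 60, 60)
    gray <- matrix(0L, 60, 60)
    gray[mask] <- 255L
    slice <- structure(list(mask = matrix(TRUE, 60, 60),
                            area_pixels = 3600L, A_s = 3600),
                       class = "slice_mask")
    for (r in 1:2) {
      fat <- segment_fat(gray, slice,
                         pipeline_config(closing_radius = r,
                                         fill_holes = FALSE))
      expect_gte(sum(fat$mask), sum(mask))
    }
  }
})
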