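test_that("roundness matches closed forms and rejects bad input", {
  # ideal unit circle: A = pi, P = 2*pi
  expect_equal(roundness(pi, 2 * pi), 1)
  # unit square
  expect_equal(roundness(1, 4), 4 / pi)
  # 2:1 ellipse, perimeter from numeric arc-length quadrature
  p_ell <- ellipse_perimeter_num(2, 1)
  expect_equal(roundness(2 * pi, p_ell), 1.1888, tolerance = 1e-4)
  expect_equal(ellipse_roundness(2, 1), roundness(2 * pi, p_ell),
               tolerance = 1e-5)

  expect_error(roundness(0, 1), "area")
  expect_error(roundness(1, -1), "perimeter")
})

test_that("roundness is scale invariant", {
  for (k in c(0.5, 2, 10)) {
    expect_equal(roundness(3 * k^2, 7 * k), roundness(3, 7))
  }
})

test_that("line-intercept perimeter is accurate on digitized shapes", {
  # disk radius 60
  d <- disk_mask(60)
  expect_lt(abs(crofton_perimeter(d) / (2 * pi * 60) - 1), 0.02)
  # axis-aligned square 100 x 100
  sq <- matrix(FALSE, 120, 120)
  sq[11:110, 11:110] <- TRUE
  expect_lt(abs(crofton_perimeter(sq) / 400 - 1), 0.02)
  # empty mask
  expect_equal(crofton_perimeter(matrix(FALSE, 5, 5)), 0)
})

test_that("digitized disk roundness converges monotonically toward 1", {
  err <- vapply(c(10, 30, 100), function(r) {
    m <- disk_mask(r)
    abs(roundness(sum(m), crofton_perimeter(m)) - 1)
  }, 0)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.01)
})

test_that("measure_particle recovers disk, square and degenerate regions", {
  # digitized disk radius 60 at 0.01 cm/px
  d <- disk_mask(60)
  lab <- matrix(0L, nrow(d), ncol(d))
  lab[d] <- 1L
  p <- measure_particle(lab, 1L, 0.01)
  expect_lt(abs(p$area_cm2 / (pi * 0.6^2) - 1), 0.01)
  expect_lt(abs(p$roundness - 1), 0.05)

  # 100 x 100 square at 0.01 cm/px: exactly 1 cm2, RF near 4/pi
  sq <- matrix(0L, 120, 120)
  sq[11:110, 11:110] <- 1L
  s <- measure_particle(sq, 1L, 0.01)
  expect_equal(s$area_cm2, 1)
  expect_lt(abs(s$roundness - 4 / pi) / (4 / pi), 0.05)

  # single-pixel particle: area = cm_per_pixel^2, finite P and RF
  one <- matrix(0L, 16, 16)
  one[8, 8] <- 1L
  q <- measure_particle(one, 1L, 0.02)
  expect_equal(q$area_cm2, 0.02^2)
  expect_true(is.finite(q$perimeter_cm) && q$perimeter_cm > 0)
  expect_true(is.finite(q$roundness))

  expect_error(measure_particle(one, 7L, 0.02), "not present")
})

test_that("visible fat content implements the area-fraction percentage", {
  expect_equal(visible_fat_content(c(1, 2, 3), 100), 6)
  expect_equal(visible_fat_content(numeric(0), 50), 0)
  expect_error(visible_fat_content(c(1), 0), "positive")
  # invariant to the calibration: only the area ratio matters
  areas <- c(0.2, 0.7, 1.3)
  expect_equal(visible_fat_content(areas * 4, 80 * 4),
               visible_fat_content(areas, 80))
})

test_that("area-class histogram bins half-open, conserves n, flags empty", {
  h <- area_class_histogram(c(0.05, 0.05, 0.3, 6.0))
  expect_equal(h$counts[1], 2L)
  expect_equal(h$counts[2], 1L) # 0.3 in [0.1, 0.5)
  expect_equal(h$counts[10], 1L) # 6.0 in [5, Inf)
  expect_equal(sum(h$counts), 4L)
  expect_equal(sum(h$frequencies), 1)

  # tie at an edge goes to the upper class
  edges <- pipeline_config()$area_class_edges
  ht <- area_class_histogram(c(0.1), edges)
  expect_equal(ht$counts[2], 1L)

  # empty list: zero counts, undefined (NA) frequencies
  h0 <- area_class_histogram(numeric(0))
  expect_true(all(h0$counts == 0L))
  expect_true(all(is.na(h0$frequencies)))

  # conservation against a brute-force loop on 1000 lognormal areas
  set.seed(8)
  a <- stats::rlnorm(1000, log(0.5), 1)
  hb <- area_class_histogram(a, edges)
  expect_equal(sum(hb$counts), 1000L)
  brute <- integer(10)
  for (x in a) {
    cls <- max(which(x >= edges))
    brute[cls] <- brute[cls] + 1L
  }
  expect_equal(hb$counts, brute)
})

test_that("measure_slice composes the chain and matches generator truth", {
  ph <- generate_phantom(small_spec(n_particles = 12, noise_sd = 0,
                                    illumination_gradient = 0, seed = 31))
  m <- measure_slice(ph$image)
  expect_equal(m$n, 12L)
  expect_lt(abs(m$vfc - attr(ph$truth, "true_vfc")), 1)
  expect_equal(m$n_per_area, m$n / m$A_s)
  # summary maxima equal a brute-force rescan of the particle table
  expect_equal(m$af_max, max(m$particles$area_cm2))
  expect_equal(m$rf_max, max(m$particles$roundness))
  expect_equal(m$af_mean, mean(m$particles$area_cm2))
  expect_gte(m$af_max, m$af_mean)
  expect_gte(m$rf_max, m$rf_mean)
  expect_equal(sum(m$histogram$counts), m$n)
})

test_that("sample summaries average replicates with n-1 SDs", {
  mk <- function(vfc) {
    structure(list(source_id = "x", n = 1L, A_s = 10, n_per_area = 0.1,
                   vfc = vfc, af_mean = 0.1, af_max = 0.2, rf_mean = 1.5,
                   rf_max = 2, particles = NULL, histogram = NULL),
              class = "slice_measurement")
  }
  s <- summarize_sample(lapply(c(10, 12, 14), mk), "S")
  expect_equal(s$vfc_mean, 12)
  expect_equal(s$vfc_sd, 2)
  expect_equal(s$replicates, 3L)

  # single replicate: SD 0 by convention, flagged by replicates == 1
  s1 <- summarize_sample(list(mk(9)), "T")
  expect_equal(s1$vfc_mean, 9)
  expect_equal(s1$vfc_sd, 0)
  expect_equal(s1$replicates, 1L)

  expect_error(summarize_sample(list(), "U"), "non-empty")
})
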