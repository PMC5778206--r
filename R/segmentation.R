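#' Convert an RGB image to 256-level grayscale
#'
#' Standard luma weighting: `round(0.299 R + 0.587 G + 0.114 B)`, clamped to
#' \[0, 255\].
#'
#' @param image a [calibrated_image()].
#' @return Integer matrix `[rows, cols]` of gray levels 0--255.
#' @export
to_grayscale <- function(image) {
  stopifnot(inherits(image, "calibrated_image"))
  p <- image$pixels
  g <- 0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
  matrix(as.integer(pmin(pmax(round(g), 0L), 255L)), nrow(g), ncol(g))
}

#' Percentile-based linear contrast stretch
#'
#' Maps the gray level at the lower percentile to 0 and the one at the upper
#' percentile to 255, linearly in between, clipping outside. The mapping is
#' monotone non-decreasing in the input level. A constant image (degenerate
#' histogram) is returned unchanged with a message.
#'
#' @param gray integer matrix of gray levels 0--255.
#' @param percentiles ordered pair in \[0, 100).
#' @return Integer matrix of stretched gray levels.
#' @export
enhance_contrast <- function(gray, percentiles = c(1, 99)) {
  stopifnot(is.matrix(gray), length(percentiles) == 2L,
            percentiles[1] < percentiles[2])
  q <- stats::quantile(gray, percentiles / 100, names = FALSE)
  if (q[2] <= q[1]) {
    message("enhance_contrast: degenerate histogram (constant image?); ",
            "returning input unchanged")
    return(gray)
  }
  out <- (gray - q[1]) / (q[2] - q[1]) * 255
  matrix(as.integer(pmin(pmax(round(out), 0L), 255L)),
         nrow(gray), ncol(gray))
}

#' Median smoothing with a square window
#'
#' Exact median filter for 256-level rasters: removes salt/pepper sensor
#' noise without displacing particle boundaries much. Implemented as a
#' vectorized binary search over the 0--255 intensity range (the window
#' median is the smallest level v with at least half the window at or
#' below v), which is exact for integer gray levels and fast for large
#' images. Edges use replicate padding. `window = 1` is the identity.
#'
#' @param gray integer matrix of gray levels 0--255.
#' @param window odd window side length (>= 1).
#' @return Integer matrix of filtered gray levels.
#' @export
smooth_gray <- function(gray, window = 3L) {
  stopifnot(is.matrix(gray))
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be an odd integer >= 1, got ", window)
  }
  if (window == 1L) return(gray)
  r <- (window - 1L) %/% 2L
  nr <- nrow(gray)
  nc <- ncol(gray)
  # replicate-pad by r
  ri <- pmin(pmax(seq_len(nr + 2L * r) - r, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2L * r) - r, 1L), nc)
  p <- gray[ri, ci]
  need <- (window * window) %/% 2L + 1L
  lo <- matrix(0L, nr, nc)
  hi <- matrix(255L, nr, nc)
  rows <- seq_len(nr) + r
  cols <- seq_len(nc) + r
  for (iter in 1:8) {
    mid <- (lo + hi) %/% 2L
    cnt <- matrix(0L, nr, nc)
    for (di in -r:r) {
      for (dj in -r:r) {
        cnt <- cnt + (p[rows + di, cols + dj] <= mid)
      }
    }
    ge <- cnt >= need
    hi[ge] <- mid[ge]
    lo[!ge] <- mid[!ge] + 1L
  }
  lo
}

#' Otsu threshold of a gray-level sample
#'
#' Exhaustive between-class-variance maximisation over the 256-level
#' histogram of the supplied pixels (which may be any subset of an image,
#' e.g. slice-interior pixels only). Returns the gray level `t` such that
#' pixels `>= t` form the bright class. Ties are broken by the midpoint of
#' the maximising plateau, the usual convention. A constant input has no
#' bright class: the returned threshold exceeds every pixel.
#'
#' @param values integer vector of gray levels 0--255.
#' @return Threshold gray level (numeric scalar).
#' @export
otsu_threshold <- function(values) {
  values <- as.integer(values)
  if (length(values) == 0L) stop("no pixels supplied")
  h <- as.numeric(tabulate(values + 1L, nbins = 256L))
  n <- sum(h)
  levels <- 0:255
  w1 <- cumsum(h)              # class {0..t}
  m1 <- cumsum(h * levels)
  mu <- m1[256]
  # between-class variance for split after level t (bright class > t)
  valid <- w1 > 0 & w1 < n
  if (!any(valid)) {
    # constant input: one class only, no bright class exists
    return(max(values) + 1)
  }
  bcv <- rep(-Inf, 256)
  bcv[valid] <- (mu * w1[valid] - n * m1[valid])^2 /
    (as.numeric(w1[valid]) * (n - w1[valid]))
  best <- which(bcv == max(bcv))
  t_after <- levels[floor(mean(best))]
  t_after + 1  # pixels >= threshold are bright
}

# Lower cut of a three-class (two-threshold) Otsu. The slice scene is
# trimodal -- near-black backdrop, red meat matrix, white fat -- and a
# two-class split can land between meat and fat when fat coverage is
# substantial; the lower cut of the three-class criterion separates the
# backdrop from everything else. Falls back to the two-class threshold
# when fewer than three populated classes exist.
otsu_lower_threshold <- function(values) {
  values <- as.integer(values)
  if (length(values) == 0L) stop("no pixels supplied")
  h <- as.numeric(tabulate(values + 1L, nbins = 256L))
  n <- sum(h)
  m_cum <- cumsum(h * (0:255))
  w_cum <- cumsum(h)
  best <- -Inf
  best_t1 <- NA_integer_
  for (t1 in 0:253) {
    w1 <- w_cum[t1 + 1L]
    if (w1 == 0) next
    if (w1 == n) break
    m1 <- m_cum[t1 + 1L]
    t2 <- (t1 + 1L):254L
    w2 <- w_cum[t2 + 1L] - w1
    m2 <- m_cum[t2 + 1L] - m1
    w3 <- n - w1 - w2
    m3 <- m_cum[256L] - m1 - m2
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    # maximizing sum w_k mu_k^2 maximizes the between-class variance
    sb <- m1^2 / w1 + m2[ok]^2 / w2[ok] + m3[ok]^2 / w3[ok]
    j <- which.max(sb)
    if (sb[j] > best) {
      best <- sb[j]
      best_t1 <- t1
    }
  }
  if (!is.finite(best)) return(otsu_threshold(values))
  best_t1 + 1 # pixels >= threshold belong to the slice or brighter
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge
# components that touch diagonally with a union-find pass.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  k <- max(lab)
  if (connectivity == 4L || k <= 1L) return(compact_labels(lab))
  nr <- nrow(lab)
  nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # \ diagonal
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # / diagonal
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) > 0L) {
    parent <- seq_len(k)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1])
      b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_len(k), find, 1L)
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  compact_labels(lab)
}

# relabel to consecutive 1..n in order of first appearance (column-major)
compact_labels <- function(lab) {
  u <- unique(lab[lab > 0L])
  if (length(u) == 0L) return(lab)
  remap <- integer(max(u))
  remap[u] <- seq_along(u)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Extract the slice region from a gray image
#'
#' The slice is the bright object on the near-black backdrop. An automatic
#' between-class-variance threshold separates backdrop from slice (the
#' lower cut of a three-class criterion, robust to the bright fat mode);
#' the largest connected component is kept and its interior holes filled.
#'
#' @param gray integer matrix of gray levels (typically from
#'   [to_grayscale()], optionally enhanced/smoothed).
#' @param image the originating [calibrated_image()] (supplies calibration).
#' @return An object of class `slice_mask`: list with `mask` (logical
#'   matrix), `area_pixels`, and `A_s` (cm2; pixel count if uncalibrated).
#' @export
extract_slice_mask <- function(gray, image) {
  stopifnot(is.matrix(gray), inherits(image, "calibrated_image"))
  thr <- otsu_lower_threshold(as.vector(gray))
  fg <- gray >= thr
  if (!any(fg) || all(fg)) stop("no slice found")
  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  mask <- lab == keep
  mask <- EBImage::fillHull(mask * 1) > 0
  area_px <- sum(mask)
  cpp <- image$cm_per_pixel
  if (is.na(cpp)) {
    warning("no spatial calibration: slice area A_s reported in pixels")
    cpp <- 1
  }
  structure(
    list(mask = mask, area_pixels = area_px, A_s = area_px * cpp^2),
    class = "slice_mask"
  )
}

#' Segment fat particles within the slice
#'
#' Thresholds slice-interior pixels (automatic between-class-variance
#' criterion or a fixed level), applies morphological closing with a square
#' structuring element of side `2 * closing_radius + 1` to close the
#' meat-matrix outlines, optionally fills holes per particle, discards
#' components below `min_particle_area_px`, and labels the survivors
#' 1..n with 8-connectivity. Zero particles is a valid outcome. The fat
#' mask is always a subset of the slice mask.
#'
#' @param gray integer gray matrix (enhanced and smoothed upstream).
#' @param slice a `slice_mask` from [extract_slice_mask()].
#' @param config a [pipeline_config()].
#' @return An object of class `fat_mask`: list with `mask` (logical),
#'   `labels` (integer matrix, 0 = background), `n_particles`, and
#'   `threshold` (the gray level used).
#' @export
segment_fat <- function(gray, slice, config = pipeline_config()) {
  stopifnot(is.matrix(gray), inherits(slice, "slice_mask"),
            inherits(config, "pipeline_config"))
  if (!any(slice$mask)) stop("slice mask is empty")
  thr <- if (config$threshold_mode == "fixed") {
    config$fixed_threshold
  } else {
    otsu_threshold(gray[slice$mask])
  }
  fat <- (gray >= thr) & slice$mask
  if (config$closing_radius > 0L) {
    side <- 2L * config$closing_radius + 1L
    brush <- EBImage::makeBrush(side, shape = "box")
    fat <- EBImage::closing(fat * 1, brush) > 0
    fat <- fat & slice$mask
  }
  if (config$fill_holes && any(fat)) {
    fat <- (EBImage::fillHull(fat * 1) > 0) & slice$mask
  }
  labels <- if (any(fat)) label_components(fat) else
    matrix(0L, nrow(fat), ncol(fat))
  if (config$min_particle_area_px > 0L && max(labels) > 0L) {
    sizes <- tabulate(labels[labels > 0L])
    small <- which(sizes < config$min_particle_area_px)
    if (length(small) > 0L) {
      labels[labels %in% small] <- 0L
      labels <- compact_labels(labels)
    }
  }
  structure(
    list(mask = labels > 0L, labels = labels,
         n_particles = max(labels), threshold = thr),
    class = "fat_mask"
  )
}

#' Export a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask logical matrix (e.g. `slice_mask$mask` or `fat_mask$mask`).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path)
  invisible(path)
}
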