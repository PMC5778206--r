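# shared fixtures: small phantoms keep the suite fast

# quarter-size phantom spec (256 px, 3 cm slice radius at 0.03 cm/px)
small_spec <- function(...) {
  phantom_spec(
    image_size = c(256L, 256L),
    slice_radius = 100L,
    cm_per_pixel = 0.03,
    ...
  )
}

# boolean raster of a centred disk (pixel centres within radius)
disk_mask <- function(radius, size = 2 * radius + 21) {
  c0 <- (size + 1) / 2
  dr <- rep(seq_len(size) - c0, times = size)
  dc <- rep(seq_len(size) - c0, each = size)
  matrix(dr^2 + dc^2 <= radius^2, size, size)
}

# independent ellipse rasterizer mirroring the generator's geometry
ellipse_pixels <- function(cr, cc, a, b, theta, nr, nc) {
  rows <- max(1, floor(cr - a - 1)):min(nr, ceiling(cr + a + 1))
  cols <- max(1, floor(cc - a - 1)):min(nc, ceiling(cc + a + 1))
  dr <- rep(rows - cr, times = length(cols))
  dc <- rep(cols - cc, each = length(rows))
  u <- (dr * cos(theta) + dc * sin(theta)) / a
  v <- (-dr * sin(theta) + dc * cos(theta)) / b
  keep <- u^2 + v^2 <= 1
  cbind(rep(rows, times = length(cols))[keep],
        rep(cols, each = length(rows))[keep])
}

# brute-force 3x3 median with replicate padding (oracle for smooth_gray)
brute_median3 <- function(g) {
  nr <- nrow(g)
  nc <- ncol(g)
  out <- g
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ri <- pmin(pmax((i - 1):(i + 1), 1), nr)
      ci <- pmin(pmax((j - 1):(j + 1), 1), nc)
      out[i, j] <- stats::median(g[ri, ci][cbind(rep(1:3, 3),
                                                 rep(1:3, each = 3))])
    }
  }
  out
}

# brute-force 8-connected component count via repeated flood fill
brute_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  k <- 0L
  nr <- nrow(mask)
  nc <- ncol(mask)
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    k <- k + 1L
    queue <- start
    lab[start] <- k
    while (length(queue) > 0L) {
      p <- queue[1]
      queue <- queue[-1]
      i <- (p - 1L) %% nr + 1L
      j <- (p - 1L) %/% nr + 1L
      for (di in -1:1) {
        for (dj in -1:1) {
          ii <- i + di
          jj <- j + dj
          if (ii < 1L || ii > nr || jj < 1L || jj > nc) next
          q <- (jj - 1L) * nr + ii
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- k
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  list(n = k, labels = lab)
}

# numeric ellipse perimeter by arc-length quadrature (oracle)
ellipse_perimeter_num <- function(a, b) {
  4 * stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                       0, pi / 2, rel.tol = 1e-10)$value
}
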