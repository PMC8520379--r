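# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests.  Everything here is deliberately naive: double
# loops and direct formula evaluation, no reuse of package internals.

# Dense 2-D convolution with a truncated Gaussian kernel and mirrored
# (edge-repeating) boundaries, evaluated at a single pixel.
oracle_blur_at <- function(img, sigma, y, x) {
  r <- ceiling(4 * sigma)
  k1 <- exp(-(-r:r)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  refl <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  ys <- refl(y + (-r:r), nrow(img))
  xs <- refl(x + (-r:r), ncol(img))
  sum(k2 * img[ys, xs])
}

# Exhaustive ratio-test matcher: all-pairs distances, nearest/second nearest
# per source row, ratio test, then one-to-one by smallest distance per target.
oracle_coarse_match <- function(A, B, ratio = 0.8) {
  keep <- list()
  for (i in seq_len(nrow(A))) {
    d <- numeric(nrow(B))
    for (j in seq_len(nrow(B))) d[j] <- sqrt(sum((A[i, ] - B[j, ])^2))
    o <- order(d)
    if (length(d) >= 2L && d[o[1]] < ratio * d[o[2]]) {
      keep[[length(keep) + 1L]] <- c(i, o[1], d[o[1]])
    }
  }
  if (length(keep) == 0L) {
    return(data.frame(src = integer(0), dst = integer(0), d = numeric(0)))
  }
  m <- as.data.frame(do.call(rbind, keep))
  names(m) <- c("src", "dst", "d")
  m <- m[order(m$d, m$src), ]
  m <- m[!duplicated(m$dst), ]
  m[order(m$src), ]
}

# Exhaustive slope pre-check: census over every candidate centre, maximal
# census wins, ties to smaller |centre| then lower source index.
oracle_prescreen_idx <- function(slopes, src_idx, t) {
  n <- length(slopes)
  census <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(slopes[j] - slopes[i]) <= t) census[i] <- census[i] + 1L
    }
  }
  cand <- which(census == max(census))
  cand <- cand[order(abs(slopes[cand]), src_idx[cand])]
  win <- cand[1L]
  which(abs(slopes - slopes[win]) <= t)
}

# Direct disparity-gradient formula between matches i and j of a match frame.
oracle_dg <- function(m, i, j) {
  di <- c(m$dst_x[i] - m$src_x[i], m$dst_y[i] - m$src_y[i])
  dj <- c(m$dst_x[j] - m$src_x[j], m$dst_y[j] - m$src_y[j])
  ci <- c(m$src_x[i] + m$dst_x[i], m$src_y[i] + m$dst_y[i]) / 2
  cj <- c(m$src_x[j] + m$dst_x[j], m$src_y[j] + m$dst_y[j]) / 2
  sep <- sqrt(sum((ci - cj)^2))
  if (sep == 0) return(Inf)
  sqrt(sum((di - dj)^2)) / sep
}

# Exhaustive K-nearest-neighbour median disparity-gradient filter.
oracle_disparity_keep <- function(m, K = 4L, dg_max = 2) {
  n <- nrow(m)
  K <- min(K, n - 1L)
  keep <- logical(n)
  for (i in seq_len(n)) {
    d2 <- (m$src_x - m$src_x[i])^2 + (m$src_y - m$src_y[i])^2
    ord <- order(d2, seq_len(n))
    nbrs <- setdiff(ord, i)[seq_len(K)]
    grads <- vapply(nbrs, function(j) oracle_dg(m, i, j), numeric(1))
    keep[i] <- median(grads) < dg_max
  }
  keep
}

# Synthetic match frame with the given slopes realized as point pairs in a
# side-by-side composite of two `width`-wide frames (offset = width).
matches_with_slopes <- function(slopes, width = 100) {
  n <- length(slopes)
  src_x <- rep(10, n)
  src_y <- seq(10, 10 + n - 1)
  dst_x <- rep(20, n)
  run <- (dst_x + width) - src_x
  data.frame(
    src_idx = seq_len(n), dst_idx = seq_len(n),
    src_x = src_x, src_y = src_y,
    dst_x = dst_x, dst_y = src_y + slopes * run,
    distance = 0.2, slope = NA_real_, status = "coarse",
    stringsAsFactors = FALSE
  )
}

# Random match frame (uniform points in two 100 x 100 frames).
random_matches <- function(n, seed) {
  set.seed(seed)
  data.frame(
    src_idx = seq_len(n), dst_idx = seq_len(n),
    src_x = runif(n, 0, 99), src_y = runif(n, 0, 99),
    dst_x = runif(n, 0, 99), dst_y = runif(n, 0, 99),
    distance = runif(n, 0.1, 0.5), slope = NA_real_, status = "coarse",
    stringsAsFactors = FALSE
  )
}

# Smooth random test image: blurred white noise rescaled to [0.05, 0.95].
smooth_image <- function(h, w, seed = 1, blur = 2) {
  set.seed(seed)
  img <- gaussian_blur(matrix(rnorm(h * w), h, w), blur)
  rng <- range(img)
  0.05 + 0.9 * (img - rng[1]) / (rng[2] - rng[1])
}

# Gaussian blob image: background plus one isotropic blob.
blob_image <- function(h, w, cx, cy, sigma_blob, amp = 0.7, bg = 0.1) {
  xg <- matrix(rep(0:(w - 1), each = h), h, w)
  yg <- matrix(rep(0:(h - 1), times = w), h, w)
  bg + amp * exp(-((xg - cx)^2 + (yg - cy)^2) / (2 * sigma_blob^2))
}

# Rotate an image grid 90 degrees; pixel (x, y) maps to (y, W - 1 - x).
rot90_image <- function(img) t(img[, ncol(img):1, drop = FALSE])

# Independent per-pixel bilinear warp: output pixel p' samples img at
# H^-1 p'; out-of-frame samples are 0.
warp_image_for_test <- function(img, H) {
  h <- nrow(img); w <- ncol(img)
  Hi <- solve(H)
  out <- matrix(0, h, w)
  for (yy in 0:(h - 1)) {
    for (xx in 0:(w - 1)) {
      v <- Hi %*% c(xx, yy, 1)
      px <- v[1] / v[3]; py <- v[2] / v[3]
      if (px < 0 || px > w - 1 || py < 0 || py > h - 1) next
      x0 <- min(floor(px), w - 2); y0 <- min(floor(py), h - 2)
      tx <- px - x0; ty <- py - y0
      out[yy + 1, xx + 1] <-
        img[y0 + 1, x0 + 1] * (1 - tx) * (1 - ty) +
        img[y0 + 1, x0 + 2] * tx * (1 - ty) +
        img[y0 + 2, x0 + 1] * (1 - tx) * ty +
        img[y0 + 2, x0 + 2] * tx * ty
    }
  }
  out
}
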