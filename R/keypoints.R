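#' Detect keypoints as scale-space extrema of the DoG pyramid
#'
#' Candidate keypoints are pixels that are strict maxima or minima over their
#' 26 neighbours (8 in-plane, 9 in the DoG level above and 9 below).  Each
#' candidate is refined by a 3-D quadratic (Taylor) fit; if the fitted offset
#' exceeds 0.5 px in any dimension the integer base point is moved and the fit
#' repeated (up to 5 times).  Survivors must pass a contrast test on the
#' interpolated DoG value and an edge test on the ratio of principal
#' curvatures of the spatial Hessian, and must lie at least 5 px from the
#' image border at their octave.
#'
#' @param ss A `scale_space` from [build_scale_space()].
#' @param contrast_thresh Minimum `|D|` at the interpolated extremum
#'   (default 0.03, intensities in `[0, 1]`).
#' @param edge_ratio Maximum ratio r of principal curvatures; points with
#'   `trace^2 / det >= (r + 1)^2 / r` are discarded (default 10).
#' @return Data frame with one row per keypoint: `x`, `y` (0-based sub-pixel
#'   coordinates in the full-resolution frame), `sigma` (characteristic scale,
#'   full-resolution pixels), `orientation` (`NA` until
#'   [assign_orientations()]), `response`, `octave`, `level` (0-based),
#'   internal octave-frame columns (`x_oct`, `y_oct`, `sigma_oct`) used by the
#'   descriptor stage, and the integer seed voxel (`oy`, `ox`, `olvl`,
#'   1-based) at which the 26-neighbourhood extremum was found.
#' @export
detect_extrema <- function(ss, contrast_thresh = 0.03, edge_ratio = 10) {
  stopifnot(inherits(ss, "scale_space"))
  s <- ss$s
  out <- list()
  for (o in seq_along(ss$octaves)) {
    oct <- ss$octaves[[o]]
    d <- oct$dog
    H <- nrow(d[[1L]]); W <- ncol(d[[1L]])
    if (H < 8L || W < 8L) next
    ri <- 2:(H - 1L); ci <- 2:(W - 1L)
    for (l in 2:(s + 1L)) {
      cur <- d[[l]][ri, ci]
      nbmax <- matrix(-Inf, length(ri), length(ci))
      nbmin <- matrix(Inf, length(ri), length(ci))
      for (ll in (l - 1L):(l + 1L)) {
        dd <- d[[ll]]
        for (dy in -1:1) for (dx in -1:1) {
          if (ll == l && dy == 0L && dx == 0L) next
          sl <- dd[ri + dy, ci + dx]
          nbmax <- pmax(nbmax, sl)
          nbmin <- pmin(nbmin, sl)
        }
      }
      cand <- which((cur > nbmax | cur < nbmin) &
                      abs(cur) >= 0.5 * contrast_thresh, arr.ind = TRUE)
      if (nrow(cand) == 0L) next
      for (ci2 in seq_len(nrow(cand))) {
        seed_y <- cand[ci2, 1L] + 1L; seed_x <- cand[ci2, 2L] + 1L
        kp <- refine_extremum(d, seed_y, seed_x, l,
                              s, contrast_thresh, edge_ratio)
        if (is.null(kp)) next
        # 5 px border margin at this octave
        if (kp$x_oct < 5 || kp$x_oct > W - 1L - 5 ||
            kp$y_oct < 5 || kp$y_oct > H - 1L - 5) next
        sigma_oct <- ss$sigma0 * ss$k^(kp$lvl_cont - 1)
        out[[length(out) + 1L]] <- data.frame(
          x = kp$x_oct * oct$scale,
          y = kp$y_oct * oct$scale,
          sigma = sigma_oct * oct$scale,
          orientation = NA_real_,
          response = kp$response,
          octave = o - 1L,
          level = l - 1L,
          x_oct = kp$x_oct, y_oct = kp$y_oct, sigma_oct = sigma_oct,
          oy = seed_y, ox = seed_x, olvl = l
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(empty_keypoints())
  }
  kps <- do.call(rbind, out)
  rownames(kps) <- NULL
  kps
}

empty_keypoints <- function() {
  data.frame(
    x = numeric(0), y = numeric(0), sigma = numeric(0),
    orientation = numeric(0), response = numeric(0),
    octave = integer(0), level = integer(0),
    x_oct = numeric(0), y_oct = numeric(0), sigma_oct = numeric(0),
    oy = integer(0), ox = integer(0), olvl = integer(0)
  )
}

# Quadratic refinement of one extremum; (y, x) 1-based in octave frame,
# l 1-based DoG level.  Returns NULL when the point is rejected.
refine_extremum <- function(d, y, x, l, s, contrast_thresh, edge_ratio) {
  H <- nrow(d[[1L]]); W <- ncol(d[[1L]])
  for (iter in 1:5) {
    D0 <- d[[l]]; Dm <- d[[l - 1L]]; Dp <- d[[l + 1L]]
    gx <- (D0[y, x + 1L] - D0[y, x - 1L]) / 2
    gy <- (D0[y + 1L, x] - D0[y - 1L, x]) / 2
    gs <- (Dp[y, x] - Dm[y, x]) / 2
    dxx <- D0[y, x + 1L] - 2 * D0[y, x] + D0[y, x - 1L]
    dyy <- D0[y + 1L, x] - 2 * D0[y, x] + D0[y - 1L, x]
    dss <- Dp[y, x] - 2 * D0[y, x] + Dm[y, x]
    dxy <- (D0[y + 1L, x + 1L] - D0[y + 1L, x - 1L] -
              D0[y - 1L, x + 1L] + D0[y - 1L, x - 1L]) / 4
    dxs <- (Dp[y, x + 1L] - Dp[y, x - 1L] -
              Dm[y, x + 1L] + Dm[y, x - 1L]) / 4
    dys <- (Dp[y + 1L, x] - Dp[y - 1L, x] -
              Dm[y + 1L, x] + Dm[y - 1L, x]) / 4
    Hm <- matrix(c(dxx, dxy, dxs,
                   dxy, dyy, dys,
                   dxs, dys, dss), 3L, 3L)
    g <- c(gx, gy, gs)
    off <- tryCatch(-solve(Hm, g), error = function(e) NULL)
    if (is.null(off) || any(!is.finite(off))) return(NULL)
    if (all(abs(off) < 0.5)) {
      Dhat <- D0[y, x] + 0.5 * sum(g * off)
      if (abs(Dhat) < contrast_thresh) return(NULL)
      tr <- dxx + dyy
      det <- dxx * dyy - dxy^2
      r <- edge_ratio
      if (det <= 0 || tr^2 / det >= (r + 1)^2 / r) return(NULL)
      return(list(
        x_oct = (x - 1L) + off[1L],
        y_oct = (y - 1L) + off[2L],
        lvl_cont = l + off[3L],
        response = Dhat
      ))
    }
    # re-localize: step at most one cell per dimension
    x <- x + sign(off[1L]) * (abs(off[1L]) > 0.5)
    y <- y + sign(off[2L]) * (abs(off[2L]) > 0.5)
    l <- l + sign(off[3L]) * (abs(off[3L]) > 0.5)
    if (x < 2L || x > W - 1L || y < 2L || y > H - 1L ||
        l < 2L || l > s + 1L) {
      return(NULL)
    }
  }
  NULL
}

# Gradient magnitude and angle of one Gaussian level (central differences;
# 1-pixel border left at zero).  Cached per (octave, level) in `cache`.
level_gradient <- function(ss, octave0, lvl, cache) {
  key <- paste0(octave0, "_", lvl)
  if (!is.null(cache[[key]])) return(cache[[key]])
  g <- ss$octaves[[octave0 + 1L]]$gauss[[lvl]]
  H <- nrow(g); W <- ncol(g)
  dx <- matrix(0, H, W); dy <- matrix(0, H, W)
  dx[, 2:(W - 1L)] <- (g[, 3:W] - g[, 1:(W - 2L)]) / 2
  dy[2:(H - 1L), ] <- (g[3:H, ] - g[1:(H - 2L), ]) / 2
  val <- list(mag = sqrt(dx^2 + dy^2), ang = atan2(dy, dx) %% (2 * pi),
              H = H, W = W)
  cache[[key]] <- val
  val
}

# Gaussian level index nearest a keypoint's continuous scale.
nearest_gauss_level <- function(ss, sigma_oct) {
  idx <- round(log(sigma_oct / ss$sigma0) / log(ss$k)) + 1L
  max(1L, min(ss$s + 3L, idx))
}

#' Assign dominant gradient orientations to keypoints
#'
#' Builds a 36-bin histogram of gradient orientations in a Gaussian-weighted
#' window (weight sigma `1.5 * sigma`, radius `3 * 1.5 * sigma`) around each
#' keypoint, smooths it, and emits one keypoint per histogram peak within 80%
#' of the maximum, with parabolic interpolation of the peak angle.  Keypoints
#' whose window contains no gradient energy are dropped.
#'
#' @param kps Keypoint data frame from [detect_extrema()].
#' @param ss The `scale_space` the keypoints were detected in.
#' @return Keypoint data frame with `orientation` filled in (radians in
#'   `[0, 2*pi)`); may contain more rows than the input (multiple peaks) or
#'   fewer (flat windows).
#' @export
assign_orientations <- function(kps, ss) {
  stopifnot(inherits(ss, "scale_space"))
  if (nrow(kps) == 0L) return(kps)
  cache <- new.env(parent = emptyenv())
  nbins <- 36L
  bw <- 2 * pi / nbins
  rows <- vector("list", nrow(kps))
  for (i in seq_len(nrow(kps))) {
    kp <- kps[i, ]
    lvl <- nearest_gauss_level(ss, kp$sigma_oct)
    gr <- level_gradient(ss, kp$octave, lvl, cache)
    sig_w <- 1.5 * kp$sigma_oct
    rad <- max(1L, round(3 * sig_w))
    y0 <- round(kp$y_oct) + 1L; x0 <- round(kp$x_oct) + 1L
    ys <- max(2L, y0 - rad):min(gr$H - 1L, y0 + rad)
    xs <- max(2L, x0 - rad):min(gr$W - 1L, x0 + rad)
    if (length(ys) == 0L || length(xs) == 0L) next
    dy <- ys - 1L - kp$y_oct
    dx <- xs - 1L - kp$x_oct
    r2 <- outer(dy^2, dx^2, `+`)
    w <- gr$mag[ys, xs, drop = FALSE] * exp(-r2 / (2 * sig_w^2))
    ang <- gr$ang[ys, xs, drop = FALSE]
    keep <- r2 <= (rad + 0.5)^2 & w > 0
    if (!any(keep)) next
    bins <- (floor(ang[keep] / bw) %% nbins) + 1L
    hist <- numeric(nbins)
    acc <- rowsum(w[keep], bins)
    hist[as.integer(rownames(acc))] <- acc
    hist <- smooth_circular(smooth_circular(hist))
    mx <- max(hist)
    if (mx <= 0) next
    left <- hist[c(nbins, 1:(nbins - 1L))]
    right <- hist[c(2:nbins, 1L)]
    pk <- which(hist > left & hist > right & hist >= 0.8 * mx)
    if (length(pk) == 0L) pk <- which.max(hist)
    for (p in pk) {
      l <- left[p]; r <- right[p]
      denom <- l - 2 * hist[p] + r
      dpk <- if (abs(denom) > 1e-12) 0.5 * (l - r) / denom else 0
      theta <- ((p - 1L) + 0.5 + dpk) * bw
      row <- kp
      row$orientation <- theta %% (2 * pi)
      rows[[length(rows) + 1L]] <- row
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty_keypoints())
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# [1 4 6 4 1]/16 circular smoothing of an orientation histogram.
smooth_circular <- function(h) {
  n <- length(h)
  idx <- function(o) h[((seq_len(n) - 1L + o) %% n) + 1L]
  (idx(-2L) + 4 * idx(-1L) + 6 * h + 4 * idx(1L) + idx(2L)) / 16
}

#' Compute 128-dimensional gradient-histogram descriptors
#'
#' Standard 4 x 4 spatial grid of 8-bin orientation histograms, computed in
#' the keypoint's octave at the Gaussian level nearest its scale.  Pixel
#' contributions are rotated into the keypoint's orientation frame, spread by
#' trilinear interpolation over space and orientation, and Gaussian-weighted
#' by distance from the keypoint.  The vector is normalized to unit length,
#' clamped at 0.2 per component (illumination robustness) and renormalized.
#' Windows without gradient energy yield an all-zero (degenerate) descriptor.
#'
#' @param kps Oriented keypoint data frame from [assign_orientations()].
#' @param ss The `scale_space` the keypoints live in.
#' @return Numeric matrix, one 128-value row per keypoint; degenerate rows are
#'   all zero.
#' @export
compute_descriptors <- function(kps, ss) {
  stopifnot(inherits(ss, "scale_space"))
  D <- matrix(0, nrow(kps), 128L)
  if (nrow(kps) == 0L) return(D)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(kps))) {
    D[i, ] <- descriptor_one(kps[i, ], ss, cache)
  }
  D
}

#' @rdname compute_descriptors
#' @param kp A single keypoint row.
#' @export
compute_descriptor <- function(kp, ss) {
  as.numeric(compute_descriptors(kp, ss))
}

descriptor_one <- function(kp, ss, cache) {
  d <- 4L; nb <- 8L
  if (is.na(kp$orientation)) {
    stop("keypoint has no orientation; run assign_orientations() first",
         call. = FALSE)
  }
  lvl <- nearest_gauss_level(ss, kp$sigma_oct)
  gr <- level_gradient(ss, kp$octave, lvl, cache)
  hist_width <- 3 * kp$sigma_oct
  rad <- round(hist_width * sqrt(2) * (d + 1) / 2)
  rad <- min(rad, floor(sqrt(gr$H^2 + gr$W^2)))
  y0 <- round(kp$y_oct) + 1L; x0 <- round(kp$x_oct) + 1L
  ys <- max(2L, y0 - rad):min(gr$H - 1L, y0 + rad)
  xs <- max(2L, x0 - rad):min(gr$W - 1L, x0 + rad)
  if (length(ys) == 0L || length(xs) == 0L || ys[1] > ys[length(ys)] ||
      xs[1] > xs[length(xs)]) {
    return(numeric(128L))
  }
  ct <- cos(kp$orientation); st <- sin(kp$orientation)
  dy <- ys - 1L - kp$y_oct
  dx <- xs - 1L - kp$x_oct
  J <- matrix(dx, length(dy), length(dx), byrow = TRUE)   # x offsets
  I <- matrix(dy, length(dy), length(dx))                 # y offsets
  xr <- (J * ct + I * st) / hist_width
  yr <- (-J * st + I * ct) / hist_width
  rbin <- yr + d / 2 - 0.5
  cbin <- xr + d / 2 - 0.5
  mag <- gr$mag[ys, xs, drop = FALSE]
  keep <- rbin > -1 & rbin < d & cbin > -1 & cbin < d & mag > 0
  if (!any(keep)) return(numeric(128L))
  rbin <- rbin[keep]; cbin <- cbin[keep]
  w <- mag[keep] * exp(-(xr[keep]^2 + yr[keep]^2) / (0.5 * d^2))
  obin <- ((gr$ang[ys, xs, drop = FALSE][keep] - kp$orientation) %%
             (2 * pi)) / (2 * pi / nb)
  r0 <- floor(rbin); c0 <- floor(cbin); o0 <- floor(obin)
  fr <- rbin - r0; fc <- cbin - c0; fo <- obin - o0
  # accumulate into a (d+2) x (d+2) x nb array; border rows/cols discarded
  hist <- numeric((d + 2L)^2 * nb)
  for (dr in 0:1) for (dc in 0:1) for (do in 0:1) {
    wr <- if (dr == 0L) 1 - fr else fr
    wc <- if (dc == 0L) 1 - fc else fc
    wo <- if (do == 0L) 1 - fo else fo
    rr <- r0 + dr + 1L          # 0-based in padded grid (range 0..d+1)
    cc <- c0 + dc + 1L
    oo <- (o0 + do) %% nb
    idx <- rr + (d + 2L) * cc + (d + 2L)^2 * oo + 1L
    ww <- w * wr * wc * wo
    acc <- rowsum(ww, idx)
    ii <- as.integer(rownames(acc))
    hist[ii] <- hist[ii] + acc
  }
  harr <- array(hist, dim = c(d + 2L, d + 2L, nb))
  v <- as.numeric(harr[2:(d + 1L), 2:(d + 1L), ])
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12) return(numeric(128L))
  v <- pmin(v / nrm, 0.2)
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12) return(numeric(128L))
  v / nrm
}

#' Detect, orient and describe keypoints in one call
#'
#' @param img Grayscale matrix in `[0, 1]`.
#' @param config Parameter list from [default_config()]; relevant entries:
#'   `n_octaves`, `s`, `sigma0`, `upsample`, `contrast_thresh`, `edge_ratio`.
#' @return List with `keypoints` (data frame) and `descriptors`
#'   (matrix, one row per keypoint).
#' @export
detect_and_describe <- function(img, config = default_config()) {
  n_oct <- config$n_octaves
  max_oct <- floor(log2(min(dim(img)) / 8)) + 1L
  n_oct <- max(1L, min(n_oct, max_oct))
  ss <- build_scale_space(img, n_octaves = n_oct, s = config$s,
                          sigma0 = config$sigma0,
                          upsample = isTRUE(config$upsample))
  kps <- detect_extrema(ss, config$contrast_thresh, config$edge_ratio)
  kps <- assign_orientations(kps, ss)
  desc <- compute_descriptors(kps, ss)
  list(keypoints = kps, descriptors = desc, scale_space = ss)
}

#' Write keypoints and descriptors to CSV
#'
#' Columns: `x,y,sigma,orientation,response,octave,level,d0..d127`.
#'
#' @param kps Keypoint data frame.
#' @param desc Descriptor matrix (rows aligned with `kps`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_keypoints <- function(kps, desc, path) {
  stopifnot(nrow(kps) == nrow(desc))
  df <- kps[, c("x", "y", "sigma", "orientation", "response",
                "octave", "level")]
  dd <- as.data.frame(desc)
  names(dd) <- paste0("d", seq_len(ncol(desc)) - 1L)
  utils::write.csv(cbind(df, dd), path, row.names = FALSE)
  invisible(path)
}
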