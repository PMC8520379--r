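#' Bilinear sampling at continuous coordinates
#'
#' @param img Matrix.
#' @param x,y Numeric vectors of 0-based coordinates (x = column, y = row).
#' @return List with `value` (NA outside the image) and logical `inside`.
#' @export
sample_bilinear <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  inside <- x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  val <- rep(NA_real_, length(x))
  if (any(inside)) {
    xi <- x[inside]; yi <- y[inside]
    x0 <- pmin(floor(xi), w - 2); y0 <- pmin(floor(yi), h - 2)
    x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
    tx <- xi - x0; ty <- yi - y0
    i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
    i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
    val[inside] <- img[i00] * (1 - tx) * (1 - ty) +
      img[i01] * tx * (1 - ty) +
      img[i10] * (1 - tx) * ty +
      img[i11] * tx * ty
  }
  list(value = val, inside = inside)
}

#' Warp and blend two frames into a mosaic
#'
#' The target frame is warped into the source frame by the inverse of the
#' model homography (which maps source to target coordinates) with bilinear
#' sampling; the canvas is the union bounding box of the source frame and the
#' warped target corners.  In the overlap the frames are feather-blended:
#' each frame contributes with weight proportional to the distance from its
#' own border (plus one, so edge pixels still contribute), normalized to sum
#' to 1.  Out-of-frame samples are transparent — they get zero weight rather
#' than blending in black.
#'
#' @param src,dst Grayscale matrices in `[0, 1]`.
#' @param model A `homography_model` mapping src coordinates to dst
#'   coordinates (from [estimate_homography()]), or a bare 3x3 matrix.
#' @return A `mosaic` object: list with `canvas` (matrix, NA where neither
#'   frame covers), `origin_shift` (integer x/y translation from canvas to
#'   source coordinates), `seam_mask` (0 = empty, 1 = src only, 2 = dst only,
#'   3 = blended), and the per-frame weight layers `w_src`, `w_dst`.
#' @export
stitch <- function(src, dst, model) {
  H <- if (inherits(model, "homography_model")) model$H else model
  stopifnot(is.matrix(src), is.matrix(dst), all(dim(H) == c(3L, 3L)))
  hs <- nrow(src); ws <- ncol(src)
  hd <- nrow(dst); wd <- ncol(dst)
  Hi <- solve(H)
  corners <- apply_homography(Hi, c(0, wd - 1, 0, wd - 1),
                              c(0, 0, hd - 1, hd - 1))
  xmin <- floor(min(0, corners$x)); xmax <- ceiling(max(ws - 1, corners$x))
  ymin <- floor(min(0, corners$y)); ymax <- ceiling(max(hs - 1, corners$y))
  cw <- xmax - xmin + 1L; ch <- ymax - ymin + 1L
  if (cw * ch > 20 * max(hs * ws, hd * wd)) {
    stop("divergent model: mosaic canvas would exceed 20x the input area",
         call. = FALSE)
  }
  xg <- rep(xmin:xmax, each = ch)      # column-major canvas coordinates
  yg <- rep(ymin:ymax, times = cw)

  # source layer: direct lookup
  s_in <- xg >= 0 & xg <= ws - 1 & yg >= 0 & yg <= hs - 1
  v_src <- rep(NA_real_, cw * ch)
  v_src[s_in] <- src[cbind(yg[s_in] + 1L, xg[s_in] + 1L)]
  w_src <- numeric(cw * ch)
  w_src[s_in] <- pmin(xg[s_in], ws - 1 - xg[s_in],
                      yg[s_in], hs - 1 - yg[s_in]) + 1

  # target layer: map canvas (source-frame) points into the target frame
  p <- apply_homography(H, xg, yg)
  sb <- sample_bilinear(dst, p$x, p$y)
  v_dst <- sb$value
  w_dst <- numeric(cw * ch)
  w_dst[sb$inside] <- pmin(p$x[sb$inside], wd - 1 - p$x[sb$inside],
                           p$y[sb$inside], hd - 1 - p$y[sb$inside]) + 1

  tot <- w_src + w_dst
  canvas <- rep(NA_real_, cw * ch)
  both <- w_src > 0 & w_dst > 0
  only_s <- w_src > 0 & !both
  only_d <- w_dst > 0 & !both
  canvas[only_s] <- v_src[only_s]
  canvas[only_d] <- v_dst[only_d]
  canvas[both] <- (w_src[both] * v_src[both] + w_dst[both] * v_dst[both]) /
    tot[both]
  seam <- integer(cw * ch)
  seam[only_s] <- 1L; seam[only_d] <- 2L; seam[both] <- 3L

  structure(
    list(
      canvas = matrix(canvas, ch, cw),
      origin_shift = c(x = xmin, y = ymin),
      seam_mask = matrix(seam, ch, cw),
      w_src = matrix(w_src, ch, cw),
      w_dst = matrix(w_dst, ch, cw),
      layer_src = matrix(v_src, ch, cw),
      layer_dst = matrix(v_dst, ch, cw)
    ),
    class = "mosaic"
  )
}

#' @export
print.mosaic <- function(x, ...) {
  d <- dim(x$canvas)
  cat(sprintf(
    "mosaic: %d x %d canvas, origin shift (%d, %d), %d blended px\n",
    d[1], d[2], x$origin_shift[["x"]], x$origin_shift[["y"]],
    sum(x$seam_mask == 3L)
  ))
  invisible(x)
}

#' Default pipeline configuration
#'
#' One list holding every tunable of the pipeline; [stitch_images()] and the
#' command-line front end consume it.  Values are the canonical
#' scale-space/descriptor constants plus the mismatch-filter settings
#' (slope neighbourhood `t = 0.02`, disparity-gradient bound 2).
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    n_octaves = 4L, s = 3L, sigma0 = 1.6, upsample = FALSE,
    contrast_thresh = 0.03, edge_ratio = 10,
    ratio = 0.8, slope_t = 0.02, dg_max = 2, K = 4L,
    ransac_thresh = 3.0, n_iter = 1000L, seed = 17L,
    method = "projective"
  )
}

#' Merge a partial configuration into the defaults
#'
#' @param overrides Named list (e.g. parsed from a JSON config file);
#'   unknown keys are an error.
#' @return Full configuration list.
#' @export
merge_config <- function(overrides = list()) {
  cfg <- default_config()
  if (length(overrides) == 0L) return(cfg)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad) > 0L) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  cfg
}

#' Full stitching pipeline for an image pair
#'
#' Detect -> describe -> ratio-test match -> slope pre-check ->
#' disparity-gradient filter -> RANSAC homography -> feather-blended mosaic.
#'
#' @param img_a,img_b Grayscale matrices in `[0, 1]` (source and target
#'   frames).
#' @param config Configuration list (see [default_config()]).
#' @return List with `mosaic`, `model`, `matches` (with final statuses),
#'   `keypoints_a`, `keypoints_b` and a `report` list of counts/parameters.
#' @export
stitch_images <- function(img_a, img_b, config = default_config()) {
  fa <- detect_and_describe(img_a, config)
  fb <- detect_and_describe(img_b, config)
  if (nrow(fa$keypoints) == 0L || nrow(fb$keypoints) == 0L) {
    stop("no keypoints detected in one of the frames", call. = FALSE)
  }
  m <- coarse_match(fa$keypoints, fb$keypoints, fa$descriptors,
                    fb$descriptors, ratio = config$ratio)
  m <- filter_matches(m, src_width = ncol(img_a), t = config$slope_t,
                      K = config$K, dg_max = config$dg_max)
  model <- estimate_homography(m, ransac_thresh = config$ransac_thresh,
                               n_iter = config$n_iter, seed = config$seed,
                               method = config$method)
  mos <- stitch(img_a, img_b, model)
  list(
    mosaic = mos, model = model, matches = m,
    keypoints_a = fa$keypoints, keypoints_b = fb$keypoints,
    report = c(
      filter_report(m, params = config[c("ratio", "slope_t", "dg_max", "K",
                                         "ransac_thresh", "n_iter", "seed")]),
      list(
        n_keypoints_a = nrow(fa$keypoints),
        n_keypoints_b = nrow(fb$keypoints),
        n_inliers = length(model$inlier_indices),
        rms_error_px = model$rms_error
      )
    )
  )
}
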