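#' Specification of a synthetic endoscopic fixture pair
#'
#' The generator emulates the aspects of endoscopic frame pairs that matter
#' for gradient-based feature pipelines: band-limited mucosal texture, smooth
#' polyp-like blobs, radial vignetting, a known projective transform between
#' frames, a smooth multiplicative illumination change, and sensor noise.
#'
#' @param size Frame size `c(height, width)` in pixels (default 256 x 256).
#' @param n_blobs Number of polyp-like Gaussian blobs (default 12).
#' @param vignette_strength Radial vignette depth in `[0, 1]` (default 0.3).
#' @param rotation Rotation of frame B relative to A, degrees (default 2).
#' @param scale Isotropic scale factor (default 1).
#' @param translation Translation `c(tx, ty)` in pixels (default `c(30, 10)`).
#' @param skew Perspective skew: magnitude of the two projective entries of
#'   the homography (default 0; typical "hard" value 2e-5).
#' @param noise_sigma Gaussian sensor-noise standard deviation in intensity
#'   units (default 0.01).
#' @param illum_strength Amplitude of the linear multiplicative illumination
#'   field applied to frame B (default 0.1; 0 disables it).
#' @param false_match_fraction Default fraction for
#'   [inject_false_matches()] (default 0).
#' @param n_correspondences Number of ground-truth point pairs sampled
#'   (default 40).
#' @param seed Integer seed; the seed fully determines the pair.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(size = c(256L, 256L), n_blobs = 12L,
                         vignette_strength = 0.3, rotation = 2,
                         scale = 1, translation = c(30, 10), skew = 0,
                         noise_sigma = 0.01, illum_strength = 0.1,
                         false_match_fraction = 0,
                         n_correspondences = 40L, seed = 1L) {
  stopifnot(length(size) == 2L, all(size >= 32L),
            vignette_strength >= 0, vignette_strength <= 1,
            scale > 0, noise_sigma >= 0,
            false_match_fraction >= 0, false_match_fraction <= 0.5)
  structure(
    list(size = as.integer(size), n_blobs = as.integer(n_blobs),
         vignette_strength = vignette_strength, rotation = rotation,
         scale = scale, translation = translation, skew = skew,
         noise_sigma = noise_sigma, illum_strength = illum_strength,
         false_match_fraction = false_match_fraction,
         n_correspondences = as.integer(n_correspondences),
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Build a homography from rotation / scale / translation / skew
#'
#' Rotation and scale act about the frame centre; the two perspective
#' entries (`H[3,1]`, `H[3,2]`) are set to `skew` and `-skew`.
#'
#' @param rotation Degrees.
#' @param scale Isotropic scale.
#' @param translation `c(tx, ty)` pixels.
#' @param skew Perspective entry magnitude.
#' @param center `c(cx, cy)` rotation centre (0-based pixel coordinates).
#' @return 3x3 homography with `H[3,3] = 1`, mapping frame-A coordinates to
#'   frame-B coordinates.
#' @export
make_homography <- function(rotation = 0, scale = 1, translation = c(0, 0),
                            skew = 0, center = c(0, 0)) {
  th <- rotation * pi / 180
  M <- scale * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2,
                      byrow = TRUE)
  core <- rbind(cbind(M, translation), c(skew, -skew, 1))
  Tc <- matrix(c(1, 0, center[1], 0, 1, center[2], 0, 0, 1), 3, 3,
               byrow = TRUE)
  Tci <- matrix(c(1, 0, -center[1], 0, 1, -center[2], 0, 0, 1), 3, 3,
                byrow = TRUE)
  H <- Tc %*% core %*% Tci
  H / H[3, 3]
}

# Warp img by H (output pixel p' samples img at H^-1 p'); same frame size,
# out-of-frame samples are 0.  Exact pass-through for the identity.
warp_image <- function(img, H) {
  h <- nrow(img); w <- ncol(img)
  Hi <- solve(H)
  xg <- rep(0:(w - 1L), each = h)
  yg <- rep(0:(h - 1L), times = w)
  p <- apply_homography(Hi, xg, yg)
  sb <- sample_bilinear(img, p$x, p$y)
  v <- sb$value
  v[!sb$inside] <- 0
  matrix(v, h, w)
}

#' Generate a synthetic endoscopic frame pair with ground truth
#'
#' Frame A is band-limited noise texture (Gaussian-filtered white noise,
#' sigma 3 px) plus smooth Gaussian blobs and a radial vignette.  Frame B is
#' A warped by the specified homography, multiplied by a smooth linear
#' illumination field, with Gaussian sensor noise added.  Ground-truth
#' correspondences are sampled in the overlap; each satisfies
#' `H p = p'` exactly (pre-noise).
#'
#' @param spec A [fixture_spec()].
#' @return A `fixture_pair`: list with `frame_a`, `frame_b`, `true_H`,
#'   `correspondences` (data frame `src_x, src_y, dst_x, dst_y`) and `spec`.
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  h <- spec$size[1]; w <- spec$size[2]
  center <- c((w - 1) / 2, (h - 1) / 2)
  H <- make_homography(spec$rotation, spec$scale, spec$translation,
                       spec$skew, center)
  local_seed(spec$seed, {
    base <- matrix(stats::rnorm(h * w), h, w)
    base <- gaussian_blur(base, 3)
    rng <- range(base)
    base <- 0.05 + 0.9 * (base - rng[1]) / (rng[2] - rng[1])
    xg <- matrix(rep(0:(w - 1L), each = h), h, w)
    yg <- matrix(rep(0:(h - 1L), times = w), h, w)
    for (b in seq_len(spec$n_blobs)) {
      cx <- stats::runif(1, 0.1 * w, 0.9 * w)
      cy <- stats::runif(1, 0.1 * h, 0.9 * h)
      sg <- stats::runif(1, 3, 8)
      amp <- stats::runif(1, 0.1, 0.3) * sample(c(-1, 1), 1)
      base <- base + amp * exp(-((xg - cx)^2 + (yg - cy)^2) / (2 * sg^2))
    }
    if (spec$vignette_strength > 0) {
      r2 <- ((xg - center[1])^2 + (yg - center[2])^2) /
        (center[1]^2 + center[2]^2)
      base <- base * (1 - spec$vignette_strength * r2)
    }
    base[base < 0] <- 0; base[base > 1] <- 1
    frame_a <- base

    frame_b <- warp_image(frame_a, H)
    if (spec$illum_strength > 0) {
      a <- stats::runif(1, -spec$illum_strength, spec$illum_strength)
      b2 <- stats::runif(1, -spec$illum_strength, spec$illum_strength)
      frame_b <- frame_b * (1 + a * (xg / w - 0.5) + b2 * (yg / h - 0.5))
    }
    if (spec$noise_sigma > 0) {
      frame_b <- frame_b + matrix(stats::rnorm(h * w, sd = spec$noise_sigma),
                                  h, w)
    }
    if (spec$illum_strength > 0 || spec$noise_sigma > 0) {
      frame_b[frame_b < 0] <- 0; frame_b[frame_b > 1] <- 1
    }

    margin <- 8
    n_want <- spec$n_correspondences
    sx <- numeric(0); sy <- numeric(0); dx <- numeric(0); dy <- numeric(0)
    tries <- 0L
    while (length(sx) < n_want && tries < 200L * n_want) {
      tries <- tries + 1L
      px <- stats::runif(1, margin, w - 1 - margin)
      py <- stats::runif(1, margin, h - 1 - margin)
      q <- apply_homography(H, px, py)
      if (q$x >= margin && q$x <= w - 1 - margin &&
          q$y >= margin && q$y <= h - 1 - margin) {
        sx <- c(sx, px); sy <- c(sy, py); dx <- c(dx, q$x); dy <- c(dy, q$y)
      }
    }
    if (length(sx) < max(4L, n_want %/% 2L)) {
      stop("homography maps most of the frame outside the canvas; ",
           "reduce the transform magnitude", call. = FALSE)
    }
    structure(
      list(frame_a = frame_a, frame_b = frame_b, true_H = H,
           correspondences = data.frame(src_x = sx, src_y = sy,
                                        dst_x = dx, dst_y = dy),
           spec = spec),
      class = "fixture_pair"
    )
  })
}

#' Build a match set with a known fraction of deliberate mismatches
#'
#' Returns the pair's ground-truth correspondences as coarse matches, plus
#' `round(fraction * n)` false pairs whose target points are uniformly
#' mislocated over the target frame, each at least 10 px from where the true
#' homography would put them.  The `truth` column labels rows for scoring.
#'
#' @param pair A `fixture_pair` from [generate_pair()].
#' @param fraction Fraction of false pairs relative to the number of true
#'   pairs, in `[0, 0.5]`.
#' @param seed Integer seed for the mislocation draws.
#' @return Match data frame (columns as [coarse_match()]) with an extra
#'   logical column `truth` (`TRUE` for genuine correspondences).
#' @export
inject_false_matches <- function(pair, fraction = pair$spec$false_match_fraction,
                                 seed = pair$spec$seed + 1L) {
  stopifnot(inherits(pair, "fixture_pair"), fraction >= 0, fraction <= 0.5)
  tc <- pair$correspondences
  n <- nrow(tc)
  n_false <- round(fraction * n)
  h <- pair$spec$size[1]; w <- pair$spec$size[2]
  margin <- 8
  local_seed(seed, {
    fsx <- numeric(0); fsy <- numeric(0); fdx <- numeric(0); fdy <- numeric(0)
    while (length(fsx) < n_false) {
      px <- stats::runif(1, margin, w - 1 - margin)
      py <- stats::runif(1, margin, h - 1 - margin)
      q <- apply_homography(pair$true_H, px, py)
      bx <- stats::runif(1, margin, w - 1 - margin)
      by <- stats::runif(1, margin, h - 1 - margin)
      if (sqrt((bx - q$x)^2 + (by - q$y)^2) >= 10) {
        fsx <- c(fsx, px); fsy <- c(fsy, py)
        fdx <- c(fdx, bx); fdy <- c(fdy, by)
      }
    }
    m <- data.frame(
      src_idx = seq_len(n + n_false), dst_idx = seq_len(n + n_false),
      src_x = c(tc$src_x, fsx), src_y = c(tc$src_y, fsy),
      dst_x = c(tc$dst_x, fdx), dst_y = c(tc$dst_y, fdy),
      distance = c(stats::runif(n, 0.1, 0.3),
                   stats::runif(n_false, 0.2, 0.5)),
      slope = NA_real_, status = "coarse",
      truth = c(rep(TRUE, n), rep(FALSE, n_false)),
      stringsAsFactors = FALSE
    )
    m
  })
}

#' Fixture presets
#'
#' `easy`: gentle motion (2 deg rotation, translation (30, 10), noise 0.01).
#' `hard`: stronger motion and degradation (8 deg rotation, scale 0.95,
#' perspective skew 2e-5, noise 0.02, stronger illumination change).
#'
#' @param preset `"easy"` or `"hard"`.
#' @param seed Integer seed.
#' @param size Frame size.
#' @return A [fixture_spec()].
#' @export
fixture_preset <- function(preset = c("easy", "hard"), seed = 1L,
                           size = c(256L, 256L)) {
  preset <- match.arg(preset)
  if (preset == "easy") {
    fixture_spec(size = size, seed = seed)
  } else {
    fixture_spec(size = size, rotation = 8, scale = 0.95,
                 translation = c(40, 15), skew = 2e-5, noise_sigma = 0.02,
                 illum_strength = 0.2, seed = seed)
  }
}

#' Write a fixture pair to disk
#'
#' Writes `frame_a.tif`, `frame_b.tif` (16-bit TIFF, exact to 1/65535),
#' `true_H.json` and `correspondences.csv` into `dir`.
#'
#' @param pair A `fixture_pair`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(pair$frame_a, file.path(dir, "frame_a.tif"))
  write_image(pair$frame_b, file.path(dir, "frame_b.tif"))
  jsonlite::write_json(
    list(true_H = pair$true_H, spec = unclass(pair$spec)),
    file.path(dir, "true_H.json"), digits = NA, auto_unbox = TRUE,
    matrix = "rowmajor"
  )
  utils::write.csv(pair$correspondences,
                   file.path(dir, "correspondences.csv"), row.names = FALSE)
  invisible(dir)
}
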