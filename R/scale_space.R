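#' Normalized 1-D Gaussian kernel
#'
#' Truncated at radius `ceiling(4 * sigma)` and renormalized so the weights
#' sum to 1 (within 1e-10), which keeps blurring strictly mean-preserving.
#'
#' @param sigma Positive standard deviation in pixels.
#' @return Numeric vector of length `2 * ceiling(4 * sigma) + 1`.
#' @export
gaussian_kernel <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("sigma must be a positive finite number", call. = FALSE)
  }
  r <- ceiling(4 * sigma)
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w / sum(w)
}

# Reflect an out-of-range 1-based index back into 1..n (edge pixel repeated:
# 0 -> 1, -1 -> 2, n+1 -> n, ...).  Vectorized; assumes |overshoot| < n.
reflect_index <- function(i, n) {
  i <- ifelse(i < 1L, 1L - i, i)
  ifelse(i > n, 2L * n + 1L - i, i)
}

# Dense n x n matrix applying 1-D convolution with reflective boundaries
# along one axis; blur = K_rows %*% img %*% t(K_cols).
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  for (o in seq(-r, r)) {
    src <- reflect_index(idx + o, n)
    K[cbind(idx, src)] <- K[cbind(idx, src)] + kernel[o + r + 1L]
  }
  K
}

#' Gaussian blur with reflective boundary handling
#'
#' Separable convolution with a normalized 1-D Gaussian of radius
#' `ceiling(4 * sigma)`.  Out-of-range samples are taken from the mirrored
#' image (edge pixel repeated), which avoids the dark-frame artifacts that
#' zero padding produces on vignetted endoscopic frames.
#'
#' @param img Numeric matrix.
#' @param sigma Positive standard deviation in pixels.
#' @return Blurred matrix of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img))
  k <- gaussian_kernel(sigma)
  Kr <- conv_matrix(nrow(img), k)
  Kc <- conv_matrix(ncol(img), k)
  Kr %*% img %*% t(Kc)
}

#' Build a Gaussian / difference-of-Gaussians scale-space pyramid
#'
#' Each octave holds `s + 3` Gaussian levels whose (octave-relative) scales
#' form the geometric sequence `sigma0 * k^i` with `k = 2^(1/s)`, and the
#' `s + 2` difference-of-Gaussians (DoG) levels obtained by subtracting each
#' Gaussian level from the next.  The next octave starts from the level with
#' scale `2 * sigma0`, downsampled by taking every second pixel.
#'
#' The input is treated as effectively unsmoothed: the first level is the
#' input blurred to `sigma0`.  No initial 2x upsampling is performed unless
#' `upsample = TRUE`.
#'
#' @param img Single-channel matrix with values in `[0, 1]`, at least 16 x 16.
#' @param n_octaves Number of octaves (default 4).
#' @param s Intervals per octave (default 3).
#' @param sigma0 Base scale of the first level (default 1.6 px).
#' @param upsample If `TRUE`, the image is first doubled in size by bilinear
#'   interpolation (keypoint coordinates are still reported in the original
#'   frame).
#' @return An object of class `scale_space`: a list with elements `octaves`
#'   (each a list with `gauss`, `dog`, `sigma_rel`, `sigma_abs`, `scale`),
#'   plus `s`, `sigma0`, `k`, `upsample`.
#' @export
build_scale_space <- function(img, n_octaves = 4L, s = 3L, sigma0 = 1.6,
                              upsample = FALSE) {
  stopifnot(is.matrix(img), s >= 1L, n_octaves >= 1L, sigma0 > 0)
  if (nrow(img) < 16L || ncol(img) < 16L) {
    stop("image must be at least 16 x 16 for pyramid construction",
         call. = FALSE)
  }
  base <- img
  base_scale <- 1
  if (upsample) {
    base <- upsample2x(img)
    base_scale <- 0.5
  }
  min_dim <- min(dim(base)) / 2^(n_octaves - 1L)
  if (min_dim < 8) {
    stop("image too small for ", n_octaves,
         " octaves (smallest octave would be under 8 px)", call. = FALSE)
  }
  k <- 2^(1 / s)
  sigma_rel <- sigma0 * k^(seq_len(s + 3L) - 1L)
  # incremental blurs within an octave: sigma_rel[i]^2 = sigma_rel[i-1]^2 + inc^2
  inc <- sqrt(diff(sigma_rel^2))

  octaves <- vector("list", n_octaves)
  cur <- gaussian_blur(base, sigma0)
  for (o in seq_len(n_octaves)) {
    gauss <- vector("list", s + 3L)
    gauss[[1L]] <- cur
    for (i in seq_len(s + 2L)) {
      gauss[[i + 1L]] <- gaussian_blur(gauss[[i]], inc[i])
    }
    dog <- vector("list", s + 2L)
    for (i in seq_len(s + 2L)) {
      dog[[i]] <- gauss[[i + 1L]] - gauss[[i]]
    }
    scale <- base_scale * 2^(o - 1L)
    octaves[[o]] <- list(
      gauss = gauss, dog = dog,
      sigma_rel = sigma_rel,
      sigma_abs = sigma_rel * scale,
      scale = scale
    )
    if (o < n_octaves) {
      # level s+1 has octave-relative scale 2 * sigma0
      nxt <- gauss[[s + 1L]]
      cur <- nxt[seq(1L, nrow(nxt), by = 2L), seq(1L, ncol(nxt), by = 2L),
                 drop = FALSE]
    }
  }
  structure(
    list(octaves = octaves, s = s, sigma0 = sigma0, k = k,
         upsample = upsample, input_dim = dim(img)),
    class = "scale_space"
  )
}

#' @export
print.scale_space <- function(x, ...) {
  cat("Gaussian scale space:", length(x$octaves), "octaves,",
      x$s + 3L, "levels each, sigma0 =", x$sigma0,
      ", k = 2^(1/", x$s, ")\n", sep = " ")
  for (o in seq_along(x$octaves)) {
    d <- dim(x$octaves[[o]]$gauss[[1L]])
    cat(sprintf("  octave %d: %d x %d, sigma %s\n", o - 1L, d[1], d[2],
                paste(sprintf("%.3f", x$octaves[[o]]$sigma_abs),
                      collapse = " ")))
  }
  invisible(x)
}

# 2x bilinear upsampling used by the optional --upsample flag.
upsample2x <- function(img) {
  h <- nrow(img); w <- ncol(img)
  yi <- (seq_len(2L * h) - 1) / 2
  xi <- (seq_len(2L * w) - 1) / 2
  y0 <- pmin(floor(yi), h - 1); x0 <- pmin(floor(xi), w - 1)
  ty <- yi - y0; tx <- xi - x0
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
  A <- img[y0 + 1, , drop = FALSE]; B <- img[y1 + 1, , drop = FALSE]
  rows <- A * (1 - ty) + B * ty
  C <- rows[, x0 + 1, drop = FALSE]; D <- rows[, x1 + 1, drop = FALSE]
  C * matrix(1 - tx, nrow(C), length(tx), byrow = TRUE) +
    D * matrix(tx, nrow(D), length(tx), byrow = TRUE)
}

#' Dump every pyramid level to PNG (debug aid)
#'
#' Writes one file per Gaussian level, named
#' `oct{i}_lvl{j}_sigma{sigma:.3f}.png`, with intensities clamped to `[0, 1]`.
#'
#' @param ss A `scale_space` object.
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
dump_scale_space <- function(ss, dir) {
  stopifnot(inherits(ss, "scale_space"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (o in seq_along(ss$octaves)) {
    oct <- ss$octaves[[o]]
    for (j in seq_along(oct$gauss)) {
      p <- file.path(dir, sprintf("oct%d_lvl%d_sigma%.3f.png",
                                  o - 1L, j - 1L, oct$sigma_abs[j]))
      write_image(oct$gauss[[j]], p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
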