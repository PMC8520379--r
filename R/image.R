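#' Read an image from PNG or TIFF
#'
#' Loads an 8- or 16-bit integer or float image and normalizes intensities to
#' `[0, 1]`.  Multi-channel images are kept as `H x W x C` arrays; use
#' [to_grayscale()] to obtain the single-channel matrix the pyramid code
#' expects.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix (grayscale) or `H x W x C` array with values in
#'   `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (PNG and TIFF are supported)",
         call. = FALSE)
  )
  # readPNG/readTIFF already scale integer data to [0,1]; clamp float inputs
  img[img < 0] <- 0
  img[img > 1] <- 1
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) {
    img <- img[, , 1L]
  }
  img
}

#' Write a grayscale image to PNG or TIFF
#'
#' Values are clamped to `[0, 1]`.  PNG output is 8-bit; TIFF output is
#' 16-bit, which fixture round-trips use to avoid quantization flakiness.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(is.matrix(img))
  img[img < 0] <- 0
  img[img > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 16L)
  } else {
    stop("unsupported output format '", ext, "'", call. = FALSE)
  }
  invisible(path)
}

#' Convert an image to a single-channel grayscale matrix
#'
#' Three-channel input is combined with the Rec. 601 luminance weights
#' 0.299 R + 0.587 G + 0.114 B.  Integer storage (raw counts rather than
#' `[0, 1]` floats) is divided by the maximum of its bit depth.
#'
#' @param img Numeric matrix (`H x W`) or array (`H x W x C`, `C` in `{1, 3}`).
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
to_grayscale <- function(img) {
  if (is.matrix(img)) {
    out <- img
  } else if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc == 1L) {
      out <- img[, , 1L]
    } else if (nc == 3L) {
      out <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    } else {
      stop("unsupported channel count: ", nc, " (expected 1 or 3)",
           call. = FALSE)
    }
  } else {
    stop("expected a 2-D matrix or H x W x C array", call. = FALSE)
  }
  if (is.integer(out) || max(out) > 1 + 1e-9) {
    # integer-coded pixels: normalize by the type maximum
    mx <- max(out)
    denom <- if (mx <= 255) 255 else if (mx <= 4095) 4095 else 65535
    out <- out / denom
  }
  storage.mode(out) <- "double"
  out
}

#' Evaluate/restore-safe seeded execution
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions never perturb user-level randomness.
#' @noRd
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}
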