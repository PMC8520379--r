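#' Apply a 3x3 homography to 2-D points
#'
#' @param H 3x3 matrix.
#' @param x,y Coordinate vectors.
#' @return List with transformed `x` and `y`.
#' @export
apply_homography <- function(H, x, y) {
  w <- H[3, 1] * x + H[3, 2] * y + H[3, 3]
  list(
    x = (H[1, 1] * x + H[1, 2] * y + H[1, 3]) / w,
    y = (H[2, 1] * x + H[2, 2] * y + H[2, 3]) / w
  )
}

# Hartley-normalized direct linear transform.  pts: list(sx, sy, dx, dy).
# Returns 3x3 H with H[3,3] = 1, or NULL on degeneracy.
dlt_homography <- function(sx, sy, dx, dy) {
  n <- length(sx)
  norm_pts <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    d <- mean(sqrt((x - mx)^2 + (y - my)^2))
    if (d < 1e-12) return(NULL)
    s <- sqrt(2) / d
    T <- matrix(c(s, 0, -s * mx, 0, s, -s * my, 0, 0, 1), 3, 3, byrow = TRUE)
    list(x = s * (x - mx), y = s * (y - my), T = T)
  }
  ns <- norm_pts(sx, sy); nd <- norm_pts(dx, dy)
  if (is.null(ns) || is.null(nd)) return(NULL)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- ns$x[i]; Y <- ns$y[i]; u <- nd$x[i]; v <- nd$y[i]
    A[2 * i - 1, ] <- c(-X, -Y, -1, 0, 0, 0, u * X, u * Y, u)
    A[2 * i, ] <- c(0, 0, 0, -X, -Y, -1, v * X, v * Y, v)
  }
  sv <- svd(A, nu = 0, nv = 9)
  h <- sv$v[, 9]
  Hn <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% Hn %*% ns$T
  if (abs(H[3, 3]) < 1e-12 || abs(det(H)) < 1e-12) return(NULL)
  H / H[3, 3]
}

# Least-squares affine fit (6 dof), returned as a homography matrix.
affine_fit <- function(sx, sy, dx, dy) {
  X <- cbind(sx, sy, 1)
  cf <- tryCatch(qr.solve(X, cbind(dx, dy)), error = function(e) NULL)
  if (is.null(cf)) return(NULL)
  rbind(t(cf), c(0, 0, 1))
}

# TRUE if any 3 of the 4 sampled points are (nearly) collinear.
sample_degenerate <- function(x, y) {
  combs <- utils::combn(4L, 3L)
  for (j in seq_len(ncol(combs))) {
    i <- combs[, j]
    area <- abs((x[i[2]] - x[i[1]]) * (y[i[3]] - y[i[1]]) -
                  (x[i[3]] - x[i[1]]) * (y[i[2]] - y[i[1]]))
    if (area < 1e-6) return(TRUE)
  }
  FALSE
}

#' Estimate the inter-frame homography from retained matches
#'
#' Seeded RANSAC over minimal 4-point samples solved by the normalized DLT;
#' inliers are classified by symmetric transfer error
#' (`sqrt(||H p - p'||^2 + ||H^-1 p' - p||^2) < ransac_thresh`).  The largest
#' consensus set is refit by least squares (all-inlier DLT), inliers are
#' re-classified under the refit, and the refit is repeated once more.
#'
#' @param matches Match data frame; rows with status `retained` are used
#'   (all rows if no `status` column or none retained).
#' @param ransac_thresh Inlier threshold in pixels (default 3).
#' @param n_iter Number of RANSAC iterations (default 1000).
#' @param seed RNG seed for sampling (default 17); the caller's RNG state is
#'   untouched.
#' @param method `"projective"` (default) or `"affine"` — affine is a
#'   fallback for low-parallax frame pairs where 8 dof overfit.
#' @return A `homography_model`: list with `H` (3x3, `H[3,3] = 1`),
#'   `inlier_indices` (row indices into the used matches), `rms_error`
#'   (forward reprojection RMS over inliers, px), `n_used`, `method`.
#' @export
estimate_homography <- function(matches, ransac_thresh = 3.0, n_iter = 1000L,
                                seed = 17L, method = c("projective",
                                                       "affine")) {
  method <- match.arg(method)
  if (!is.null(matches$status) && any(matches$status == "retained")) {
    matches <- matches[matches$status == "retained", , drop = FALSE]
  }
  n <- nrow(matches)
  if (n < 4L) {
    stop("homography estimation needs at least 4 matches, got ", n,
         call. = FALSE)
  }
  sx <- matches$src_x; sy <- matches$src_y
  dx <- matches$dst_x; dy <- matches$dst_y

  fit <- function(idx) {
    if (method == "affine") affine_fit(sx[idx], sy[idx], dx[idx], dy[idx])
    else dlt_homography(sx[idx], sy[idx], dx[idx], dy[idx])
  }
  sym_err <- function(H) {
    Hi <- solve(H)
    f <- apply_homography(H, sx, sy)
    b <- apply_homography(Hi, dx, dy)
    sqrt((f$x - dx)^2 + (f$y - dy)^2 + (b$x - sx)^2 + (b$y - sy)^2)
  }

  best_inl <- integer(0)
  local_seed(seed, {
    for (it in seq_len(n_iter)) {
      idx <- sample.int(n, 4L)
      if (sample_degenerate(sx[idx], sy[idx]) ||
          sample_degenerate(dx[idx], dy[idx])) next
      H <- fit(idx)
      if (is.null(H)) next
      e <- sym_err(H)
      inl <- which(is.finite(e) & e < ransac_thresh)
      if (length(inl) > length(best_inl)) best_inl <- inl
    }
  })
  if (length(best_inl) < 4L) {
    stop("RANSAC failed to find a consensus set of at least 4 matches",
         call. = FALSE)
  }
  inl <- best_inl
  for (pass in 1:2) {
    H <- fit(inl)
    if (is.null(H)) stop("degenerate consensus set", call. = FALSE)
    e <- sym_err(H)
    inl2 <- which(is.finite(e) & e < ransac_thresh)
    if (length(inl2) >= 4L) inl <- inl2 else break
  }
  H <- fit(inl)
  if (is.null(H)) stop("degenerate consensus set", call. = FALSE)
  f <- apply_homography(H, sx[inl], sy[inl])
  rms <- sqrt(mean((f$x - dx[inl])^2 + (f$y - dy[inl])^2))
  structure(
    list(H = H, inlier_indices = inl, rms_error = rms, n_used = n,
         method = method),
    class = "homography_model"
  )
}

#' @export
print.homography_model <- function(x, ...) {
  cat(sprintf("homography_model (%s): %d/%d inliers, RMS %.3f px\n",
              x$method, length(x$inlier_indices), x$n_used, x$rms_error))
  print(round(x$H, 6))
  invisible(x)
}
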