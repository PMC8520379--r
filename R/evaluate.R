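#' Benchmark the two mismatch filters on synthetic ground truth
#'
#' Generates `n_pairs` seeded fixture pairs, injects a known fraction of
#' deliberately mislocated matches into each ground-truth correspondence
#' set, runs the slope pre-check plus disparity-gradient filter, and scores
#' how many injected mismatches were removed and how many genuine
#' correspondences were kept.
#'
#' @param n_pairs Number of fixture pairs (default 20).
#' @param false_fraction Fraction of injected mismatches (default 0.3).
#' @param seed Base seed; pair `i` uses `seed + i - 1`.
#' @param preset Fixture preset (`"easy"` or `"hard"`).
#' @param t,K,dg_max Filter parameters (defaults as in [default_config()]).
#' @return List with `per_pair` (data frame: seed, n_true, n_false,
#'   false_removed, true_retained), `false_removal_rate` and
#'   `true_retention_rate` (pooled over all pairs).
#' @export
evaluate_filters <- function(n_pairs = 20L, false_fraction = 0.3,
                             seed = 1L, preset = "easy",
                             t = 0.02, K = 4L, dg_max = 2) {
  rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    sp <- fixture_preset(preset, seed = seed + i - 1L)
    pair <- generate_pair(sp)
    m <- inject_false_matches(pair, fraction = false_fraction)
    m <- filter_matches(m, src_width = sp$size[2], t = t, K = K,
                        dg_max = dg_max)
    retained <- m$status == "retained"
    rows[[i]] <- data.frame(
      seed = sp$seed,
      n_true = sum(m$truth),
      n_false = sum(!m$truth),
      false_removed = sum(!m$truth & !retained),
      true_retained = sum(m$truth & retained)
    )
  }
  per_pair <- do.call(rbind, rows)
  list(
    per_pair = per_pair,
    false_removal_rate = sum(per_pair$false_removed) /
      sum(per_pair$n_false),
    true_retention_rate = sum(per_pair$true_retained) /
      sum(per_pair$n_true)
  )
}

# Median corner-transfer error (px) between an estimated and the true
# homography over the four frame corners.
corner_transfer_error <- function(H_est, H_true, size) {
  h <- size[1]; w <- size[2]
  cx <- c(0, w - 1, 0, w - 1); cy <- c(0, 0, h - 1, h - 1)
  pe <- apply_homography(H_est, cx, cy)
  pt <- apply_homography(H_true, cx, cy)
  stats::median(sqrt((pe$x - pt$x)^2 + (pe$y - pt$y)^2))
}

#' Benchmark the full pipeline against known transforms
#'
#' Runs detection, description, matching, both mismatch filters and RANSAC
#' homography estimation on seeded 256 x 256 fixture pairs whose rotations
#' are drawn from +/-`max_rotation` degrees and scales from
#' `[1 - scale_range, 1 + scale_range]`, and reports the corner-transfer
#' error of the recovered transform against the generating one.
#'
#' @param n_pairs Number of pairs (default 10).
#' @param seed Base seed.
#' @param size Frame size (default 256 x 256).
#' @param max_rotation Maximum |rotation| in degrees (default 10).
#' @param scale_range Half-width of the scale interval (default 0.1).
#' @param noise_sigma Sensor noise level (default 0.01).
#' @param config Pipeline configuration.
#' @return List with `per_pair` (data frame: seed, rotation, scale,
#'   corner_error_px, n_retained, n_inliers) and `median_corner_error_px`.
#' @export
evaluate_endtoend <- function(n_pairs = 10L, seed = 1L,
                              size = c(256L, 256L), max_rotation = 10,
                              scale_range = 0.1, noise_sigma = 0.01,
                              config = default_config()) {
  rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    si <- seed + i - 1L
    pars <- local_seed(si * 1000L + 7L, {
      c(stats::runif(1, -max_rotation, max_rotation),
        stats::runif(1, 1 - scale_range, 1 + scale_range))
    })
    sp <- fixture_spec(size = size, rotation = pars[1], scale = pars[2],
                       translation = c(30, 10), noise_sigma = noise_sigma,
                       seed = si)
    pair <- generate_pair(sp)
    res <- tryCatch(stitch_images(pair$frame_a, pair$frame_b, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(seed = si, rotation = pars[1],
                              scale = pars[2], corner_error_px = Inf,
                              n_retained = 0L, n_inliers = 0L)
      next
    }
    err <- corner_transfer_error(res$model$H, pair$true_H, sp$size)
    rows[[i]] <- data.frame(
      seed = si, rotation = pars[1], scale = pars[2],
      corner_error_px = err,
      n_retained = sum(res$matches$status == "retained"),
      n_inliers = length(res$model$inlier_indices)
    )
  }
  per_pair <- do.call(rbind, rows)
  list(
    per_pair = per_pair,
    median_corner_error_px = stats::median(per_pair$corner_error_px)
  )
}
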