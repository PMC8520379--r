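make_kp <- function(x_oct, y_oct, sigma_oct = 1.6, octave = 0L,
                    orientation = NA_real_) {
  data.frame(
    x = x_oct * 2^octave, y = y_oct * 2^octave,
    sigma = sigma_oct * 2^octave, orientation = orientation,
    response = 0.1, octave = octave, level = 1L,
    x_oct = x_oct, y_oct = y_oct, sigma_oct = sigma_oct,
    oy = round(y_oct) + 1L, ox = round(x_oct) + 1L, olvl = 2L
  )
}

test_that("constant images yield no keypoints", {
  ss <- build_scale_space(matrix(0.5, 48, 48), n_octaves = 2L)
  expect_equal(nrow(detect_extrema(ss)), 0L)
})

test_that("an isolated Gaussian blob is found at its centre and scale", {
  img <- blob_image(96, 96, cx = 48, cy = 48, sigma_blob = 4)
  ss <- build_scale_space(img, n_octaves = 3L)
  kps <- detect_extrema(ss)
  expect_gte(nrow(kps), 1L)
  d <- sqrt((kps$x - 48)^2 + (kps$y - 48)^2)
  best <- which.min(d)
  expect_lt(d[best], 2)
  # characteristic scale within a factor 1.6 of sigma_blob * sqrt(2)
  target <- 4 * sqrt(2)
  expect_gt(kps$sigma[best], target / 1.6)
  expect_lt(kps$sigma[best], target * 1.6)
})

test_that("edge responses are suppressed by the curvature-ratio test", {
  # vertical step edge, slightly smoothed so the DoG response is strong
  img <- matrix(0.1, 64, 64)
  img[, 33:64] <- 0.9
  img <- gaussian_blur(img, 1)
  ss <- build_scale_space(img, n_octaves = 2L)
  kps <- detect_extrema(ss, edge_ratio = 10)
  if (nrow(kps) > 0L) {
    # nothing surviving on the edge line itself
    expect_false(any(abs(kps$x - 32) < 3))
  } else {
    succeed()
  }
})

test_that("every keypoint re-verifies as a 26-neighbourhood extremum", {
  img <- generate_pair(fixture_spec(size = c(128L, 128L), seed = 11,
                                    noise_sigma = 0))$frame_a
  ss <- build_scale_space(img, n_octaves = 3L)
  kps <- detect_extrema(ss)
  expect_gt(nrow(kps), 5L)
  for (i in seq_len(nrow(kps))) {
    d <- ss$octaves[[kps$octave[i] + 1L]]$dog
    y <- kps$oy[i]; x <- kps$ox[i]; l <- kps$olvl[i]
    centre <- d[[l]][y, x]
    nb <- c()
    for (ll in (l - 1L):(l + 1L)) {
      for (dy in -1:1) for (dx in -1:1) {
        if (ll == l && dy == 0L && dx == 0L) next
        nb <- c(nb, d[[ll]][y + dy, x + dx])
      }
    }
    expect_true(centre > max(nb) || centre < min(nb))
  }
})

test_that("a linear ramp yields the analytic gradient orientation", {
  w <- 64
  # ramp rising along +x: column j holds the constant value 0.2 + 0.005 * j
  img <- matrix(rep(0.2 + 0.005 * (0:(w - 1)), each = w), w, w)
  ss <- build_scale_space(img, n_octaves = 1L)
  kp <- make_kp(32, 32)
  out <- assign_orientations(kp, ss)
  expect_gte(nrow(out), 1L)
  # circular distance from 0 (the +x direction)
  d <- abs(((out$orientation[1] + pi) %% (2 * pi)) - pi)
  expect_lt(d, 5 * pi / 180)
})

test_that("an isotropic blob centre still receives an orientation", {
  img <- blob_image(64, 64, cx = 32, cy = 32, sigma_blob = 6)
  ss <- build_scale_space(img, n_octaves = 1L)
  out <- assign_orientations(make_kp(32, 32, sigma_oct = 3.2), ss)
  expect_gte(nrow(out), 1L)
})

test_that("detection, orientations and descriptors are 90-degree equivariant", {
  img <- generate_pair(fixture_spec(size = c(128L, 128L), seed = 5,
                                    noise_sigma = 0))$frame_a
  rot <- rot90_image(img)
  fa <- detect_and_describe(img)
  fb <- detect_and_describe(rot)
  expect_gt(nrow(fa$keypoints), 10L)

  w <- ncol(img)
  mx <- fa$keypoints$y                  # (x, y) -> (y, W - 1 - x)
  my <- w - 1 - fa$keypoints$x
  nn_dist <- numeric(nrow(fa$keypoints))
  nn_idx <- integer(nrow(fa$keypoints))
  for (i in seq_along(mx)) {
    d <- sqrt((fb$keypoints$x - mx[i])^2 + (fb$keypoints$y - my[i])^2)
    nn_idx[i] <- which.min(d)
    nn_dist[i] <- min(d)
  }
  expect_gte(mean(nn_dist <= 2), 0.7)

  matched <- which(nn_dist <= 2)
  # orientations rotate with the image: theta -> theta - pi/2
  dtheta <- (fb$keypoints$orientation[nn_idx[matched]] -
               fa$keypoints$orientation[matched] + pi / 2 + pi) %%
    (2 * pi) - pi
  expect_lt(median(abs(dtheta)), 5 * pi / 180)

  # descriptors travel with their keypoints: the rotated counterpart is
  # closer than 95% of unrelated keypoints for most matches
  frac_beaten <- vapply(matched, function(i) {
    di <- sqrt(rowSums((fb$descriptors -
                          matrix(fa$descriptors[i, ], nrow(fb$descriptors),
                                 128, byrow = TRUE))^2))
    mean(di[-nn_idx[i]] > di[nn_idx[i]])
  }, numeric(1))
  expect_gte(mean(frac_beaten >= 0.95), 0.7)
})

test_that("descriptors are unit norm, flat patches degenerate, brightness invariant", {
  img <- generate_pair(fixture_spec(size = c(128L, 128L), seed = 9,
                                    noise_sigma = 0))$frame_a
  res <- detect_and_describe(img)
  expect_gt(nrow(res$keypoints), 5L)
  norms <- sqrt(rowSums(res$descriptors^2))
  nondeg <- norms > 0
  expect_true(any(nondeg))
  expect_lt(max(abs(norms[nondeg] - 1)), 1e-6)

  # flat patch: all-zero flagged descriptor
  ss_flat <- build_scale_space(matrix(0.5, 64, 64), n_octaves = 1L)
  d_flat <- compute_descriptor(make_kp(32, 32, orientation = 0), ss_flat)
  expect_equal(d_flat, numeric(128))

  # a global intensity rescale by 1.5 (no clipping: compare the frame with
  # the same frame dimmed to 1/1.5) leaves descriptors unchanged
  ss_dim <- build_scale_space(img / 1.5,
                              n_octaves = length(res$scale_space$octaves))
  d_dim <- compute_descriptors(res$keypoints, ss_dim)
  expect_lt(max(abs(d_dim - res$descriptors)), 1e-3)
})
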