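test_that("grayscale conversion handles trivial and random inputs", {
  zero <- array(0, dim = c(4, 5, 3))
  expect_equal(to_grayscale(zero), matrix(0, 4, 5))

  white <- array(1, dim = c(4, 5, 3))
  expect_equal(to_grayscale(white), matrix(1, 4, 5))

  set.seed(42)
  rgb <- array(sample(0:255, 6 * 7 * 3, replace = TRUE), dim = c(6, 7, 3))
  got <- to_grayscale(rgb)
  want <- matrix(0, 6, 7)
  for (i in 1:6) for (j in 1:7) {
    want[i, j] <- (0.299 * rgb[i, j, 1] + 0.587 * rgb[i, j, 2] +
                     0.114 * rgb[i, j, 3]) / 255
  }
  expect_lt(max(abs(got - want)), 1e-6)

  expect_error(to_grayscale(array(0, dim = c(4, 4, 2))), "channel")
})

test_that("Gaussian kernels are normalized and blur preserves constants", {
  for (sg in c(0.5, 1.6, 3.2)) {
    expect_lt(abs(sum(gaussian_kernel(sg)) - 1), 1e-10)
  }
  expect_error(gaussian_kernel(-1), "positive")
  expect_error(gaussian_blur(matrix(0, 8, 8), 0), "positive")

  const <- matrix(0.37, 20, 24)
  expect_lt(max(abs(gaussian_blur(const, 2.5) - const)), 1e-8)
})

test_that("blur composition obeys the Gaussian semigroup property", {
  img <- smooth_image(64, 64, seed = 7, blur = 1)
  s1 <- 1.2; s2 <- 2.0
  twice <- gaussian_blur(gaussian_blur(img, s1), s2)
  once <- gaussian_blur(img, sqrt(s1^2 + s2^2))
  m <- ceiling(4 * sqrt(s1^2 + s2^2))
  interior <- (m + 1):(64 - m)
  expect_lt(mean(abs(twice[interior, interior] - once[interior, interior])),
            1e-4)
})

test_that("impulse response matches a dense 2-D convolution oracle", {
  img <- matrix(0, 31, 31)
  img[16, 16] <- 1
  blurred <- gaussian_blur(img, 1.6)
  expect_lt(abs(blurred[16, 16] - oracle_blur_at(img, 1.6, 16, 16)), 1e-8)
  # off-centre pixel too
  expect_lt(abs(blurred[13, 19] - oracle_blur_at(img, 1.6, 13, 19)), 1e-8)
})

test_that("scale space has geometric sigmas, halving octaves, exact DoG", {
  img <- smooth_image(64, 64, seed = 3)
  ss <- build_scale_space(img, n_octaves = 2L, s = 3L, sigma0 = 1.6)

  for (oct in ss$octaves) {
    ratios <- oct$sigma_rel[-1] / oct$sigma_rel[-length(oct$sigma_rel)]
    expect_equal(ratios, rep(2^(1 / 3), length(ratios)), tolerance = 1e-12)
    # DoG levels reconstruct bitwise as differences of stored Gaussian levels
    for (i in seq_along(oct$dog)) {
      expect_identical(oct$dog[[i]], oct$gauss[[i + 1]] - oct$gauss[[i]])
    }
  }
  expect_equal(dim(ss$octaves[[2]]$gauss[[1]]), c(32L, 32L))
  expect_equal(length(ss$octaves[[1]]$gauss), 6L)
  expect_equal(length(ss$octaves[[1]]$dog), 5L)

  # DoG of a constant image is identically zero
  ss0 <- build_scale_space(matrix(0.5, 32, 32), n_octaves = 2L)
  for (oct in ss0$octaves) {
    for (d in oct$dog) expect_lt(max(abs(d)), 1e-10)
  }

  # linearity: doubling intensity doubles every DoG value
  ss2 <- build_scale_space(2 * img, n_octaves = 2L)
  for (o in 1:2) {
    for (i in seq_along(ss$octaves[[o]]$dog)) {
      expect_lt(max(abs(ss2$octaves[[o]]$dog[[i]] -
                          2 * ss$octaves[[o]]$dog[[i]])), 1e-8)
    }
  }

  expect_error(build_scale_space(matrix(0.5, 20, 20), n_octaves = 4L),
               "octaves")
  expect_error(build_scale_space(matrix(0.5, 8, 8)), "16 x 16")
})
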