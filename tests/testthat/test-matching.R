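fake_kps <- function(n, seed) {
  set.seed(seed)
  data.frame(x = runif(n, 0, 99), y = runif(n, 0, 99))
}

test_that("identical descriptor sets match one-to-one at distance zero", {
  set.seed(1)
  D <- matrix(runif(30 * 128), 30, 128)
  D <- D / sqrt(rowSums(D^2))
  kps <- fake_kps(30, 2)
  m <- coarse_match(kps, kps, D, D)
  expect_equal(nrow(m), 30L)
  expect_equal(m$src_idx, m$dst_idx)
  expect_lt(max(m$distance), 1e-6)
})

test_that("the ratio test accepts and rejects at the threshold", {
  a <- matrix(0, 1, 128); a[1, 1] <- 1
  # targets at distances 0.9 and 1.0 -> ratio 0.9, rejected at 0.8
  b <- matrix(0, 2, 128)
  b[1, 1] <- 1; b[1, 2] <- 0.9
  b[2, 1] <- 1; b[2, 3] <- 1.0
  kps1 <- data.frame(x = 1, y = 1)
  kps2 <- data.frame(x = c(1, 2), y = c(1, 2))
  expect_equal(nrow(coarse_match(kps1, kps2, a, b, ratio = 0.8)), 0L)
  # distances 0.5 and 1.0 -> ratio 0.5, accepted
  b[1, 2] <- 0.5
  expect_equal(nrow(coarse_match(kps1, kps2, a, b, ratio = 0.8)), 1L)

  expect_warning(coarse_match(kps1, kps2, matrix(0, 1, 128),
                              matrix(0, 2, 128)), "degenerate")
})

test_that("coarse matching equals the exhaustive double-loop oracle", {
  set.seed(10)
  A <- matrix(runif(50 * 128), 50, 128)
  B <- matrix(runif(60 * 128), 60, 128)
  m <- coarse_match(fake_kps(50, 3), fake_kps(60, 4), A, B)
  o <- oracle_coarse_match(A, B)
  expect_equal(m$src_idx, o$src)
  expect_equal(m$dst_idx, o$dst)
  expect_equal(m$distance, o$d, tolerance = 1e-12)
})

test_that("composite slopes follow the closed forms and the oracle", {
  p <- prescreen_params(t = 0.02, composite_offset = 100)
  # pure horizontal translation: all slopes exactly 0
  m <- data.frame(src_idx = 1:5, dst_idx = 1:5,
                  src_x = 1:5 * 10, src_y = seq(5, 45, by = 10),
                  dst_x = 1:5 * 10 + 20, dst_y = seq(5, 45, by = 10),
                  distance = 0.2, slope = NA_real_, status = "coarse")
  expect_equal(composite_slopes(m, p)$slope, rep(0, 5))

  # pure vertical translation d with aligned x: slope = d / offset
  m2 <- m
  m2$dst_x <- m2$src_x
  m2$dst_y <- m2$src_y + 7
  expect_equal(composite_slopes(m2, p)$slope, rep(7 / 100, 5))

  # known similarity transform: per-pair recomputation oracle
  set.seed(5)
  m3 <- random_matches(20, seed = 5)
  got <- composite_slopes(m3, p)$slope
  want <- vapply(seq_len(20), function(i) {
    (m3$dst_y[i] - m3$src_y[i]) / ((m3$dst_x[i] + 100) - m3$src_x[i])
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)

  expect_error(composite_slopes(m, p, src_width = 150), "composite_offset")
})

test_that("prescreen keeps dense slope clusters and drops outliers", {
  p <- prescreen_params(t = 0.02, composite_offset = 100)

  # single tight cluster: everything preselected
  m <- composite_slopes(matches_with_slopes(rep(0.01, 20)), p)
  out <- prescreen(m, p)
  expect_true(all(out$status == "preselected"))

  # 15 inliers around 0 plus 5 gross outliers: exactly the inliers survive
  set.seed(8)
  slopes <- c(runif(15, -0.005, 0.005), 0.3, -0.4, 0.9, -0.7, 0.5)
  m2 <- composite_slopes(matches_with_slopes(slopes), p)
  out2 <- prescreen(m2, p)
  expect_equal(which(out2$status == "preselected"), 1:15)
  expect_equal(which(out2$status == "rejected_slope"), 16:20)
  # agreement with the exhaustive census oracle over all 20 centres
  expect_equal(which(out2$status == "preselected"),
               oracle_prescreen_idx(m2$slope, m2$src_idx, 0.02))

  expect_warning(prescreen(m2[1:2, ], p), "fewer than 3")
})

test_that("prescreen tie-breaks deterministically and is order-invariant", {
  p <- prescreen_params(t = 0.02, composite_offset = 100)
  # two equal-size clusters at +0.1 and -0.1
  slopes <- c(rep(0.1, 6), rep(-0.1, 6))
  m <- composite_slopes(matches_with_slopes(slopes), p)
  out <- prescreen(m, p)
  kept1 <- sort(out$src_idx[out$status == "preselected"])
  expect_equal(length(kept1), 6L)

  for (perm_seed in 1:5) {
    set.seed(perm_seed)
    mp <- m[sample(nrow(m)), ]
    outp <- prescreen(mp, p)
    expect_equal(sort(outp$src_idx[outp$status == "preselected"]), kept1)
  }
})

test_that("tightening t never adds matches when the winning centre is fixed", {
  # a dominant exactly-repeated slope forces the same centre at both widths
  set.seed(14)
  slopes <- c(rep(0, 8), rnorm(12, 0, 0.015))
  m <- matches_with_slopes(slopes)
  p1 <- prescreen_params(t = 0.01, composite_offset = 100)
  p2 <- prescreen_params(t = 0.02, composite_offset = 100)
  k1 <- prescreen(composite_slopes(m, p1), p1)
  k2 <- prescreen(composite_slopes(m, p2), p2)
  s1 <- k1$src_idx[k1$status == "preselected"]
  s2 <- k2$src_idx[k2$status == "preselected"]
  expect_true(all(s1 %in% s2))
})

test_that("disparity gradient matches hand arithmetic and the oracle", {
  mk <- function(sx, sy, dx, dy) {
    data.frame(src_x = sx, src_y = sy, dst_x = dx, dst_y = dy)
  }
  # equal disparities (pure translation): gradient 0 exactly
  expect_equal(disparity_gradient(mk(0, 0, 5, 3), mk(10, 10, 15, 13)), 0)
  # d(m) = (2,0), d(n) = (0,0), midpoints 4 px apart -> 0.5
  expect_equal(disparity_gradient(mk(0, 0, 2, 0), mk(5, 0, 5, 0)), 0.5)
  # coincident midpoints -> Inf
  expect_equal(disparity_gradient(mk(0, 0, 2, 0), mk(2, 0, 0, 0)), Inf)
  # identical match twice -> error
  expect_error(disparity_gradient(mk(1, 2, 3, 4), mk(1, 2, 3, 4)),
               "undefined")

  # pairwise gradients on 30 random matches vs direct recomputation
  m <- random_matches(30, seed = 12)
  for (i in 1:10) {
    for (j in (i + 1):11) {
      expect_equal(disparity_gradient(m[i, ], m[j, ]), oracle_dg(m, i, j),
                   tolerance = 1e-12)
    }
  }
})

test_that("disparity filter keeps translations, drops the opposing injection", {
  # one global translation: everything retained
  g <- expand.grid(x = seq(0, 40, 10), y = seq(0, 30, 10))
  m <- data.frame(src_idx = seq_len(nrow(g)), dst_idx = seq_len(nrow(g)),
                  src_x = g$x, src_y = g$y,
                  dst_x = g$x + 5, dst_y = g$y + 2,
                  distance = 0.2, slope = 0, status = "preselected")
  out <- disparity_filter(m)
  expect_true(all(out$status == "retained"))

  # inject one match whose disparity opposes its 20 consistent neighbours
  # (all true matches translated by (5, 0); the injected one by (-30, 0))
  m_true <- m
  m_true$dst_y <- g$y
  inj <- data.frame(src_idx = 21L, dst_idx = 21L, src_x = 55, src_y = 15,
                    dst_x = 55 - 30, dst_y = 15, distance = 0.2, slope = 0,
                    status = "preselected")
  m2 <- rbind(m_true, inj)
  out2 <- disparity_filter(m2)
  expect_equal(which(out2$status == "rejected_disparity"), 21L)
  expect_equal(oracle_disparity_keep(m2), out2$status == "retained")
})

test_that("a gradient of exactly 2 is rejected (strict inequality)", {
  # midpoints on a vertical line, disparities growing at exactly twice the
  # midpoint separation: every pairwise gradient is exactly 2
  i <- 0:4
  m <- data.frame(src_idx = i + 1L, dst_idx = i + 1L,
                  src_x = -i, src_y = i, dst_x = i, dst_y = i,
                  distance = 0.2, slope = 0, status = "preselected")
  for (a in 1:4) {
    expect_equal(disparity_gradient(m[a, ], m[a + 1, ]), 2)
  }
  out <- disparity_filter(m, K = 4)
  expect_true(all(out$status == "rejected_disparity"))
})

test_that("both filters are order-invariant on random inputs", {
  for (seed in c(21, 22, 23)) {
    m <- random_matches(40, seed = seed)
    ref <- filter_matches(m, src_width = 100)
    ref_keep <- sort(ref$src_idx[ref$status == "retained"])
    set.seed(seed + 100)
    mp <- m[sample(nrow(m)), ]
    got <- filter_matches(mp, src_width = 100)
    expect_equal(sort(got$src_idx[got$status == "retained"]), ref_keep)
  }
})
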