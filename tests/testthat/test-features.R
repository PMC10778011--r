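test_that("mean gray value is the masked arithmetic mean", {
  m <- matrix(1L, 4, 4)
  expect_equal(mean_gray_value(matrix(7, 4, 4), m), 7)

  ch <- matrix(0, 3, 3)
  ch[1, 1] <- 10
  ch[2, 2] <- 20
  ch[3, 3] <- 30
  mask3 <- diag(3)
  expect_equal(mean_gray_value(ch, mask3), 20)

  # checkerboard 0/255 under a mask with 50 pixels of each
  board <- matrix(rep_len(c(0, 255), 100), 10, 10)
  mask10 <- matrix(1L, 10, 10)
  expect_equal(sum(board == 255), 50)
  expect_equal(mean_gray_value(board, mask10), 127.5)
  # direct summation oracle
  expect_equal(mean_gray_value(board, mask10), sum(board) / 100)
})

test_that("mean gray value guards its inputs", {
  expect_error(
    mean_gray_value(matrix(1, 3, 3), matrix(0L, 3, 3)),
    class = "breslowmsi_domain_error"
  )
  expect_error(
    mean_gray_value(matrix(1, 3, 3), matrix(1L, 4, 4)),
    class = "breslowmsi_input_error"
  )
})

test_that("perimeter matches analytic shapes", {
  sq10 <- square_mask(32, 10, 10)
  expect_lt(abs(measure_perimeter(sq10) - 40) / 40, 0.05)

  d50 <- disk_mask(128, 50)
  expect_lt(abs(measure_perimeter(d50) - 2 * pi * 50) / (2 * pi * 50), 0.02)
  # accuracy holds across radii
  for (r in c(20, 35)) {
    dd <- disk_mask(96, r)
    expect_lt(abs(measure_perimeter(dd) - 2 * pi * r) / (2 * pi * r), 0.02)
  }

  px <- matrix(0L, 5, 5)
  px[3, 3] <- 1L
  p1 <- measure_perimeter(px)
  expect_gt(p1, 0)
  expect_lt(p1, 6)
  expect_error(measure_perimeter(matrix(0L, 3, 3)), class = "breslowmsi_domain_error")
})

test_that("shape descriptors hit their analytic limits", {
  d50 <- disk_mask(128, 50)
  dd <- shape_descriptors(d50)
  expect_gte(dd$circularity, 0.98)
  expect_lte(dd$circularity, 1)
  expect_gte(dd$solidity, 0.98)
  expect_lt(abs(dd$roundness - 1), 0.02)

  sq <- square_mask(128, 50, 30)
  ds <- shape_descriptors(sq)
  expect_lt(abs(ds$circularity - pi / 4), 0.05)
  expect_gte(ds$solidity, 0.98)

  ell <- grid_mask(160, function(x, y) {
    ((x - 80) / 60)^2 + ((y - 80) / 30)^2 <= 1
  })
  de <- shape_descriptors(ell)
  expect_lt(abs(de$roundness - 0.5), 0.05)
  # moment major axis of the 2:1 ellipse is its full width
  expect_lt(abs(de$major_axis_px - 120) / 120, 0.02)
})

test_that("solidity of a plus-sign matches an independent hull-area oracle", {
  plus <- grid_mask(21, function(x, y) {
    (x >= 9 & x <= 13) | (y >= 9 & y <= 13)
  })
  # trim to a plus (clip the full-width bars to 5..17)
  plus <- grid_mask(21, function(x, y) {
    (x >= 9 & x <= 13 & y >= 3 & y <= 19) |
      (y >= 9 & y <= 13 & x >= 3 & x <= 19)
  })
  d <- shape_descriptors(plus)
  pts <- which(plus == 1L, arr.ind = TRUE)
  oracle <- sum(plus) / hull_area_oracle(pts)
  expect_lt(d$solidity, 1)
  expect_equal(d$solidity, oracle, tolerance = 1e-12)
})

test_that("circularity equals the brute-force area/perimeter recomputation", {
  set.seed(123)
  for (i in 1:20) {
    m <- blob_mask(72, radius = 15 + (i %% 8), amp = 0.04 + 0.02 * (i %% 6), seed = 1000 + i)
    d <- shape_descriptors(m)
    oracle <- min(4 * pi * sum(m) / measure_perimeter(m)^2, 1)
    expect_identical(d$circularity, oracle)
  }
})

test_that("descriptors are invariant to 90-degree rotation and stable at 45", {
  ell <- grid_mask(128, function(x, y) {
    ((x - 64.5) / 40)^2 + ((y - 64.5) / 25)^2 <= 1
  })
  d0 <- shape_descriptors(ell)
  d90 <- shape_descriptors(rotate90(ell))
  expect_equal(d0$circularity, d90$circularity)
  expect_equal(d0$solidity, d90$solidity)
  expect_equal(d0$roundness, d90$roundness)
  expect_equal(d0$area_px, d90$area_px)

  d45 <- shape_descriptors(rotate_nn(ell, 45))
  expect_lt(abs(d0$circularity - d45$circularity), 0.05)
  expect_lt(abs(d0$solidity - d45$solidity), 0.05)
  expect_lt(abs(d0$roundness - d45$roundness), 0.05)
})

test_that("descriptors are stable under 2x and 4x rescaling", {
  blob_at_scale <- function(s) {
    n <- 64 * s
    grid_mask(n, function(x, y) {
      xc <- x - (n + 1) / 2
      yc <- y - (n + 1) / 2
      th <- atan2(yc, xc)
      r <- sqrt(xc^2 + yc^2)
      rb <- s * 20 * (1 + 0.15 * cos(2 * th + 1) +
        0.1 * cos(3 * th + 2.5) + 0.07 * cos(5 * th + 4))
      r <= rb
    })
  }
  d1 <- shape_descriptors(blob_at_scale(1))
  for (s in c(2, 4)) {
    ds <- shape_descriptors(blob_at_scale(s))
    expect_lt(abs(d1$circularity - ds$circularity), 0.03)
    expect_lt(abs(d1$solidity - ds$solidity), 0.03)
    expect_lt(abs(d1$roundness - ds$roundness), 0.03)
  }
})

test_that("degenerate and multi-component masks are rejected", {
  tiny <- matrix(0L, 8, 8)
  tiny[4, 4:6] <- 1L # 3 px < 5
  expect_error(shape_descriptors(tiny), class = "breslowmsi_domain_error")

  two <- matrix(0L, 20, 20)
  two[3:6, 3:6] <- 1L
  two[14:17, 14:17] <- 1L
  expect_error(shape_descriptors(two), class = "breslowmsi_domain_error")

  # diagonal adjacency counts as connected (8-connectivity)
  diag8 <- matrix(0L, 12, 12)
  diag8[3:5, 3:5] <- 1L
  diag8[6:8, 6:8] <- 1L
  expect_silent(shape_descriptors(diag8))
})

test_that("extract_features applies one mask to all channels and is pure", {
  mask <- disk_mask(48, 15)
  img <- list(channels = list(
    AF = matrix(3L, 48, 48),
    G = matrix(12L, 48, 48),
    R = matrix(80L, 48, 48),
    IR = matrix(140L, 48, 48)
  ))
  f <- extract_features(img, mask)
  expect_equal(f$mean_G, 12)
  expect_equal(f$mean_R, 80)
  expect_equal(f$mean_IR, 140)
  expect_gte(f$circularity, 0.95)
  expect_identical(f, extract_features(img, mask))
  expect_error(
    extract_features(list(channels = img$channels[c("G", "R")]), mask),
    class = "breslowmsi_input_error"
  )
})
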