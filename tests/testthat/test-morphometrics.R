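test_that("circularity matches closed forms", {
  expect_equal(circularity(100 * pi, 20 * pi), 1)          # circle r = 10
  expect_equal(circularity(100, 40), pi / 4)               # square side 10
  expect_error(circularity(-1, 10), "positive")
  expect_error(circularity(10, 0), "positive")
})

test_that("circularity round-trips the published example pair by inversion", {
  # area 815 um^2 with circularity 0.53 implies the perimeter below
  perimeter <- sqrt(4 * pi * 815 / 0.53)
  expect_equal(circularity(815, perimeter), 0.53, tolerance = 0.005 / 0.53)
})

test_that("circularity is scale-invariant", {
  set.seed(42)
  for (i in 1:20) {
    a <- runif(1, 10, 1000); p <- runif(1, 20, 200); k <- runif(1, 0.1, 10)
    expect_equal(circularity(k^2 * a, k * p), circularity(a, p))
  }
})

test_that("measured digital disk has circularity near 1", {
  # marching squares tracks the pixel staircase on curved boundaries, an
  # upward perimeter bias of up to ~6% on disks, so circularity reads up
  # to ~12% low there; the band reflects the estimator, not the shape
  m <- disk_mask(50)
  meas <- measure_mask(m, pixel_size = 1)
  expect_equal(meas$area, sum(m))
  expect_gt(meas$circularity, 0.85)
  expect_lte(meas$circularity, 1)
  expect_equal(meas$perimeter, 2 * pi * 50, tolerance = 0.07)
})

test_that("measured square matches hand-derived contour geometry", {
  m <- matrix(FALSE, 14, 14)
  m[3:12, 3:12] <- TRUE   # 10x10 filled square
  meas <- measure_mask(m, pixel_size = 1)
  expect_equal(meas$area, 100)
  # marching squares cuts each corner: 4 straight runs of length 9 plus
  # 4 diagonal corner segments of length sqrt(2)/2
  expect_equal(meas$perimeter, 4 * 9 + 4 * sqrt(2) / 2, tolerance = 1e-6)
  expect_lt(abs(meas$circularity - pi / 4) / (pi / 4), 0.10)
})

test_that("single-pixel masks scale area with pixel size and clip circularity", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_warning(meas <- measure_mask(m, pixel_size = 2), "clipped")
  expect_equal(meas$area, 4)
  expect_equal(meas$circularity, 1)
})

test_that("measure_mask rejects empty and multi-component masks", {
  expect_error(measure_mask(matrix(FALSE, 4, 4)), "empty mask")
  m <- matrix(FALSE, 8, 8); m[2, 2] <- TRUE; m[6, 6] <- TRUE
  expect_error(measure_mask(m), "2 connected components")
})

test_that("the digital disk maximizes circularity among random blobs", {
  disk <- suppressWarnings(measure_mask(disk_mask(20))$circularity)
  set.seed(7)
  for (i in 1:10) {
    m <- disk_mask(20)
    # carve random bites out of the disk rim to roughen it
    idx <- which(m, arr.ind = TRUE)
    rim <- idx[(idx[, 1] - 23)^2 + (idx[, 2] - 23)^2 > 15^2, , drop = FALSE]
    bite <- rim[sample(nrow(rim), nrow(rim) %/% 3), , drop = FALSE]
    m[bite] <- FALSE
    comp <- EBImage::bwlabel(m * 1)
    main <- which.max(tabulate(comp[comp > 0]))
    m2 <- comp == main
    rough <- suppressWarnings(measure_mask(m2)$circularity)
    expect_lte(rough, disk + 1e-9)
  }
})

test_that("masked fluorescence sums intensities under the mask", {
  img <- matrix(0, 5, 5)
  img[1, 1] <- 10; img[2, 2] <- 20; img[3, 3] <- 30
  mask <- matrix(FALSE, 5, 5)
  mask[1, 1] <- mask[2, 2] <- mask[3, 3] <- TRUE
  expect_equal(masked_fluorescence(mask, img), 60)
  # disjoint mask -> 0
  mask2 <- matrix(FALSE, 5, 5); mask2[5, 5] <- TRUE
  expect_equal(masked_fluorescence(mask2, img), 0)
  # full mask over ones
  expect_equal(masked_fluorescence(matrix(TRUE, 4, 4), matrix(1, 4, 4)), 16)
  expect_error(masked_fluorescence(matrix(TRUE, 4, 4), matrix(1, 5, 5)),
               "geometry")
})

test_that("masked fluorescence is additive over disjoint masks", {
  set.seed(11)
  img <- matrix(runif(100, 0, 50), 10, 10)
  m1 <- matrix(FALSE, 10, 10); m1[1:5, ] <- TRUE
  m2 <- !m1
  expect_equal(masked_fluorescence(m1, img) + masked_fluorescence(m2, img),
               sum(img))
})
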