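test_that("ellipsoid volume matches its closed form and symmetries", {
  expect_equal(ellipsoid_volume(1, 1, 1), pi / 6)
  expect_equal(ellipsoid_volume(2, 2, 2), 4 * pi / 3)
  expect_equal(ellipsoid_volume(2, 1, 1), 2 * ellipsoid_volume(1, 1, 1))
  # symmetric under axis permutation, degree-3 homogeneous
  expect_equal(ellipsoid_volume(3, 5, 7), ellipsoid_volume(7, 3, 5))
  expect_equal(ellipsoid_volume(2 * 3, 2 * 5, 2 * 7),
               8 * ellipsoid_volume(3, 5, 7))
  expect_error(ellipsoid_volume(0, 1, 1), "positive")
  expect_error(ellipsoid_volume(1, -2, 1), "positive")
})

test_that("ellipsoid volume agrees with Monte-Carlo voxel integration", {
  set.seed(4242)
  for (i in 1:5) {
    dims <- runif(3, 0.5, 12)
    mc <- ellipsoid_volume_mc_oracle(dims[1], dims[2], dims[3])
    expect_lt(abs(ellipsoid_volume(dims[1], dims[2], dims[3]) - mc) / mc, 0.02)
  }
})

test_that("darkness channel endpoints and histogram median are exact", {
  expect_equal(darkness_channel(0), 222L)   # pure black pixel
  expect_equal(darkness_channel(1), 0L)     # pure white pixel
  expect_error(darkness_channel(1.5), "intensity")

  # lower-median convention on an even count: {0, 0, 222, 222} -> 0
  img <- matrix(c(1, 1, 0, 0), 2, 2)
  mask <- matrix(TRUE, 2, 2)
  expect_equal(measure_darkness(img, mask), 0L)

  # uniform regions hit the exact endpoints
  expect_equal(measure_darkness(matrix(0, 4, 4), matrix(TRUE, 4, 4)), 222L)
  expect_equal(measure_darkness(matrix(1, 4, 4), matrix(TRUE, 4, 4)), 0L)

  # brute-force check of the histogram median on random masked regions
  set.seed(99)
  for (i in 1:20) {
    img <- matrix(runif(100), 10, 10)
    mask <- matrix(runif(100) < 0.6, 10, 10)
    if (!any(mask)) next
    vals <- sort(as.integer(round((1 - img[mask]) * 222)))
    expect_equal(measure_darkness(img, mask),
                 vals[ceiling(length(vals) / 2)])
  }

  expect_error(measure_darkness(matrix(0.5, 3, 3), matrix(FALSE, 3, 3)),
               "empty body mask")
})

test_that("darkness is invariant to background pixels and translation", {
  img <- matrix(0.89, 20, 20)
  img[5:10, 5:12] <- 0.3
  mask <- matrix(FALSE, 20, 20)
  mask[5:10, 5:12] <- TRUE
  d0 <- measure_darkness(img, mask)
  # add arbitrary background junk outside the mask
  img2 <- img
  img2[15:20, ] <- runif(120)
  expect_equal(measure_darkness(img2, mask), d0)
  # translate the masked region
  img3 <- matrix(0.89, 20, 20); mask3 <- matrix(FALSE, 20, 20)
  img3[8:13, 7:14] <- 0.3; mask3[8:13, 7:14] <- TRUE
  expect_equal(measure_darkness(img3, mask3), d0)
})

test_that("dimensions are mask extents times pixel scale", {
  # rectangle spanning exactly 100 x 50 px at 0.1 mm/px -> 10 x 5 mm
  mk_view <- function(nr, nc, rows, cols) {
    m <- matrix(FALSE, nr, nc); m[rows, cols] <- TRUE
    list(image = matrix(0.5, nr, nc), mask = m)
  }
  imgs <- structure(list(
    views = list(dorsal = mk_view(60, 120, 6:55, 11:110),
                 lateral = mk_view(60, 120, 21:40, 11:110),
                 anterior = mk_view(60, 120, 21:40, 6:55)),
    pixel_scale = 0.1, record = NULL), class = "specimen_images")
  dims <- extract_dimensions(imgs)
  expect_equal(unname(dims), c(10, 5, 2))

  # degenerate single-pixel mask -> one pixel extent in each direction
  imgs1 <- structure(list(
    views = list(dorsal = mk_view(9, 9, 5, 5),
                 lateral = mk_view(9, 9, 5, 5),
                 anterior = mk_view(9, 9, 5, 5)),
    pixel_scale = 0.25, record = NULL), class = "specimen_images")
  expect_equal(unname(extract_dimensions(imgs1)), c(0.25, 0.25, 0.25))

  imgs_bad <- imgs
  imgs_bad$views$lateral$mask[] <- FALSE
  expect_error(extract_dimensions(imgs_bad), "lateral")
})

test_that("rendered specimens round-trip through measurement", {
  recs <- list(list(body_volume_mm3 = 150, darkness = 40),
               list(body_volume_mm3 = 600, darkness = 120),
               list(body_volume_mm3 = 20, darkness = 201.4))
  for (rec in recs) {
    img <- render_specimen(rec, target_px = 260)
    m <- measure_specimen(img)
    truth <- img$record$dims
    got <- extract_dimensions(img)
    expect_lt(max(abs(got - truth)), img$pixel_scale + 1e-9)
    expect_lt(abs(m$volume - rec$body_volume_mm3) / rec$body_volume_mm3, 0.02)
    expect_lt(abs(m$darkness - rec$darkness), 1)
    # pixel-count oracle: dorsal mask area ~ pi/4 * L * W / scale^2
    area <- sum(img$views$dorsal$mask)
    expect_lt(abs(area - pi / 4 * truth[["length"]] * truth[["width"]] /
                    img$pixel_scale^2) / area, 0.02)
  }

  # endpoint darkness renders to the exact channel extremes
  black <- measure_specimen(render_specimen(
    list(body_volume_mm3 = 100, darkness = 222), target_px = 80))
  white <- measure_specimen(render_specimen(
    list(body_volume_mm3 = 100, darkness = 0), target_px = 80))
  expect_equal(black$darkness, 222L)
  expect_equal(white$darkness, 0L)

  # doubling resolution with halved pixel scale leaves measurements alone
  rec <- list(body_volume_mm3 = 300, darkness = 80)
  lo <- measure_specimen(render_specimen(rec, target_px = 150))
  hi <- measure_specimen(render_specimen(rec, target_px = 300))
  expect_lt(abs(lo$volume - hi$volume) / hi$volume, 0.05)
  expect_lt(abs(lo$darkness - hi$darkness), 1)

  expect_error(render_specimen(list(body_volume_mm3 = 100, darkness = 250)),
               "darkness")
  expect_error(render_specimen(list(body_volume_mm3 = -5, darkness = 50)),
               "volume")
  expect_error(render_specimen(list(body_volume_mm3 = 10, darkness = 50),
                               target_px = -10), "image size")
})

test_that("image sets survive a PNG write/read cycle", {
  dir <- withr::local_tempdir()
  img <- render_specimen(list(body_volume_mm3 = 250, darkness = 77),
                         target_px = 120)
  write_specimen_images(img, dir)
  back <- read_specimen_images(dir)
  m0 <- measure_specimen(img)
  m1 <- measure_specimen(back)
  expect_equal(m1$length, m0$length)
  expect_equal(m1$width, m0$width)
  expect_equal(m1$height, m0$height)
  expect_lt(abs(m1$darkness - m0$darkness), 2)
})
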