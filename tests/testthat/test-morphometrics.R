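test_that("solid rectangle reproduces closed-form traits", {
  reg <- rect_region(30, 40, 11, 20, 6, 25)        # 10 x 20 rectangle
  tr <- compute_morphometrics(mask_from_region(reg$fg), "class_norm")
  expect_equal(tr$area, 200)
  expect_equal(tr$filled_area, 200)
  expect_equal(tr$convex_area, 200)
  expect_equal(tr$extent, 1.0)
  expect_equal(tr$solidity, 1.0)
  expect_equal(tr$equivalent_diameter, sqrt(800 / pi), tolerance = 1e-12)
  expect_equal(tr$perimeter, 2 * (9 + 19))          # contour steps
  expect_gt(tr$major_axis_length, tr$minor_axis_length)
  expect_equal(tr$aspect_ratio,
               tr$major_axis_length / tr$minor_axis_length)
})

test_that("degenerate regions: single pixel and empty class", {
  fg <- matrix(FALSE, 5, 5); fg[3, 3] <- TRUE
  tr <- compute_morphometrics(mask_from_region(fg), "class_norm")
  expect_equal(tr$area, 1)
  expect_equal(tr$equivalent_diameter, 2 / sqrt(pi), tolerance = 1e-12)
  expect_equal(tr$major_axis_length, 0)
  expect_equal(tr$minor_axis_length, 0)
  expect_equal(tr$eccentricity, 0)
  expect_true(is.na(tr$aspect_ratio))

  empty <- compute_morphometrics(seg_mask(matrix(0L, 5, 5), "C"),
                                 "class_antho")
  expect_equal(empty$area, 0)
  for (col in setdiff(names(empty), "area")) {
    expect_true(is.na(empty[[col]]), info = col)
  }
})

test_that("plus-shaped region has extent 5/9", {
  fg <- matrix(FALSE, 7, 7)
  fg[3, 4] <- fg[5, 4] <- fg[4, 3:5] <- TRUE
  tr <- compute_morphometrics(mask_from_region(fg), "class_norm")
  expect_equal(tr$area, 5)
  expect_equal(tr$extent, 5 / 9)
})

test_that("large rasterized disk approaches the ideal circle", {
  reg <- disk_region(201, 201, 101, 101, 50)
  tr <- compute_morphometrics(mask_from_region(reg$fg), "class_norm")
  expect_lt(abs(tr$area - pi * 50^2) / (pi * 50^2), 0.01)
  expect_gte(tr$solidity, 0.98)
  expect_equal(tr$eccentricity, 0, tolerance = 0.05)
  expect_equal(tr$major_axis_length, 100, tolerance = 2)
  expect_equal(tr$equivalent_diameter, sqrt(4 * tr$area / pi),
               tolerance = 1e-9)
})

test_that("holes are filled with 4-connected background", {
  fg <- matrix(FALSE, 12, 12)
  fg[3:9, 3:9] <- TRUE
  fg[5:7, 5:7] <- FALSE                     # 3x3 hole
  tr <- compute_morphometrics(mask_from_region(fg), "class_norm")
  expect_equal(tr$area, 49 - 9)
  expect_equal(tr$filled_area, 49)
  # a corridor to the border makes the cavity reachable background,
  # so nothing is filled
  open <- fg
  open[6, 3:4] <- FALSE
  tr_open <- compute_morphometrics(mask_from_region(open), "class_norm")
  expect_equal(tr_open$filled_area, tr_open$area)
})

test_that("traits are translation invariant and rotation consistent", {
  set.seed(42)
  fg <- random_blob(20, 20)
  base <- compute_morphometrics(mask_from_region(fg), "class_norm")

  shifted <- matrix(FALSE, 32, 32)
  shifted[7:26, 9:28] <- fg
  tr_s <- compute_morphometrics(mask_from_region(shifted), "class_norm")
  expect_equal(as.list(tr_s), as.list(base), tolerance = 1e-12)

  rotated <- t(fg[nrow(fg):1, ])            # 90 degree rotation
  tr_r <- compute_morphometrics(mask_from_region(rotated), "class_norm")
  for (col in c("area", "convex_area", "solidity", "eccentricity",
                "equivalent_diameter", "extent", "perimeter")) {
    expect_equal(tr_r[[col]], base[[col]], tolerance = 1e-9, info = col)
  }
})

test_that("disconnected class pixels are phenotyped as one region", {
  fg <- matrix(FALSE, 20, 20)
  fg[2:5, 2:5] <- TRUE
  fg[15:18, 15:18] <- TRUE
  tr <- compute_morphometrics(mask_from_region(fg), "class_norm")
  expect_equal(tr$area, 32)
  # hull spans both patches, so solidity is far below 1
  expect_gt(tr$convex_area, 100)
  expect_lt(tr$solidity, 0.35)
  expect_equal(tr$convex_area, oracle_convex_area(fg))
})

test_that("area additivity: plant_region equals norm plus antho", {
  set.seed(7)
  for (i in 1:10) {
    m <- matrix(sample(0:3, 18 * 18, replace = TRUE,
                       prob = c(0.5, 0.25, 0.15, 0.1)), 18, 18)
    cm <- seg_mask(m, "C")
    a_norm <- compute_morphometrics(cm, "class_norm")$area
    a_antho <- compute_morphometrics(cm, "class_antho")$area
    a_pr <- compute_morphometrics(cm, "plant_region")$area
    expect_identical(a_pr, a_norm + a_antho)
  }
})

test_that("random blobs agree with exhaustive-counting oracles", {
  set.seed(123)
  for (i in 1:25) {
    fg <- random_blob(18, 18)
    if (!any(fg)) next
    tr <- compute_morphometrics(mask_from_region(fg), "class_norm")
    orc <- oracle_basic_traits(fg)
    expect_identical(tr$area, as.numeric(orc$area))
    expect_equal(tr$extent, orc$extent, tolerance = 1e-12)
    expect_identical(tr$convex_area, as.numeric(oracle_convex_area(fg)))
    expect_true(tr$area <= tr$filled_area)
    expect_true(tr$filled_area <= tr$convex_area + 1e-9)
    expect_equal(tr$solidity, tr$area / tr$convex_area, tolerance = 1e-12)
  }
})
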