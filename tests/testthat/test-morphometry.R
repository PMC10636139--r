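test_that("rasterized disks score circularity near 1", {
  for (r in c(20L, 40L)) {
    f <- compute_features(raster_disk(r))
    expect_gte(f$circularity, 0.95)
    expect_lte(f$circularity, 1.05)
    # lattice points in the hull of a disk are all disk pixels
    expect_equal(f$solidity_ratio, 1)
  }
  # finer rasterization moves a disk's circularity toward 1
  err <- vapply(c(8L, 16L, 32L),
                function(r) abs(compute_features(raster_disk(r))$circularity - 1),
                numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("a filled square matches the closed-form ratios", {
  side <- 41L
  f <- compute_features(raster_square(side))
  expect_equal(f$area_px, side^2)
  expect_equal(f$hull_area_px, side^2)
  expect_equal(f$solidity_ratio, 1)
  # F runs between opposite corner pixel centers: (side-1)*sqrt(2)
  expect_equal(f$max_border_distance_px, (side - 1) * sqrt(2))
  expect_equal(f$circle_ratio, side^2 / (pi * ((side - 1) * sqrt(2) / 2)^2),
               tolerance = 1e-12)
  # converges to 2/pi with size; circularity is near (1 + 2/pi)/2
  expect_equal(f$circularity, (1 + 2 / pi) / 2, tolerance = 0.03)
  f2 <- compute_features(raster_square(121L))
  expect_lt(abs(f2$circle_ratio - 2 / pi), abs(f$circle_ratio - 2 / pi))
  expect_equal(f2$circle_ratio, (121 / 120)^2 * 2 / pi, tolerance = 1e-12)
})

test_that("equivalent diameter follows d = 2*sqrt(A/pi)*s", {
  m <- matrix(0L, 40, 40)
  m[3:34, 3:34] <- 1L  # exactly 1024 pixels
  f <- compute_features(m, um_per_pixel = 0.25)
  expect_equal(f$area_px, 1024L)
  expect_equal(f$equivalent_diameter_um, 2 * sqrt(1024 / pi) * 0.25,
               tolerance = 1e-12)
  expect_equal(f$equivalent_diameter_um, 9.027033, tolerance = 1e-6)
})

test_that("max border distance matches the exhaustive pairwise oracle", {
  # collinear pixel centers
  seg <- matrix(0L, 5, 15); seg[3, 3:13] <- 1L
  expect_equal(compute_features(seg)$max_border_distance_px, 10)
  # single pixel: F = 0 and circle_ratio = 1 by convention
  px <- matrix(0L, 3, 3); px[2, 2] <- 1L
  f1 <- compute_features(px)
  expect_equal(f1$max_border_distance_px, 0)
  expect_equal(f1$circle_ratio, 1)
  expect_equal(f1$hull_area_px, 1)
  # random blobs against the O(n^2) oracle on independently derived borders
  set.seed(71)
  for (k in 1:100) {
    m <- random_blob(50L)
    border <- oracle_border(m)
    expect_equal(compute_features(m)$max_border_distance_px,
                 oracle_max_dist(border), tolerance = 1e-12)
    expect_equal(max_border_distance(border[, 1], border[, 2]),
                 oracle_max_dist(border), tolerance = 1e-12)
  }
})

test_that("circularity is exactly the mean of the two ratios", {
  scene <- small_scene(seed = 9, n = 30L, merged = 0.2)
  f <- compute_features(scene$mask)
  expect_identical(f$circularity, (f$solidity_ratio + f$circle_ratio) / 2)
  expect_true(all(f$solidity_ratio > 0 & f$solidity_ratio <= 1))
  expect_true(all(f$circle_ratio > 0))
})

test_that("features are invariant to translation and 90-degree rotation", {
  set.seed(5)
  m <- random_blob(60L, size = 30L)
  pad <- function(x, before) {
    out <- matrix(0L, nrow(x) + before, ncol(x) + before)
    out[(before + 1):(before + nrow(x)), (before + 1):(before + ncol(x))] <- x
    out
  }
  f0 <- compute_features(m)
  ft <- compute_features(pad(m, 7L))
  fr <- compute_features(t(m[nrow(m):1, ]))  # 90-degree rotation
  for (col in c("area_px", "hull_area_px", "max_border_distance_px",
                "solidity_ratio", "circle_ratio", "circularity",
                "equivalent_diameter_um")) {
    expect_equal(ft[[col]], f0[[col]], tolerance = 1e-12)
    expect_equal(fr[[col]], f0[[col]], tolerance = 1e-12)
  }
})

test_that("measured areas and centroids agree with generator truth", {
  scene <- small_scene(seed = 13, n = 60L)
  f <- compute_features(scene$mask, um_per_pixel = 0.25)
  expect_identical(f$area_px, scene$truth$n_pixels)
  rel <- abs(f$equivalent_diameter_um - scene$truth$true_equivalent_diameter_um) /
    scene$truth$true_equivalent_diameter_um
  expect_lt(max(rel), 0.05)
  expect_lt(max(abs(f$centroid_row - scene$truth$centroid_row)), 1)
  expect_lt(max(abs(f$centroid_col - scene$truth$centroid_col)), 1)
})

test_that("convex shapes keep solidity near 1 at radius >= 20", {
  scene <- small_scene(seed = 21, n = 40L,
                       mix = c(0, 0, 1))  # large nuclei, radius ~19-22 px
  f <- compute_features(scene$mask)
  expect_true(all(f$solidity_ratio >= 0.95))
})

test_that("empty and non-contiguous masks are handled explicitly", {
  expect_identical(nrow(compute_features(matrix(0L, 4, 4))), 0L)
  bad <- matrix(0L, 4, 4); bad[1, 1] <- 2L
  expect_error(compute_features(bad), "contiguous")
})
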