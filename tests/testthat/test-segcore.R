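# Shared segmentation primitives: filters, thresholds, morphology,
# skeletons, profiles. Brute-force oracle equivalence lives in
# test-acceptance.R at full scale; here each primitive is checked on
# constructed cases plus one small oracle instance.

test_that("gaussian_denoise is identity at sigma 0, preserves constants and mass", {
  img <- matrix(runif(400), 20, 20)
  expect_identical(gaussian_denoise(img, 0), img)
  expect_equal(gaussian_denoise(matrix(3, 16, 16), 2), matrix(3, 16, 16),
               tolerance = 1e-10)
  spot <- matrix(0, 31, 31); spot[16, 16] <- 7
  expect_equal(sum(gaussian_denoise(spot, 2)), 7, tolerance = 1e-6)
  expect_error(gaussian_denoise(img, -1), "non-negative")
})

test_that("rolling-ball background removes smooth structure, keeps lines", {
  expect_equal(rolling_ball_background(matrix(5, 20, 20), 4),
               matrix(0, 20, 20))
  # thin bright line on flat background
  img <- matrix(100, 40, 40); img[20, ] <- 400
  out <- rolling_ball_background(img, 6)
  expect_gte(min(out[20, ]), 299)
  expect_lte(max(out[-20, ]), 1)
  # planar ramp with period >> radius is flattened
  ramp <- matrix(rep(seq(0, 50, length.out = 60), each = 60), 60, 60)
  res <- rolling_ball_background(ramp, 5)
  expect_lt(sd(res), 0.1 * sd(ramp))
})

test_that("Otsu dark separates a bimodal image and matches brute force", {
  img <- matrix(10, 20, 20); img[1:2, ] <- 200
  m <- otsu_dark_mask(img)
  expect_identical(unname(m$values), unname(img == 200))
  expect_error(otsu_dark_mask(matrix(1, 5, 5)), "constant")
  blob <- gaussian_denoise({z <- matrix(0, 31, 31); z[16, 16] <- 1; z}, 3) * 1e4
  mb <- otsu_dark_mask(blob)
  expect_true(mb$values[16, 16])
  expect_false(mb$values[1, 1])
  set.seed(11)
  for (i in 1:5) {
    mix <- matrix(c(rnorm(300, 30, 5), rnorm(100, 120, 15)), 20, 20)
    expect_identical(mitoquant:::otsu_threshold_bin(mix), oracle_otsu_bin(mix))
  }
})

test_that("Phansalkar matches the per-pixel formula and rejects bad radii", {
  expect_error(phansalkar_mask(matrix(1:4, 2, 2), 0.5), "radius")
  expect_false(any(phansalkar_mask(matrix(runif(1), 10, 10), 3)$values))
  set.seed(5)
  img <- matrix(runif(32 * 32, 10, 50), 32, 32)
  img[16, 5:28] <- 200  # bright line
  got <- phansalkar_mask(img, 4)$values
  expect_identical(unname(got), unname(oracle_phansalkar(img, 4)))
  expect_true(all(got[16, 8:25]))
})

test_that("find_maxima honours prominence, plateaus and edges", {
  img <- matrix(0, 40, 40)
  img[10, 10] <- 1000; img[30, 30] <- 1000.5
  img <- gaussian_denoise(img, 2) * 100
  s <- find_maxima(img, prominence = 100)
  expect_equal(nrow(s), 2L)
  expect_equal(s$y, c(9, 29), tolerance = 0.01)
  expect_equal(nrow(find_maxima(matrix(c(rep(0, 99), 50), 10, 10) +
                                  seq(0, 1e-3, length.out = 100),
                                prominence = 100, exclude_edges = FALSE)), 1L)
  # a 50-high peak fails a 100 prominence cut unless it is the global max
  low <- gaussian_denoise({z <- matrix(0, 20, 20); z[10, 10] <- 1; z}, 2)
  two <- low * 5000
  two[3, 3] <- max(two) + 60  # higher second peak, low saddle
  s2 <- find_maxima(two, prominence = 100, exclude_edges = FALSE)
  expect_equal(nrow(s2), 2L)  # both prominent here
  # plateau reported once at its centroid
  pl <- matrix(0, 15, 15); pl[7:8, 7:9] <- 5
  sp <- find_maxima(pl, prominence = 1, exclude_edges = FALSE)
  expect_equal(nrow(sp), 1L)
  expect_equal(c(sp$y, sp$x), c(6.5, 7))
  # border maxima removed when excluded
  edge <- matrix(0, 12, 12); edge[1, 6] <- 10; edge[6, 6] <- 8
  expect_equal(nrow(find_maxima(edge, 1, exclude_edges = TRUE)), 1L)
  expect_equal(nrow(find_maxima(edge, 1, exclude_edges = FALSE)), 2L)
})

test_that("find_maxima agrees with the widest-path prominence oracle", {
  for (seed in 1:3) {
    img <- smooth_random_field(24, 24, sigma = 2, seed = seed)
    got <- find_maxima(img, prominence = 1e-9, exclude_edges = FALSE)
    ref <- oracle_prominence(img)
    expect_equal(nrow(got), nrow(ref))
    expect_equal(got$y, ref$y, tolerance = 1e-12)
    expect_equal(got$x, ref$x, tolerance = 1e-12)
    fin <- is.finite(ref$prominence)
    expect_equal(got$prominence[fin], ref$prominence[fin], tolerance = 1e-9)
    expect_identical(is.finite(got$prominence), fin)
  }
})

test_that("morph_offset erodes/dilates by physical distance", {
  cal <- calibration(0.1)
  m <- binary_mask(disc_mask(80, 80, 40, 40, 30), cal, "dna")  # r = 3 um
  expect_identical(morph_offset(m, 0)$values, m$values)
  er <- morph_offset(m, -0.2)
  r_er <- sqrt(sum(er$values) / pi) # ~28 px
  expect_lt(abs(r_er - 28), 1)
  di <- morph_offset(m, 0.5)
  expect_lt(abs(sqrt(sum(di$values) / pi) - 35), 1)
  # dilate then erode on a convex mask ~ identity (within 1 px)
  back <- morph_offset(morph_offset(m, 0.4), -0.4)
  expect_true(all(m$values | !back$values | back$values))
  expect_lt(sum(xor(back$values, m$values)) / sum(m$values), 0.08)
  # erosion to nothing is flagged
  tiny <- binary_mask(disc_mask(20, 20, 10, 10, 2), cal, "dna")
  expect_true(attr(morph_offset(tiny, -1), "empty"))
})

test_that("ring_roi produces the analytic annulus", {
  cal <- calibration(0.1)
  m <- binary_mask(disc_mask(100, 100, 50, 50, 20), cal, "dna")  # r = 2 um
  ring <- ring_roi(m, extend_um = 1.5, width_um = 0.5)
  g <- expand.grid(y = 0:99, x = 0:99)
  r <- matrix(sqrt((g$y - 50)^2 + (g$x - 50)^2), 100, 100) * 0.1
  inside_band <- r > 3.05 & r <= 3.45
  outside_band <- r < 2.95 | r > 3.55
  expect_true(all(ring$values[inside_band]))
  expect_false(any(ring$values[outside_band]))
  expect_error(ring_roi(m, 0.5, 1.5), "extend_um >= width_um")
  empty <- binary_mask(matrix(FALSE, 10, 10), cal, "dna")
  expect_false(any(ring_roi(empty, 1, 0.5)$values))
})

test_that("regions_from_mask filters by size and matches flood fill", {
  cal <- calibration(1)
  m <- disc_mask(40, 40, 10, 10, 4) | disc_mask(40, 40, 30, 30, 0.5)
  rs <- regions_from_mask(binary_mask(m, cal), min_size = 5)
  expect_equal(nrow(rs$table), 1L)
  expect_equal(sum(rs$labels > 0), sum(disc_mask(40, 40, 10, 10, 4)))
  expect_equal(nrow(regions_from_mask(binary_mask(matrix(FALSE, 5, 5), cal))$table), 0L)
  set.seed(3)
  blobs <- gaussian_denoise(matrix(rbinom(60 * 60, 1, 0.02), 60, 60) * 1, 1.5) > 0.05
  lab <- regions_from_mask(binary_mask(blobs, cal), 0)$labels
  ref <- oracle_label8(blobs)
  # same partition: label images agree up to renaming
  expect_equal(max(lab), max(ref))
  expect_true(all(tapply(ref[blobs], lab[blobs], function(v) length(unique(v))) == 1))
})

test_that("skeleton length follows the step-length rule", {
  cal <- calibration(0.05)
  bar <- matrix(FALSE, 20, 110); bar[9:11, 6:105] <- TRUE
  sl <- skeletonize_length(binary_mask(bar, cal, "tub"))
  expect_gt(sl$length_um, 95 * 0.05)
  expect_lt(sl$length_um, 100 * 0.05)
  expect_equal(skeletonize_length(binary_mask(matrix(FALSE, 10, 10), cal))$length_um, 0)
  diagm <- matrix(FALSE, 30, 30); diagm[cbind(5:25, 5:25)] <- TRUE
  expect_equal(skeletonize_length(binary_mask(diagm, cal))$length_um,
               20 * sqrt(2) * 0.05, tolerance = 1e-10)
})

test_that("signed surface distances match the analytic disc", {
  cal <- calibration(0.1)
  m <- binary_mask(disc_mask(80, 80, 40, 40, 20), cal, "dna")  # r = 2 um
  pts <- data.frame(y = c(40, 40, 40), x = c(40, 60, 70))
  d <- distance_to_mask_surface(pts, m)
  expect_equal(d[1], -2, tolerance = 0.1)   # center: 2 um inside
  expect_equal(d[2], 0, tolerance = 0.1)    # on the boundary
  expect_equal(d[3], 1, tolerance = 0.1)    # 1 um outside
  expect_error(distance_to_mask_surface(pts,
    binary_mask(matrix(FALSE, 5, 5), cal)), "empty")
})

test_that("3D surface distances scale z by its calibration", {
  cal <- calibration(0.1, z_step = 0.5)
  vol <- array(FALSE, c(21, 21, 9)); vol[6:16, 6:16, 3:7] <- TRUE
  pts <- data.frame(y = 10, x = 10, z = 4.5)  # center, 2 slices from z-face
  d <- distance_to_mask_surface(pts, binary_mask(vol, cal, "dna"))
  # nearest surface: along y/x (5 px * 0.1 = 0.5 um) equals z (1 slice*0.5);
  # boundary voxels make it ~0.4-0.5 um inside
  expect_lt(d, -0.3); expect_gt(d, -0.8)
})

test_that("line profiles are exact on constants and localize step edges", {
  img <- matrix(7, 30, 30)
  pr <- line_profile(img, c(15, 2), c(15, 27), width_px = 1, pixel_size_um = 0.2)
  expect_true(all(pr$intensity == 7))
  expect_identical(line_profile(img, c(15, 2), c(15, 27), width_px = 5)$intensity,
                   line_profile(img, c(15, 2), c(15, 27), width_px = 1)$intensity)
  step <- matrix(0, 30, 40); step[, 21:40] <- 10
  ps <- line_profile(step, c(15, 0), c(15, 39), width_px = 3, pixel_size_um = 0.5)
  # half-rise between pixels 19 and 20 (0-based), i.e. at 19.5 px = 9.75 um
  i <- which(ps$intensity >= 5)[1]
  frac <- (5 - ps$intensity[i - 1]) / (ps$intensity[i] - ps$intensity[i - 1])
  cross <- ps$distance_um[i - 1] + frac * diff(ps$distance_um[(i - 1):i])
  expect_equal(cross, 9.75, tolerance = 0.3)
  expect_error(line_profile(img, c(5, 5), c(5, 5)), "zero-length")
})

test_that("radial profiles integrate sectors correctly", {
  img <- matrix(0, 61, 61); img[31, 41] <- 5  # point at radius 10, +x side
  rp <- radial_profile(img, c(30, 30))
  expect_equal(rp$intensity[11], 5)
  expect_equal(sum(rp$intensity), 5)
  # half-plane orientation 0 excludes everything at x < center
  left <- matrix(0, 41, 41); left[, 1:20] <- 3
  rl <- radial_profile(left, c(20, 20), theta_deg = 180, orientation_deg = 0)
  expect_true(all(rl$intensity == 0))
  # uniform disc: bin sums proportional to annulus areas (~2 pi r)
  disc <- disc_mask(101, 101, 50, 50, 45) * 1
  rd <- radial_profile(disc, c(50, 50))
  mid <- 10:40
  expect_lt(max(abs(rd$intensity[mid + 1] / (2 * pi * mid) - 1)), 0.15)
})

test_that("primitives are shift-equivariant for whole-pixel translations", {
  set.seed(8)
  base <- gaussian_denoise(matrix(runif(40 * 40), 40, 40), 2) * 100
  img <- matrix(0, 60, 60); img[6:45, 6:45] <- base
  shifted <- matrix(0, 60, 60); shifted[11:50, 13:52] <- base
  s1 <- find_maxima(img, 1, exclude_edges = FALSE)
  s2 <- find_maxima(shifted, 1, exclude_edges = FALSE)
  keep1 <- s1$y > 7 & s1$y < 43 & s1$x > 7 & s1$x < 43
  m1 <- s1[keep1, ]
  m2 <- s2[s2$y > 12 & s2$y < 48 & s2$x > 14 & s2$x < 50, ]
  expect_equal(m1$y + 5, m2$y)
  expect_equal(m1$x + 7, m2$x)
})
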