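test_that("pole detection recovers generator geometry", {
  sc <- make_cell_scene("bipolar", list(), seed = 13)
  tp <- sc$truth$true_params
  poles <- detect_poles(get_channel(sc$stack, "tubulin"), "bipolar",
                        pixel_size_um = 0.1)
  truth <- tp$pole_positions_px
  err <- min(max(abs(poles - truth)), max(abs(poles[2:1, ] - truth)))
  expect_lt(err, 1)
  mono <- make_cell_scene("monopolar", list(), seed = 14)
  ctr <- detect_poles(get_channel(mono$stack, "tubulin"), "monopolar")
  expect_lt(max(abs(ctr - mono$truth$true_params$pole_position_px)), 0.5)
  expect_error(detect_poles(matrix(1, 20, 20), "bipolar"), "constant")
})

test_that("congression fraction handles degenerate and noisy scenes", {
  # all mass inside the central window
  img <- matrix(0, 100, 100); img[45:55, 48:52] <- 50
  ax <- axis_spec(c(50, 10), c(50, 90), length_um = 80, width_um = 20,
                  central_window_um = 10)
  expect_equal(congression_fraction(img, ax, 0, pixel_size_um = 1), 1)
  img2 <- matrix(0, 100, 100); img2[45:55, 15:20] <- 50
  expect_equal(congression_fraction(img2, ax, 0, pixel_size_um = 1), 0)
  expect_error(congression_fraction(matrix(0, 100, 100) + 1, ax, 10, 1),
               "empty")
  # invariances: uniform scaling; adding the subtracted background
  sc <- make_cell_scene("bipolar", list(central_fraction = 0.5), seed = 3)
  tp <- sc$truth$true_params
  axs <- axis_spec(tp$pole_positions_px[1, ], tp$pole_positions_px[2, ])
  dna <- get_channel(sc$stack, "dna")
  f1 <- congression_fraction(dna, axs, tp$dna_bg, 0.1)
  expect_equal(congression_fraction(dna * 3, axs, tp$dna_bg * 3, 0.1), f1,
               tolerance = 1e-12)
  expect_equal(congression_fraction(dna + 40, axs, tp$dna_bg + 40, 0.1), f1,
               tolerance = 1e-12)
  expect_lt(abs(f1 - tp$central_fraction), 0.03)
})

test_that("chromatin density recovers amplitude ratios", {
  sc <- make_cell_scene("bipolar", list(), seed = 9)
  dna <- get_channel(sc$stack, "dna")
  d <- chromatin_density(dna)
  expect_equal(as.numeric(chromatin_density(dna, reference_mean = as.numeric(d))),
               1, tolerance = 1e-12)
  expect_error(chromatin_density(dna, reference_mean = 0), "reference_mean")
  for (r in c(0.29, 0.53)) {
    ref <- make_cell_scene("bipolar", list(), seed = 9)
    per <- make_cell_scene("bipolar", list(density_scale = r), seed = 9)
    bg <- ref$truth$true_params$dna_bg
    ratio <- as.numeric(chromatin_density(get_channel(per$stack, "dna"),
                                          background = bg)) /
             as.numeric(chromatin_density(get_channel(ref$stack, "dna"),
                                          background = bg))
    expect_lt(abs(ratio - r), 0.03)
  }
})

test_that("line-peak density averages the peak window", {
  prof <- structure(list(distance_um = seq(0, 2, by = 0.05),
                         intensity = 100 - 50 * abs(seq(0, 2, by = 0.05) - 1)),
                    class = "line_profile")
  expect_equal(as.numeric(density_line_peak(prof, 0.2)), 97.5, tolerance = 1)
  flat <- structure(list(distance_um = seq(0, 2, by = 0.1),
                         intensity = rep(4, 21)), class = "line_profile")
  v <- density_line_peak(flat)
  expect_equal(as.numeric(v), 4)
  expect_true(attr(v, "flat"))
  expect_error(density_line_peak(structure(list(distance_um = c(0, 0.1),
    intensity = c(1, 2)), class = "line_profile"), 0.2), "shorter")
})

test_that("radial displacement ratio matches analytic discs and truth", {
  # uniform disc: area ratio pi(0.3R)^2 : pi(R^2-(0.3R)^2) = 0.09/0.91
  for (R in c(35, 60)) {
    disc <- disc_mask(151, 151, 75, 75, R) * 10
    ratio <- radial_displacement_ratio(disc, c(75, 75), pixel_size_um = 1)
    expect_lt(abs(ratio / (0.09 / 0.91) - 1), 0.03)
  }
  mono <- make_cell_scene("monopolar", list(inner_mass_fraction = 0.15), seed = 8)
  tp <- mono$truth$true_params
  meas <- radial_displacement_ratio(get_channel(mono$stack, "dna"),
                                    detect_poles(get_channel(mono$stack, "tubulin"),
                                                 "monopolar"),
                                    background = tp$dna_bg, pixel_size_um = 0.1)
  expect_lt(abs(meas - tp$inner_outer_ratio), 0.02)
  empty_out <- make_cell_scene("monopolar", list(noise = FALSE), seed = 2)
  expect_equal(radial_displacement_ratio(get_channel(empty_out$stack, "dna"),
               c(119.5, 119.5), background = 20, pixel_size_um = 0.1), 0,
               tolerance = 1e-6)
})

test_that("peripheral distribution splits pole and periphery", {
  cellm <- disc_mask(100, 100, 50, 50, 45)
  inside_pole <- matrix(0, 100, 100); inside_pole[48:52, 48:52] <- 10
  pd <- peripheral_distribution(inside_pole, c(50, 50), cellm,
                                pole_radius_um = 5, pixel_size_um = 1)
  expect_equal(pd$fraction, 0)
  outside_pole <- matrix(0, 100, 100); outside_pole[20:25, 20:25] <- 7
  pd2 <- peripheral_distribution(outside_pole, c(50, 50), cellm,
                                 pole_radius_um = 5, pixel_size_um = 1)
  expect_equal(pd2$fraction, 1)
  expect_equal(pd2$peripheral_sum, sum(outside_pole))
})

test_that("condensation CV matches its definition and ranks fields", {
  expect_error(condensation_cv(matrix(0, 4, 4)), "zero-mean")
  two <- matrix(c(0, 2), 10, 10)
  expect_equal(condensation_cv(two), sd(two) / mean(two))
  expect_equal(condensation_cv(matrix(5, 8, 8)), 0)
  dro <- make_droplet_field(list(partition_ratio = 8), seed = 5)
  disp <- make_droplet_field(list(partition_ratio = 1), seed = 5)
  expect_gt(condensation_cv(get_channel(dro$stack, "probe")),
            condensation_cv(get_channel(disp$stack, "probe")))
})

test_that("normalized channel ratio recovers generator mark ratios", {
  roi <- disc_mask(50, 50, 25, 25, 10)
  den <- matrix(40, 50, 50) + 5
  num <- matrix(120, 50, 50) + 5
  r <- normalized_channel_ratio(num, den, roi, bg_num = 5, bg_den = 5)
  expect_equal(r, 3, tolerance = 1e-12)
  expect_equal(normalized_channel_ratio(den, den, roi), 1)
  expect_error(normalized_channel_ratio(num, den, roi, bg_den = 60),
               "not positive")
  set.seed(4)
  noisy_num <- matrix(rpois(2500, 120), 50, 50) + 5
  noisy_den <- matrix(rpois(2500, 40), 50, 50) + 5
  r2 <- normalized_channel_ratio(noisy_num, noisy_den, roi, bg_num = 5, bg_den = 5)
  expect_lt(abs(r2 / 3 - 1), 0.02)
})
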