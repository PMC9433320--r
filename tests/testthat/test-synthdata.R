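# The scene generator: determinism, noise-model expectations, and the
# agreement between recorded ground truth and independent re-integration
# of the rendered continuous models.

test_that("generators are deterministic given params and seed", {
  a <- make_cell_scene("bipolar", list(n_spots_inside = 3L), seed = 21)
  b <- make_cell_scene("bipolar", list(n_spots_inside = 3L), seed = 21)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$true_params$spots, b$truth$true_params$spots)
  d1 <- make_droplet_field(list(n_droplets = 10L), seed = 4)
  d2 <- make_droplet_field(list(n_droplets = 10L), seed = 4)
  expect_identical(d1$stack$data, d2$stack$data)
  expect_false(identical(d1$stack$data,
                         make_droplet_field(list(n_droplets = 10L), seed = 5)$stack$data))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(make_cell_scene("bipolar", list(), seed = 99))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("noise model preserves expectations", {
  truth_img <- matrix(c(50, 200, 400, 1000), 2, 2)[rep(1:2, 10), rep(1:2, 10)]
  noise <- list(poisson = TRUE, photons_per_unit = 1, gaussian_sd = 5)
  set.seed(2)
  acc <- 0
  for (i in 1:400) acc <- acc + apply_camera_noise(truth_img, noise)
  expect_lt(max(abs(acc / 400 - truth_img) / truth_img), 0.05)
})

test_that("bipolar DNA mass matches the requested central fraction", {
  for (f in c(0.2, 0.6, 0.9)) {
    sc <- make_cell_scene("bipolar", list(central_fraction = f, noise = FALSE),
                          seed = 31)
    tp <- sc$truth$true_params
    expect_lt(abs(tp$central_fraction - f), 0.01)
    # independent re-integration of the noiseless DNA channel over the band
    dna <- tp$noiseless_channels$dna - tp$dna_bg
    px <- tp$pixel_size_um
    cy <- tp$cell_center_px[1] * px; cx <- tp$cell_center_px[2] * px
    g <- expand.grid(y = (0:239) * px, x = (0:239) * px)
    in_band <- matrix(abs(g$x - cx) <= tp$band_length_um / 2 &
                      abs(g$y - cy) <= tp$band_width_um / 2, 240, 240)
    in_win <- in_band & matrix(abs(g$x - cx) <= tp$central_window_um / 2, 240, 240)
    frac <- sum(dna[in_win]) / sum(dna[in_band])
    expect_equal(frac, tp$central_fraction, tolerance = 1e-6)
  }
  expect_error(make_cell_scene("bipolar", list(central_fraction = 1.2)), "0, 1")
})

test_that("degenerate placements give degenerate truths", {
  all_in <- make_cell_scene("bipolar", list(central_fraction = 1, noise = FALSE),
                            seed = 1)
  expect_gt(all_in$truth$true_params$central_fraction, 0.99)
  none_in <- make_cell_scene("bipolar", list(central_fraction = 0, noise = FALSE),
                             seed = 1)
  expect_lt(none_in$truth$true_params$central_fraction, 0.02)
  # monopolar annulus entirely beyond 30% of the edge radius
  mono <- make_cell_scene("monopolar", list(noise = FALSE), seed = 2)
  expect_equal(mono$truth$true_params$inner_outer_ratio, 0)
})

test_that("droplet fields realize the prescribed partition by construction", {
  df <- make_droplet_field(list(partition_ratio = 5, noise = FALSE,
                                psf_sigma_px = 0), seed = 6)
  tp <- df$truth$true_params
  probe <- tp$noiseless_channels$probe
  px <- tp$pixel_size_um
  interior <- vapply(seq_along(tp$radii_um), function(i) {
    cyx <- round(tp$centers_um[i, ] / px) + 1
    probe[cyx[1], cyx[2]]
  }, numeric(1))
  expect_true(all(interior == 5 * tp$buffer_level))
  br <- tp$buffer_rect_px
  expect_true(all(probe[(br[1]:br[2]) + 1, (br[3]:br[4]) + 1] == tp$buffer_level))
  # P = 1: probe statistically uniform
  u <- make_droplet_field(list(partition_ratio = 1), seed = 6)
  pr <- get_channel(u$stack, "probe")
  expect_lt(abs(condensation_cv(pr) - sqrt(100) / 100), 0.05)
})

test_that("filament truth equals brute-force dense clipping", {
  ff <- make_filament_field(list(n_segments = 60L, noise = FALSE), seed = 11)
  tp <- ff$truth$true_params
  # dense re-clipping of the same segments at 0.002 um
  discs <- tp$chromatin_discs
  tot_in <- 0; tot <- 0
  for (i in seq_len(nrow(tp$segments_a_um))) {
    a <- tp$segments_a_um[i, ]; b <- tp$segments_b_um[i, ]
    L <- sqrt(sum((b - a)^2)); if (L == 0) next
    np <- ceiling(L / 0.002)
    ts <- (seq_len(np) - 0.5) / np
    py <- a[1] + ts * (b[1] - a[1]); px <- a[2] + ts * (b[2] - a[2])
    inside <- rep(FALSE, np)
    for (j in seq_len(nrow(discs)))
      inside <- inside | ((py - discs$y_um[j])^2 + (px - discs$x_um[j])^2 <=
                          discs$r_um[j]^2)
    tot_in <- tot_in + sum(inside) * L / np
    tot <- tot + L
  }
  expect_equal(tp$length_inside_um, tot_in, tolerance = 1e-3)
  expect_equal(tp$length_inside_um + tp$length_outside_um, tot, tolerance = 1e-9)
  excl <- make_filament_field(list(exclusion = TRUE, n_segments = 40L), seed = 2)
  expect_equal(excl$truth$true_params$length_inside_um, 0)
})

test_that("FRAP series follow the stated recovery model", {
  # m = 1, tau = 0.5 s, no acquisition bleaching, no noise: the ROI trace at
  # t = tau sits exactly halfway between bleach floor and full recovery
  fs <- make_frap_series(list(mobile_fraction = 1, half_time_s = 0.5,
                              beta = 1, noise = FALSE, time_step_s = 0.1),
                         seed = 1)
  tp <- fs$truth$true_params
  ser <- measure_frap_series(fs$stack, tp$roi_mask, tp$nucleus_mask, tp$bg,
                             tp$n_pre + 1L)
  ncurve <- frap_normalize(ser)
  post <- ncurve[ncurve$time_s >= 0, ]
  floor_ <- 1 - tp$bleach_depth
  at_tau <- post$N[which.min(abs(post$time_s - 0.5))]
  expect_equal(at_tau, floor_ + 0.5 * (1 - floor_), tolerance = 1e-9)
  # m = 0: constant at the post-bleach level
  f0 <- make_frap_series(list(mobile_fraction = 0, beta = 1, noise = FALSE),
                         seed = 1)
  tp0 <- f0$truth$true_params
  n0 <- frap_normalize(measure_frap_series(f0$stack, tp0$roi_mask,
                                           tp0$nucleus_mask, tp0$bg,
                                           tp0$n_pre + 1L))
  postN <- n0$N[n0$time_s >= 0]
  expect_lt(diff(range(postN)), 1e-9)
  expect_error(make_frap_series(list(mobile_fraction = 1.5)), "mobile_fraction")
  expect_error(make_frap_series(list(half_time_s = -1)), "half_time")
})

test_that("FRET pairs realize the prescribed ratio exactly when noiseless", {
  fp <- make_fret_pair(list(fret_ratio = 1.2, noise = FALSE), seed = 3)
  tp <- fp$truth$true_params
  cfp <- get_channel(fp$stack, "cfp") - tp$bg_cfp
  fret <- get_channel(fp$stack, "fret") - tp$bg_fret
  core <- cfp > 0.5 * max(cfp)
  expect_equal(fret[core] / cfp[core], rep(1.2, sum(core)), tolerance = 1e-9)
  expect_error(make_fret_pair(list(fret_ratio = -1)), "fret_ratio")
})
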