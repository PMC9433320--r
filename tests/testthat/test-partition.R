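# Partition-coefficient variants. The full P-grid recovery study runs in
# the acceptance suite; here: exact construction cases, uniform-probe
# checks and the error contracts.

plate_scene <- function(P, seed, extra = list()) {
  make_cell_scene("bipolar", utils::modifyList(list(
    partition_ratio = P, central_fraction = 1, n_blobs_central = 1L,
    blob_r_um = 4, psf_sigma_px = 1), extra), seed = seed)
}

test_that("noiseless step profiles give the exact line coefficient", {
  probe <- matrix(100, 60, 120); probe[, 61:120] <- 20  # P = 0.2 inside right
  dna <- matrix(5, 60, 120); dna[, 61:120] <- 200
  pm <- partition_line(probe, dna, c(30, 30), c(30, 90),
                       width_px = 5, offset_um = 1, pixel_size_um = 0.1)
  expect_equal(pm$coefficient, 0.2, tolerance = 1e-6)
  expect_equal(attr(pm, "boundary_um"), 0.5 * (90 - 30) * 0.1 + 1.5,
               tolerance = 0.1)
  # uniform probe -> 1 regardless of the DNA reference
  expect_equal(partition_line(matrix(7, 60, 120), dna, c(30, 30), c(30, 90),
                              pixel_size_um = 0.1)$coefficient, 1)
})

test_that("short segments are extended and flagged", {
  probe <- matrix(100, 60, 120); probe[, 61:120] <- 20
  dna <- matrix(5, 60, 120); dna[, 61:120] <- 200
  # a 1.3 um segment cannot hold +/- 1 um offsets unextended
  pm <- partition_line(probe, dna, c(30, 54), c(30, 67),
                       width_px = 5, offset_um = 1, pixel_size_um = 0.1)
  expect_equal(pm$coefficient, 0.2, tolerance = 1e-6)
  expect_true(attr(pm, "extended"))
})

test_that("mask/ring coefficient subtracts background correctly", {
  sc <- plate_scene(0.5, 21, list(probe_bg = 100, psf_sigma_px = 1.5))
  pr <- get_channel(sc$stack, "probe"); dn <- get_channel(sc$stack, "dna")
  bgm <- matrix(FALSE, 240, 240); bgm[1:15, 1:15] <- TRUE
  pm <- partition_mask_ring(pr, dn, background = bgm, pixel_size_um = 0.1)
  expect_lt(abs(pm$coefficient - 0.5), 0.05 * 0.5 + 0.02)
  expect_error(partition_mask_ring(pr, dn, background = max(pr) + 1,
                                   pixel_size_um = 0.1), "background exceeds")
  # uniform probe -> 1
  u <- partition_mask_ring(matrix(50, 240, 240) + 0, dn, background = 0,
                           pixel_size_um = 0.1)
  expect_equal(u$coefficient, 1)
})

test_that("circle variant needs a valid cytoplasmic placement", {
  sc <- plate_scene(3, 22)
  tp <- sc$truth$true_params
  pr <- get_channel(sc$stack, "probe"); dn <- get_channel(sc$stack, "dna")
  g <- mitoquant:::pixel_grid(240, 240)
  cellm <- (g$y - tp$cell_center_px[1])^2 + (g$x - tp$cell_center_px[2])^2 <=
    (tp$cell_radius_um / 0.1)^2
  regs <- regions_from_mask(otsu_dark_mask(gaussian_denoise(dn, 2),
                                           calibration(0.1)), 5)
  pm <- partition_circle(pr, regs, cell_mask = cellm, pixel_size_um = 0.1)
  expect_lt(abs(pm$coefficient - 3) / 3, 0.1)
  # a cell too small to host the disc with clearance errors out
  small <- cellm & ((g$y - tp$cell_center_px[1])^2 +
                    (g$x - tp$cell_center_px[2])^2 <= 30^2)
  expect_error(partition_circle(pr, regs, cell_mask = small,
                                pixel_size_um = 0.1), "no valid")
  expect_equal(partition_circle(matrix(9, 240, 240), regs, cell_mask = cellm,
                                pixel_size_um = 0.1)$coefficient, 1)
})

test_that("droplet variant is exact on noiseless fields and guards the buffer", {
  df <- make_droplet_field(list(partition_ratio = 5, noise = FALSE,
                                psf_sigma_px = 0), seed = 6)
  tp <- df$truth$true_params
  pm <- partition_droplet(get_channel(df$stack, "probe"),
                          get_channel(df$stack, "dna"),
                          tp$buffer_rect_px, pixel_size_um = 0.1)
  expect_equal(pm$coefficient, 5, tolerance = 1e-9)
  # buffer rectangle covering a droplet is rejected
  cy <- round(tp$centers_um[1, 1] / 0.1); cx <- round(tp$centers_um[1, 2] / 0.1)
  bad <- c(max(cy - 5, 0), cy + 5, max(cx - 5, 0), cx + 5)
  expect_error(partition_droplet(get_channel(df$stack, "probe"),
                                 get_channel(df$stack, "dna"), bad,
                                 pixel_size_um = 0.1), "intersects")
})

test_that("recovered coefficients increase strictly with the true ratio", {
  got <- vapply(c(0.2, 1, 5), function(P) {
    df <- make_droplet_field(list(partition_ratio = P), seed = 17)
    partition_droplet(get_channel(df$stack, "probe"),
                      get_channel(df$stack, "dna"),
                      df$truth$true_params$buffer_rect_px,
                      pixel_size_um = 0.1)$coefficient
  }, numeric(1))
  expect_true(all(diff(got) > 0))
})
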