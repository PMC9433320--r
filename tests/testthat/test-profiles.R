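# Ki-67 surface-confinement: peak alignment, half-max alignment, S/I ratio.

synthetic_shell_profile <- function(id, group, jitter_um = 0, peak = 100,
                                    interior = 25, width_um = 0.3) {
  x <- seq(0, 8, by = 0.05)
  edge <- 3 + jitter_um
  v <- interior / (1 + exp(-(x - edge) / 0.08)) +
    peak * exp(-(x - edge)^2 / (2 * width_um^2))
  data.frame(profile_id = id, group = group, distance_um = x, ki67 = v,
             dna = 200 / (1 + exp(-(x - edge) / 0.1)))
}

test_that("identical shifted copies align to a zero-variance curve", {
  profs <- do.call(rbind, lapply(1:4, function(i)
    synthetic_shell_profile(sprintf("c%d", i), "control",
                            jitter_um = c(-0.4, 0.2, 0, 0.5)[i])))
  al <- align_profiles_first_peak(profs, "control")
  ctrl <- al$curves[al$curves$group == "control", ]
  expect_lt(max(ctrl$sd), 1e-6)
  # control normalized so its peak is 1
  expect_equal(max(ctrl$mean), 1, tolerance = 1e-6)
  expect_error(align_profiles_first_peak(
    data.frame(profile_id = "f", group = "control",
               distance_um = seq(0, 1, 0.1), ki67 = seq(1, 2, 0.1)), "control"),
    "no detectable peak")
})

test_that("confinement ratio uses control-defined positions and scales out", {
  profs <- rbind(
    do.call(rbind, lapply(1:3, function(i)
      synthetic_shell_profile(sprintf("c%d", i), "control"))),
    do.call(rbind, lapply(1:3, function(i) {
      p <- synthetic_shell_profile(sprintf("t%d", i), "treated", peak = 25,
                                   interior = 25)
      p  # flat-ish condition: shell equals interior
    })))
  al <- align_profiles_first_peak(profs, "control")
  ratios <- ki67_confinement(al$curves, "control",
                             chromatid_center_offset_um = 3)
  expect_equal(unname(ratios["control"]),
               max(al$curves$mean[al$curves$group == "control"]) /
                 approx(al$curves$x_um[al$curves$group == "control"],
                        al$curves$mean[al$curves$group == "control"],
                        xout = al$curves$x_um[al$curves$group == "control"][
                          which.max(al$curves$mean[al$curves$group == "control"])] + 3)$y)
  # global scaling of a condition curve cancels
  scaled <- al$curves
  scaled$mean[scaled$group == "treated"] <- scaled$mean[scaled$group == "treated"] * 13
  expect_equal(ki67_confinement(scaled, "control", 3)["treated"],
               ratios["treated"], tolerance = 1e-12)
  expect_error(ki67_confinement(al$curves, "control", 100), "outside")
})

test_that("confinement recovers the generator shell/interior contrast", {
  mk <- function(sd, group) {
    sc <- make_cell_scene("bipolar", list(central_fraction = 1,
      n_blobs_central = 1L, blob_r_um = 4,
      ki67 = list(shell_amp = 400, interior = 100, cyto = 0, bg = 0,
                  shell_width_um = 0.25)), seed = sd)
    tp <- sc$truth$true_params
    k <- get_channel(sc$stack, "ki67"); d <- get_channel(sc$stack, "dna")
    ctr <- tp$chromatin_centers_um[1, ] / 0.1
    x_edge <- ctr[2] - 4 / 0.1
    j <- runif(1, -4, 4)
    pk <- line_profile(k, c(ctr[1], x_edge - 30 + j), c(ctr[1], ctr[2]),
                       width_px = 10, pixel_size_um = 0.1)
    pd <- line_profile(d, c(ctr[1], x_edge - 30 + j), c(ctr[1], ctr[2]),
                       width_px = 10, pixel_size_um = 0.1)
    data.frame(profile_id = sprintf("%s-%d", group, sd), group = group,
               distance_um = pk$distance_um, ki67 = pk$intensity,
               dna = pd$intensity)
  }
  set.seed(7)
  profs <- do.call(rbind, lapply(1:4, function(i) mk(i, "control")))
  al <- align_profiles_first_peak(profs, "control")
  ratios <- ki67_confinement(al$curves, "control", chromatid_center_offset_um = 3)
  expect_lt(abs(ratios[["control"]] - 4) / 4, 0.1)
})

test_that("half-max alignment collapses boundary jitter", {
  jit <- c(-0.5, -0.2, 0.1, 0.4, 0.6)
  profs <- do.call(rbind, lapply(seq_along(jit), function(i)
    synthetic_shell_profile(sprintf("p%d", i), "g", jitter_um = jit[i])))
  al <- align_profiles_half_max(profs)
  sd_at_edge <- mean(al$curves$sd[abs(al$curves$x_um) < 0.2])
  # pre-alignment spread at the nominal edge position
  raw <- do.call(cbind, lapply(split(profs, profs$profile_id),
                               function(p) p$ki67[abs(p$distance_um - 3) < 0.2]))
  expect_lt(sd_at_edge, 0.2 * mean(apply(raw, 1, sd)))
  # step-edge DNA aligns at the step; monotone ramp has a unique crossing
  ramp <- data.frame(profile_id = "r", group = "g",
                     distance_um = seq(0, 2, 0.1),
                     ki67 = seq(0, 2, 0.1), dna = seq(0, 20, 1))
  alr <- align_profiles_half_max(ramp)
  expect_equal(unname(alr$edge_um["r"]), 1, tolerance = 0.01)
  bad <- ramp; bad$dna <- rev(bad$dna)  # starts above half-max
  expect_error(align_profiles_half_max(bad), "never crosses")
})
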