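#' Synthetic mitotic cell scene
#'
#' Renders a bipolar (metaphase-like) or monopolar (STLC-like) mitotic cell
#' with configurable channels and full ground truth. The DNA channel is a
#' union of hard chromatin discs blurred by a Gaussian PSF; for bipolar
#' geometry the amplitudes of the central and peripheral disc groups are
#' rebalanced analytically so that the true fraction of DNA mass inside the
#' central congression window matches `central_fraction` (recorded exactly
#' in the truth, within 1% of the request). Tubulin carries two Gaussian
#' pole maxima (bipolar) or a single central aster (monopolar). Optional
#' channels: `cenpa` kinetochore point sources with inside/outside labels,
#' a `probe` channel with a prescribed chromatin/cytoplasm partition ratio,
#' and a `ki67` boundary shell.
#'
#' @param geometry `"bipolar"` or `"monopolar"`.
#' @param params Named list of overrides; see Details.
#' @param seed Integer RNG seed.
#' @details Principal parameters (defaults in parentheses): image size
#'   `ny`/`nx` (240), `pixel_size_um` (0.1), `central_fraction` (0.6),
#'   `pole_sep_um` (11), `cell_radius_um` (10), chromatin disc radius
#'   `blob_r_um` (1.2), DNA amplitude `dna_amp` (200) times
#'   `density_scale` (1), backgrounds `dna_bg` (20) / `tub_bg` (10),
#'   PSF `psf_sigma_px` (1.5), kinetochores `n_spots_inside` (6) /
#'   `n_spots_outside` (0) at `outside_distance_um` (1),
#'   `partition_ratio` (NULL = no probe channel), `ki67` (NULL or list
#'   `shell_amp`, `shell_width_um`, `interior`), monopolar annulus
#'   `annulus_r_um` (c(3, 5)) with `inner_mass_fraction` (0) in an inner
#'   disc of `inner_disc_r_um` (1), and `noise` (TRUE).
#' @return List with `stack` (a [calibrated_stack()]) and `truth`
#'   (a [scene_truth()]).
#' @export
make_cell_scene <- function(geometry = c("bipolar", "monopolar"),
                            params = list(), seed = 1) {
  geometry <- match.arg(geometry)
  p <- utils::modifyList(list(
    ny = 240L, nx = 240L, pixel_size_um = 0.1,
    central_fraction = 0.6, pole_sep_um = 11,
    band_length_um = 22.5, band_width_um = 7.06, central_window_um = 5,
    cell_radius_um = 10, blob_r_um = 1.2,
    n_blobs_central = 6L, n_blobs_peripheral = 4L,
    dna_amp = 200, density_scale = 1, dna_bg = 20,
    tub_amp = 500, tub_bg = 10, cyto_level = 30,
    psf_sigma_px = 1.5,
    n_spots_inside = 0L, n_spots_outside = 0L, outside_distance_um = 1,
    spot_amp = 1000, spot_sigma_px = 2, cenpa_bg = 5,
    partition_ratio = NULL, probe_cyto = 100, probe_bg = 0,
    ki67 = NULL,
    annulus_r_um = c(3, 5), inner_mass_fraction = 0, inner_disc_r_um = 1,
    aster_sigma_um = 1.5,
    noise = TRUE
  ), params)
  with_seed(seed, {
    if (geometry == "bipolar") .bipolar_scene(p, seed)
    else .monopolar_scene(p, seed)
  })
}

.bipolar_scene <- function(p, seed) {
  ny <- p$ny; nx <- p$nx; px <- p$pixel_size_um
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2             # px, 0-based
  cy_um <- cy * px; cx_um <- cx * px
  half_sep_px <- p$pole_sep_um / 2 / px
  poles <- rbind(c(cy, cx - half_sep_px), c(cy, cx + half_sep_px))

  f <- p$central_fraction
  if (f < 0 || f > 1) stop("central_fraction must lie in [0, 1]")
  half_win <- p$central_window_um / 2
  half_wid <- p$band_width_um / 2
  r_blob <- p$blob_r_um

  # central discs: fully inside the window (with margin for the PSF);
  # peripheral discs: fully outside it
  max_cdx <- if (f >= 0.97) 0.9 else half_win - r_blob - 0.2
  n_c <- if (f == 0) 0L else p$n_blobs_central
  n_p <- if (f >= 0.97) 0L else p$n_blobs_peripheral
  cen_c <- if (n_c > 0) cbind(cy_um + runif(n_c, -2.2, 2.2),
                              cx_um + runif(n_c, -max_cdx, max_cdx))
           else matrix(0, 0, 2)
  sides <- rep_len(c(-1, 1), n_p)
  cen_p <- if (n_p > 0) cbind(cy_um + runif(n_p, -2.2, 2.2),
                              cx_um + sides * runif(n_p, half_win + r_blob + 0.3,
                                                    half_win + r_blob + 1.7))
           else matrix(0, 0, 2)

  Ic <- if (n_c > 0) render_discs(ny, nx, px, cen_c, rep(r_blob, n_c),
                                  p$psf_sigma_px) else matrix(0, ny, nx)
  Ip <- if (n_p > 0) render_discs(ny, nx, px, cen_p, rep(r_blob, n_p),
                                  p$psf_sigma_px) else matrix(0, ny, nx)

  g <- pixel_grid(ny, nx)
  in_band <- abs(g$x * px - cx_um) <= p$band_length_um / 2 &
             abs(g$y * px - cy_um) <= half_wid
  in_win <- in_band & abs(g$x * px - cx_um) <= half_win
  A <- sum(Ic[in_win]); B <- sum(Ic[in_band & !in_win])
  C <- sum(Ip[in_win]); D <- sum(Ip[in_band & !in_win])
  if (n_c > 0 && n_p > 0) {
    alpha <- (f * (C + D) - C) / (A - f * (A + B))
    if (!is.finite(alpha) || alpha < 0)
      stop(sprintf("requested central_fraction %.3g not achievable with this layout", f))
  } else alpha <- 1
  dna_shape <- alpha * Ic + Ip
  achieved <- (alpha * A + C) / (alpha * (A + B) + C + D)
  if (abs(achieved - f) > 0.01 && f > 0 && f < 0.97)
    stop("internal: central fraction rebalance failed")

  dna <- p$dna_amp * p$density_scale * dna_shape + p$dna_bg

  cell_soft <- render_discs(ny, nx, px, rbind(c(cy_um, cx_um)),
                            p$cell_radius_um, p$psf_sigma_px)
  tub <- p$tub_bg + p$cyto_level * cell_soft +
    render_gaussian_spots(ny, nx, poles, rep(p$tub_amp, 2), 3)

  centers_all <- rbind(cen_c, cen_p)
  radii_all <- rep(r_blob, nrow(centers_all))
  channels <- list(dna = dna, tubulin = tub)

  spots <- NULL
  if (p$n_spots_inside + p$n_spots_outside > 0) {
    if (nrow(centers_all) == 0) stop("kinetochore spots need chromatin discs")
    spots <- .place_spots(p, centers_all, radii_all, cy_um, cx_um)
    spots_px <- cbind(spots$y_um / px, spots$x_um / px)
    channels$cenpa <- p$cenpa_bg +
      render_gaussian_spots(ny, nx, spots_px, rep(p$spot_amp, nrow(spots_px)),
                            p$spot_sigma_px)
    spots$y <- spots$y_um / px; spots$x <- spots$x_um / px
  }

  chrom_soft <- if (nrow(centers_all) > 0)
    render_discs(ny, nx, px, centers_all, radii_all, p$psf_sigma_px)
  else matrix(0, ny, nx)

  if (!is.null(p$partition_ratio)) {
    P <- p$partition_ratio
    if (P < 0) stop("partition_ratio must be >= 0")
    channels$probe <- p$probe_bg + p$probe_cyto * cell_soft +
      (P - 1) * p$probe_cyto * chrom_soft
    if (any(channels$probe < 0)) channels$probe <- pmax(channels$probe, 0)
  }

  if (!is.null(p$ki67)) {
    k <- utils::modifyList(list(shell_amp = 400, shell_width_um = 0.15,
                                interior = 100, cyto = 25, bg = 5), p$ki67)
    sdst <- disc_union_signed_distance(ny, nx, px, centers_all, radii_all)
    channels$ki67 <- k$bg + k$cyto * cell_soft +
      k$interior * (sdst < -k$shell_width_um) +
      k$shell_amp * exp(-sdst^2 / (2 * k$shell_width_um^2))
  }

  noise_rec <- lapply(channels, function(ch) default_noise(max(ch), p$noise))
  noisy <- Map(apply_camera_noise, channels, noise_rec)
  stack <- calibrated_stack(noisy, calibration(px))

  truth <- scene_truth(
    scene_id = sprintf("bipolar-seed%s", format(seed)), geometry = "bipolar",
    true_params = list(
      pixel_size_um = px,
      pole_positions_px = poles,
      cell_center_px = c(cy, cx), cell_radius_um = p$cell_radius_um,
      band_length_um = p$band_length_um, band_width_um = p$band_width_um,
      central_window_um = p$central_window_um,
      central_fraction_requested = f, central_fraction = achieved,
      chromatin_centers_um = centers_all, chromatin_radii_um = radii_all,
      dna_amplitude = p$dna_amp * p$density_scale, density_scale = p$density_scale,
      dna_bg = p$dna_bg, tub_bg = p$tub_bg,
      probe_bg = p$probe_bg, probe_cyto = p$probe_cyto,
      partition_ratio = p$partition_ratio,
      ki67 = p$ki67,
      spots = spots,
      noiseless_channels = channels
    ),
    seed = seed, noise = noise_rec)
  list(stack = stack, truth = truth)
}

.place_spots <- function(p, centers, radii, cy_um, cx_um, min_sep_um = 1) {
  res <- data.frame(y_um = numeric(0), x_um = numeric(0),
                    label = character(0), true_distance_um = numeric(0))
  sd_union <- function(pt) min(sqrt((centers[, 1] - pt[1])^2 +
                                    (centers[, 2] - pt[2])^2) - radii)
  # spots must be mutually resolvable: enforce a minimum pairwise distance
  separated <- function(pt) nrow(res) == 0 ||
    min(sqrt((res$y_um - pt[1])^2 + (res$x_um - pt[2])^2)) >= min_sep_um
  n_in <- p$n_spots_inside
  for (i in seq_len(n_in)) {
    placed <- FALSE
    for (try in 1:1000) {
      j <- sample(length(radii), 1)
      rr <- (radii[j] - 0.35) * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
      pt <- c(centers[j, 1] + rr * sin(th), centers[j, 2] + rr * cos(th))
      d <- sd_union(pt)
      if (d <= -0.3 && separated(pt)) { placed <- TRUE; break }
    }
    if (!placed) stop("could not place resolvable inside spots")
    res[nrow(res) + 1L, ] <- list(pt[1], pt[2], "inside", d)
  }
  for (i in seq_len(p$n_spots_outside)) {
    placed <- FALSE
    for (try in 1:1000) {
      j <- sample(length(radii), 1)
      th <- runif(1, 0, 2 * pi)
      pt <- c(centers[j, 1] + (radii[j] + p$outside_distance_um) * sin(th),
              centers[j, 2] + (radii[j] + p$outside_distance_um) * cos(th))
      d <- sd_union(pt)
      in_cell <- sqrt((pt[1] - cy_um)^2 + (pt[2] - cx_um)^2) < p$cell_radius_um - 1
      if (abs(d - p$outside_distance_um) < 0.05 && in_cell && separated(pt)) {
        placed <- TRUE; break
      }
    }
    if (!placed) stop("could not place spot in the cytoplasm")
    res[nrow(res) + 1L, ] <- list(pt[1], pt[2], "outside", d)
  }
  res
}

.monopolar_scene <- function(p, seed) {
  ny <- p$ny; nx <- p$nx; px <- p$pixel_size_um
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  cy_um <- cy * px; cx_um <- cx * px
  g <- pixel_grid(ny, nx)
  r_um <- sqrt((g$y * px - cy_um)^2 + (g$x * px - cx_um)^2)

  ring <- r_um >= p$annulus_r_um[1] & r_um <= p$annulus_r_um[2]
  ring <- gaussian_denoise(ring * 1, p$psf_sigma_px)
  q <- p$inner_mass_fraction
  if (q < 0 || q >= 1) stop("inner_mass_fraction must lie in [0, 1)")
  dna_shape <- ring
  if (q > 0) {
    inner <- gaussian_denoise((r_um <= p$inner_disc_r_um) * 1, p$psf_sigma_px)
    w <- q / (1 - q) * sum(ring) / sum(inner)
    dna_shape <- ring + w * inner
  }
  dna <- p$dna_amp * p$density_scale * dna_shape + p$dna_bg

  aster_sigma_px <- p$aster_sigma_um / px
  tub <- p$tub_bg + render_gaussian_spots(ny, nx, rbind(c(cy, cx)),
                                          p$tub_amp, aster_sigma_px)

  # truth: pixel-exact cumulative radial distribution of the noiseless DNA
  # mass (background excluded), independent of the binned metric path
  mass <- as.numeric(dna - p$dna_bg)
  ord <- order(as.numeric(r_um))
  cum <- cumsum(mass[ord])
  R_edge <- as.numeric(r_um)[ord][which(cum >= 0.99 * sum(mass))[1]]
  inner_mass <- sum(mass[as.numeric(r_um) <= 0.3 * R_edge])
  outer_mass <- sum(mass[as.numeric(r_um) > 0.3 * R_edge &
                         as.numeric(r_um) <= R_edge])
  channels <- list(dna = dna, tubulin = tub)
  noise_rec <- lapply(channels, function(ch) default_noise(max(ch), p$noise))
  noisy <- Map(apply_camera_noise, channels, noise_rec)
  stack <- calibrated_stack(noisy, calibration(px))
  truth <- scene_truth(
    scene_id = sprintf("monopolar-seed%s", format(seed)), geometry = "monopolar",
    true_params = list(
      pixel_size_um = px, pole_position_px = c(cy, cx),
      annulus_r_um = p$annulus_r_um, inner_mass_fraction = q,
      edge_radius_um = R_edge,
      inner_outer_ratio = if (outer_mass > 0) inner_mass / outer_mass else Inf,
      dna_amplitude = p$dna_amp * p$density_scale, dna_bg = p$dna_bg,
      noiseless_channels = channels
    ),
    seed = seed, noise = noise_rec)
  list(stack = stack, truth = truth)
}
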