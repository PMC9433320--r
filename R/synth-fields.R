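#' Synthetic in vitro droplet field
#'
#' Renders a field of non-overlapping chromatin droplets (discs) in buffer.
#' The probe channel is `buffer_level` outside droplets and
#' `partition_ratio * buffer_level` inside (plus an optional additive
#' `background`), blurred by a small PSF; the DNA channel marks the
#' droplets. A droplet-free rectangle is reserved for the buffer ROI and
#' recorded in the truth.
#'
#' @param params Named list of overrides: `ny`/`nx` (256),
#'   `pixel_size_um` (0.1), `n_droplets` (30), `radius_range_um`
#'   (c(0.8, 1.6)), `partition_ratio` (5), `buffer_level` (100),
#'   `background` (0), `dna_amp` (300), `psf_sigma_px` (1.0),
#'   `noise` (TRUE), `allow_overlap` (FALSE).
#' @param seed Integer RNG seed.
#' @return List with `stack` (channels `dna`, `probe`) and `truth`
#'   recording `partition_ratio`, droplet `centers_um`/`radii_um` and
#'   `buffer_rect_px` (0-based y0, y1, x0, x1).
#' @export
make_droplet_field <- function(params = list(), seed = 1) {
  p <- utils::modifyList(list(
    ny = 256L, nx = 256L, pixel_size_um = 0.1,
    n_droplets = 30L, radius_range_um = c(0.8, 1.6),
    partition_ratio = 5, buffer_level = 100, background = 0,
    dna_amp = 300, psf_sigma_px = 1.0, noise = TRUE, allow_overlap = FALSE
  ), params)
  with_seed(seed, {
    px <- p$pixel_size_um
    w_um <- p$nx * px; h_um <- p$ny * px
    # reserve the upper-left 6 x 6 um corner for the buffer rectangle
    buf_um <- 6
    centers <- matrix(0, 0, 2); radii <- numeric(0)
    tries <- 0
    while (length(radii) < p$n_droplets && tries < 20000) {
      tries <- tries + 1
      r <- runif(1, p$radius_range_um[1], p$radius_range_um[2])
      cyx <- c(runif(1, r + 0.3, h_um - r - 0.3), runif(1, r + 0.3, w_um - r - 0.3))
      if (cyx[1] < buf_um + r + 0.5 && cyx[2] < buf_um + r + 0.5) next
      if (!p$allow_overlap && length(radii) > 0) {
        dmin <- min(sqrt((centers[, 1] - cyx[1])^2 + (centers[, 2] - cyx[2])^2) -
                    (radii + r))
        if (dmin < 0.8) next
      }
      centers <- rbind(centers, cyx); radii <- c(radii, r)
    }
    if (length(radii) < p$n_droplets) {
      if (!p$allow_overlap)
        stop("could not place the requested droplets without overlap")
    }
    droplet <- render_discs(p$ny, p$nx, px, centers, radii, 0)
    droplet_soft <- gaussian_denoise(droplet, p$psf_sigma_px)
    P <- p$partition_ratio
    if (P < 0) stop("partition_ratio must be >= 0")
    probe <- p$background + p$buffer_level * (1 + (P - 1) * droplet_soft)
    dna <- 5 + p$dna_amp * droplet_soft
    channels <- list(dna = dna, probe = probe)
    noise_rec <- lapply(channels, function(ch) default_noise(max(ch), p$noise))
    noisy <- Map(apply_camera_noise, channels, noise_rec)
    stack <- calibrated_stack(noisy, calibration(px))
    buf_px <- floor(buf_um / px) - 2L
    truth <- scene_truth(
      scene_id = sprintf("droplets-seed%s", format(seed)),
      geometry = "droplet_field",
      true_params = list(
        pixel_size_um = px, partition_ratio = P,
        buffer_level = p$buffer_level, background = p$background,
        centers_um = centers, radii_um = radii,
        buffer_rect_px = c(y0 = 0L, y1 = buf_px, x0 = 0L, x1 = buf_px),
        noiseless_channels = channels
      ),
      seed = seed, noise = noise_rec)
    list(stack = stack, truth = truth)
  })
}

#' Synthetic filament field with analytic per-domain lengths
#'
#' Renders straight filament segments (microtubules) over a chromatin
#' region made of disjoint discs. With `exclusion = TRUE`, the parts of
#' every segment inside chromatin are removed before rendering (mimicking
#' microtubule exclusion); with `FALSE` filaments cross chromatin freely.
#' The truth records the exact total filament length inside and outside
#' the chromatin region, from analytic clipping of each segment against
#' the disc union (union of per-disc chord intervals).
#'
#' @param params Named list of overrides: `ny`/`nx` (256),
#'   `pixel_size_um` (0.1), `n_segments` (400), `length_range_um`
#'   (c(1.5, 4)), `chromatin_discs` (data.frame y_um, x_um, r_um; default
#'   one centred disc covering ~20% of the field), `exclusion` (FALSE),
#'   `filament_amp` (150), `dna_amp` (200), `psf_sigma_px` (1.5),
#'   `bg` (10), `noise` (TRUE).
#' @param seed Integer RNG seed.
#' @return List with `stack` (channels `tubulin`, `dna`) and `truth`
#'   recording `length_inside_um`, `length_outside_um`, segment endpoints
#'   and the chromatin geometry.
#' @export
make_filament_field <- function(params = list(), seed = 1) {
  p <- utils::modifyList(list(
    ny = 256L, nx = 256L, pixel_size_um = 0.1,
    n_segments = 400L, length_range_um = c(1.5, 4),
    chromatin_discs = NULL, exclusion = FALSE,
    filament_amp = 150, dna_amp = 200, psf_sigma_px = 1.5, bg = 10,
    noise = TRUE
  ), params)
  with_seed(seed, {
    px <- p$pixel_size_um
    w_um <- p$nx * px; h_um <- p$ny * px
    discs <- p$chromatin_discs
    if (is.null(discs)) {
      r20 <- sqrt(0.2 * w_um * h_um / pi)
      discs <- data.frame(y_um = h_um / 2, x_um = w_um / 2, r_um = r20)
    }
    if (any(discs$r_um <= 0)) stop("chromatin region must have positive area")
    n <- p$n_segments
    len <- runif(n, p$length_range_um[1], p$length_range_um[2])
    th <- runif(n, 0, 2 * pi)
    # midpoints are drawn from a padded region and segments clipped to the
    # field, so the line process is stationary across the whole image
    pad <- p$length_range_um[2] / 2
    mid_y <- runif(n, -pad, h_um + pad); mid_x <- runif(n, -pad, w_um + pad)
    a <- cbind(mid_y - len / 2 * sin(th), mid_x - len / 2 * cos(th))
    b <- cbind(mid_y + len / 2 * sin(th), mid_x + len / 2 * cos(th))
    # clamp to the field by shrinking toward the midpoint
    for (i in seq_len(n)) {
      lo <- c(0.05, 0.05); hi <- c(h_um - 0.05, w_um - 0.05)
      tmin <- 0; tmax <- 1
      pa <- a[i, ]; pb <- b[i, ]
      for (dimk in 1:2) {
        dv <- pb[dimk] - pa[dimk]
        if (dv != 0) {
          t1 <- (lo[dimk] - pa[dimk]) / dv; t2 <- (hi[dimk] - pa[dimk]) / dv
          tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
        }
      }
      out_of_field <- any(pa < lo & pb < lo) || any(pa > hi & pb > hi)
      if (tmax < tmin || out_of_field) { tmax <- tmin <- 0 }
      a[i, ] <- pa + tmin * (pb - pa); b[i, ] <- pa + tmax * (pb - pa)
    }
    len <- sqrt(rowSums((b - a)^2))

    inside_len <- vapply(seq_len(n), function(i)
      .segment_inside_length(a[i, ], b[i, ], discs), numeric(1))
    if (p$exclusion) {
      total_inside <- 0
      total_outside <- sum(len - inside_len)
    } else {
      total_inside <- sum(inside_len)
      total_outside <- sum(len - inside_len)
    }

    img <- matrix(0, p$ny, p$nx)
    step_um <- 0.25 * px
    for (i in seq_len(n)) {
      if (len[i] <= 0) next
      ts <- seq(0, len[i], by = step_um) / len[i]
      pts_y <- a[i, 1] + ts * (b[i, 1] - a[i, 1])
      pts_x <- a[i, 2] + ts * (b[i, 2] - a[i, 2])
      keep <- rep(TRUE, length(ts))
      if (p$exclusion) {
        for (j in seq_len(nrow(discs)))
          keep <- keep & ((pts_y - discs$y_um[j])^2 + (pts_x - discs$x_um[j])^2 >
                          discs$r_um[j]^2)
      }
      iy <- pmin(pmax(round(pts_y[keep] / px), 0), p$ny - 1) + 1
      ix <- pmin(pmax(round(pts_x[keep] / px), 0), p$nx - 1) + 1
      for (k in seq_along(iy)) img[iy[k], ix[k]] <- img[iy[k], ix[k]] + 0.25
    }
    tub <- p$bg + p$filament_amp * gaussian_denoise(img, p$psf_sigma_px)
    dna <- 5 + p$dna_amp * render_discs(p$ny, p$nx, px,
                                        cbind(discs$y_um, discs$x_um),
                                        discs$r_um, 1)
    channels <- list(tubulin = tub, dna = dna)
    noise_rec <- lapply(channels, function(ch) default_noise(max(ch), p$noise))
    noisy <- Map(apply_camera_noise, channels, noise_rec)
    stack <- calibrated_stack(noisy, calibration(px))
    chrom_area_um2 <- sum(pi * discs$r_um^2)
    truth <- scene_truth(
      scene_id = sprintf("filaments-seed%s", format(seed)),
      geometry = "filament_field",
      true_params = list(
        pixel_size_um = px, exclusion = p$exclusion,
        segments_a_um = a, segments_b_um = b,
        chromatin_discs = discs,
        chromatin_area_um2 = chrom_area_um2,
        field_area_um2 = w_um * h_um,
        length_inside_um = total_inside, length_outside_um = total_outside,
        noiseless_channels = channels
      ),
      seed = seed, noise = noise_rec)
    list(stack = stack, truth = truth)
  })
}

# Exact length of the sub-segments of [a, b] (um) lying inside the union of
# discs: per-disc chord intervals in the segment parameter, merged.
.segment_inside_length <- function(a, b, discs) {
  d <- b - a
  L <- sqrt(sum(d^2))
  if (L == 0) return(0)
  u <- d / L
  ints <- matrix(0, 0, 2)
  for (j in seq_len(nrow(discs))) {
    cvec <- c(discs$y_um[j] - a[1], discs$x_um[j] - a[2])
    tm <- sum(cvec * u)
    h2 <- sum(cvec^2) - tm^2
    r2 <- discs$r_um[j]^2
    if (h2 >= r2) next
    half <- sqrt(r2 - h2)
    t1 <- max(0, tm - half); t2 <- min(L, tm + half)
    if (t2 > t1) ints <- rbind(ints, c(t1, t2))
  }
  if (nrow(ints) == 0) return(0)
  ints <- ints[order(ints[, 1]), , drop = FALSE]
  tot <- 0; cur <- ints[1, ]
  for (j in seq_len(nrow(ints))[-1]) {
    if (ints[j, 1] <= cur[2]) cur[2] <- max(cur[2], ints[j, 2])
    else { tot <- tot + cur[2] - cur[1]; cur <- ints[j, ] }
  }
  tot + cur[2] - cur[1]
}

# Generator-side ground truth for tomogram fixtures: per-domain polyline
# length by very dense point sampling (default 0.5 nm pitch) with
# point-in-voxel membership, restricted to the z-window. Deliberately a
# separate code path from the tomogram metric implementation.
polyline_domain_lengths <- function(polylines, mask, voxel_um, z_window,
                                    pitch_um = 0.0005) {
  d <- dim(mask)
  len_in <- 0; len_out <- 0
  zlo <- (z_window[1] - 1) * voxel_um[3]; zhi <- z_window[2] * voxel_um[3]
  for (pl in polylines) {
    for (s in seq_len(nrow(pl) - 1L)) {
      a <- pl[s, ]; b <- pl[s + 1L, ]
      L <- sqrt(sum((b - a)^2))
      if (L == 0) next
      np <- max(2L, ceiling(L / pitch_um))
      ts <- (seq_len(np) - 0.5) / np
      py <- a[1] + ts * (b[1] - a[1]); pxx <- a[2] + ts * (b[2] - a[2])
      pz <- a[3] + ts * (b[3] - a[3])
      inwin <- pz >= zlo & pz < zhi
      iy <- pmin(pmax(floor(py / voxel_um[1]), 0), d[1] - 1) + 1
      ix <- pmin(pmax(floor(pxx / voxel_um[2]), 0), d[2] - 1) + 1
      iz <- pmin(pmax(floor(pz / voxel_um[3]), 0), d[3] - 1) + 1
      inside <- mask[cbind(iy, ix, iz)] & inwin
      seglen <- L / np
      len_in <- len_in + sum(inside) * seglen
      len_out <- len_out + sum(!inside & inwin) * seglen
    }
  }
  list(length_chromatin_um = len_in, length_cytoplasm_um = len_out)
}

domain_volumes <- function(mask, voxel_um, z_window) {
  sl <- mask[, , z_window[1]:z_window[2], drop = FALSE]
  vvox <- prod(voxel_um)
  list(volume_chromatin_um3 = sum(sl) * vvox,
       volume_cytoplasm_um3 = sum(!sl) * vvox)
}

#' Synthetic electron-tomogram fixture
#'
#' Produces manual-annotation-style inputs for the tomogram density
#' analysis: 3D polylines (microtubule traces, micrometre coordinates) and
#' a voxelized chromatin mask, plus ground-truth per-domain lengths
#' computed by very dense subsampling (0.5 nm pitch) against the voxel
#' mask within the analysed z-window.
#'
#' @param params Named list of overrides: grid `ny`/`nx`/`nz`
#'   (64, 64, 40), `voxel_um` (c(0.008, 0.008, 0.008)), `n_polylines`
#'   (30), steps per polyline `n_steps` (10) of length `step_um` (0.05),
#'   `chromatin_radius_um` (0.18, a central ball), `z_exclude` (5 slices
#'   at top and bottom).
#' @param seed Integer RNG seed.
#' @return List with `polylines` (list of n x 3 matrices, columns
#'   `y, x, z` in micrometres), `mask` (3D logical array), `voxel_um`,
#'   `z_window` (1-based inclusive slice range) and `truth` with
#'   `length_chromatin_um`, `length_cytoplasm_um` and domain volumes.
#' @export
make_tomogram_fixture <- function(params = list(), seed = 1) {
  p <- utils::modifyList(list(
    ny = 64L, nx = 64L, nz = 40L, voxel_um = c(0.008, 0.008, 0.008),
    n_polylines = 30L, n_steps = 10L, step_um = 0.05,
    chromatin_radius_um = 0.18, z_exclude = 5L
  ), params)
  with_seed(seed, {
    v <- p$voxel_um
    ext <- c(p$ny, p$nx, p$nz) * v
    cen <- ext / 2
    g <- expand.grid(y = seq_len(p$ny), x = seq_len(p$nx), z = seq_len(p$nz))
    d2 <- ((g$y - 0.5) * v[1] - cen[1])^2 + ((g$x - 0.5) * v[2] - cen[2])^2 +
          ((g$z - 0.5) * v[3] - cen[3])^2
    mask <- array(d2 <= p$chromatin_radius_um^2, c(p$ny, p$nx, p$nz))
    polylines <- lapply(seq_len(p$n_polylines), function(i) {
      pt <- c(runif(1, 0.05, ext[1] - 0.05), runif(1, 0.05, ext[2] - 0.05),
              runif(1, 0.02, ext[3] - 0.02))
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      out <- matrix(0, p$n_steps + 1L, 3); out[1, ] <- pt
      for (s in seq_len(p$n_steps)) {
        dir <- dir + rnorm(3, sd = 0.25); dir <- dir / sqrt(sum(dir^2))
        pt <- pt + dir * p$step_um
        pt <- pmin(pmax(pt, c(0.01, 0.01, 0.005)), ext - c(0.01, 0.01, 0.005))
        out[s + 1L, ] <- pt
      }
      colnames(out) <- c("y", "x", "z")
      out
    })
    z_window <- c(p$z_exclude + 1L, p$nz - p$z_exclude)
    truth_len <- polyline_domain_lengths(polylines, mask, v, z_window,
                                         pitch_um = 0.0005)
    vol <- domain_volumes(mask, v, z_window)
    truth <- scene_truth(
      scene_id = sprintf("tomogram-seed%s", format(seed)),
      geometry = "tomogram_fixture",
      true_params = c(truth_len, vol,
                      list(voxel_um = v, z_window = z_window)),
      seed = seed, noise = list(poisson = FALSE, gaussian_sd = 0))
    list(polylines = polylines, mask = mask, voxel_um = v,
         z_window = z_window, truth = truth)
  })
}
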