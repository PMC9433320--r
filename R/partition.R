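#' Partition measurement record
#'
#' Inside/outside mean intensities, backgrounds, and their ratio -- the
#' equilibrium partition coefficient of a probe between chromatin (or
#' droplet) interior and the surrounding phase.
#'
#' @param inside_mean,outside_mean Mean probe intensities.
#' @param background Background level subtracted from both (0 = none).
#' @param method One of `"line"`, `"mask_ring"`, `"circle"`, `"droplet"`.
#' @param params Named list of geometry parameters used.
#' @return An object of class `partition_measurement` with field
#'   `coefficient`.
#' @export
partition_measurement <- function(inside_mean, outside_mean, background = 0,
                                  method, params = list()) {
  method <- match.arg(method, c("line", "mask_ring", "circle", "droplet"))
  coefficient <- (inside_mean - background) / (outside_mean - background)
  structure(list(inside_mean = inside_mean, outside_mean = outside_mean,
                 background = background, coefficient = coefficient,
                 method = method, params = params),
            class = "partition_measurement")
}

#' @export
print.partition_measurement <- function(x, ...) {
  cat(sprintf("partition (%s): P = %.4g (in %.4g / out %.4g, bg %.4g)\n",
              x$method, x$coefficient, x$inside_mean, x$outside_mean,
              x$background))
  invisible(x)
}

#' Line-profile partition coefficient
#'
#' Samples probe and DNA reference along a line crossing the chromatin
#' boundary. The boundary is localized at the 50% point between the
#' inside and outside plateaus of the DNA profile (the side with the
#' higher DNA mean is "inside"); the coefficient is the probe intensity
#' `offset_um` inside the boundary divided by the intensity `offset_um`
#' outside. When the stated segment is too short to reach both offsets
#' the sampled line is extended along its direction and the result is
#' flagged.
#'
#' @param probe,dna Numeric matrices (same geometry).
#' @param start,end 0-based `(y, x)` endpoints of the measurement line.
#' @param width_px Perpendicular averaging width (default 5 px).
#' @param offset_um Offset from the boundary on each side (default 1 um).
#' @param pixel_size_um Micrometres per pixel.
#' @return A [partition_measurement()] (method `"line"`); attribute
#'   `extended` flags line extension, attribute `boundary_um` gives the
#'   boundary position along the (possibly extended) profile.
#' @export
partition_line <- function(probe, dna, start, end, width_px = 5,
                           offset_um = 1, pixel_size_um = 1) {
  dvec <- end - start
  len_px <- sqrt(sum(dvec^2))
  if (len_px == 0) stop("zero-length segment")
  u <- dvec / len_px
  ext_px <- (offset_um + 0.5) / pixel_size_um
  s2 <- start - u * ext_px
  e2 <- end + u * ext_px
  prof_dna <- line_profile(dna, s2, e2, width_px, pixel_size_um)
  prof_probe <- line_profile(probe, s2, e2, width_px, pixel_size_um)
  n <- length(prof_dna$intensity)
  half1 <- seq_len(floor(n / 2)); half2 <- (floor(n / 2) + 1L):n
  inside_first <- mean(prof_dna$intensity[half1]) > mean(prof_dna$intensity[half2])
  dvals <- prof_dna$intensity; pvals <- prof_probe$intensity
  dist <- prof_dna$distance_um
  if (inside_first) {  # orient so distance increases toward the inside
    dvals <- rev(dvals); pvals <- rev(pvals)
  }
  k <- max(3L, round(0.2 * n))
  out_lev <- mean(dvals[seq_len(k)])
  in_lev <- mean(dvals[(n - k + 1L):n])
  half <- (in_lev + out_lev) / 2
  above <- which(dvals >= half)
  if (length(above) == 0 || above[1] == 1L)
    stop("profile does not cross the chromatin boundary")
  i <- above[1]
  frac <- (half - dvals[i - 1]) / (dvals[i] - dvals[i - 1])
  b_um <- dist[i - 1] + frac * (dist[i] - dist[i - 1])
  p_in <- stats::approx(dist, pvals, xout = b_um + offset_um)$y
  p_out <- stats::approx(dist, pvals, xout = b_um - offset_um)$y
  if (is.na(p_in) || is.na(p_out))
    stop("offset falls beyond the sampled profile")
  pm <- partition_measurement(p_in, p_out, 0, "line",
                              list(offset_um = offset_um, width_px = width_px))
  attr(pm, "extended") <- (b_um + offset_um > len_px * pixel_size_um + ext_px *
                             pixel_size_um) ||
                          (b_um - offset_um < 0) || len_px * pixel_size_um <
                            2 * offset_um
  attr(pm, "boundary_um") <- b_um
  pm
}

#' Mask/ring partition coefficient
#'
#' Chromatin mask from the sigma = 2 denoised DNA channel (Otsu dark),
#' shrunk by `shrink_um`; cytoplasm measured in a ring of `ring_width_um`
#' obtained by extending the mask by `extend_um`; an extracellular
#' background mean is subtracted from both before dividing.
#'
#' @param probe,dna Numeric matrices.
#' @param background Background ROI (logical matrix / [binary_mask()]) or
#'   a numeric background level.
#' @param shrink_um,extend_um,ring_width_um Geometry (defaults 0.2, 1.5,
#'   0.5 um).
#' @param pixel_size_um Micrometres per pixel.
#' @param sigma DNA denoising sigma.
#' @return A [partition_measurement()] (method `"mask_ring"`).
#' @export
partition_mask_ring <- function(probe, dna, background = 0, shrink_um = 0.2,
                                extend_um = 1.5, ring_width_um = 0.5,
                                pixel_size_um = 1, sigma = 2) {
  mask <- otsu_dark_mask(gaussian_denoise(dna, sigma),
                         calibration = calibration(pixel_size_um),
                         source_channel = "dna")
  shrunk <- morph_offset(mask, -shrink_um)
  if (!any(shrunk$values)) stop("mask empty after shrinking")
  ring <- ring_roi(mask, extend_um, ring_width_um)
  if (!any(ring$values)) stop("empty cytoplasmic ring")
  bg <- if (is.numeric(background) && length(background) == 1) background
        else mean(probe[as_mask_matrix(background)])
  inside <- mean(probe[shrunk$values])
  outside <- mean(probe[ring$values])
  if (bg >= outside)
    stop("background exceeds the cytoplasmic ring intensity")
  partition_measurement(inside, outside, bg, "mask_ring",
                        list(shrink_um = shrink_um, extend_um = extend_um,
                             ring_width_um = ring_width_um))
}

#' Chromatin/cytoplasmic-circle partition coefficient
#'
#' Mean probe intensity over the DNA regions divided by the mean in a
#' cytoplasmic disc of `circle_diameter_um` placed at least
#' `min_clearance_um` from every DNA region (the placement maximizes the
#' clearance, searched on the distance transform).
#'
#' @param probe Numeric matrix.
#' @param dna_regions A `region_set` from [regions_from_mask()] (or a
#'   [binary_mask()] of the DNA).
#' @param circle_diameter_um Disc diameter (default 5 um).
#' @param min_clearance_um Minimum distance from DNA regions (default 1 um).
#' @param cell_mask Optional mask restricting the search (cytoplasm).
#' @param pixel_size_um Micrometres per pixel.
#' @return A [partition_measurement()] (method `"circle"`); attribute
#'   `circle_center` gives the chosen 0-based `(y, x)` center.
#' @export
partition_circle <- function(probe, dna_regions, circle_diameter_um = 5,
                             min_clearance_um = 1, cell_mask = NULL,
                             pixel_size_um = 1) {
  dna_mask <- if (inherits(dna_regions, "region_set")) dna_regions$labels > 0
              else as_mask_matrix(dna_regions)
  if (!any(dna_mask)) stop("no DNA regions")
  R_px <- circle_diameter_um / 2 / pixel_size_um
  need_px <- R_px + min_clearance_um / pixel_size_um
  d <- EBImage::distmap((1 - dna_mask) * 1)  # distance to nearest DNA pixel
  ny <- nrow(d); nx <- ncol(d)
  g <- pixel_grid(ny, nx)
  ok <- d >= need_px & g$y >= R_px & g$y <= ny - 1 - R_px &
        g$x >= R_px & g$x <= nx - 1 - R_px
  if (!is.null(cell_mask)) {
    cm <- as_mask_matrix(cell_mask)
    # the whole disc, not just its center, must lie in the cytoplasm
    dc <- EBImage::distmap(cm * 1)
    ok <- ok & cm & dc >= R_px
  }
  if (!any(ok)) stop("no valid cytoplasmic disc placement")
  i <- which(ok)[which.max(d[ok])]
  cy <- (i - 1) %% ny; cx <- (i - 1) %/% ny
  disc <- (g$y - cy)^2 + (g$x - cx)^2 <= R_px^2
  inside <- mean(probe[dna_mask])
  outside <- mean(probe[disc])
  pm <- partition_measurement(inside, outside, 0, "circle",
                              list(circle_diameter_um = circle_diameter_um,
                                   min_clearance_um = min_clearance_um))
  attr(pm, "circle_center") <- c(y = cy, x = cx)
  pm
}

#' In vitro droplet partition coefficient
#'
#' Segments droplets from the DNA channel (sigma = 2 denoise, Otsu dark,
#' particles >= `min_size_px`), measures the probe in a concentric disc
#' covering `interior_area_fraction` of each droplet's area, and divides
#' the pooled disc mean by the mean in a droplet-free rectangular buffer
#' ROI. One coefficient per field.
#'
#' @param probe,dna Numeric matrices.
#' @param buffer_rect 0-based inclusive rectangle `c(y0, y1, x0, x1)`.
#' @param interior_area_fraction Disc area as a fraction of droplet area.
#' @param min_size_px Minimum droplet size in pixels.
#' @param pixel_size_um Micrometres per pixel.
#' @param sigma DNA denoising sigma.
#' @return A [partition_measurement()] (method `"droplet"`); attribute
#'   `n_droplets`.
#' @export
partition_droplet <- function(probe, dna, buffer_rect,
                              interior_area_fraction = 0.25,
                              min_size_px = 5, pixel_size_um = 1, sigma = 2) {
  mask <- otsu_dark_mask(gaussian_denoise(dna, sigma),
                         calibration = calibration(pixel_size_um))
  regs <- regions_from_mask(mask, min_size = min_size_px, size_units = "px2")
  if (nrow(regs$table) == 0) stop("no droplets detected")
  ny <- nrow(probe); nx <- ncol(probe)
  br <- buffer_rect
  buf <- matrix(FALSE, ny, nx)
  buf[(br[1]:br[2]) + 1, (br[3]:br[4]) + 1] <- TRUE
  if (any(regs$labels[buf] > 0))
    stop("buffer rectangle intersects droplets")
  g <- pixel_grid(ny, nx)
  disc_all <- matrix(FALSE, ny, nx)
  for (id in regs$table$id) {
    sel <- regs$labels == id
    cy <- mean(g$y[sel]); cx <- mean(g$x[sel])
    r_px <- sqrt(interior_area_fraction * sum(sel) / pi)
    disc_all <- disc_all | ((g$y - cy)^2 + (g$x - cx)^2 <= r_px^2)
  }
  inside <- mean(probe[disc_all])
  outside <- mean(probe[buf])
  pm <- partition_measurement(inside, outside, 0, "droplet",
                              list(interior_area_fraction = interior_area_fraction,
                                   min_size_px = min_size_px))
  attr(pm, "n_droplets") <- nrow(regs$table)
  pm
}
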