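#' Pole-to-pole axis specification for congression profiles
#'
#' Geometry of the DNA congression measurement: a band profile along the
#' pole-to-pole axis. Defaults follow the standard metaphase preset
#' (22.5 um length, 7.06 um width, central 5 um window); a wide-band
#' preset uses 12.04 um width.
#'
#' @param p1,p2 Pole positions, 0-based `(y, x)` pixels.
#' @param length_um Profile length in micrometres.
#' @param width_um Band width in micrometres.
#' @param central_window_um Central congression window in micrometres.
#' @param z_range_um z-projection range in micrometres (bookkeeping only).
#' @return An object of class `axis_spec`.
#' @export
axis_spec <- function(p1, p2, length_um = 22.5, width_um = 7.06,
                      central_window_um = 5, z_range_um = 2.4) {
  if (!(length_um > central_window_um && central_window_um > 0))
    stop("require length_um > central_window_um > 0")
  structure(list(p1 = p1, p2 = p2, length_um = length_um,
                 width_um = width_um, central_window_um = central_window_um,
                 z_range_um = z_range_um),
            class = "axis_spec")
}

#' Detect spindle poles in a tubulin channel
#'
#' Bipolar mode: after sigma = 2 Gaussian denoising, the two
#' highest-prominence intensity maxima separated by at least
#' `min_separation_um`. Monopolar mode: the intensity centroid of the
#' (minimum-subtracted) tubulin signal, the centre of the aster.
#'
#' @param tubulin Numeric matrix.
#' @param mode `"bipolar"` or `"monopolar"`.
#' @param pixel_size_um Micrometres per pixel.
#' @param min_separation_um Minimum pole separation (bipolar).
#' @param sigma Denoising sigma in pixels.
#' @return Bipolar: 2 x 2 matrix of 0-based `(y, x)` pole positions.
#'   Monopolar: length-2 vector.
#' @export
detect_poles <- function(tubulin, mode = c("bipolar", "monopolar"),
                         pixel_size_um = 1, min_separation_um = 3, sigma = 2) {
  mode <- match.arg(mode)
  sm <- gaussian_denoise(tubulin, sigma)
  if (mode == "monopolar") {
    g <- pixel_grid(nrow(sm), ncol(sm))
    w <- sm - min(sm)
    return(c(y = sum(g$y * w) / sum(w), x = sum(g$x * w) / sum(w)))
  }
  rng <- diff(range(sm))
  if (rng == 0) stop("tubulin channel is constant; no poles detectable")
  spots <- find_maxima(sm, prominence = 0.05 * rng, exclude_edges = TRUE)
  spots <- spots[order(-spots$prominence, -spots$intensity), , drop = FALSE]
  if (nrow(spots) < 2) stop("fewer than 2 tubulin maxima found")
  min_px <- min_separation_um / pixel_size_um
  first <- spots[1, ]
  for (i in 2:nrow(spots)) {
    d <- sqrt((spots$y[i] - first$y)^2 + (spots$x[i] - first$x)^2)
    if (d >= min_px)
      return(rbind(c(first$y, first$x), c(spots$y[i], spots$x[i])))
  }
  stop("fewer than 2 tubulin maxima separated by the minimum distance")
}

#' DNA congression fraction
#'
#' Fraction of DNA density in the central window of the pole-to-pole band
#' profile: the channel is averaged over z (if 3D), sampled as a band of
#' `width_um` along the axis over `length_um` centred between the poles,
#' the extracellular background mean is subtracted per sample (negatives
#' clipped to 0), and the sum over the central `central_window_um` is
#' divided by the sum over the whole profile.
#'
#' @param dna Numeric matrix or `(y, x, z)` array (averaged over z).
#' @param axis An [axis_spec()].
#' @param background_mean Extracellular background level to subtract.
#' @param pixel_size_um Micrometres per pixel.
#' @return Fraction in \[0, 1\].
#' @export
congression_fraction <- function(dna, axis, background_mean = 0,
                                 pixel_size_um = 1) {
  if (length(dim(dna)) == 3) dna <- apply(dna, c(1, 2), mean)
  mid <- (axis$p1 + axis$p2) / 2
  u <- axis$p2 - axis$p1
  u <- u / sqrt(sum(u^2))
  half_px <- axis$length_um / 2 / pixel_size_um
  start <- mid - u * half_px
  end <- mid + u * half_px
  width_px <- max(1L, round(axis$width_um / pixel_size_um))
  prof <- line_profile(dna, start, end, width_px = width_px,
                       pixel_size_um = pixel_size_um)
  vals <- pmax(prof$intensity - background_mean, 0)
  total <- sum(vals)
  if (total <= 0) stop("profile is empty after background subtraction")
  centre <- axis$length_um / 2
  in_win <- abs(prof$distance_um - centre) <= axis$central_window_um / 2
  sum(vals[in_win]) / total
}

#' Mask-based chromatin density
#'
#' The mean DNA intensity within the Otsu-dark chromatin mask of the
#' sigma = 2 denoised channel, divided by a reference mean (the
#' unperturbed-control normalization).
#'
#' @param dna Numeric matrix (central z-section).
#' @param reference_mean Positive reference density (default 1 = raw).
#' @param sigma Denoising sigma in pixels.
#' @param background Camera/extracellular offset subtracted from the
#'   in-mask mean before normalization (default 0).
#' @return Normalized density; attribute `mask` holds the chromatin mask.
#' @export
chromatin_density <- function(dna, reference_mean = 1, sigma = 2,
                              background = 0) {
  if (!is.numeric(reference_mean) || reference_mean <= 0)
    stop("reference_mean must be > 0")
  sm <- gaussian_denoise(dna, sigma)
  mask <- otsu_dark_mask(sm)
  if (!any(mask$values)) stop("empty chromatin mask")
  val <- (mean(dna[mask$values]) - background) / reference_mean
  attr(val, "mask") <- mask
  val
}

#' Peak-window density along a line profile
#'
#' Mean intensity in a window (default 0.2 um) centred on the global peak
#' of the profile -- the line-profile form of the chromatin density
#' readout. A flat profile takes its first maximum and is flagged.
#'
#' @param profile A [line_profile()].
#' @param window_um Window width in micrometres.
#' @return Mean density near the peak; attribute `flat` flags degenerate
#'   profiles.
#' @export
density_line_peak <- function(profile, window_um = 0.2) {
  if (max(profile$distance_um) <= window_um)
    stop("profile shorter than the peak window")
  i <- which.max(profile$intensity)
  sel <- abs(profile$distance_um - profile$distance_um[i]) <= window_um / 2
  out <- mean(profile$intensity[sel])
  attr(out, "flat") <- length(unique(profile$intensity)) == 1L
  out
}

#' Radial displacement ratio around a monopole
#'
#' Quantifies DNA displacement away from a monopolar spindle: from the
#' radial intensity profile around the pole, the edge radius R is the
#' smallest radius containing `edge_quantile` (default 99%) of the
#' cumulative intensity, and the ratio is the intensity within
#' `inner_fraction * R` of the pole divided by the intensity between
#' there and R.
#'
#' @param h2b Numeric matrix (maximum z-projection already applied).
#' @param center Pole position, 0-based `(y, x)` pixels.
#' @param inner_fraction Inner radius as a fraction of R (default 0.3).
#' @param edge_quantile Cumulative-intensity quantile defining R.
#' @param theta_deg Integration angle (degrees; 360 = full circle).
#' @param orientation_deg Sector orientation.
#' @param background Background level subtracted before analysis.
#' @param pixel_size_um Micrometres per pixel.
#' @return Ratio >= 0 (`Inf`, flagged, when no mass lies outside).
#' @export
radial_displacement_ratio <- function(h2b, center, inner_fraction = 0.30,
                                      edge_quantile = 0.99, theta_deg = 360,
                                      orientation_deg = 0, background = 0,
                                      pixel_size_um = 1) {
  # negatives are kept so that background noise cancels in the cumulative;
  # sums are taken at full pixel-radius resolution (the limit of an
  # infinitesimal-bin radial profile), which avoids whole-bin quantization
  # at the 0.3 R and R cuts
  img <- h2b - background
  g <- pixel_grid(nrow(img), ncol(img))
  dy <- g$y - center[1]; dx <- g$x - center[2]
  r_um <- sqrt(dy^2 + dx^2) * pixel_size_um
  ang <- atan2(dy, dx) * 180 / pi
  dang <- ((ang - orientation_deg + 180) %% 360) - 180
  sel <- abs(dang) <= theta_deg / 2
  rv <- as.numeric(r_um[sel]); iv <- as.numeric(img[sel])
  total <- sum(iv)
  if (total <= 0) stop("no intensity in the integration sector")
  ord <- order(rv)
  cum <- cumsum(iv[ord])
  R <- rv[ord][which(cum >= edge_quantile * total)[1]]
  inner <- sum(iv[rv <= inner_fraction * R])
  outer <- sum(iv[rv > inner_fraction * R & rv <= R])
  if (outer == 0) {
    out <- Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  max(inner / outer, 0)
}

#' Pole-peripheral intensity distribution
#'
#' Total channel intensity in the cell outside a circular pole region
#' (radius `pole_radius_um`, default 5 um): `sum(cell) - sum(pole disc)`.
#' Dataset-level normalization (by the mean of per-cell totals) is applied
#' separately with [normalize_to_reference()].
#'
#' @param channel Numeric matrix (max projection).
#' @param pole_position 0-based `(y, x)` pixel position of the pole.
#' @param cell_mask A [binary_mask()] of the cell outline.
#' @param pole_radius_um Pole disc radius in micrometres.
#' @param pixel_size_um Micrometres per pixel.
#' @return List with `peripheral_sum`, `total_sum` and their ratio
#'   `fraction`; warns when the pole disc is clipped by the cell mask.
#' @export
peripheral_distribution <- function(channel, pole_position, cell_mask,
                                    pole_radius_um = 5, pixel_size_um = 1) {
  cm <- as_mask_matrix(cell_mask)
  g <- pixel_grid(nrow(channel), ncol(channel))
  disc <- ((g$y - pole_position[1])^2 + (g$x - pole_position[2])^2) *
    pixel_size_um^2 <= pole_radius_um^2
  if (any(disc & !cm))
    warning("pole disc extends beyond the cell mask; clipped")
  total <- sum(channel[cm])
  pole <- sum(channel[disc & cm])
  list(peripheral_sum = total - pole, total_sum = total,
       fraction = (total - pole) / total)
}

#' Coefficient of variation of a field
#'
#' `CV = sd / mean` over the whole field: the condensation score for in
#' vitro nucleosome-array fields (droplet formation raises the CV).
#'
#' @param img Numeric matrix or array.
#' @return CV >= 0.
#' @export
condensation_cv <- function(img) {
  mu <- mean(img)
  if (mu == 0) stop("zero-mean field")
  stats::sd(img) / mu
}

#' Background-corrected two-channel intensity ratio
#'
#' `(mean(numerator in roi) - bg_num) / (mean(denominator in roi) -
#' bg_den)`, divided by a reference value -- the shared form of the
#' degradation-validation, histone-acetylation and cyclin-B1 readouts.
#'
#' @param numerator,denominator Numeric matrices.
#' @param roi A [binary_mask()] (or logical matrix) of the measured region.
#' @param reference Positive reference value (default 1 = unnormalized).
#' @param bg_num,bg_den Per-channel background levels.
#' @return Normalized ratio.
#' @export
normalized_channel_ratio <- function(numerator, denominator, roi,
                                     reference = 1, bg_num = 0, bg_den = 0) {
  if (reference <= 0) stop("reference must be > 0")
  m <- as_mask_matrix(roi)
  if (!any(m)) stop("empty ROI")
  den <- mean(denominator[m]) - bg_den
  if (den <= 0) stop("denominator is not positive after background subtraction")
  ((mean(numerator[m]) - bg_num) / den) / reference
}
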