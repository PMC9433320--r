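#' Microtubule skeleton-length ratio (chromatin / buffer)
#'
#' The in vitro microtubule-exclusion readout: the tubulin channel is
#' denoised (sigma = 2), background-subtracted (rolling ball), locally
#' thresholded (Phansalkar) and skeletonized; chromatin ROIs come from the
#' denoised DNA channel (Otsu dark, particles >= `min_size_px`). The ratio
#' of total skeleton length inside chromatin ROIs to that in the
#' surrounding buffer is returned, together with the area-normalized
#' ratio (lengths per unit area).
#'
#' @param tubulin,chromatin Numeric matrices.
#' @param rolling_radius Rolling-ball radius in pixels (classic preset
#'   740; radii larger than the image reduce to global-minimum
#'   subtraction).
#' @param phansalkar_radius Local-threshold radius in pixels (classic
#'   preset 100).
#' @param min_size_px Minimum chromatin particle size (pixels).
#' @param pixel_size_um Micrometres per pixel.
#' @param sigma Denoising sigma.
#' @return List with `ratio` (raw length ratio), `ratio_per_area`,
#'   `length_in_um`, `length_out_um`, `area_in_um2`, `area_out_um2` and
#'   the `skeleton` mask.
#' @export
mt_skeleton_ratio <- function(tubulin, chromatin, rolling_radius = 740,
                              phansalkar_radius = 100, min_size_px = 5,
                              pixel_size_um = 1, sigma = 2) {
  cal <- calibration(pixel_size_um)
  tub <- gaussian_denoise(tubulin, sigma)
  tub <- rolling_ball_background(tub, rolling_radius)
  mtm <- phansalkar_mask(tub, phansalkar_radius, calibration = cal,
                         source_channel = "tubulin")
  sk <- skeletonize_length(mtm)$skeleton

  chrom <- otsu_dark_mask(gaussian_denoise(chromatin, sigma),
                          calibration = cal, source_channel = "dna")
  regs <- regions_from_mask(chrom, min_size = min_size_px, size_units = "px2")
  if (nrow(regs$table) == 0) stop("no chromatin regions detected")
  inroi <- regs$labels > 0

  len_in <- skeleton_length_um(sk$values & inroi, pixel_size_um)
  len_out <- skeleton_length_um(sk$values & !inroi, pixel_size_um)
  if (len_out == 0) stop("zero buffer skeleton length")
  area_in <- sum(inroi) * pixel_size_um^2
  area_out <- sum(!inroi) * pixel_size_um^2
  list(ratio = len_in / len_out,
       ratio_per_area = (len_in / area_in) / (len_out / area_out),
       length_in_um = len_in, length_out_um = len_out,
       area_in_um2 = area_in, area_out_um2 = area_out,
       skeleton = sk)
}

#' Microtubule density per domain from tomogram annotations
#'
#' Clips annotated microtubule polylines against a voxelized chromatin
#' domain within the analysed z-window (the blurry top and bottom slices
#' are excluded) and normalizes the per-domain summed length by the domain
#' volume. Clipping subsamples each segment at a quarter of the smallest
#' voxel pitch and assigns sub-segments by midpoint membership.
#'
#' @param polylines List of n x 3 matrices of `(y, x, z)` points in
#'   micrometres.
#' @param mask 3D logical array `(y, x, z)`: TRUE = chromatin.
#' @param voxel_um Voxel size `(y, x, z)` in micrometres.
#' @param z_window 1-based inclusive slice range analysed.
#' @return List with `density_chromatin`, `density_cytoplasm` (um per
#'   um^3), per-domain lengths and volumes.
#' @export
tomogram_mt_density <- function(polylines, mask, voxel_um,
                                z_window = c(1L, dim(mask)[3])) {
  d <- dim(mask)
  pitch <- 0.25 * min(voxel_um)
  zlo <- (z_window[1] - 1) * voxel_um[3]; zhi <- z_window[2] * voxel_um[3]
  len_in <- 0; len_out <- 0
  for (pl in polylines) {
    for (s in seq_len(nrow(pl) - 1L)) {
      a <- pl[s, ]; b <- pl[s + 1L, ]
      L <- sqrt(sum((b - a)^2))
      if (L == 0) next
      np <- max(1L, ceiling(L / pitch))
      ts <- (seq_len(np) - 0.5) / np
      py <- a[1] + ts * (b[1] - a[1]); px <- a[2] + ts * (b[2] - a[2])
      pz <- a[3] + ts * (b[3] - a[3])
      inwin <- pz >= zlo & pz < zhi
      iy <- pmin(pmax(floor(py / voxel_um[1]), 0), d[1] - 1) + 1
      ix <- pmin(pmax(floor(px / voxel_um[2]), 0), d[2] - 1) + 1
      iz <- pmin(pmax(floor(pz / voxel_um[3]), 0), d[3] - 1) + 1
      member <- mask[cbind(iy, ix, iz)]
      seglen <- L / np
      len_in <- len_in + sum(member & inwin) * seglen
      len_out <- len_out + sum(!member & inwin) * seglen
    }
  }
  vvox <- prod(voxel_um)
  sl <- mask[, , z_window[1]:z_window[2], drop = FALSE]
  vol_in <- sum(sl) * vvox
  vol_out <- sum(!sl) * vvox
  if (vol_in == 0 || vol_out == 0) stop("empty domain volume")
  list(density_chromatin = len_in / vol_in,
       density_cytoplasm = len_out / vol_out,
       length_chromatin_um = len_in, length_cytoplasm_um = len_out,
       volume_chromatin_um3 = vol_in, volume_cytoplasm_um3 = vol_out)
}
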