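#' Fraction of kinetochores displaced outside chromatin
#'
#' Detects kinetochores as prominence maxima of the (sigma = 1 denoised)
#' CENP-A channel, builds the chromatin mask from the sigma = 2 denoised
#' DNA channel by Otsu-dark thresholding, and classifies each spot by its
#' signed distance to the mask surface: displaced iff strictly more than
#' `distance_cut_um` (default 0.5 um) outside.
#'
#' @param cenpa,dna Numeric matrices sharing geometry (z-projected).
#' @param prominence Spot-detection prominence in intensity units
#'   (100 for immunofluorescence presets, 2000 for live imaging).
#' @param distance_cut_um Displacement cutoff in micrometres.
#' @param pixel_size_um Micrometres per pixel.
#' @param cenpa_sigma,dna_sigma Denoising sigmas.
#' @return Fraction of spots outside chromatin; attributes `spots`
#'   (per-spot table with signed distances) and `n_spots`.
#' @export
kinetochore_displacement <- function(cenpa, dna, prominence,
                                     distance_cut_um = 0.5,
                                     pixel_size_um = 1,
                                     cenpa_sigma = 1, dna_sigma = 2) {
  sm <- gaussian_denoise(dna, dna_sigma)
  mask <- otsu_dark_mask(sm, calibration = calibration(pixel_size_um),
                         source_channel = "dna")
  spots <- find_maxima(gaussian_denoise(cenpa, cenpa_sigma), prominence,
                       exclude_edges = TRUE)
  if (nrow(spots) == 0) stop("no kinetochore spots detected")
  d <- distance_to_mask_surface(spots, mask)
  spots$distance_um <- d
  spots$outside <- d > distance_cut_um
  out <- mean(spots$outside)
  attr(out, "spots") <- spots
  attr(out, "n_spots") <- nrow(spots)
  out
}

#' Count DNA-damage foci inside chromatin
#'
#' Counts prominence maxima of the (max-projected, sigma = 2 denoised)
#' foci channel whose positions fall inside the Otsu-dark DNA mask --
#' the gammaH2A.X focus readout.
#'
#' @param foci Numeric matrix (maximum z-projection) or `(y, x, z)` array
#'   (max-projected internally).
#' @param dna Numeric matrix (same geometry after projection).
#' @param prominence Spot prominence (default 3000).
#' @param sigma Denoising sigma.
#' @return Integer focus count (0 allowed); attribute `spots`.
#' @export
count_foci <- function(foci, dna, prominence = 3000, sigma = 2) {
  if (length(dim(foci)) == 3) foci <- apply(foci, c(1, 2), max)
  if (length(dim(dna)) == 3) dna <- apply(dna, c(1, 2), max)
  mask <- otsu_dark_mask(gaussian_denoise(dna, sigma))
  spots <- find_maxima(gaussian_denoise(foci, sigma), prominence,
                       exclude_edges = TRUE)
  if (nrow(spots) == 0) {
    out <- 0L
    attr(out, "spots") <- spots
    return(out)
  }
  iy <- pmin(pmax(round(spots$y) + 1, 1), nrow(dna))
  ix <- pmin(pmax(round(spots$x) + 1, 1), ncol(dna))
  inside <- mask$values[cbind(iy, ix)]
  out <- sum(inside)
  attr(out, "spots") <- spots[inside, , drop = FALSE]
  out
}

#' Apoptotic index from per-cell marker intensities
#'
#' A cell is positive for a marker when its mean intensity exceeds 1.2x
#' the median of the untreated control population for that marker. Under
#' the default joint rule a cell must be positive for both pSIVA and PI to
#' count as apoptotic; `rule = "or"` requires either. The index is the
#' positive fraction.
#'
#' @param cells data.frame with per-cell columns `mean_pSIVA`, `mean_PI`.
#' @param control data.frame of untreated control cells (same columns).
#' @param rule `"and"` (joint, default) or `"or"`.
#' @param threshold_factor Multiplier on the control median (default 1.2).
#' @return List with `index`, per-cell `flags` data.frame and the
#'   thresholds used.
#' @export
apoptotic_index <- function(cells, control, rule = c("and", "or"),
                            threshold_factor = 1.2) {
  rule <- match.arg(rule)
  if (nrow(control) == 0) stop("empty control population")
  thr_psiva <- threshold_factor * median(control$mean_pSIVA)
  thr_pi <- threshold_factor * median(control$mean_PI)
  pos_psiva <- cells$mean_pSIVA > thr_psiva
  pos_pi <- cells$mean_PI > thr_pi
  pos <- if (rule == "and") pos_psiva & pos_pi else pos_psiva | pos_pi
  list(index = mean(pos),
       flags = data.frame(positive_pSIVA = pos_psiva, positive_PI = pos_pi,
                          positive = pos),
       thresholds = c(pSIVA = thr_psiva, PI = thr_pi),
       rule = rule)
}
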