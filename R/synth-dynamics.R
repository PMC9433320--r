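#' Synthetic FRAP time series
#'
#' Generates a photobleaching recovery movie of a chromatin region: a
#' nuclear disc at uniform pre-bleach level, a bleach ROI whose signal
#' follows
#' `bg + beta^f * pre * ((1 - d) + d * m * (1 - 2^(-t / tau)))`
#' (d = bleach depth, m = mobile fraction, tau = half recovery time,
#' beta = per-frame acquisition-bleaching factor, f = frame index, t =
#' time since bleach), while the whole-region mean follows
#' `bg + beta^f * pre` (recovery drawn from a large pool). The bleach
#' ROI, nucleus and background masks and all parameters are recorded in
#' the truth.
#'
#' @param params Named list of overrides: `ny`/`nx` (64),
#'   `pixel_size_um` (0.1), `time_step_s` (0.1), `n_pre` (5),
#'   `n_frames` (120), `pre_level` (200), `bleach_depth` (0.8),
#'   `mobile_fraction` (0.9), `half_time_s` (2), `beta` (0.999),
#'   `bg` (10), `nucleus_radius_um` (2.5), `roi_radius_um` (0.7),
#'   `noise` (TRUE).
#' @param seed Integer RNG seed.
#' @return List with `stack` (channel `h2b`, one frame per time point),
#'   `series` (a [frap_series()] measured noiselessly is NOT provided --
#'   measure the stack with [measure_frap_series()]), and `truth`.
#' @export
make_frap_series <- function(params = list(), seed = 1) {
  p <- utils::modifyList(list(
    ny = 64L, nx = 64L, pixel_size_um = 0.1, time_step_s = 0.1,
    n_pre = 5L, n_frames = 120L, pre_level = 200,
    bleach_depth = 0.8, mobile_fraction = 0.9, half_time_s = 2,
    beta = 0.999, bg = 10, nucleus_radius_um = 2.5, roi_radius_um = 0.7,
    noise = TRUE
  ), params)
  m <- p$mobile_fraction; tau <- p$half_time_s
  if (m < 0 || m > 1) stop("mobile_fraction must lie in [0, 1]")
  if (tau <= 0) stop("half_time_s must be > 0")
  with_seed(seed, {
    ny <- p$ny; nx <- p$nx; px <- p$pixel_size_um
    cy <- (ny - 1) / 2 * px; cx <- (nx - 1) / 2 * px
    g <- pixel_grid(ny, nx)
    r2n <- (g$y * px - cy)^2 + (g$x * px - cx)^2
    nucleus <- r2n <= p$nucleus_radius_um^2
    roi <- (g$y * px - cy + 1)^2 + (g$x * px - cx)^2 <= p$roi_radius_um^2
    roi <- roi & nucleus
    n_roi <- sum(roi); n_nuc <- sum(nucleus)
    frames <- array(0, c(ny, nx, 1L, 1L, p$n_frames))
    d <- p$bleach_depth
    for (f in seq_len(p$n_frames)) {
      fade <- p$beta^(f - 1L)
      if (f <= p$n_pre) {
        roi_sig <- p$pre_level * fade
      } else {
        t <- (f - p$n_pre - 1L) * p$time_step_s
        roi_sig <- fade * p$pre_level *
          ((1 - d) + d * m * (1 - 2^(-t / tau)))
      }
      # the rest of the nucleus compensates so the whole-region mean stays
      # at fade * pre_level (recovery from a large mobile pool)
      rest_sig <- (n_nuc * fade * p$pre_level - n_roi * roi_sig) / (n_nuc - n_roi)
      img <- matrix(p$bg, ny, nx)
      img[nucleus] <- p$bg + rest_sig
      img[roi] <- p$bg + roi_sig
      frames[, , 1, 1, f] <- img
    }
    noise_rec <- default_noise(max(frames), p$noise)
    if (p$noise) for (f in seq_len(p$n_frames))
      frames[, , 1, 1, f] <- apply_camera_noise(frames[, , 1, 1, f], noise_rec)
    stack <- calibrated_stack(frames,
                              calibration(px, time_step = p$time_step_s),
                              channel_names = "h2b")
    truth <- scene_truth(
      scene_id = sprintf("frap-seed%s", format(seed)), geometry = "frap_series",
      true_params = list(
        pixel_size_um = px, time_step_s = p$time_step_s,
        n_pre = p$n_pre, pre_level = p$pre_level,
        bleach_depth = d, mobile_fraction = m, half_time_s = tau,
        beta = p$beta, bg = p$bg,
        roi_mask = roi, nucleus_mask = nucleus
      ),
      seed = seed, noise = noise_rec)
    list(stack = stack, truth = truth)
  })
}

#' Synthetic FRET biosensor channel triplet
#'
#' A nuclear disc expressing a ratiometric biosensor: inside the nucleus
#' `FRET = r * CFP` for the prescribed true ratio `r`; YFP marks the
#' nucleus for masking. Each channel has its own extracellular background.
#'
#' @param params Named list of overrides: `ny`/`nx` (96),
#'   `pixel_size_um` (0.1), `fret_ratio` (0.7), `cfp_level` (200),
#'   `yfp_level` (300), backgrounds `bg_cfp` (20) / `bg_fret` (15) /
#'   `bg_yfp` (10), `nucleus_radius_um` (3), `psf_sigma_px` (1),
#'   `noise` (TRUE).
#' @param seed Integer RNG seed.
#' @return List with `stack` (channels `cfp`, `fret`, `yfp`) and `truth`
#'   recording `fret_ratio` and the background ROI (1 um corner square).
#' @export
make_fret_pair <- function(params = list(), seed = 1) {
  p <- utils::modifyList(list(
    ny = 96L, nx = 96L, pixel_size_um = 0.1,
    fret_ratio = 0.7, cfp_level = 200, yfp_level = 300,
    bg_cfp = 20, bg_fret = 15, bg_yfp = 10,
    nucleus_radius_um = 3, psf_sigma_px = 1, noise = TRUE
  ), params)
  r <- p$fret_ratio
  if (r < 0) stop("fret_ratio must be >= 0")
  with_seed(seed, {
    px <- p$pixel_size_um
    cy <- (p$ny - 1) / 2 * px; cx <- (p$nx - 1) / 2 * px
    nucleus <- render_discs(p$ny, p$nx, px, rbind(c(cy, cx)),
                            p$nucleus_radius_um, p$psf_sigma_px)
    cfp <- p$bg_cfp + p$cfp_level * nucleus
    fret <- p$bg_fret + r * p$cfp_level * nucleus
    yfp <- p$bg_yfp + p$yfp_level * nucleus
    channels <- list(cfp = cfp, fret = fret, yfp = yfp)
    noise_rec <- lapply(channels, function(ch) default_noise(max(ch), p$noise))
    noisy <- Map(apply_camera_noise, channels, noise_rec)
    stack <- calibrated_stack(noisy, calibration(px))
    bgn <- max(2L, round(1 / px))  # 1 um x 1 um corner square
    truth <- scene_truth(
      scene_id = sprintf("fret-seed%s", format(seed)), geometry = "fret_pair",
      true_params = list(
        pixel_size_um = px, fret_ratio = r,
        cfp_level = p$cfp_level, yfp_level = p$yfp_level,
        bg_cfp = p$bg_cfp, bg_fret = p$bg_fret, bg_yfp = p$bg_yfp,
        nucleus_radius_um = p$nucleus_radius_um,
        bg_rect_px = c(y0 = 0L, y1 = bgn - 1L, x0 = 0L, x1 = bgn - 1L)
      ),
      seed = seed, noise = noise_rec)
    list(stack = stack, truth = truth)
  })
}
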