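#' FRAP trace container
#'
#' Raw traces of a photobleaching experiment: bleach-ROI mean, whole-region
#' mean, and background mean per frame, with the index of the first
#' post-bleach frame.
#'
#' @param times Acquisition times in seconds, strictly increasing.
#' @param roi Bleach-ROI mean intensity per frame.
#' @param total Whole-region mean intensity per frame.
#' @param background Background mean per frame (scalar recycled).
#' @param first_post 1-based index of the first post-bleach frame
#'   (at least 2 pre-bleach frames required).
#' @return An object of class `frap_series`.
#' @export
frap_series <- function(times, roi, total, background, first_post) {
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (first_post < 3) stop("at least 2 pre-bleach frames required")
  n <- length(times)
  stopifnot(length(roi) == n, length(total) == n)
  background <- rep_len(background, n)
  structure(list(times = times, roi = roi, total = total,
                 background = background, first_post = as.integer(first_post)),
            class = "frap_series")
}

#' Measure FRAP traces from an image time series
#'
#' @param stack A [calibrated_stack()] time series (single channel).
#' @param roi_mask,region_mask Logical matrices (bleach ROI; whole
#'   measured region).
#' @param background Background level: numeric, or a logical mask measured
#'   per frame.
#' @param first_post 1-based index of the first post-bleach frame.
#' @param channel Channel to measure (default first).
#' @return A [frap_series()].
#' @export
measure_frap_series <- function(stack, roi_mask, region_mask, background,
                                first_post, channel = 1L) {
  nt <- n_frames(stack)
  dt <- stack$calibration$time_step %||% 1
  roi <- numeric(nt); tot <- numeric(nt); bg <- numeric(nt)
  roi_mask <- as_mask_matrix(roi_mask); region_mask <- as_mask_matrix(region_mask)
  bg_is_mask <- !(is.numeric(background) && length(background) == 1)
  if (bg_is_mask) background_m <- as_mask_matrix(background)
  for (f in seq_len(nt)) {
    img <- get_channel(stack, channel, t = f)
    roi[f] <- mean(img[roi_mask])
    tot[f] <- mean(img[region_mask])
    bg[f] <- if (bg_is_mask) mean(img[background_m]) else background
  }
  frap_series((seq_len(nt) - 1) * dt, roi, tot, bg, first_post)
}

#' FRAP double normalization
#'
#' Corrects the bleach-ROI trace for background and for acquisition
#' bleaching using the whole-region trace:
#' `N(t) = ((Iroi(t) - bg) / (Itot(t) - bg)) * ((Itot_pre - bg) /
#' (Iroi_pre - bg))`, with pre-bleach values averaged over the pre-bleach
#' frames. By construction the pre-bleach level is 1 and any per-frame
#' multiplicative factor common to both traces cancels.
#'
#' @param series A [frap_series()].
#' @return data.frame with `time_s` (0 at the first post-bleach frame) and
#'   `N`; attribute `first_post`.
#' @export
frap_normalize <- function(series) {
  stopifnot(inherits(series, "frap_series"))
  pre <- seq_len(series$first_post - 1L)
  roi_c <- series$roi - series$background
  tot_c <- series$total - series$background
  if (any(tot_c <= 0) || mean(roi_c[pre]) <= 0)
    stop("non-positive background-corrected denominator")
  N <- (roi_c / tot_c) * (mean(tot_c[pre]) / mean(roi_c[pre]))
  out <- data.frame(time_s = series$times - series$times[series$first_post],
                    N = N)
  attr(out, "first_post") <- series$first_post
  out
}

#' Fit mobile fraction and half-time to a normalized FRAP curve
#'
#' Least-squares fit of the post-bleach points to
#' `N(t) = F0 + m * (1 - F0) * (1 - 2^(-t / tau))`, where `F0` is the
#' post-bleach floor, `m` the mobile fraction and `tau` directly the
#' half-recovery time (base-2 parameterization). Bounded
#' Levenberg-Marquardt with quantile-based initialization.
#'
#' @param curve Output of [frap_normalize()].
#' @return List with `mobile_fraction`, `half_time_s`, `F0`, `converged`,
#'   and the `fit` object (NULL when not converged).
#' @export
frap_fit <- function(curve) {
  fp <- attr(curve, "first_post")
  post <- curve[seq(fp, nrow(curve)), ]
  if (nrow(post) < 10) stop("need >= 10 post-bleach points")
  t <- post$time_s - post$time_s[1]
  y <- post$N
  F0_0 <- min(max(y[1], 0), 0.95)
  plateau <- mean(y[t >= stats::quantile(t, 0.8)])
  m0 <- min(max((plateau - F0_0) / max(1 - F0_0, 1e-6), 0.05), 1)
  half_level <- F0_0 + 0.5 * (plateau - F0_0)
  i_half <- which(y >= half_level)[1]
  tau0 <- if (is.na(i_half) || t[i_half] <= 0) max(t) / 4 else t[i_half]
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ F0 + m * (1 - F0) * (1 - 2^(-t / tau)),
                      start = list(F0 = F0_0, m = m0, tau = tau0),
                      lower = c(F0 = 0, m = 0, tau = 1e-6),
                      upper = c(F0 = 1, m = 1, tau = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate (flat) curves defeat the optimizer; fall back to the
    # closed-form plateau estimate with an undefined half-time
    m_raw <- min(max((plateau - F0_0) / max(1 - F0_0, 1e-6), 0), 1)
    return(list(mobile_fraction = m_raw, half_time_s = NA_real_,
                F0 = F0_0, converged = FALSE, fit = NULL))
  }
  cf <- coef(fit)
  list(mobile_fraction = unname(cf["m"]), half_time_s = unname(cf["tau"]),
       F0 = unname(cf["F0"]), converged = TRUE, fit = fit)
}

#' Ratiometric FRET/CFP map
#'
#' Background-subtracts the FRET and CFP channels (extracellular ROI means
#' or levels), denoises both with a sigma = 5 Gaussian, and forms the
#' FRET/CFP ratio inside the nuclear mask segmented from the (sigma = 5
#' denoised) YFP channel by Otsu-dark thresholding. Pixels whose corrected
#' CFP is not positive are excluded and counted. The rendering map is
#' clipped to `clip` (default 0 to 1.4).
#'
#' @param cfp,fret,yfp Numeric matrices (average z-projections).
#' @param bg_cfp,bg_fret Backgrounds: numeric levels or logical ROI masks.
#' @param sigma Denoising sigma (default 5).
#' @param clip Display clip range.
#' @return List with `ratio_map` (NA outside the mask), `mean_ratio`,
#'   `mask`, `n_excluded`, and `clipped_map`.
#' @export
fret_ratio_map <- function(cfp, fret, yfp, bg_cfp = 0, bg_fret = 0,
                           sigma = 5, clip = c(0, 1.4)) {
  bgv <- function(bg, img) if (is.numeric(bg) && length(bg) == 1) bg
                           else mean(img[as_mask_matrix(bg)])
  b_c <- bgv(bg_cfp, cfp); b_f <- bgv(bg_fret, fret)
  mask <- otsu_dark_mask(gaussian_denoise(yfp, sigma))
  if (!any(mask$values)) stop("empty nuclear mask")
  c_d <- gaussian_denoise(cfp - b_c, sigma)
  f_d <- gaussian_denoise(fret - b_f, sigma)
  valid <- mask$values & c_d > 0
  n_excluded <- sum(mask$values & !valid)
  ratio <- matrix(NA_real_, nrow(cfp), ncol(cfp))
  ratio[valid] <- f_d[valid] / c_d[valid]
  clipped <- pmin(pmax(ratio, clip[1]), clip[2])
  clipped[!valid] <- NA_real_
  list(ratio_map = ratio, mean_ratio = mean(ratio[valid]),
       mask = mask, n_excluded = n_excluded, clipped_map = clipped)
}
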