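#' Otsu threshold with dark background
#'
#' Classic 256-bin Otsu: the threshold maximizes the between-class variance
#' of the intensity histogram; "dark" means the background is the dark
#' class, so the mask is the strictly brighter class. Ties in the variance
#' maximum resolve to the lowest threshold.
#'
#' @param img Numeric matrix (or `(y, x, z)` array, thresholded globally).
#' @param calibration Optional [calibration()] attached to the returned mask.
#' @param source_channel Channel label recorded on the mask.
#' @param n_bins Histogram bins (default 256).
#' @return A [binary_mask()] with attribute `threshold` (intensity units).
#' @export
otsu_dark_mask <- function(img, calibration = NULL, source_channel = NA_character_,
                           n_bins = 256L) {
  rng <- range(img)
  if (rng[1] == rng[2]) stop("cannot threshold a constant image")
  thr_bin <- otsu_threshold_bin(img, n_bins)
  binw <- (rng[2] - rng[1]) / n_bins
  bins <- pmin(floor((img - rng[1]) / binw), n_bins - 1L)
  vals <- bins > thr_bin
  dim(vals) <- dim(img)
  threshold <- rng[1] + (thr_bin + 1) * binw
  m <- binary_mask(vals, calibration %||% calibration(1),
                   source_channel = source_channel)
  attr(m, "threshold") <- threshold
  m
}

# Bin index k (0-based) such that bins <= k form the background class,
# chosen to maximize between-class variance.
otsu_threshold_bin <- function(img, n_bins = 256L) {
  rng <- range(img)
  binw <- (rng[2] - rng[1]) / n_bins
  bins <- pmin(floor((img - rng[1]) / binw), n_bins - 1L)
  h <- tabulate(as.integer(bins) + 1L, nbins = n_bins)
  p <- h / sum(h)
  centers <- (seq_len(n_bins) - 0.5)
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  k <- seq_len(n_bins - 1L)
  valid <- w0[k] > 0 & w0[k] < 1
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mu_t * w0[k][valid] - mu[k][valid])^2 /
    (w0[k][valid] * (1 - w0[k][valid]))
  which.max(bcv) - 1L  # 0-based bin index
}

#' Phansalkar local threshold
#'
#' Local adaptive threshold for low-contrast structures: after min-max
#' rescaling to \[0, 1\], a pixel is foreground iff
#' `value > m * (1 + p * exp(-q * m) + k * (s / r - 1))`, where `m` and `s`
#' are the mean and (population) standard deviation over the disc
#' neighbourhood of the given radius, and `(k, r, p, q) = (0.25, 0.5, 2, 10)`.
#' Border neighbourhoods are clipped to the image.
#'
#' @param img Numeric matrix.
#' @param radius Neighbourhood radius in pixels (>= 1).
#' @param k,r,p,q Formula constants.
#' @param calibration Optional [calibration()] attached to the mask.
#' @param source_channel Channel label recorded on the mask.
#' @return A [binary_mask()].
#' @export
phansalkar_mask <- function(img, radius, k = 0.25, r = 0.5, p = 2.0, q = 10.0,
                            calibration = NULL,
                            source_channel = NA_character_) {
  if (radius < 1) stop("radius must be >= 1")
  rng <- range(img)
  x <- if (rng[1] == rng[2]) matrix(0, nrow(img), ncol(img))
       else (img - rng[1]) / (rng[2] - rng[1])
  st <- local_window_stats(x, disc_offsets(radius))
  m <- st$sum / st$count
  s <- sqrt(pmax(st$sumsq / st$count - m^2, 0))
  thr <- m * (1 + p * exp(-q * m) + k * (s / r - 1))
  binary_mask(x > thr, calibration %||% calibration(1),
              source_channel = source_channel)
}
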