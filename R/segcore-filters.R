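#' Gaussian denoising
#'
#' Isotropic Gaussian blur of a single channel, the standard denoising step
#' applied before thresholding and spot detection. `sigma = 0` is the
#' identity. 3D input is filtered slice-wise in (y, x), matching the
#' per-section analysis the metrics perform.
#'
#' @param img Numeric matrix or `(y, x, z)` array.
#' @param sigma Gaussian standard deviation in pixels (>= 0).
#' @return Filtered image of the same shape.
#' @export
gaussian_denoise <- function(img, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0)
    stop("sigma must be a single non-negative number")
  if (sigma == 0) return(img)
  if (length(dim(img)) == 3) {
    out <- img
    for (z in seq_len(dim(img)[3])) out[, , z] <- EBImage::gblur(img[, , z], sigma)
    return(out)
  }
  EBImage::gblur(img, sigma)
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grayscale opening of the image with
#' a disc structuring element of the given radius, and subtracts it
#' (negative residuals clipped to 0). Structures narrower than the disc are
#' preserved; smooth gradients are removed. This is the morphological form
#' of the classic rolling-ball correction; the paraboloid variant is not
#' implemented because the result only preconditions a threshold.
#'
#' @param img Numeric matrix.
#' @param radius Structuring-element radius in pixels (>= 1).
#' @return Background-subtracted image, same shape, clipped at 0.
#' @export
rolling_ball_background <- function(img, radius) {
  if (radius < 1) stop("radius must be >= 1")
  if (radius >= max(dim(img))) {
    bg <- min(img)
  } else {
    bg <- max_filter_disc(min_filter_disc(img, radius), radius)
  }
  pmax(img - bg, 0)
}
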