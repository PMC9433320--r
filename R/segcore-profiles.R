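#' Averaged line profile
#'
#' Samples the image along the segment from `start` to `end` at a fixed
#' step (default 1 px), averaging `width_px` bilinear samples taken
#' perpendicular to the segment at 1 px spacing, symmetric about it.
#' Distances are reported in micrometres from `start`.
#'
#' @param img Numeric matrix.
#' @param start,end 0-based `(y, x)` pixel coordinates (numeric length 2).
#' @param width_px Number of perpendicular samples averaged (>= 1).
#' @param pixel_size_um Micrometres per pixel.
#' @param step_px Sampling step along the segment in pixels.
#' @return A `line_profile`: list with `distance_um`, `intensity`, and the
#'   sampling geometry.
#' @export
line_profile <- function(img, start, end, width_px = 1L, pixel_size_um = 1,
                         step_px = 1) {
  stopifnot(length(start) == 2, length(end) == 2, width_px >= 1)
  dvec <- c(end[1] - start[1], end[2] - start[2])
  len <- sqrt(sum(dvec^2))
  if (len == 0) stop("zero-length segment")
  u <- dvec / len
  nvec <- c(-u[2], u[1])
  s <- seq(0, len, by = step_px)
  offs <- seq_len(width_px) - (width_px + 1) / 2
  acc <- numeric(length(s))
  for (o in offs) {
    py <- start[1] + s * u[1] + o * nvec[1]
    px <- start[2] + s * u[2] + o * nvec[2]
    acc <- acc + bilinear_sample(img, py, px)
  }
  structure(list(distance_um = s * pixel_size_um,
                 intensity = acc / width_px,
                 start = start, end = end, width_px = width_px,
                 step_um = step_px * pixel_size_um,
                 pixel_size_um = pixel_size_um),
            class = "line_profile")
}

#' Radial intensity profile around a center
#'
#' Per integer-radius bin, the sum of intensities of pixels whose distance
#' from `center` rounds to that bin and whose direction lies within the
#' integration sector: angular distance to `orientation_deg` at most
#' `theta_deg / 2` (so `theta_deg = 180` integrates a half-plane and
#' `theta_deg = 360` the full circle). Orientation 0 deg points toward +x.
#'
#' @param img Numeric matrix.
#' @param center 0-based `(y, x)` center (inside the image).
#' @param theta_deg Full integration angle in degrees (default 360).
#' @param orientation_deg Sector orientation in degrees.
#' @param pixel_size_um Micrometres per pixel.
#' @return A `radial_profile`: list with `radius_um`, `intensity` (bin
#'   sums), `counts` and the sector geometry.
#' @export
radial_profile <- function(img, center, theta_deg = 360, orientation_deg = 0,
                           pixel_size_um = 1) {
  ny <- nrow(img); nx <- ncol(img)
  if (center[1] < 0 || center[1] > ny - 1 || center[2] < 0 || center[2] > nx - 1)
    stop("center must lie inside the image")
  g <- pixel_grid(ny, nx)
  dy <- g$y - center[1]; dx <- g$x - center[2]
  r <- sqrt(dy^2 + dx^2)
  bin <- round(r)
  ang <- atan2(dy, dx) * 180 / pi
  dang <- ((ang - orientation_deg + 180) %% 360) - 180
  sel <- abs(dang) <= theta_deg / 2
  nb <- max(bin) + 1L
  sums <- numeric(nb); counts <- numeric(nb)
  idx <- bin[sel] + 1L
  agg <- rowsum(as.numeric(img[sel]), idx)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  counts <- tabulate(idx, nbins = nb)
  structure(list(radius_um = (0:(nb - 1L)) * pixel_size_um,
                 intensity = sums, counts = counts,
                 center = center, theta_deg = theta_deg,
                 orientation_deg = orientation_deg,
                 pixel_size_um = pixel_size_um),
            class = "radial_profile")
}
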