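# Synthetic microscopy scenes. Every generator renders a continuous model
# onto the pixel grid, records all true parameters in a scene_truth, and
# only then applies the noise model, so each downstream metric can be
# validated by parameter recovery without real data.

#' Ground-truth record of a synthetic scene
#'
#' @param scene_id Identifier string.
#' @param geometry One of `"bipolar"`, `"monopolar"`, `"droplet_field"`,
#'   `"filament_field"`, `"frap_series"`, `"fret_pair"`,
#'   `"tomogram_fixture"`.
#' @param true_params Named list of every true parameter a test may assert.
#' @param seed The RNG seed used.
#' @param noise Named list of noise-model parameters.
#' @return An object of class `scene_truth`.
#' @export
scene_truth <- function(scene_id, geometry, true_params, seed, noise) {
  geometry <- match.arg(geometry,
    c("bipolar", "monopolar", "droplet_field", "filament_field",
      "frap_series", "fret_pair", "tomogram_fixture"))
  structure(list(scene_id = scene_id, geometry = geometry,
                 true_params = true_params, seed = seed, noise = noise),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("scene_truth %s (%s), seed %s\n", x$scene_id, x$geometry,
              format(x$seed)))
  utils::str(x$true_params, max.level = 1)
  invisible(x)
}

#' Write / read a scene truth as JSON
#' @param truth A [scene_truth()].
#' @param path JSON path.
#' @return `path` (write) or the restored `scene_truth` (read).
#' @export
write_scene_truth <- function(truth, path) {
  x <- unclass(truth)
  x$true_params$noiseless_channels <- NULL  # images live in the TIFF, not here
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_scene_truth
#' @export
read_scene_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scene_truth(x$scene_id, x$geometry, x$true_params, x$seed, x$noise)
}

#' Camera noise model
#'
#' Poisson shot noise applied to the noiseless expectation (interpreting
#' intensities as photon counts scaled by `photons_per_unit`), followed by
#' additive Gaussian read noise. Expectations are preserved: averaging many
#' realizations converges to the noiseless scene (up to the clip of rare
#' negative read-noise excursions at 0).
#'
#' @param img Noiseless non-negative image (matrix or array).
#' @param noise List with `poisson` (logical), `photons_per_unit`
#'   (counts per intensity unit) and `gaussian_sd` (intensity units).
#' @return Noisy image, clipped at 0.
#' @export
apply_camera_noise <- function(img, noise) {
  out <- img
  if (isTRUE(noise$poisson)) {
    ppu <- noise$photons_per_unit %||% 1
    out[] <- rpois(length(img), lambda = as.numeric(img) * ppu) / ppu
  }
  gs <- noise$gaussian_sd %||% 0
  if (gs > 0) out[] <- out + rnorm(length(img), sd = gs)
  pmax(out, 0)
}

default_noise <- function(noiseless_max, on = TRUE) {
  if (!on) return(list(poisson = FALSE, photons_per_unit = 1, gaussian_sd = 0))
  # Poisson shot noise at one photon per intensity unit plus read noise at
  # 2% of the dynamic range: the package's stated camera convention.
  list(poisson = TRUE, photons_per_unit = 1, gaussian_sd = 0.02 * noiseless_max)
}

# Render a union of hard discs (centers/radii in um) as an indicator image,
# then optionally blur by a PSF sigma (px). Returns the (y, x) matrix.
render_discs <- function(ny, nx, px_um, centers_um, radii_um, psf_sigma_px = 0) {
  img <- matrix(0, ny, nx)
  g <- pixel_grid(ny, nx)
  for (i in seq_along(radii_um)) {
    d2 <- (g$y * px_um - centers_um[i, 1])^2 + (g$x * px_um - centers_um[i, 2])^2
    img[d2 <= radii_um[i]^2] <- 1
  }
  if (psf_sigma_px > 0) img <- gaussian_denoise(img, psf_sigma_px)
  img
}

render_gaussian_spots <- function(ny, nx, spots_px, amplitudes, sigma_px) {
  img <- matrix(0, ny, nx)
  g <- pixel_grid(ny, nx)
  for (i in seq_len(nrow(spots_px))) {
    d2 <- (g$y - spots_px[i, 1])^2 + (g$x - spots_px[i, 2])^2
    img <- img + amplitudes[i] * exp(-d2 / (2 * sigma_px^2))
  }
  img
}

# Signed distance (um) of every pixel to the union-of-discs surface
# (negative inside), used for boundary shells.
disc_union_signed_distance <- function(ny, nx, px_um, centers_um, radii_um) {
  g <- pixel_grid(ny, nx)
  sd <- matrix(Inf, ny, nx)
  for (i in seq_along(radii_um)) {
    d <- sqrt((g$y * px_um - centers_um[i, 1])^2 +
              (g$x * px_um - centers_um[i, 2])^2) - radii_um[i]
    sd <- pmin(sd, d)
  }
  sd
}
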