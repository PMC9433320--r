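#' Physical calibration of an image stack
#'
#' Records the physical size of a pixel and, where applicable, the z-slice
#' spacing and frame interval. All distances in the package are computed as
#' index differences multiplied by these values.
#'
#' @param pixel_size_xy Lateral pixel size in micrometres per pixel.
#' @param z_step Axial step in micrometres per z-slice, or `NULL` for 2D data.
#' @param time_step Frame interval in seconds, or `NULL` for static data.
#' @return An object of class `calibration`.
#' @export
#' @examples
#' calibration(0.1)
#' calibration(0.1, z_step = 0.5, time_step = 0.025)
calibration <- function(pixel_size_xy, z_step = NULL, time_step = NULL) {
  vals <- c(pixel_size_xy = pixel_size_xy, z_step = z_step, time_step = time_step)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("calibration values must be strictly positive and finite")
  structure(list(pixel_size_xy = pixel_size_xy, z_step = z_step,
                 time_step = time_step),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration: %.6g um/px", x$pixel_size_xy))
  if (!is.null(x$z_step)) cat(sprintf(", z %.6g um", x$z_step))
  if (!is.null(x$time_step)) cat(sprintf(", dt %.6g s", x$time_step))
  cat("\n")
  invisible(x)
}

#' Multi-channel calibrated image stack
#'
#' The universal image container: a non-negative intensity array indexed
#' internally as (y, x, z, channel, time), with named channels and a
#' physical [calibration()]. 2D and static data simply have singleton z and
#' time axes.
#'
#' @param channels Either a named list of 2D matrices (or 3D `(y, x, z)`
#'   arrays), one per channel and a single time point, or a 5D array with
#'   dimensions `(y, x, z, channel, time)`.
#' @param calibration A [calibration()] object.
#' @param channel_names Channel labels; taken from `names(channels)` when
#'   `channels` is a list.
#' @return An object of class `calibrated_stack`.
#' @export
#' @examples
#' s <- calibrated_stack(list(dna = matrix(1, 8, 8)), calibration(0.1))
#' dim(s)
calibrated_stack <- function(channels, calibration, channel_names = NULL) {
  stopifnot(inherits(calibration, "calibration"))
  if (is.list(channels)) {
    channel_names <- channel_names %||% names(channels)
    if (is.null(channel_names))
      stop("channel names are required")
    arrs <- lapply(channels, function(ch) {
      if (is.matrix(ch)) array(ch, c(dim(ch), 1L)) else ch
    })
    d <- dim(arrs[[1]])
    if (length(d) != 3) stop("channels must be 2D matrices or (y, x, z) arrays")
    if (!all(vapply(arrs, function(a) identical(dim(a), d), logical(1))))
      stop("all channels must share the same spatial shape")
    data <- array(0, c(d, length(arrs), 1L))
    for (i in seq_along(arrs)) data[, , , i, 1] <- arrs[[i]]
  } else {
    data <- channels
    if (length(dim(data)) != 5)
      stop("array input must be 5D (y, x, z, channel, time)")
  }
  if (is.null(channel_names)) stop("channel names are required")
  channel_names <- as.character(channel_names)
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  if (length(channel_names) != dim(data)[4])
    stop(sprintf("channel count mismatch: %d channels in data, %d names",
                 dim(data)[4], length(channel_names)))
  if (!all(is.finite(data)) || any(data < 0))
    stop("intensities must be finite and non-negative")
  if (dim(data)[3] > 1 && is.null(calibration$z_step))
    stop("z_step calibration required for 3D data")
  structure(list(data = data, channel_names = channel_names,
                 calibration = calibration),
            class = "calibrated_stack")
}

#' @export
dim.calibrated_stack <- function(x) dim(x$data)

#' @export
print.calibrated_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("calibrated_stack: %d x %d px, %d z, %d channel(s) [%s], %d frame(s)\n",
              d[1], d[2], d[3], d[4], paste(x$channel_names, collapse = ", "), d[5]))
  print(x$calibration)
  invisible(x)
}

#' Extract one channel of a stack
#'
#' @param stack A [calibrated_stack()].
#' @param channel Channel name or index.
#' @param t Time index (default 1).
#' @param z Optional z index; when omitted, a 2D matrix is returned for
#'   single-slice data and a `(y, x, z)` array otherwise.
#' @return A matrix or 3D array of intensities.
#' @export
get_channel <- function(stack, channel, t = 1L, z = NULL) {
  stopifnot(inherits(stack, "calibrated_stack"))
  ci <- if (is.character(channel)) match(channel, stack$channel_names) else channel
  if (is.na(ci) || ci < 1 || ci > dim(stack$data)[4])
    stop(sprintf("unknown channel: %s", channel))
  if (!is.null(z)) return(stack$data[, , z, ci, t])
  a <- stack$data[, , , ci, t, drop = FALSE]
  if (dim(a)[3] == 1L) a[, , 1, 1, 1] else a[, , , 1, 1]
}

#' Number of frames in a stack
#' @param stack A [calibrated_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$data)[5]

#' Binary mask in image geometry
#'
#' A logical matrix (or `(y, x, z)` array) carrying the calibration and the
#' name of the channel it was derived from.
#'
#' @param values Logical matrix or array.
#' @param calibration A [calibration()].
#' @param source_channel Label of the originating channel.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, calibration, source_channel = NA_character_) {
  stopifnot(inherits(calibration, "calibration"))
  storage.mode(values) <- "logical"
  structure(list(values = values, calibration = calibration,
                 source_channel = source_channel),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %s px, %d foreground (source: %s)\n",
              paste(dim(x$values), collapse = " x "), sum(x$values),
              x$source_channel))
  invisible(x)
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "binary_mask")) mask$values else mask != 0
}

#' One row of the metrics table
#'
#' @param scene_id Identifier of the analysed scene or image.
#' @param metric_name Name of the metric.
#' @param value Finite numeric value.
#' @param units Unit string ("" for dimensionless).
#' @param parameters Named list of the parameters used (serialized to JSON
#'   in the CSV output).
#' @param normalization_reference Label of the reference group/value the
#'   metric was normalized to, or `NA`.
#' @return A one-row data.frame with the fixed metrics columns.
#' @export
metrics_record <- function(scene_id, metric_name, value, units = "",
                           parameters = list(),
                           normalization_reference = NA_character_) {
  if (!is.finite(value)) stop("metric value must be finite")
  data.frame(scene_id = as.character(scene_id),
             metric_name = as.character(metric_name),
             value = as.numeric(value),
             units = as.character(units),
             parameters = as.character(
               jsonlite::toJSON(parameters, auto_unbox = TRUE, digits = NA)),
             normalization_reference = as.character(normalization_reference),
             stringsAsFactors = FALSE)
}
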