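# TIFF + sidecar I/O. Images travel as multi-page TIFF with pages ordered
# (time, channel, z); a JSON sidecar ("<path>.json") carries channel names,
# calibration, axis lengths and the intensity scale so that arbitrary
# intensity ranges round-trip. Integer data are stored losslessly at 16
# bits when they fit, otherwise 32-bit float (~1e-7 relative).

sidecar_path <- function(path) paste0(path, ".json")

#' Write a calibrated stack as multi-page TIFF
#'
#' Pages are ordered (time, channel, z). Metadata (channel names,
#' calibration, dimensions, intensity scaling) is written to a JSON sidecar
#' next to the TIFF so [read_stack()] can restore the stack exactly.
#'
#' @param stack A [calibrated_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "calibrated_stack"))
  d <- dim(stack$data)
  mx <- max(stack$data)
  integer_data <- all(stack$data == round(stack$data))
  use16 <- integer_data && mx <= 65535
  scale <- if (use16) 65535 else max(mx, .Machine$double.eps)
  pages <- list()
  for (t in seq_len(d[5])) for (ci in seq_len(d[4])) for (z in seq_len(d[3]))
    pages[[length(pages) + 1L]] <- stack$data[, , z, ci, t] / scale
  tiff::writeTIFF(pages, path, bits.per.sample = if (use16) 16L else 32L)
  meta <- list(channel_names = stack$channel_names,
               ny = d[1], nx = d[2], nz = d[3], nt = d[5],
               scale = scale, integer_data = integer_data,
               pixel_size_xy = stack$calibration$pixel_size_xy,
               z_step = stack$calibration$z_step,
               time_step = stack$calibration$time_step)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a calibrated stack from TIFF
#'
#' With a JSON sidecar (as written by [write_stack()]) the full geometry,
#' channel names and calibration are restored. Without one, pages are
#' interpreted as channels of a single 2D time point and `channel_names`
#' plus `calibration` must be supplied.
#'
#' @param path TIFF path.
#' @param channel_names Channel labels (override / required without sidecar).
#' @param calibration Optional [calibration()] override.
#' @return A [calibrated_stack()].
#' @export
read_stack <- function(path, channel_names = NULL, calibration = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    cal <- calibration %||% calibration(meta$pixel_size_xy,
                                        z_step = meta$z_step,
                                        time_step = meta$time_step)
    chn <- channel_names %||% meta$channel_names
    if (length(chn) != length(meta$channel_names))
      stop(sprintf("channel count mismatch: file has %d channels, %d names given",
                   length(meta$channel_names), length(chn)))
    data <- array(0, c(meta$ny, meta$nx, meta$nz, length(chn), meta$nt))
    i <- 1L
    for (t in seq_len(meta$nt)) for (ci in seq_along(chn)) for (z in seq_len(meta$nz)) {
      pg <- pages[[i]] * meta$scale
      if (isTRUE(meta$integer_data)) pg <- round(pg)
      data[, , z, ci, t] <- pg
      i <- i + 1L
    }
    return(calibrated_stack(data, cal, channel_names = chn))
  }
  if (is.null(channel_names))
    stop("channel_names required when no metadata sidecar is present")
  if (length(pages) != length(channel_names))
    stop(sprintf("channel count mismatch: %d pages, %d names",
                 length(pages), length(channel_names)))
  if (is.null(calibration)) stop("calibration required without sidecar")
  chans <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  names(chans) <- channel_names
  calibrated_stack(chans, calibration)
}

#' Write metrics records to CSV
#'
#' One row per record; column order is fixed (`scene_id`, `metric_name`,
#' `value`, `units`, `parameters`, `normalization_reference`) and values
#' round-trip at full double precision.
#'
#' @param records A data.frame of rows built with [metrics_record()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(records, path) {
  cols <- c("scene_id", "metric_name", "value", "units", "parameters",
            "normalization_reference")
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("records must be a non-empty data.frame")
  if (!all(cols %in% names(records)))
    stop("records must contain the fixed metrics columns")
  out <- records[, cols]
  out$value <- sprintf("%.17g", out$value)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a metrics CSV written by [write_metrics()]
#' @param path CSV path.
#' @return A data.frame with the fixed metrics columns.
#' @export
read_metrics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$value <- as.numeric(df$value)
  df
}
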