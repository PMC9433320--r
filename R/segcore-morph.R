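px_of <- function(mask) {
  if (inherits(mask, "binary_mask")) mask$calibration$pixel_size_xy else 1
}

#' Erode or dilate a mask by a physical distance
#'
#' Offsets the mask boundary by a signed Euclidean distance in micrometres:
#' negative offsets erode (pixels closer than `|offset|` to the background
#' are dropped), positive offsets dilate (background pixels within `offset`
#' of the mask are added). Implemented by thresholding the exact Euclidean
#' distance transform.
#'
#' @param mask A [binary_mask()] (2D).
#' @param offset_um Signed offset in micrometres.
#' @return A [binary_mask()]; attribute `empty` is `TRUE` when an erosion
#'   removed every pixel (the caller decides how to proceed).
#' @export
morph_offset <- function(mask, offset_um) {
  m <- as_mask_matrix(mask)
  if (length(dim(m)) != 2) stop("morph_offset operates on 2D masks")
  px <- abs(offset_um) / px_of(mask)
  if (offset_um == 0) {
    out <- m
  } else if (offset_um < 0) {
    if (!any(m)) {
      out <- m
    } else {
      d <- EBImage::distmap(m * 1)
      out <- m & d > px
    }
  } else {
    if (all(m)) {
      out <- m
    } else {
      d <- EBImage::distmap((1 - m) * 1)
      out <- m | (!m & d <= px)
    }
  }
  res <- binary_mask(out, mask$calibration, mask$source_channel)
  attr(res, "empty") <- offset_um < 0 && any(m) && !any(out)
  res
}

#' Ring region around a mask
#'
#' The cytoplasmic-reference ring: extend the mask outward by `extend_um`
#' and keep only the outermost `width_um` of the extension, i.e.
#' `dilate(mask, extend) \ dilate(mask, extend - width)`.
#'
#' @param mask A [binary_mask()].
#' @param extend_um Outward extension in micrometres.
#' @param width_um Ring width in micrometres (`extend_um >= width_um > 0`).
#' @return A [binary_mask()] of the ring; warns when the ring is clipped by
#'   the image border.
#' @export
ring_roi <- function(mask, extend_um, width_um) {
  if (!(extend_um >= width_um && width_um > 0))
    stop("require extend_um >= width_um > 0")
  outer <- morph_offset(mask, extend_um)
  inner <- morph_offset(mask, extend_um - width_um)
  ring <- outer$values & !inner$values
  if (any(ring[c(1, nrow(ring)), ]) || any(ring[, c(1, ncol(ring))]))
    warning("ring reaches the image border and is clipped")
  binary_mask(ring, mask$calibration, mask$source_channel)
}

#' Region set from a mask
#'
#' Labels the 8-connected components of a 2D mask and keeps those at least
#' `min_size` large. Size may be counted in pixels ("px2", the default,
#' matching the unitless particle-size convention) or square micrometres.
#' Surviving regions are relabelled 1..n in first-pixel order.
#'
#' @param mask A [binary_mask()] (2D).
#' @param min_size Minimum region size (>= 0) in `size_units`.
#' @param size_units `"px2"` or `"um2"`.
#' @return A `region_set`: list with integer `labels` matrix, a `table`
#'   data.frame (`id`, `size_px`, `size_um2`), and the calibration.
#' @export
regions_from_mask <- function(mask, min_size = 0, size_units = c("px2", "um2")) {
  size_units <- match.arg(size_units)
  m <- as_mask_matrix(mask)
  lab <- label_components8(m)
  px <- px_of(mask)
  ids <- seq_len(max(lab, 0L))
  sizes_px <- tabulate(lab[lab > 0], nbins = length(ids))
  sizes <- if (size_units == "px2") sizes_px else sizes_px * px^2
  keep <- ids[sizes >= min_size]
  relab <- integer(length(ids))
  relab[keep] <- seq_along(keep)
  lab[lab > 0] <- relab[lab[lab > 0]]
  structure(list(
    labels = lab,
    table = data.frame(id = seq_along(keep),
                       size_px = sizes_px[keep],
                       size_um2 = sizes_px[keep] * px^2),
    calibration = if (inherits(mask, "binary_mask")) mask$calibration else calibration(1)
  ), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %d region(s)\n", nrow(x$table)))
  invisible(x)
}

#' Skeletonize a mask and measure total skeleton length
#'
#' Zhang-Suen topology-preserving thinning to one-pixel-wide curves,
#' followed by length measurement: the sum over 8-adjacent skeleton pixel
#' pairs of the step length (1 for axis-aligned, sqrt(2) for diagonal
#' steps), scaled to micrometres.
#'
#' @param mask A [binary_mask()] (2D).
#' @return List with `skeleton` (a [binary_mask()]) and `length_um`.
#' @export
skeletonize_length <- function(mask) {
  m <- as_mask_matrix(mask)
  if (length(dim(m)) != 2) stop("skeletonize_length operates on 2D masks")
  sk <- zhang_suen_thin(m)
  list(skeleton = binary_mask(sk, if (inherits(mask, "binary_mask"))
                                    mask$calibration else calibration(1),
                              if (inherits(mask, "binary_mask"))
                                mask$source_channel else NA_character_),
       length_um = skeleton_length_um(sk, px_of(mask)))
}

skeleton_length_um <- function(sk, px) {
  ny <- nrow(sk); nx <- ncol(sk)
  if (!any(sk)) return(0)
  h <- sum(sk[, -nx] & sk[, -1])
  v <- sum(sk[-ny, ] & sk[-1, ])
  d1 <- sum(sk[-ny, -nx] & sk[-1, -1])
  d2 <- sum(sk[-1, -nx] & sk[-ny, -1])
  (h + v + sqrt(2) * (d1 + d2)) * px
}

zhang_suen_thin <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  p <- matrix(FALSE, ny + 2, nx + 2)
  p[2:(ny + 1), 2:(nx + 1)] <- m
  shift <- function(mat, dy, dx)
    mat[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx)]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      n2 <- shift(p, -1, 0); n3 <- shift(p, -1, 1); n4 <- shift(p, 0, 1)
      n5 <- shift(p, 1, 1);  n6 <- shift(p, 1, 0);  n7 <- shift(p, 1, -1)
      n8 <- shift(p, 0, -1); n9 <- shift(p, -1, -1)
      B <- n2 + n3 + n4 + n5 + n6 + n7 + n8 + n9
      A <- (!n2 & n3) + (!n3 & n4) + (!n4 & n5) + (!n5 & n6) +
           (!n6 & n7) + (!n7 & n8) + (!n8 & n9) + (!n9 & n2)
      core <- p[2:(ny + 1), 2:(nx + 1)] & B >= 2 & B <= 6 & A == 1
      del <- if (step == 1)
        core & !(n2 & n4 & n6) & !(n4 & n6 & n8)
      else
        core & !(n2 & n4 & n8) & !(n2 & n6 & n8)
      if (any(del)) {
        q <- p[2:(ny + 1), 2:(nx + 1)]
        q[del] <- FALSE
        p[2:(ny + 1), 2:(nx + 1)] <- q
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p[2:(ny + 1), 2:(nx + 1)]
}

#' Signed distance from points to the mask surface
#'
#' For each point, the Euclidean distance (micrometres) to the nearest
#' boundary pixel of the mask, negative when the point lies inside the
#' mask. Boundary pixels are foreground pixels with a 4-neighbour (2D) or
#' 6-neighbour (3D) in the background. Anisotropic z is handled by scaling
#' coordinates with the calibration before measuring.
#'
#' @param points data.frame with 0-based pixel coordinates `y`, `x` and
#'   optionally `z` (fractional allowed), e.g. a `spot_set`.
#' @param mask A [binary_mask()] (2D matrix or 3D `(y, x, z)` array).
#' @return Numeric vector of signed distances in micrometres.
#' @export
distance_to_mask_surface <- function(points, mask) {
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("mask is empty")
  cal <- if (inherits(mask, "binary_mask")) mask$calibration else calibration(1)
  px <- cal$pixel_size_xy
  nd <- length(dim(m))
  if (nd == 2) {
    ny <- nrow(m); nx <- ncol(m)
    pad <- matrix(FALSE, ny + 2, nx + 2); pad[2:(ny + 1), 2:(nx + 1)] <- m
    nb_bg <- !(pad[1:ny, 2:(nx + 1)] & pad[3:(ny + 2), 2:(nx + 1)] &
               pad[2:(ny + 1), 1:nx] & pad[2:(ny + 1), 3:(nx + 2)])
    boundary <- which(m & nb_bg, arr.ind = TRUE)
    by <- (boundary[, 1] - 1) * px; bx <- (boundary[, 2] - 1) * px
    vapply(seq_len(nrow(points)), function(i) {
      py <- points$y[i] * px; pxx <- points$x[i] * px
      d <- sqrt(min((by - py)^2 + (bx - pxx)^2))
      iy <- min(max(round(points$y[i]) + 1, 1), ny)
      ix <- min(max(round(points$x[i]) + 1, 1), nx)
      if (m[iy, ix]) -d else d
    }, numeric(1))
  } else {
    zs <- cal$z_step %||% stop("z_step calibration required for 3D masks")
    d <- dim(m)
    padd <- array(FALSE, d + 2)
    padd[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
    inner <- padd[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] &
      padd[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
      padd[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
      padd[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
      padd[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
      padd[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
      padd[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
    boundary <- which(m & !inner, arr.ind = TRUE)
    by <- (boundary[, 1] - 1) * px; bx <- (boundary[, 2] - 1) * px
    bz <- (boundary[, 3] - 1) * zs
    vapply(seq_len(nrow(points)), function(i) {
      py <- points$y[i] * px; pxx <- points$x[i] * px; pz <- points$z[i] * zs
      dd <- sqrt(min((by - py)^2 + (bx - pxx)^2 + (bz - pz)^2))
      iy <- min(max(round(points$y[i]) + 1, 1), d[1])
      ix <- min(max(round(points$x[i]) + 1, 1), d[2])
      iz <- min(max(round(points$z[i]) + 1, 1), d[3])
      if (m[iy, ix, iz]) -dd else dd
    }, numeric(1))
  }
}
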