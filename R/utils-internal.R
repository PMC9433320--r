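# Internal numeric helpers shared across modules. Coordinate convention
# throughout the package: 0-based (y, x) pixel indices, pixel centers at
# integer coordinates, physical distance = index difference * pixel size.


# Offsets (dy, dx) of the disc neighbourhood of a given pixel radius,
# inclusive boundary (dy^2 + dx^2 <= r^2).
disc_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g <- g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

# Clipped local sums over an arbitrary offset neighbourhood: for every pixel,
# sum / sum-of-squares / count over in-bounds neighbours. Exact (no padding
# convention): border neighbourhoods are the intersection with the image.
local_window_stats <- function(img, offsets) {
  ny <- nrow(img); nx <- ncol(img)
  s <- matrix(0, ny, nx); s2 <- matrix(0, ny, nx); n <- matrix(0, ny, nx)
  img2 <- img * img
  for (k in seq_len(nrow(offsets))) {
    dy <- offsets[k, 1]; dx <- offsets[k, 2]
    ys <- max(1, 1 - dy):min(ny, ny - dy)  # target rows
    xs <- max(1, 1 - dx):min(nx, nx - dx)
    s[ys, xs] <- s[ys, xs] + img[ys + dy, xs + dx]
    s2[ys, xs] <- s2[ys, xs] + img2[ys + dy, xs + dx]
    n[ys, xs] <- n[ys, xs] + 1
  }
  list(sum = s, sumsq = s2, count = n)
}

# Grayscale erosion (min filter) / dilation (max filter) over a disc
# neighbourhood, border handled by clipping to the image (so a constant
# image is a fixed point). Works on arbitrary intensity ranges.
min_filter_disc <- function(img, radius) .extremum_filter(img, radius, min = TRUE)
max_filter_disc <- function(img, radius) .extremum_filter(img, radius, min = FALSE)

.extremum_filter <- function(img, radius, min = TRUE) {
  off <- disc_offsets(radius)
  ny <- nrow(img); nx <- ncol(img)
  out <- matrix(if (min) Inf else -Inf, ny, nx)
  for (k in seq_len(nrow(off))) {
    dy <- off[k, 1]; dx <- off[k, 2]
    ys <- max(1, 1 - dy):min(ny, ny - dy)
    xs <- max(1, 1 - dx):min(nx, nx - dx)
    blk <- img[ys + dy, xs + dx, drop = FALSE]
    out[ys, xs] <- if (min) pmin(out[ys, xs], blk) else pmax(out[ys, xs], blk)
  }
  out
}

# 8-connected labeling of a logical matrix by iterative label minimisation.
# Returns an integer matrix with labels 1..n contiguous in first-pixel
# (column-major) order, 0 = background.
label_components8 <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0, ny, nx)
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(matrix(0L, ny, nx))
  shifts <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                  c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  repeat {
    old <- lab
    for (k in seq_len(nrow(shifts))) {
      dy <- shifts[k, 1]; dx <- shifts[k, 2]
      ys <- max(1, 1 - dy):min(ny, ny - dy)
      xs <- max(1, 1 - dx):min(nx, nx - dx)
      nb <- lab[ys + dy, xs + dx, drop = FALSE]
      cur <- lab[ys, xs, drop = FALSE]
      upd <- nb > 0 & cur > 0 & nb < cur
      if (any(upd)) {
        cur[upd] <- nb[upd]
        lab[ys, xs] <- cur
      }
    }
    # propagate label equivalences through the representative map
    reps <- lab[mask]
    map <- seq_len(max(reps))
    repeat {
      m2 <- map[map]
      if (identical(m2, map)) break
      map <- m2
    }
    lab[mask] <- map[reps]
    if (identical(lab, old)) break
  }
  ids <- sort(unique(lab[lab > 0]))
  relabel <- integer(max(ids)); relabel[ids] <- seq_along(ids)
  lab[lab > 0] <- relabel[lab[lab > 0]]
  storage.mode(lab) <- "integer"
  lab
}

# Bilinear interpolation of img at fractional 0-based (y, x) positions.
# Positions outside the image are clamped to the border.
bilinear_sample <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  y <- pmin(pmax(y, 0), ny - 1)
  x <- pmin(pmax(x, 0), nx - 1)
  y0 <- floor(y); x0 <- floor(x)
  y1 <- pmin(y0 + 1, ny - 1); x1 <- pmin(x0 + 1, nx - 1)
  fy <- y - y0; fx <- x - x0
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i01 <- img[cbind(y0 + 1, x1 + 1)]
  i10 <- img[cbind(y1 + 1, x0 + 1)]
  i11 <- img[cbind(y1 + 1, x1 + 1)]
  i00 * (1 - fy) * (1 - fx) + i01 * (1 - fy) * fx +
    i10 * fy * (1 - fx) + i11 * fy * fx
}

# Grid of 0-based pixel center coordinates for an ny x nx image.
pixel_grid <- function(ny, nx) {
  list(y = matrix(0:(ny - 1), ny, nx),
       x = matrix(0:(nx - 1), ny, nx, byrow = TRUE))
}

# Evaluate an expression with a temporarily seeded RNG, restoring the
# caller's random state afterwards. All generators route through this so
# that no global state leaks.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
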