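#' Local maxima by topographic prominence
#'
#' Detects intensity peaks whose prominence -- the height of the peak above
#' the highest saddle connecting it to any higher region -- is at least the
#' given threshold. This is the spot-detection criterion used for
#' kinetochores and DNA-damage foci. Equal-valued plateau maxima are
#' reported once, at the plateau centroid. The global maximum has no higher
#' region and is always reported (prominence `Inf`). When two maxima of
#' exactly equal height merge, the one whose plateau starts earlier in
#' raster order survives.
#'
#' @param img Numeric matrix.
#' @param prominence Minimum prominence, in intensity units (> 0).
#' @param exclude_edges Drop maxima whose plateau touches the image border.
#' @return A `spot_set`: data.frame with 0-based fractional `y`, `x`
#'   (plateau centroid), `intensity` (peak height) and `prominence`;
#'   attribute `prominence_threshold` records the cutoff.
#' @export
find_maxima <- function(img, prominence, exclude_edges = TRUE) {
  if (!is.numeric(prominence) || prominence <= 0)
    stop("prominence must be > 0")
  ny <- nrow(img); nx <- ncol(img)
  n <- ny * nx
  v <- as.numeric(img)
  # raster order = row-major (y, then x); column-major index -> raster rank
  ys <- ((seq_len(n) - 1L) %% ny)
  xs <- ((seq_len(n) - 1L) %/% ny)
  raster <- ys * nx + xs
  ord <- order(-v, raster)

  parent <- seq_len(n)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  peak_val <- v          # per-root peak height
  peak_rank <- raster    # raster rank of the founding plateau's first pixel
  max_id <- integer(n)   # per-root id of the founding maximum (0 = none yet)
  active <- logical(n)

  # per-maximum records (grown as maxima are founded)
  m_prom <- numeric(0); m_pix <- list(); m_height <- numeric(0)

  neighbours <- function(i) {
    y <- ys[i]; x <- xs[i]
    dy <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dx <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    yy <- y + dy; xx <- x + dx
    ok <- yy >= 0L & yy < ny & xx >= 0L & xx < nx
    (xx[ok]) * ny + yy[ok] + 1L
  }

  i0 <- 1L
  while (i0 <= n) {
    val <- v[ord[i0]]
    i1 <- i0
    while (i1 < n && v[ord[i1 + 1L]] == val) i1 <- i1 + 1L
    group <- ord[i0:i1]
    active[group] <- TRUE
    for (pix in group) {
      for (nb in neighbours(pix)) {
        if (!active[nb]) next
        r1 <- find_root(pix); r2 <- find_root(nb)
        if (r1 == r2) next
        # survivor: higher peak; ties -> earlier raster founding pixel
        if (peak_val[r1] > peak_val[r2] ||
            (peak_val[r1] == peak_val[r2] && peak_rank[r1] < peak_rank[r2])) {
          win <- r1; lose <- r2
        } else {
          win <- r2; lose <- r1
        }
        if (max_id[lose] > 0L)  # losing maximum dies at saddle level = val
          m_prom[max_id[lose]] <- peak_val[lose] - val
        parent[lose] <- win
      }
    }
    # any component whose root still peaks at this value was founded now:
    # it is a maximum plateau
    roots <- unique(vapply(group, find_root, integer(1)))
    for (r in roots) {
      if (peak_val[r] == val && max_id[r] == 0L) {
        id <- length(m_prom) + 1L
        m_prom[id] <- NA_real_   # still alive
        plateau <- group[vapply(group, find_root, integer(1)) == r]
        m_pix[[id]] <- plateau
        m_height[id] <- val
        max_id[r] <- id
        # founding raster rank = earliest plateau pixel
        peak_rank[r] <- min(raster[plateau])
      }
    }
    i0 <- i1 + 1L
  }
  if (length(m_prom)) m_prom[is.na(m_prom)] <- Inf

  keep <- which(m_prom >= prominence)
  if (exclude_edges && length(keep)) {
    on_edge <- vapply(keep, function(id) {
      p <- m_pix[[id]]
      any(ys[p] == 0L | ys[p] == ny - 1L | xs[p] == 0L | xs[p] == nx - 1L)
    }, logical(1))
    keep <- keep[!on_edge]
  }
  spots <- data.frame(
    y = vapply(keep, function(id) mean(ys[m_pix[[id]]]), numeric(1)),
    x = vapply(keep, function(id) mean(xs[m_pix[[id]]]), numeric(1)),
    intensity = m_height[keep],
    prominence = m_prom[keep]
  )
  spots <- spots[order(spots$y, spots$x), , drop = FALSE]
  rownames(spots) <- NULL
  structure(spots, prominence_threshold = prominence, class = c("spot_set", "data.frame"))
}
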