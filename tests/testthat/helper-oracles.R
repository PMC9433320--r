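# Independent brute-force oracles used to validate the segmentation
# primitives and statistics. Deliberately naive implementations, separate
# from the package's code paths.

# Otsu: exhaustive between-class-variance search over all histogram splits,
# computed directly from per-class bin weights.
oracle_otsu_bin <- function(img, n_bins = 256L) {
  rng <- range(img)
  binw <- (rng[2] - rng[1]) / n_bins
  bins <- pmin(floor((img - rng[1]) / binw), n_bins - 1L)
  h <- tabulate(as.integer(bins) + 1L, nbins = n_bins)
  centers <- seq_len(n_bins) - 0.5
  best <- -Inf; best_k <- 0L
  for (k in 0:(n_bins - 2L)) {
    w0 <- sum(h[seq_len(k + 1L)]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[seq_len(k + 1L)] * centers[seq_len(k + 1L)]) / w0
    mu1 <- sum(h[(k + 2L):n_bins] * centers[(k + 2L):n_bins]) / w1
    bcv <- (w0 / sum(h)) * (w1 / sum(h)) * (mu0 - mu1)^2
    if (bcv > best + 1e-12) { best <- bcv; best_k <- k }
  }
  best_k
}

# Phansalkar: direct per-pixel evaluation of the local formula over the
# clipped disc neighbourhood.
oracle_phansalkar <- function(img, radius, k = 0.25, r = 0.5, p = 2, q = 10) {
  rng <- range(img)
  x <- (img - rng[1]) / (rng[2] - rng[1])
  ny <- nrow(x); nx <- ncol(x)
  out <- matrix(FALSE, ny, nx)
  ir <- floor(radius)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    vals <- c()
    for (di in -ir:ir) for (dj in -ir:ir) {
      if (di^2 + dj^2 > radius^2) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= ny && jj >= 1 && jj <= nx)
        vals <- c(vals, x[ii, jj])
    }
    m <- mean(vals)
    s <- sqrt(mean(vals^2) - m^2)
    out[i, j] <- x[i, j] > m * (1 + p * exp(-q * m) + k * (s / r - 1))
  }
  out
}

# Prominence: for each strict local maximum, grow a region greedily by
# always absorbing the highest-valued frontier pixel; when a pixel higher
# than the maximum is reached, the saddle is the lowest value absorbed so
# far (widest-path formulation). Requires all-distinct pixel values.
oracle_prominence <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  nb <- function(i, j) {
    d <- expand.grid(di = -1:1, dj = -1:1)
    d <- d[!(d$di == 0 & d$dj == 0), ]
    ii <- i + d$di; jj <- j + d$dj
    ok <- ii >= 1 & ii <= ny & jj >= 1 & jj <= nx
    cbind(ii[ok], jj[ok])
  }
  is_max <- matrix(FALSE, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx))
    is_max[i, j] <- all(img[nb(i, j)] < img[i, j])
  res <- data.frame(y = integer(0), x = integer(0), height = numeric(0),
                    prominence = numeric(0))
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    if (!is_max[i, j]) next
    h <- img[i, j]
    if (h == max(img)) {
      res[nrow(res) + 1L, ] <- list(i - 1L, j - 1L, h, Inf)
      next
    }
    in_region <- matrix(FALSE, ny, nx); in_region[i, j] <- TRUE
    frontier <- nb(i, j)
    lowest <- h
    repeat {
      fv <- img[frontier]
      kbest <- which.max(fv)
      pix <- frontier[kbest, , drop = FALSE]
      frontier <- frontier[-kbest, , drop = FALSE]
      if (in_region[pix]) next
      if (img[pix] > h) break
      in_region[pix] <- TRUE
      lowest <- min(lowest, img[pix])
      nn <- nb(pix[1], pix[2])
      nn <- nn[!in_region[nn], , drop = FALSE]
      frontier <- rbind(frontier, nn)
    }
    res[nrow(res) + 1L, ] <- list(i - 1L, j - 1L, h, h - lowest)
  }
  res[order(res$y, res$x), ]
}

# BFS flood-fill labeling (8-connected), queue-based.
oracle_label8 <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  cur <- 0L
  for (j in seq_len(nx)) for (i in seq_len(ny)) {
    if (!mask[i, j] || lab[i, j] > 0) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii < 1 || ii > ny || jj < 1 || jj > nx) next
        if (mask[ii, jj] && lab[ii, jj] == 0) {
          lab[ii, jj] <- cur
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of group
# assignments (small n, assumes no ties across groups).
oracle_mw_exact_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  U_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- U_of(a, b)
  mu <- na * nb / 2
  combs <- utils::combn(na + nb, na)
  us <- apply(combs, 2, function(idx) U_of(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Dense-sampling polyline clipping oracle at ~1 nm pitch.
oracle_polyline_lengths <- function(polylines, mask, voxel_um, z_window,
                                    pitch_um = 0.001) {
  d <- dim(mask)
  zlo <- (z_window[1] - 1) * voxel_um[3]; zhi <- z_window[2] * voxel_um[3]
  len_in <- 0; len_out <- 0
  for (pl in polylines) for (s in seq_len(nrow(pl) - 1L)) {
    a <- pl[s, ]; b <- pl[s + 1L, ]
    L <- sqrt(sum((b - a)^2))
    if (L == 0) next
    np <- max(2L, ceiling(L / pitch_um))
    ts <- (seq_len(np) - 0.5) / np
    py <- a[1] + ts * (b[1] - a[1]); px <- a[2] + ts * (b[2] - a[2])
    pz <- a[3] + ts * (b[3] - a[3])
    inwin <- pz >= zlo & pz < zhi
    iy <- pmin(pmax(floor(py / voxel_um[1]), 0), d[1] - 1) + 1
    ix <- pmin(pmax(floor(px / voxel_um[2]), 0), d[2] - 1) + 1
    iz <- pmin(pmax(floor(pz / voxel_um[3]), 0), d[3] - 1) + 1
    inside <- mask[cbind(iy, ix, iz)] & inwin
    len_in <- len_in + sum(inside) * L / np
    len_out <- len_out + sum(!inside & inwin) * L / np
  }
  c(chromatin = len_in, cytoplasm = len_out)
}

# Smooth random field with all-distinct values (for the prominence oracle).
smooth_random_field <- function(ny, nx, sigma = 2, seed = 1) {
  set.seed(seed)
  f <- mitoquant::gaussian_denoise(matrix(stats::runif(ny * nx), ny, nx), sigma)
  f * 1000 + matrix(seq_len(ny * nx) * 1e-7, ny, nx)  # break exact ties
}

disc_mask <- function(ny, nx, cy, cx, r_px) {
  g <- expand.grid(y = 0:(ny - 1), x = 0:(nx - 1))
  m <- matrix((g$y - cy)^2 + (g$x - cx)^2 <= r_px^2, ny, nx)
  m
}
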