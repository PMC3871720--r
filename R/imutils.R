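# Internal image primitives shared by segmentation and the generator.
# Matrices are [row = y + 1, col = x + 1]; coordinates 0-based.

# Separable Gaussian smoothing with replicate boundaries, computed by
# clamped-index shifts (FFT-free: cost is independent of how awkwardly the
# image dimensions factorize).
.smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- as.integer(ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  .convCols(.convRows(x, w), w)
}

.convRows <- function(x, w) {
  r <- (length(w) - 1L) %/% 2L
  n <- nrow(x)
  out <- w[r + 1L] * x
  for (k in seq_len(r)) {
    up <- pmax(seq_len(n) - k, 1L)
    dn <- pmin(seq_len(n) + k, n)
    out <- out + w[r + 1L - k] * x[up, , drop = FALSE] +
      w[r + 1L + k] * x[dn, , drop = FALSE]
  }
  out
}

.convCols <- function(x, w) {
  r <- (length(w) - 1L) %/% 2L
  n <- ncol(x)
  out <- w[r + 1L] * x
  for (k in seq_len(r)) {
    lf <- pmax(seq_len(n) - k, 1L)
    rt <- pmin(seq_len(n) + k, n)
    out <- out + w[r + 1L - k] * x[, lf, drop = FALSE] +
      w[r + 1L + k] * x[, rt, drop = FALSE]
  }
  out
}

# Otsu threshold on an arbitrary-scale plane; NA for constant planes.
.otsuThreshold <- function(x, levels = 256L) {
  rng <- range(x)
  if (!is.finite(diff(rng)) || diff(rng) == 0) return(NA_real_)
  th01 <- EBImage::otsu(EBImage::Image((x - rng[1]) / diff(rng)),
                        range = c(0, 1), levels = levels)
  rng[1] + th01 * diff(rng)
}

# Sobel gradient magnitude via the separable decomposition
# ([1 2 1] smoothing x [-1 0 1] difference), replicate boundaries.
.gradientMagnitude <- function(x) {
  gx <- .convRows(.convCols(x, c(-1, 0, 1)), c(1, 2, 1))
  gy <- .convCols(.convRows(x, c(-1, 0, 1)), c(1, 2, 1))
  sqrt(gx^2 + gy^2)
}

# 8-connected labeling. EBImage::bwlabel is 4-connected; merge labels that
# touch diagonally with a union-find pass.
.label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # down-right diagonal
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]   # down-left diagonal
  s1 <- a1 > 0 & b1 > 0 & a1 != b1
  s2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[s1], b1[s1]), cbind(a2[s2], b2[s2])))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  nz <- lab > 0
  out[nz] <- dense[lab[nz]]
  out
}

# Drop labels below min_area and renumber densely in raster-scan order of
# the surviving labels. Returns list(labels, area) with area indexed by the
# new dense ids.
.filterLabelsByArea <- function(lab, min_area) {
  n <- max(lab)
  if (n == 0L) return(list(labels = lab, area = integer(0)))
  area <- tabulate(lab[lab > 0], nbins = n)
  keep <- which(area >= min_area)
  map <- integer(n)
  map[keep] <- seq_along(keep)
  out <- lab
  nz <- lab > 0
  out[nz] <- map[lab[nz]]
  list(labels = out, area = area[keep])
}

# Per-label pixel-count, centroid (0-based x = col - 1, y = row - 1).
.componentStats <- function(lab) {
  n <- max(lab)
  if (n == 0L)
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area_px2 = numeric(0)))
  h <- nrow(lab)
  idx <- which(lab > 0)
  l <- lab[idx]
  rows <- (idx - 1L) %% h
  cols <- (idx - 1L) %/% h
  area <- tabulate(l, nbins = n)
  sx <- rowsum(as.numeric(cols), l)
  sy <- rowsum(as.numeric(rows), l)
  ids <- as.integer(rownames(sx))
  data.frame(label = ids,
             x = as.numeric(sx) / area[ids],
             y = as.numeric(sy) / area[ids],
             area_px2 = as.numeric(area[ids]))
}

# Perimeter estimate per label (ids 1..max(lab)): exposed pixel-edge
# count scaled by pi/4 (Cauchy-Crofton correction; exact for digital
# disks, where 8r exposed edges correspond to a true perimeter 2*pi*r).
# Fully vectorized -- per-object contour tracing is far too slow on
# slides with tens of thousands of globules.
.perimeterEstimate <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(numeric(0))
  h <- nrow(lab); w <- ncol(lab)
  z <- 0L
  cnt <- (rbind(z, lab[-h, , drop = FALSE]) != lab) +
         (rbind(lab[-1, , drop = FALSE], z) != lab) +
         (cbind(z, lab[, -w, drop = FALSE]) != lab) +
         (cbind(lab[, -1, drop = FALSE], z) != lab)
  idx <- which(lab > 0)
  e <- rowsum(as.numeric(cnt[idx]), lab[idx])
  out <- numeric(n)
  out[as.integer(rownames(e))] <- as.numeric(e) * (pi / 4)
  out
}

.circularity <- function(area, perimeter) {
  pmin(4 * pi * area / pmax(perimeter, 1)^2, 1.05)
}

.discBrush <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")

# Extend labels into the background by <= d px, nearest object wins,
# without ever reassigning a labelled pixel. Used only as the intensity
# integration support.
.expandLabels <- function(lab, d) {
  if (d <= 0 || max(lab) == 0L) return(lab)
  mask <- lab > 0
  dm <- EBImage::dilate(mask, .discBrush(d)) > 0
  ext <- EBImage::propagate(EBImage::Image(array(0, dim(lab))),
                            seeds = lab, mask = dm)
  EBImage::imageData(ext)
}

# --- rasterizers ------------------------------------------------------------

# Linear indices (into an h x w matrix) of pixels with
# r0 < dist <= r1 from (cx, cy) and, unless half >= pi, angular distance
# to theta <= half. Coordinates 0-based; pixel centers at integers.
.arcPixels <- function(cx, cy, r0, r1, theta, half, h, w) {
  rlo <- max(1L, floor(cy - r1) + 1L)
  rhi <- min(h, ceiling(cy + r1) + 1L)
  clo <- max(1L, floor(cx - r1) + 1L)
  chi <- min(w, ceiling(cx + r1) + 1L)
  if (rlo > rhi || clo > chi) return(integer(0))
  dy <- (rlo:rhi) - 1 - cy
  dx <- (clo:chi) - 1 - cx
  nr <- length(dy); nc <- length(dx)
  d2 <- outer(dy^2, dx^2, `+`)
  sel <- if (r0 >= 0) d2 > r0^2 & d2 <= r1^2 else d2 <= r1^2
  if (half < pi) {
    ang <- atan2(matrix(dy, nr, nc), matrix(dx, nr, nc, byrow = TRUE))
    dang <- abs((ang - theta + pi) %% (2 * pi) - pi)
    sel <- sel & dang <= half
  }
  sub <- which(sel)
  if (!length(sub)) return(integer(0))
  srow <- rlo + (sub - 1L) %% nr
  scol <- clo + (sub - 1L) %/% nr
  (scol - 1L) * h + srow
}

.diskPixels <- function(cx, cy, r, h, w) {
  .arcPixels(cx, cy, -1, r, 0, pi, h, w)
}

.indexCentroid <- function(idx, h) {
  c(x = mean((idx - 1L) %/% h), y = mean((idx - 1L) %% h))
}
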