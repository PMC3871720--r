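# Shared fixtures, all built in code.

# Segmentation setup for synthetic renders: rims carry real intensity
# contrast, so direct thresholding applies (the gradient path is for
# real DIC optics and is exercised separately on rim-style images).
synthSegParams <- function(...) {
  segmentationParams(globule_strategy = "intensity", ...)
}

# A small scene that runs in ~2 s.
quickScene <- function(seed = 1, ...) {
  generateScene(sceneParams(seed = seed, ...))
}

# Filled disk of radius r centered at 0-based (cx, cy) on an h x w plane.
diskPlane <- function(h, w, cx, cy, r, value = 300, background = 0) {
  d2 <- outer(((1:h) - 1 - cy)^2, ((1:w) - 1 - cx)^2, `+`)
  m <- matrix(background, h, w)
  m[d2 <= r^2] <- value
  m
}

# Greedy nearest-centroid matching of detected records against truth;
# returns per-detection distance to its matched truth row.
nearestTruthDist <- function(det, truth) {
  stopifnot(nrow(det) == nrow(truth))
  d <- sqrt(outer(det$x, truth$x, `-`)^2 + outer(det$y, truth$y, `-`)^2)
  apply(d, 1, min)
}

# Brute-force reference for crescent linking: independent all-pairs scan
# with explicit loops, including the tie and orphan rules.
bruteForceLink <- function(crescents, globules, max_link_distance = 25) {
  n <- nrow(crescents)
  out <- data.frame(linked_globule_id = rep(NA_integer_, n),
                    link_distance = rep(NA_real_, n),
                    orphan = rep(TRUE, n))
  if (n == 0 || nrow(globules) == 0) return(out)
  for (i in seq_len(n)) {
    bestId <- NA_integer_
    bestD <- Inf
    for (j in seq_len(nrow(globules))) {
      d <- sqrt((crescents$x[i] - globules$x[j])^2 +
                (crescents$y[i] - globules$y[j])^2) -
        globules$equiv_radius[j]
      if (d < bestD ||
          (d == bestD && globules$globule_id[j] < bestId)) {
        bestD <- d
        bestId <- globules$globule_id[j]
      }
    }
    if (bestD <= max_link_distance) {
      out$linked_globule_id[i] <- bestId
      out$link_distance[i] <- bestD
      out$orphan[i] <- FALSE
    }
  }
  out
}

# Zero-row object table in canonical column order.
.emptyTableFixture <- function() {
  data.frame(image_id = character(0), object_id = integer(0),
             kind = character(0), x = numeric(0), y = numeric(0),
             area_px2 = numeric(0), area_um2 = numeric(0),
             linked_globule_id = integer(0), link_distance_px = numeric(0),
             flags = character(0), stringsAsFactors = FALSE)
}

randomLinkInstance <- function(n_crescents, n_globules, extent = 200) {
  list(
    crescents = data.frame(
      x = runif(n_crescents, 0, extent), y = runif(n_crescents, 0, extent),
      area_px2 = runif(n_crescents, 5, 80),
      integrated_intensity = runif(n_crescents, 0, 1e4)),
    globules = data.frame(
      globule_id = seq_len(n_globules),
      x = runif(n_globules, 0, extent), y = runif(n_globules, 0, extent),
      area_px2 = rep(1, n_globules),
      equiv_radius = runif(n_globules, 2, 15),
      circularity = rep(1, n_globules))
  )
}
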