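#' Correct globule geometry by hole filling
#'
#' Rim-only detections (DIC shows globule boundaries, not filled disks)
#' leave each globule as an annulus; this fills every component's holes
#' and recomputes area, centroid, equivalent radius and circularity on the
#' filled component. The operation is idempotent: already-solid globules
#' are returned unchanged.
#'
#' @param globule_labels integer label matrix.
#' @param records matching globule records (see [segmentGlobules()]).
#' @return list with the filled `labels` and the corrected `records`.
#' @examples
#' m <- matrix(0L, 48, 48)
#' d2 <- outer((1:48 - 24)^2, (1:48 - 24)^2, "+")
#' m[d2 <= 20^2 & d2 >= 15^2] <- 1L
#' rec <- data.frame(globule_id = 1L, x = 23, y = 23,
#'                   area_px2 = sum(m), equiv_radius = sqrt(sum(m) / pi),
#'                   circularity = 0.9)
#' correctGlobuleGeometry(m, rec)$records$area_px2  # ~ pi * 20^2
#' @export
correctGlobuleGeometry <- function(globule_labels, records) {
  stopifnot(is.data.frame(records))
  if (max(globule_labels) > 0 &&
      !all(records$globule_id %in% unique(globule_labels[globule_labels > 0])))
    stop("records and label map are inconsistent")
  if (nrow(records) == 0)
    return(list(labels = globule_labels, records = records))
  filled <- EBImage::imageData(EBImage::fillHull(globule_labels))
  st <- .componentStats(filled)
  per <- .perimeterEstimate(filled)
  m <- match(records$globule_id, st$label)
  out <- records
  out$x <- st$x[m]
  out$y <- st$y[m]
  out$area_px2 <- st$area_px2[m]
  out$equiv_radius <- sqrt(out$area_px2 / pi)
  out$circularity <- .circularity(out$area_px2, per[st$label[m]])
  list(labels = filled, records = out)
}

#' Link each crescent to its closest milk fat globule
#'
#' The linking distance is the Euclidean distance between the crescent
#' centroid and the globule centroid, minus the globule's equivalent
#' radius -- i.e. the distance to the idealized globule boundary, which
#' may be negative when the centroid falls inside the disk. Each crescent
#' links to the globule minimizing this distance; exact ties break toward
#' the lowest `globule_id`. Crescents farther than `max_link_distance`
#' from every boundary, or any crescent when no globules exist, are
#' retained as orphans (`linked_globule_id = NA`): they still count as
#' exosomal RNA, but contribute no globule to the crescent-incidence
#' numerator.
#'
#' @param crescent_candidates data.frame with at least `x, y, area_px2,
#'   integrated_intensity` (e.g. the `crescents` element of
#'   [classifyRnaObjects()]).
#' @param globule_records data.frame with `globule_id, x, y,
#'   equiv_radius`.
#' @param params a [linkParams()] bundle.
#' @return data.frame `crescent_id, x, y, area_px2, integrated_intensity,
#'   dna_overlap_fraction, linked_globule_id, link_distance, orphan`, in
#'   the input row order.
#' @examples
#' g <- data.frame(globule_id = 1:2, x = c(0, 100), y = 0,
#'                 area_px2 = pi * 100, equiv_radius = 10,
#'                 circularity = 0.9)
#' x <- data.frame(x = 12, y = 0, area_px2 = 40, integrated_intensity = 1)
#' linkCrescents(x, g)$link_distance  # 2
#' @export
linkCrescents <- function(crescent_candidates, globule_records,
                          params = linkParams()) {
  nx <- nrow(crescent_candidates)
  out <- data.frame(
    crescent_id = seq_len(nx),
    x = as.numeric(crescent_candidates$x),
    y = as.numeric(crescent_candidates$y),
    area_px2 = as.numeric(crescent_candidates$area_px2),
    integrated_intensity =
      as.numeric(crescent_candidates$integrated_intensity),
    dna_overlap_fraction =
      if ("dna_overlap_fraction" %in% names(crescent_candidates))
        as.numeric(crescent_candidates$dna_overlap_fraction)
      else rep(NA_real_, nx),
    linked_globule_id = rep(NA_integer_, nx),
    link_distance = rep(NA_real_, nx),
    orphan = rep(TRUE, nx))
  if (nx == 0 || nrow(globule_records) == 0) return(out)
  g <- globule_records[order(globule_records$globule_id), , drop = FALSE]
  # chunk the distance matrix so n_crescents x n_globules stays bounded
  chunk <- max(1L, as.integer(5e6 / max(nrow(g), 1L)))
  for (s in seq(1L, nx, by = chunk)) {
    e <- min(s + chunk - 1L, nx)
    dx <- outer(out$x[s:e], g$x, `-`)
    dy <- outer(out$y[s:e], g$y, `-`)
    d <- sqrt(dx^2 + dy^2) -
      matrix(g$equiv_radius, e - s + 1L, nrow(g), byrow = TRUE)
    j <- max.col(-d, ties.method = "first")  # g is sorted by globule_id
    best <- d[cbind(seq_len(e - s + 1L), j)]
    ok <- best <= params$max_link_distance
    rows <- (s:e)[ok]
    out$linked_globule_id[rows] <- g$globule_id[j[ok]]
    out$link_distance[rows] <- best[ok]
    out$orphan[rows] <- FALSE
  }
  out
}
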