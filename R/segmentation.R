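#' Detect milk fat globules in the DIC channel
#'
#' Globules appear in DIC as bright-rimmed "gray bubbles", not filled
#' disks. The default strategy therefore thresholds the smoothed Sobel
#' gradient magnitude (`"gradient"`), closes the resulting rim mask with a
#' 3x3 structuring element, fills holes, and labels 8-connected
#' components; `"intensity"` thresholds the smoothed plane directly. Both
#' apply the area and circularity filters afterwards. Hole filling happens
#' before any measurement, so [correctGlobuleGeometry()] is a no-op on the
#' output (the correction contract is idempotent).
#'
#' A constant plane under Otsu thresholding yields zero objects with a
#' warning, not an error. The fraction of area-passing objects with
#' circularity below 0.8 -- a proxy for touching globules merged into one
#' component, which this version does not split -- is attached as
#' attribute `low_circularity_fraction` of the returned records.
#'
#' @param dic numeric matrix, the DIC plane.
#' @param params a [segmentationParams()] bundle.
#' @return list with elements `labels` (integer matrix; 0 = background)
#'   and `records` (data.frame `globule_id, x, y, area_px2, equiv_radius,
#'   circularity`, sorted by `globule_id`), plus `threshold`.
#' @examples
#' plane <- matrix(0, 64, 64)
#' plane[as.logical(outer((1:64 - 32)^2, (1:64 - 32)^2, "+") <= 144)] <- 300
#' g <- segmentGlobules(plane, segmentationParams(
#'   globule_strategy = "intensity", smoothing_sigma = 0))
#' g$records
#' @export
segmentGlobules <- function(dic, params = segmentationParams()) {
  stopifnot(is.matrix(dic), length(dic) > 0)
  sm <- .smooth(dic, params$smoothing_sigma)
  feat <- switch(params$globule_strategy,
                 gradient = .gradientMagnitude(sm),
                 intensity = sm)
  th <- .channelThreshold(feat, params, "dic")
  empty <- list(labels = matrix(0L, nrow(dic), ncol(dic)),
                records = .emptyGlobuleRecords(), threshold = th)
  if (is.na(th)) {
    warning("zero-variance DIC feature plane; no globules detected")
    return(empty)
  }
  mask <- feat > th
  if (!any(mask) ||
      .lowContrast(feat, mask, th, params, "dic"))
    return(empty)
  mask <- EBImage::fillHull(EBImage::closing(mask, .closingBrush)) > 0
  lab <- .label8(mask)
  flt <- .filterLabelsByArea(lab, params$min_globule_area)
  lab <- flt$labels
  if (max(lab) == 0L) return(empty)
  st <- .componentStats(lab)
  per <- .perimeterEstimate(lab)
  circ <- .circularity(st$area_px2, per[st$label])
  lowCirc <- mean(circ < 0.8)
  keep <- which(circ >= params$circularity_min)
  map <- integer(max(lab)); map[st$label[keep]] <- seq_along(keep)
  nz <- lab > 0
  lab[nz] <- map[lab[nz]]
  records <- data.frame(
    globule_id = seq_along(keep),
    x = st$x[keep], y = st$y[keep],
    area_px2 = st$area_px2[keep],
    equiv_radius = sqrt(st$area_px2[keep] / pi),
    circularity = circ[keep])
  attr(records, "low_circularity_fraction") <- lowCirc
  list(labels = lab, records = records, threshold = th)
}

.closingBrush <- matrix(1L, 3L, 3L)

# TRUE when an automatic threshold fails the minimum-contrast guard:
# on a signal-free plane Otsu cuts mid-noise, so the threshold sits only
# ~1 robust SD above the background median instead of clearing it by a
# wide margin. Fixed thresholds are trusted as given.
.lowContrast <- function(plane, mask, th, params, channel) {
  if (params$threshold_method == "fixed" &&
      !is.na(params$fixed_thresholds[[channel]])) return(FALSE)
  if (all(mask)) return(FALSE)
  below <- plane[!mask]
  spread <- stats::mad(below)
  if (spread == 0) return(FALSE)
  th - stats::median(below) < params$min_contrast_sigma * spread
}

.emptyGlobuleRecords <- function() {
  data.frame(globule_id = integer(0), x = numeric(0), y = numeric(0),
             area_px2 = numeric(0), equiv_radius = numeric(0),
             circularity = numeric(0))
}

# Fixed thresholds apply per channel; NA entries fall back to Otsu so a
# single low-signal channel can be pinned while the others stay adaptive.
.channelThreshold <- function(plane, params, channel) {
  if (params$threshold_method == "fixed") {
    th <- params$fixed_thresholds[[channel]]
    if (!is.na(th)) return(th)
  }
  .otsuThreshold(plane)
}

#' Detect objects in one fluorescence channel
#'
#' Gaussian smoothing, thresholding (Otsu or fixed), 8-connected
#' components, and an area filter. Integrated intensity is the
#' background-subtracted sum over the object's support, where background
#' is the median intensity of below-threshold pixels and per-pixel values
#' are clamped at zero. The support extends `intensity_dilation_px` beyond
#' the component (nearest object wins; see [segmentationParams()]); the
#' reported area and label map always refer to the undilated component.
#'
#' @param plane numeric matrix (AO-RNA or AO-DNA).
#' @param min_area minimum object area in px^2.
#' @param params a [segmentationParams()] bundle.
#' @param channel `"rna"`, `"dna"` or `"dic"`; selects the fixed threshold
#'   when `threshold_method = "fixed"`.
#' @return list with `labels` (integer matrix), `objects` (data.frame
#'   `object_id, x, y, area_px2, integrated_intensity`), `threshold` and
#'   `background`.
#' @export
segmentChannelObjects <- function(plane, min_area,
                                  params = segmentationParams(),
                                  channel = "rna") {
  stopifnot(is.matrix(plane), length(plane) > 0, min_area > 0)
  sm <- .smooth(plane, params$smoothing_sigma)
  th <- .channelThreshold(sm, params, channel)
  empty <- list(labels = matrix(0L, nrow(plane), ncol(plane)),
                objects = .emptyChannelObjects(),
                threshold = th, background = NA_real_)
  if (is.na(th)) {
    warning(sprintf("zero-variance '%s' plane; no objects detected",
                    channel))
    return(empty)
  }
  mask <- sm > th
  bg <- if (all(mask)) 0 else stats::median(sm[!mask])
  empty$background <- bg
  if (!any(mask) || .lowContrast(sm, mask, th, params, channel))
    return(empty)
  lab <- .label8(mask)
  flt <- .filterLabelsByArea(lab, min_area)
  lab <- flt$labels
  if (max(lab) == 0L) return(empty)
  st <- .componentStats(lab)
  ext <- .expandLabels(lab, params$intensity_dilation_px)
  idx <- which(ext > 0)
  contrib <- rowsum(pmax(sm[idx] - bg, 0), ext[idx])
  intens <- numeric(max(lab))
  intens[as.integer(rownames(contrib))] <- as.numeric(contrib)
  objects <- data.frame(
    object_id = st$label,
    x = st$x, y = st$y,
    area_px2 = st$area_px2,
    integrated_intensity = intens[st$label])
  list(labels = lab, objects = objects, threshold = th, background = bg)
}

.emptyChannelObjects <- function() {
  data.frame(object_id = integer(0), x = numeric(0), y = numeric(0),
             area_px2 = numeric(0), integrated_intensity = numeric(0))
}

#' Classify RNA objects as crescents or nucleated cells
#'
#' Acridine orange stains RNA red and DNA green, so cytoplasmic crescents
#' carry RNA-only signal while nucleated cells show both. Each RNA
#' object's `dna_overlap_fraction` -- the fraction of its member pixels
#' inside the DNA mask dilated by `dna_dilation_px` (tolerating chromatic
#' misregistration) -- is compared with `coloc_fraction`: objects at or
#' above the cutoff (boundary inclusive) become nucleated cells, the rest
#' crescent candidates. Every input object lands in exactly one output
#' list.
#'
#' @param rna_labels integer label matrix from [segmentChannelObjects()]
#'   on the RNA plane.
#' @param rna_objects the matching `objects` data.frame.
#' @param dna_mask logical/binary matrix of DNA-positive pixels, same
#'   shape as `rna_labels`.
#' @param params a [segmentationParams()] bundle.
#' @return list with `crescents` (data.frame `object_id, x, y, area_px2,
#'   integrated_intensity, dna_overlap_fraction, kind`), `cells`
#'   (data.frame `cell_id, x, y, rna_area_px2, dna_area_px2,
#'   integrated_rna_intensity, dna_overlap_fraction`) and `rna_objects`
#'   (all inputs with their fraction and kind).
#' @export
classifyRnaObjects <- function(rna_labels, rna_objects, dna_mask,
                               params = segmentationParams()) {
  if (!identical(dim(rna_labels), dim(dna_mask)))
    stop("rna_labels and dna_mask must share the same shape")
  dm <- dna_mask > 0
  if (params$dna_dilation_px > 0 && any(dm))
    dm <- EBImage::dilate(dm, .discBrush(params$dna_dilation_px)) > 0
  n <- nrow(rna_objects)
  frac <- numeric(n)
  if (n > 0) {
    idx <- which(rna_labels > 0)
    if (length(idx)) {
      ov <- rowsum(as.numeric(dm[idx]), rna_labels[idx])
      ids <- as.integer(rownames(ov))
      m <- match(rna_objects$object_id, ids)
      hit <- !is.na(m)
      frac[hit] <- as.numeric(ov)[m[hit]] / rna_objects$area_px2[hit]
    }
  }
  isCell <- frac >= params$coloc_fraction
  all <- cbind(rna_objects,
               dna_overlap_fraction = frac,
               kind = ifelse(isCell, "nucleated_cell", "crescent_candidate"),
               stringsAsFactors = FALSE)
  cres <- all[!isCell, , drop = FALSE]
  rownames(cres) <- NULL
  cel <- all[isCell, , drop = FALSE]
  cells <- data.frame(
    cell_id = seq_len(nrow(cel)),
    x = cel$x, y = cel$y,
    rna_area_px2 = cel$area_px2,
    dna_area_px2 = round(cel$dna_overlap_fraction * cel$area_px2),
    integrated_rna_intensity = cel$integrated_intensity,
    dna_overlap_fraction = cel$dna_overlap_fraction)
  list(crescents = cres, cells = cells, rna_objects = all)
}
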