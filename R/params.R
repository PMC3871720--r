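#' Segmentation parameters
#'
#' Bundles every knob of the detection stage. Element names double as the
#' keys of the YAML configuration file, so a config written by hand and a
#' bundle built in code are interchangeable.
#'
#' @param min_globule_area minimum globule area in px^2 (default 50).
#' @param min_rna_area,min_dna_area minimum area in px^2 for objects in the
#'   fluorescence channels (default 5).
#' @param circularity_min minimum circularity `4*pi*area/perimeter^2` for
#'   globules only, in `[0, 1]` (default 0.6). Perimeter is estimated from the
#'   exposed-boundary-edge count with a pi/4 Crofton correction (exact for
#'   digital disks); values are clamped at 1.05 to absorb
#'   discretization.
#' @param threshold_method `"otsu"` (per image or per tile) or `"fixed"`.
#' @param fixed_thresholds named numeric vector `c(dic=, rna=, dna=)` used
#'   when `threshold_method = "fixed"`; `NA` entries fall back to Otsu for
#'   that channel. For the DIC channel the threshold applies to the
#'   feature image of the chosen `globule_strategy`.
#' @param smoothing_sigma Gaussian pre-smoothing sigma in px (default 1).
#' @param coloc_fraction minimum fraction of an RNA object's pixels inside
#'   the (dilated) DNA mask for it to be classified as a nucleated cell
#'   rather than a crescent; boundary inclusive (default 0.3).
#' @param dna_dilation_px dilation of the DNA mask before colocalization,
#'   tolerating chromatic misregistration (default 1).
#' @param globule_strategy `"gradient"` (smoothed Sobel gradient magnitude,
#'   then threshold; DIC shows globule rims, not filled disks) or
#'   `"intensity"` (direct thresholding, for simple or synthetic images).
#'   Both are followed by 3x3 morphological closing and hole filling.
#' @param min_contrast_sigma minimum contrast, in robust standard
#'   deviations (MAD) of the below-threshold pixels, that an automatic
#'   threshold must clear above the background median before any object
#'   is accepted. Otsu always returns a cut, even on a signal-free plane
#'   where it lands mid-noise and turns speckle into a giant mask; this
#'   guard makes empty channels (and empty tiles) yield zero objects.
#'   Ignored for channels with a fixed threshold (default 4).
#' @param intensity_dilation_px how far (px) the background-subtracted
#'   intensity integration region extends beyond the thresholded component
#'   (nearest-object assignment; recaptures signal displaced by smoothing).
#'   Object areas and label maps always use the undilated component.
#' @return a validated list of class `SegmentationParams`.
#' @seealso [segmentGlobules()], [segmentChannelObjects()],
#'   [classifyRnaObjects()]
#' @examples
#' segmentationParams(min_globule_area = 80)
#' @export
segmentationParams <- function(min_globule_area = 50,
                               min_rna_area = 5,
                               min_dna_area = 5,
                               circularity_min = 0.6,
                               threshold_method = c("otsu", "fixed"),
                               fixed_thresholds = c(dic = NA_real_,
                                                    rna = NA_real_,
                                                    dna = NA_real_),
                               smoothing_sigma = 1.0,
                               coloc_fraction = 0.3,
                               dna_dilation_px = 1L,
                               globule_strategy = c("gradient", "intensity"),
                               min_contrast_sigma = 4,
                               intensity_dilation_px = 2L) {
  threshold_method <- match.arg(threshold_method)
  globule_strategy <- match.arg(globule_strategy)
  stopifnot(
    min_globule_area > 0, min_rna_area > 0, min_dna_area > 0,
    circularity_min >= 0, circularity_min <= 1,
    smoothing_sigma >= 0,
    coloc_fraction >= 0, coloc_fraction <= 1,
    dna_dilation_px >= 0, min_contrast_sigma >= 0,
    intensity_dilation_px >= 0
  )
  ft <- c(dic = NA_real_, rna = NA_real_, dna = NA_real_)
  ft[names(fixed_thresholds)] <- as.numeric(fixed_thresholds)
  structure(list(
    min_globule_area = min_globule_area,
    min_rna_area = min_rna_area,
    min_dna_area = min_dna_area,
    circularity_min = circularity_min,
    threshold_method = threshold_method,
    fixed_thresholds = ft,
    smoothing_sigma = smoothing_sigma,
    coloc_fraction = coloc_fraction,
    dna_dilation_px = as.integer(dna_dilation_px),
    globule_strategy = globule_strategy,
    min_contrast_sigma = min_contrast_sigma,
    intensity_dilation_px = as.integer(intensity_dilation_px)
  ), class = "SegmentationParams")
}

#' Crescent-to-globule linking parameters
#'
#' @param max_link_distance maximum centroid-to-globule-boundary distance
#'   in px beyond which a crescent is left unlinked (orphan); default 25.
#'   Ties between equidistant globules are always broken toward the lowest
#'   `globule_id`.
#' @return a validated list of class `LinkParams`.
#' @seealso [linkCrescents()]
#' @export
linkParams <- function(max_link_distance = 25) {
  stopifnot(is.numeric(max_link_distance), max_link_distance >= 0)
  structure(list(max_link_distance = as.numeric(max_link_distance)),
            class = "LinkParams")
}

#' Synthetic scene parameters
#'
#' Defines one simulated AO-stained whole-milk field. Globule radii follow
#' a lognormal law truncated to `[globule_radius_min, globule_radius_max]`
#' (sub-resolution globules are not countable objects; the upper bound
#' caps the object diameter for the tiling-overlap contract). Crescents
#' are annular arcs hugging the outside of their owner globule's boundary;
#' nucleated cells are free-floating disks carrying both RNA and DNA
#' signal. Intensity units are arbitrary; only ratios are contractual.
#'
#' @param width,height canvas size in px.
#' @param n_globules number of globules.
#' @param globule_radius_median,globule_radius_sigma median (px) and sigma
#'   of the log of the globule radius law.
#' @param globule_radius_min,globule_radius_max truncation bounds (px).
#' @param crescent_incidence probability that a globule carries a crescent
#'   (ignored when `crescent_count` is given).
#' @param crescent_count exact number of distinct crescent-bearing
#'   globules, or `NULL` for Bernoulli placement at `crescent_incidence`.
#' @param crescent_arc_fraction fractional angular extent of a crescent
#'   arc (of the full circle).
#' @param crescent_thickness radial thickness of the arc in px.
#' @param n_cells number of nucleated cells.
#' @param cell_radius cell disk radius in px.
#' @param dic_background,globule_rim_contrast,rim_thickness DIC plane:
#'   background level, additive rim brightness, radial rim width (px,
#'   drawn on the inside of the boundary).
#' @param rna_background,crescent_rna_level,cell_rna_level RNA plane
#'   levels (background and per-pixel object signal above background).
#' @param dna_background,cell_dna_level DNA plane levels.
#' @param blur_sigma Gaussian optical blur sigma in px applied to all
#'   channels at render time.
#' @param noise `"gaussian"`, `"poisson"` or `"none"`.
#' @param noise_sigma standard deviation of Gaussian noise (intensity
#'   units); ignored for the other noise models.
#' @param seed integer seed; generation and rendering are bit-reproducible
#'   given the seed.
#' @param min_separation minimum boundary-to-boundary clearance between
#'   globules (and between cells and globules), px.
#' @param target_cellular_share optional ground-truth cellular share of
#'   integrated RNA signal, in percent; when set, the crescent RNA level
#'   is rescaled after placement so the share is met exactly. See
#'   [calibrateSceneParams()] for choosing a crescent count that keeps the
#'   rescaling factor near 1.
#' @param max_place_retries placement attempts per object before the
#'   generator declares the packing infeasible.
#' @return a validated list of class `SceneParams`.
#' @seealso [generateScene()], [renderChannels()]
#' @export
sceneParams <- function(width = 512, height = 512,
                        n_globules = 200,
                        globule_radius_median = 8,
                        globule_radius_sigma = 0.25,
                        globule_radius_min = 5,
                        globule_radius_max = 20,
                        crescent_incidence = 0.06,
                        crescent_count = NULL,
                        crescent_arc_fraction = 0.35,
                        crescent_thickness = 3,
                        n_cells = 10,
                        cell_radius = 5,
                        dic_background = 500,
                        globule_rim_contrast = 300,
                        rim_thickness = 2,
                        rna_background = 50,
                        crescent_rna_level = 400,
                        cell_rna_level = 400,
                        dna_background = 50,
                        cell_dna_level = 400,
                        blur_sigma = 1.0,
                        noise = c("gaussian", "none", "poisson"),
                        noise_sigma = 5,
                        seed = 1L,
                        min_separation = 6,
                        target_cellular_share = NULL,
                        max_place_retries = 200L) {
  noise <- match.arg(noise)
  stopifnot(
    width >= 16, height >= 16,
    n_globules >= 0, n_cells >= 0,
    globule_radius_median > 0, globule_radius_sigma >= 0,
    globule_radius_min > 0,
    globule_radius_max >= globule_radius_min,
    crescent_incidence >= 0, crescent_incidence <= 1,
    is.null(crescent_count) ||
      (crescent_count >= 0 && crescent_count <= n_globules),
    crescent_arc_fraction > 0, crescent_arc_fraction <= 1,
    crescent_thickness >= 1,
    cell_radius >= 1,
    dic_background >= 0, globule_rim_contrast >= 0, rim_thickness >= 1,
    rna_background >= 0, crescent_rna_level >= 0, cell_rna_level >= 0,
    dna_background >= 0, cell_dna_level >= 0,
    blur_sigma >= 0, noise_sigma >= 0,
    min_separation >= 0, max_place_retries >= 1,
    is.null(target_cellular_share) ||
      (target_cellular_share > 0 && target_cellular_share < 100)
  )
  structure(list(
    width = as.integer(width), height = as.integer(height),
    n_globules = as.integer(n_globules),
    globule_radius_median = globule_radius_median,
    globule_radius_sigma = globule_radius_sigma,
    globule_radius_min = globule_radius_min,
    globule_radius_max = globule_radius_max,
    crescent_incidence = crescent_incidence,
    crescent_count = if (is.null(crescent_count)) NULL
                     else as.integer(crescent_count),
    crescent_arc_fraction = crescent_arc_fraction,
    crescent_thickness = crescent_thickness,
    n_cells = as.integer(n_cells),
    cell_radius = cell_radius,
    dic_background = dic_background,
    globule_rim_contrast = globule_rim_contrast,
    rim_thickness = rim_thickness,
    rna_background = rna_background,
    crescent_rna_level = crescent_rna_level,
    cell_rna_level = cell_rna_level,
    dna_background = dna_background,
    cell_dna_level = cell_dna_level,
    blur_sigma = blur_sigma,
    noise = noise,
    noise_sigma = noise_sigma,
    seed = as.integer(seed),
    min_separation = min_separation,
    target_cellular_share = target_cellular_share,
    max_place_retries = as.integer(max_place_retries)
  ), class = "SceneParams")
}
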