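#' Load a three-channel micrograph
#'
#' Reads the DIC, AO-RNA and AO-DNA planes of one field from TIFF. Channel
#' identity is always caller-declared through `channel_map` -- input TIFFs
#' carry no reliable channel metadata -- either as 1-based page indices
#' into a single multi-page file, or as one file path per channel. Planes
#' are used at their native intensity scale; no normalization is applied
#' at load time (thresholding happens downstream, per image or per tile).
#'
#' @param path path to a multi-page TIFF; ignored (may be `NA`) when
#'   `channel_map` holds per-channel file paths.
#' @param channel_map named list with exactly the entries `dic`, `rna` and
#'   `dna`; values are 1-based page indices (numeric) or file paths
#'   (character).
#' @param pixel_size pixel edge length in micrometres (default 1, i.e.
#'   areas are reported in px^2 only).
#' @param image_id identifier recorded in results; defaults to the file
#'   base name.
#' @return a validated [ChannelStack-class]; the original bit depth is
#'   recorded in the `bitDepth` slot.
#' @examples
#' s <- renderChannels(generateScene(sceneParams(
#'   width = 64, height = 64, n_globules = 3, n_cells = 1, seed = 1)))
#' f <- tempfile(fileext = ".tif")
#' writeChannelStack(s, f)
#' loadChannelStack(f, list(dic = 1, rna = 2, dna = 3))
#' @export
loadChannelStack <- function(path, channel_map = list(dic = 1, rna = 2,
                                                      dna = 3),
                             pixel_size = 1, image_id = NULL) {
  roles <- c("dic", "rna", "dna")
  if (!setequal(names(channel_map), roles) ||
      length(channel_map) != 3L)
    stop("channel_map must name exactly the three roles dic, rna, dna")
  perFile <- all(vapply(channel_map, is.character, logical(1)))
  planes <- list()
  depth <- NA_integer_
  if (perFile) {
    for (ch in roles) {
      f <- channel_map[[ch]]
      if (!file.exists(f))
        stop(sprintf("channel '%s': file not found: %s", ch, f))
      pg <- tiff::readTIFF(f, all = FALSE, as.is = TRUE, info = TRUE)
      depth <- .tiffDepth(pg, depth)
      planes[[ch]] <- .asPlane(pg, ch)
    }
    if (is.null(image_id)) image_id <- basename(channel_map[["dic"]])
  } else {
    if (!file.exists(path))
      stop(sprintf("file not found: %s", path))
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    for (ch in roles) {
      i <- as.integer(channel_map[[ch]])
      if (is.na(i) || i < 1L || i > length(pages))
        stop(sprintf(
          "channel '%s' requests plane %s but the file has %d plane(s)",
          ch, channel_map[[ch]], length(pages)))
      depth <- .tiffDepth(pages[[i]], depth)
      planes[[ch]] <- .asPlane(pages[[i]], ch)
    }
    if (is.null(image_id)) image_id <- basename(path)
  }
  d <- dim(planes$dic)
  for (ch in roles)
    if (!identical(dim(planes[[ch]]), d))
      stop(sprintf(
        "plane shape mismatch: channel '%s' is %s, expected %s", ch,
        paste(dim(planes[[ch]]), collapse = "x"),
        paste(d, collapse = "x")))
  ChannelStack(planes$dic, planes$rna, planes$dna,
               pixelSize = pixel_size, imageId = image_id,
               bitDepth = depth)
}

.tiffDepth <- function(page, prev) {
  b <- attr(page, "bits.per.sample")
  if (is.null(b)) prev else as.integer(b)
}

.asPlane <- function(page, ch) {
  m <- page
  if (length(dim(m)) == 3L) {
    if (dim(m)[3] != 1L)
      stop(sprintf(
        "channel '%s': expected a single-sample grayscale plane, got %d samples",
        ch, dim(m)[3]))
    m <- m[, , 1]
  }
  if (length(dim(m)) != 2L)
    stop(sprintf("channel '%s' is not a 2-D plane", ch))
  storage.mode(m) <- "double"
  attributes(m) <- list(dim = dim(m))
  m
}

#' Write a ChannelStack to a multi-page TIFF
#'
#' Pages are written in the order dic, rna, dna as unsigned integers;
#' intensities are rounded and clipped to the representable range, so
#' integer-valued stacks round-trip bit-exactly through
#' [loadChannelStack()].
#'
#' @param stack a [ChannelStack-class].
#' @param path output path.
#' @param bits_per_sample 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @export
writeChannelStack <- function(stack, path, bits_per_sample = 16L) {
  stopifnot(is(stack, "ChannelStack"), bits_per_sample %in% c(8L, 16L))
  mx <- 2^bits_per_sample - 1
  planes <- lapply(list(stack@dic, stack@rna, stack@dna), function(p)
    pmin(pmax(round(p), 0), mx) / mx)
  tiff::writeTIFF(planes, path, bits.per.sample = as.integer(bits_per_sample))
  invisible(path)
}

#' Split an image into overlapping tiles
#'
#' Cuts a stack into a row-major grid of [Tile-class]s. Each tile owns a
#' core rectangle; the cores partition the parent exactly (half-open
#' intervals, no gaps, no overlaps), while tile extents add `overlap` px
#' of shared margin on interior sides so objects near a core boundary are
#' seen whole by the tile that owns them. Callers must choose `overlap`
#' at least as large as the maximum expected object diameter (twice that
#' for exact whole-vs-tiled agreement, see [aggregateTiles()]).
#'
#' @param stack a [ChannelStack-class].
#' @param tile_size maximum tile edge length in px; must exceed
#'   `2 * overlap`.
#' @param overlap shared margin in px.
#' @return list of [Tile-class] in row-major order.
#' @examples
#' z <- matrix(0, 100, 100)
#' length(tileIterator(ChannelStack(z, z, z), 60, 10))  # 4 tiles
#' @export
tileIterator <- function(stack, tile_size, overlap) {
  stopifnot(is(stack, "ChannelStack"))
  tile_size <- as.integer(tile_size); overlap <- as.integer(overlap)
  if (overlap < 0L) stop("overlap must be >= 0")
  if (tile_size <= 2L * overlap)
    stop("tile_size must exceed 2 * overlap")
  d <- dim(stack@dic)
  cy <- .axisCores(d[1], tile_size, overlap)
  cx <- .axisCores(d[2], tile_size, overlap)
  tiles <- vector("list", nrow(cy) * nrow(cx))
  k <- 0L
  for (iy in seq_len(nrow(cy))) {
    for (ix in seq_len(nrow(cx))) {
      x0 <- cx[ix, "t0"]; x1 <- cx[ix, "t1"]
      y0 <- cy[iy, "t0"]; y1 <- cy[iy, "t1"]
      sub <- ChannelStack(
        stack@dic[(y0 + 1L):y1, (x0 + 1L):x1, drop = FALSE],
        stack@rna[(y0 + 1L):y1, (x0 + 1L):x1, drop = FALSE],
        stack@dna[(y0 + 1L):y1, (x0 + 1L):x1, drop = FALSE],
        pixelSize = stack@pixelSize, imageId = stack@imageId,
        bitDepth = stack@bitDepth)
      k <- k + 1L
      tiles[[k]] <- new("Tile", stack = sub,
                        originX = x0, originY = y0,
                        coreBounds = unname(c(cx[ix, "c0"], cx[ix, "c1"],
                                              cy[iy, "c0"], cy[iy, "c1"])))
    }
  }
  tiles
}

# Core/tile intervals along one axis of length n (0-based, half-open).
# Interior cores have width tile_size - 2*overlap; the two edge cores
# absorb the remainder (each may extend to tile_size - overlap).
.axisCores <- function(n, tile_size, overlap) {
  if (n <= tile_size)
    return(cbind(c0 = 0L, c1 = n, t0 = 0L, t1 = n))
  cint <- tile_size - 2L * overlap
  k <- max(2L, as.integer(ceiling((n - 2L * overlap) / cint)))
  while (2L * (tile_size - overlap) + (k - 2L) * cint < n) k <- k + 1L
  leftover <- n - (k - 2L) * cint
  e1 <- leftover %/% 2L
  widths <- c(e1, rep(cint, k - 2L), leftover - e1)
  c1 <- cumsum(widths)
  c0 <- c(0L, c1[-k])
  t0 <- pmax(c0 - overlap, 0L)
  t1 <- pmin(c1 + overlap, n)
  cbind(c0 = as.integer(c0), c1 = as.integer(c1),
        t0 = as.integer(t0), t1 = as.integer(t1))
}

#' Combine detected objects into the canonical object table
#'
#' One row per detected object with the documented columns `image_id,
#' object_id, kind, x, y, area_px2, area_um2, linked_globule_id,
#' link_distance_px, flags`. `area_um2` is `area_px2 * pixel_size^2`;
#' kinds are `"globule"`, `"crescent"` and `"cell"`; orphan crescents
#' carry the flag `"orphan"`.
#'
#' @param result a [SceneResult-class].
#' @param pixel_size pixel edge length in micrometres.
#' @return `data.frame` with the columns above.
#' @seealso [writeObjectTable()]
#' @export
objectTable <- function(result, pixel_size = 1) {
  stopifnot(is(result, "SceneResult"))
  g <- result@globules; x <- result@crescents; ce <- result@cells
  rows <- list()
  if (nrow(g))
    rows$globules <- data.frame(
      image_id = result@imageId, object_id = g$globule_id,
      kind = "globule", x = g$x, y = g$y, area_px2 = g$area_px2,
      linked_globule_id = NA_integer_, link_distance_px = NA_real_,
      flags = "", stringsAsFactors = FALSE)
  if (nrow(x))
    rows$crescents <- data.frame(
      image_id = result@imageId, object_id = x$crescent_id,
      kind = "crescent", x = x$x, y = x$y, area_px2 = x$area_px2,
      linked_globule_id = x$linked_globule_id,
      link_distance_px = x$link_distance,
      flags = ifelse(x$orphan, "orphan", ""), stringsAsFactors = FALSE)
  if (nrow(ce))
    rows$cells <- data.frame(
      image_id = result@imageId, object_id = ce$cell_id,
      kind = "cell", x = ce$x, y = ce$y, area_px2 = ce$rna_area_px2,
      linked_globule_id = NA_integer_, link_distance_px = NA_real_,
      flags = "", stringsAsFactors = FALSE)
  tab <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else .emptyObjectTable()
  tab$area_um2 <- tab$area_px2 * pixel_size^2
  tab[, .objectTableColumns()]
}

.objectTableColumns <- function() {
  c("image_id", "object_id", "kind", "x", "y", "area_px2", "area_um2",
    "linked_globule_id", "link_distance_px", "flags")
}

.emptyObjectTable <- function() {
  data.frame(image_id = character(0), object_id = integer(0),
             kind = character(0), x = numeric(0), y = numeric(0),
             area_px2 = numeric(0), area_um2 = numeric(0),
             linked_globule_id = integer(0),
             link_distance_px = numeric(0), flags = character(0),
             stringsAsFactors = FALSE)
}

#' Write an object table to CSV
#'
#' UTF-8, comma-delimited, with the canonical header (see
#' [objectTable()]). An empty record set yields a header-only file.
#'
#' @param records a [SceneResult-class] or a data.frame already in
#'   canonical form (missing `area_um2` is filled from `pixel_size`).
#' @param path output path.
#' @param pixel_size pixel edge length in micrometres, used when
#'   `records` needs conversion.
#' @return `path`, invisibly.
#' @export
writeObjectTable <- function(records, path, pixel_size = 1) {
  tab <- if (is(records, "SceneResult")) objectTable(records, pixel_size)
  else {
    tab <- as.data.frame(records)
    if (!"area_um2" %in% names(tab) && "area_px2" %in% names(tab))
      tab$area_um2 <- tab$area_px2 * pixel_size^2
    missing <- setdiff(.objectTableColumns(), names(tab))
    if (length(missing))
      stop("object table is missing columns: ",
           paste(missing, collapse = ", "))
    tab[, .objectTableColumns()]
  }
  utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8",
                   na = "")
  invisible(path)
}

#' Read back an object table written by [writeObjectTable()]
#'
#' @param path CSV path.
#' @return `data.frame` with the canonical columns.
#' @export
readObjectTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                  colClasses = c(image_id = "character", kind = "character",
                                 flags = "character"))
}
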