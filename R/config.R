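#' Default run configuration
#'
#' A nested list holding every tunable of a processing run: the
#' [segmentationParams()] and [linkParams()] keys (verbatim), tiling,
#' attribution mode, channel map, pixel size, scene parameters for
#' simulation, seed and log level. [readRunConfig()] merges a YAML file
#' over these defaults and rejects unknown keys; [writeRunManifest()]
#' serializes the effective configuration next to every run's outputs so
#' results are reproducible from inputs plus manifest alone.
#'
#' @param ... named overrides of top-level sections or scalar settings.
#' @return nested list of class `RunConfig`.
#' @examples
#' cfg <- runConfig(attribution_mode = "area")
#' cfg$segmentation$min_globule_area
#' @export
runConfig <- function(...) {
  cfg <- list(
    segmentation = unclass(segmentationParams()),
    linking = unclass(linkParams()),
    tiling = list(tile_size = NULL, overlap = 104L),
    attribution_mode = "intensity",
    channel_map = list(dic = 1L, rna = 2L, dna = 3L),
    pixel_size = 1,
    scene = unclass(sceneParams()),
    seed = 1L,
    log_level = "info"
  )
  dots <- list(...)
  .mergeConfig(cfg, dots, context = "runConfig")
}

.mergeConfig <- function(base, override, context = "config") {
  if (!length(override)) return(structure(base, class = "RunConfig"))
  nms <- names(override)
  if (is.null(nms) || any(!nzchar(nms)))
    stop(context, ": all settings must be named")
  for (k in nms) {
    if (!k %in% names(base))
      stop(sprintf("%s: unknown key '%s'", context, k))
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      sub <- override[[k]]
      bad <- setdiff(names(sub), names(base[[k]]))
      if (length(bad))
        stop(sprintf("%s: unknown key '%s.%s'", context, k, bad[1]))
      for (k2 in names(sub)) base[[k]][[k2]] <- sub[[k2]]
    } else {
      base[[k]] <- override[[k]]
    }
  }
  structure(base, class = "RunConfig")
}

.validateConfig <- function(config) {
  if (inherits(config, "RunConfig")) return(config)
  .mergeConfig(unclass(runConfig()), as.list(config))
}

#' Read a YAML run configuration
#'
#' Top-level sections and keys must match [runConfig()]; unknown keys are
#' rejected (typos must not silently fall back to defaults). Keys absent
#' from the file keep their documented defaults, reported via `message()`
#' at the `debug` log level.
#'
#' @param path YAML file path.
#' @return nested list of class `RunConfig`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  .mergeConfig(unclass(runConfig()), raw, context = basename(path))
}

#' Write the run manifest
#'
#' JSON record of the effective configuration, package version, seed and
#' per-image status of one run.
#'
#' @param config a `RunConfig`.
#' @param path output JSON path.
#' @param extra named list appended verbatim (e.g. per-image status).
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(config, path, extra = list()) {
  manifest <- c(list(
    package = "lactoscan",
    version = as.character(utils::packageVersion("lactoscan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = .dropNulls(unclass(config))
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

.dropNulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, .dropNulls)
  x[!vapply(x, is.null, logical(1))]
}
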