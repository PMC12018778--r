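## TIFF map I/O, CSV export of profiles/extents and YAML run configuration.
## Count maps are stored as 32-bit TIFF scaled by a fixed factor (the tiff
## package stores values in [0, 1]); the factor round-trips counts up to
## 65535 with float precision.

.TIFF_SCALE <- 65535

#' Write an element map or mask as single-channel TIFF
#'
#' @param x numeric or logical matrix; values must lie in `[0, 65535]`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_element_map <- function(x, path) {
  stopifnot(is.matrix(x))
  x <- x * 1.0
  if (any(x < 0 | x > .TIFF_SCALE)) {
    stop("map values must be within [0, 65535]", call. = FALSE)
  }
  tiff::writeTIFF(x / .TIFF_SCALE, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read an element map written by [write_element_map()]
#'
#' @param path TIFF file path.
#' @param integer round to integer counts.
#' @return numeric matrix.
#' @export
read_element_map <- function(path, integer = FALSE) {
  x <- tiff::readTIFF(path) * .TIFF_SCALE
  if (integer) x <- round(x)
  x
}

#' Write a synthetic map bundle to a directory
#'
#' Writes `map.tif`, `root.tif`, `pore.tif` and the ground-truth record as
#' `truth.json`.
#'
#' @param sm an `rg_synthmap` from [generate_map()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_synthmap <- function(sm, dir) {
  stopifnot(inherits(sm, "rg_synthmap"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_element_map(sm$map, file.path(dir, "map.tif"))
  write_element_map(sm$root * 1, file.path(dir, "root.tif"))
  write_element_map(sm$pore * 1, file.path(dir, "pore.tif"))
  jsonlite::write_json(c(sm$truth, sm$recipe[setdiff(names(sm$recipe), "style")]),
                       file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a run configuration from YAML
#'
#' Physical values in the configuration carry explicit unit strings
#' (`value:`/`unit:` pairs) which are converted to the internal cm/s/mol
#' system at load time; an unsupported unit is an error, which catches the
#' litre-versus-cm3 class of mistake before it reaches the solver.
#'
#' @param path YAML file.
#' @return named list with the converted values merged over the package
#'   defaults: `threshold` (mol cm-3), `hair_spacing_mode`, solver control
#'   fields, `seed`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  conv <- function(x, to) {
    if (is.list(x) && !is.null(x$value)) convert_units(x$value, x$unit, to) else x
  }
  cfg <- list(threshold = 8e-7, hair_spacing_mode = "hair-radius",
              n_cells = 300, rtol = 1e-8, atol = 1e-14, seed = 1L,
              include_extras = FALSE)
  for (nm in names(raw)) {
    cfg[[nm]] <- switch(nm,
      threshold = conv(raw[[nm]], "mol cm-3"),
      raw[[nm]])
  }
  cfg
}

#' Write the resolved configuration next to a run's outputs
#'
#' @param cfg configuration list.
#' @param dir output directory.
#' @return invisibly, the file path.
#' @export
write_resolved_config <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "resolved_config.yaml")
  cfg$package_version <- as.character(utils::packageVersion("rhizograd"))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
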