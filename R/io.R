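# Volume I/O: multi-page 32-bit TIFF stacks (plane order = z ascending) with a
# JSON sidecar carrying grid geometry, the affine intensity scaling (the TIFF
# backend stores 32-bit samples scaled into [0, 1]), and provenance.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a volume as a multi-page 32-bit TIFF stack
#'
#' Planes are written in ascending z. Values are affinely mapped to `[0, 1]`
#' for storage; the offset and scale are recorded in a JSON sidecar
#' (`<path>.json`) together with the grid, any metadata supplied (e.g. the
#' master seed and pipeline stage), and the package version, so a run can be
#' reproduced from its outputs.
#'
#' @param v real 3-D array `(nz, ny, nx)`, all values finite
#' @param path output TIFF path
#' @param voxel_xy,voxel_z voxel sizes in nm recorded in the sidecar
#' @param meta named list of extra provenance fields (seed, stage, config, ...)
#' @return `path`, invisibly
#' @export
write_stack <- function(v, path, voxel_xy = NA, voxel_z = NA, meta = list()) {
  nbad <- sum(!is.finite(v))
  if (nbad > 0) stop("refusing to write ", nbad, " non-finite values")
  if (length(dim(v)) != 3L) stop("expected a 3-D array (nz, ny, nx)")
  offset <- min(v)
  scale <- max(v) - offset
  vn <- if (scale > 0) (v - offset) / scale else v * 0
  pages <- lapply(seq_len(dim(v)[1]), function(iz) vn[iz, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "deflate")
  side <- c(list(shape = dim(v), axis_order = "z,y,x",
                 voxel_xy_nm = voxel_xy, voxel_z_nm = voxel_z,
                 offset = offset, scale = scale,
                 package = "ssos",
                 version = as.character(utils::packageVersion("ssos"))),
            meta)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a multi-page TIFF stack as a volume
#'
#' Accepts 8/16-bit integer or 32-bit stacks with uniform page shape; pages map
#' to ascending z. Integer stacks keep their integer values exactly. If a JSON
#' sidecar written by [write_stack()] sits next to the file, its affine
#' intensity scaling is inverted so the round trip restores the original
#' values. Single-page files are accepted (with a notice) as `nz = 1` volumes.
#'
#' @param path TIFF path
#' @return real 3-D array `(nz, ny, nx)`
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- lapply(pages, dim)
  if (length(unique(vapply(shp, paste, "", collapse = "x"))) != 1L) {
    stop("ragged TIFF: pages differ in shape")
  }
  if (length(pages) == 1L) message("single-page TIFF read as an nz = 1 volume")
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  v <- array(0, c(length(pages), ny, nx))
  for (iz in seq_along(pages)) v[iz, , ] <- pages[[iz]]
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(side$scale) && !is.null(side$offset)) {
      # as.is = TRUE returns 32-bit data as raw integers scaled by the reader;
      # readTIFF returns [0,1] doubles for 32-bit samples only without as.is,
      # so re-read in normalized form before inverting the affine map.
      vn <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(vn)) vn <- list(vn)
      for (iz in seq_along(vn)) v[iz, , ] <- vn[[iz]]
      v <- v * side$scale + side$offset
    }
  }
  v
}

#' Export a complex spectrum as magnitude and phase stacks
#'
#' Writes `<stem>_mag.tif` and `<stem>_phase.tif` (radians) with sidecars.
#'
#' @param S complex DC-centred spectrum
#' @param stem output path stem
#' @param meta extra sidecar metadata
#' @return character vector of the two paths, invisibly
#' @export
write_spectrum <- function(S, stem, meta = list()) {
  p1 <- paste0(stem, "_mag.tif")
  p2 <- paste0(stem, "_phase.tif")
  write_stack(Mod(S), p1, meta = c(meta, list(component = "magnitude")))
  write_stack(Arg(S), p2, meta = c(meta, list(component = "phase")))
  invisible(c(p1, p2))
}

run_config_blocks <- c("optics", "grid", "pattern", "recon", "noise",
                       "output_dir", "verbosity")

#' Read a run configuration file (YAML or JSON)
#'
#' The file holds named blocks: `optics` (NA, refractive index, wavelengths,
#' voxel sizes), `grid` (shape), `pattern` (raw modulation `m`, anisotropy `r`
#' or ratio `t`, frequency fraction `f`, phase), `recon` ([recon_options()]
#' fields), `noise` (peak photons, seed), plus `output_dir` and `verbosity`.
#' Unknown top-level keys are rejected. A pattern frequency fraction `f >= 0.5`
#' triggers a warning: smaller fractions give the best optical sectioning.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON configuration file
#' @return named list of validated blocks
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, " (use YAML or JSON)")
  }
  unknown <- setdiff(names(cfg), run_config_blocks)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  f <- cfg$pattern$f
  if (!is.null(f) && f >= 0.5) {
    warning("pattern frequency fraction f = ", f, " is >= 0.5; values below ",
            "50% of the lateral cutoff give the best optical sectioning")
  }
  cfg
}
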