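#' Read and write detector images and height maps as text grids
#'
#' Portable plain-text storage: the 2-D array is written as a
#' whitespace-separated grid (one matrix row per line) and the acquisition
#' geometry goes in a JSON sidecar `<path>.json`. Detector sidecars carry
#' `distance_mm`, `wavelength_nm`, `pixel_size_mm`, `beam_center` and an
#' optional `mask_path` pointing at a 0/1 grid of the same shape; height
#' map sidecars carry `pixel_pitch_nm`.
#'
#' @param path grid file path.
#' @return `read_detector_image` returns a [detector_image()];
#'   `read_height_map` a [height_map()]; the writers return `path`
#'   invisibly.
#' @name grid_io
NULL

read_grid <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  m
}

write_grid <- function(m, path) {
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname grid_io
#' @export
read_detector_image <- function(path) {
  g <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  intensity <- read_grid(path)
  mask <- NULL
  if (!is.null(g$mask_path)) {
    mp <- file.path(dirname(path), g$mask_path)
    mask <- read_grid(mp) != 0
  }
  detector_image(intensity, beam_center = g$beam_center,
                 pixel_size_mm = g$pixel_size_mm,
                 distance_mm = g$distance_mm,
                 wavelength_nm = g$wavelength_nm, mask = mask)
}

#' @rdname grid_io
#' @param img a [detector_image()].
#' @export
write_detector_image <- function(img, path) {
  stopifnot(inherits(img, "detector_image"))
  write_grid(img$intensity, path)
  sidecar <- list(distance_mm = img$distance_mm,
                  wavelength_nm = img$wavelength_nm,
                  pixel_size_mm = img$pixel_size_mm,
                  beam_center = img$beam_center)
  if (any(img$mask)) {
    mask_path <- paste0(basename(path), ".mask")
    write_grid(img$mask * 1L, file.path(dirname(path), mask_path))
    sidecar$mask_path <- mask_path
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname grid_io
#' @export
read_height_map <- function(path) {
  g <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  height_map(read_grid(path), pixel_pitch_nm = g$pixel_pitch_nm)
}

#' @rdname grid_io
#' @param map a [height_map()].
#' @export
write_height_map <- function(map, path) {
  stopifnot(inherits(map, "height_map"))
  write_grid(map$height_nm, path)
  jsonlite::write_json(list(pixel_pitch_nm = map$pixel_pitch_nm),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
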