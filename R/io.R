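# Plain-format interchange: observations and admin membership as CSV,
# raster cubes as multi-band 32-bit float TIFF with a JSON sidecar naming
# the bands (the grid is abstract unit cells, so no georeferencing is
# carried). Values are affinely packed into [0, 1] for the TIFF container;
# the sidecar stores the offset/scale needed to unpack exactly.

#' Write an observation set to CSV
#' @param obs An `observation_set`.
#' @param path Output file path.
#' @export
write_observations <- function(obs, path) {
  validate_observations(obs)
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an observation set from CSV
#' @param path CSV file written by [write_observations()].
#' @return An `observation_set`.
#' @export
read_observations <- function(path) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  obs$cell_id <- as.integer(obs$cell_id)
  obs$polygon_id <- as.integer(obs$polygon_id)
  class(obs) <- c("observation_set", "data.frame")
  validate_observations(obs)
  obs
}

#' Write admin membership to CSV
#' @param grid A [grid_spec()].
#' @param path Output file path.
#' @export
write_membership <- function(grid, path) {
  utils::write.csv(grid$membership, path, row.names = FALSE)
  invisible(path)
}

#' Write a raster cube as multi-band TIFF plus JSON sidecar
#'
#' One TIFF band per (year, layer) pair; the sidecar (`<path>.json`) names
#' each band and records grid dimensions, years, layer names and the linear
#' packing (offset, scale) per band.
#'
#' @param cube A [raster_cube()].
#' @param path Output `.tif` path.
#' @export
write_raster_cube <- function(cube, path) {
  vals <- cube$values
  n_t <- dim(vals)[2L]; n_l <- dim(vals)[3L]
  grid <- cube$grid
  bands <- list(); meta <- list()
  b <- 0L
  for (l in seq_len(n_l)) for (t in seq_len(n_t)) {
    b <- b + 1L
    m <- matrix(vals[, t, l], grid$n_rows, grid$n_cols, byrow = TRUE)
    lo <- min(m); hi <- max(m)
    scale <- if (hi > lo) hi - lo else 1
    bands[[b]] <- (m - lo) / scale
    meta[[b]] <- list(band = b, layer = cube$layers[l],
                      year = grid$years[t], offset = lo, scale = scale)
  }
  tiff::writeTIFF(bands, path, bits.per.sample = 32L)
  sidecar <- list(n_rows = grid$n_rows, n_cols = grid$n_cols,
                  years = grid$years, layers = cube$layers, bands = meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raster cube written by [write_raster_cube()]
#'
#' @param path `.tif` path (sidecar expected at `<path>.json`).
#' @param grid A [grid_spec()] the cube must align to.
#' @return A [raster_cube()].
#' @export
read_raster_cube <- function(path, grid) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (sidecar$n_rows != grid$n_rows || sidecar$n_cols != grid$n_cols ||
      !identical(as.integer(sidecar$years), grid$years))
    stop("raster file does not match grid", call. = FALSE)
  bands <- tiff::readTIFF(path, all = TRUE)
  layers <- sidecar$layers
  n_t <- length(grid$years)
  vals <- array(NA_real_, c(grid$n_cells, n_t, length(layers)))
  for (i in seq_len(nrow(sidecar$bands))) {
    bi <- sidecar$bands[i, ]
    m <- bands[[bi$band]] * bi$scale + bi$offset
    l <- match(bi$layer, layers); t <- match(bi$year, grid$years)
    vals[, t, l] <- as.numeric(t(m))
  }
  raster_cube(vals, grid, layers)
}
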