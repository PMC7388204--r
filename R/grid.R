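#' Define an abstract modelling grid with nested administrative units
#'
#' The grid is a rectangular lattice of unit cells (row-major, 0-based cell
#' ids, distances between cell centres in cell units). Every cell belongs to
#' exactly one second-administrative unit (admin2), which nests in a
#' first-administrative unit (admin1), which nests in a country, which nests
#' in a modelling region. Models are fitted independently per region;
#' aggregation and inequality metrics operate on the admin hierarchy.
#'
#' @param n_rows,n_cols Grid dimensions (each at least 2).
#' @param years Ordered integer vector of modelled years.
#' @param n_countries Number of countries (vertical column bands).
#' @param admin1_per_country Admin1 units per country (horizontal row bands).
#' @param admin2_per_admin1 Admin2 units per admin1 (column sub-bands).
#' @param n_regions Number of modelling regions; countries are dealt to
#'   regions in contiguous blocks.
#' @return An object of class `grid_spec`: list with `n_rows`, `n_cols`,
#'   `n_cells`, `years`, a `membership` data frame
#'   (`cell_id`, `admin2_id`, `admin1_id`, `country_id`, `region_id`),
#'   and cell-centre coordinates `coords` (n_cells x 2, columns `x`, `y`).
#' @examples
#' g <- grid_spec(10, 10, years = 2000:2003)
#' head(g$membership)
#' @export
grid_spec <- function(n_rows = 30L, n_cols = 30L, years = 2000:2005,
                      n_countries = 3L, admin1_per_country = 4L,
                      admin2_per_admin1 = 4L, n_regions = 2L) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 2L || n_cols < 2L)
    stop("grid must have at least 2 rows and 2 columns", call. = FALSE)
  years <- as.integer(years)
  if (length(years) < 1L || is.unsorted(years, strictly = TRUE))
    stop("`years` must be a strictly increasing integer vector", call. = FALSE)
  if (n_countries > n_cols)
    stop("more countries than grid columns", call. = FALSE)
  if (n_regions > n_countries)
    stop("more regions than countries", call. = FALSE)

  n_cells <- n_rows * n_cols
  cell_id <- 0:(n_cells - 1L)
  row <- cell_id %/% n_cols
  col <- cell_id %% n_cols

  # contiguous integer banding: split `n` positions into `k` near-equal bands
  band <- function(pos, n, k) pmin(k - 1L, as.integer(floor(pos * k / n)))

  country <- band(col, n_cols, n_countries)
  region <- band(country, n_countries, n_regions)
  admin1_local <- band(row, n_rows, admin1_per_country)
  admin1 <- country * admin1_per_country + admin1_local
  # within a country's columns, sub-band columns into admin2 slots
  col0 <- col - as.integer(floor(country * n_cols / n_countries))
  ccols <- as.integer(floor((country + 1L) * n_cols / n_countries)) -
    as.integer(floor(country * n_cols / n_countries))
  admin2_local <- pmin(admin2_per_admin1 - 1L,
                       as.integer(floor(col0 * admin2_per_admin1 / ccols)))
  admin2 <- admin1 * admin2_per_admin1 + admin2_local

  membership <- data.frame(
    cell_id = cell_id,
    admin2_id = admin2,
    admin1_id = admin1,
    country_id = country,
    region_id = region
  )
  coords <- cbind(x = col + 0.5, y = row + 0.5)

  structure(
    list(n_rows = n_rows, n_cols = n_cols, n_cells = n_cells,
         years = years, membership = membership, coords = coords),
    class = "grid_spec"
  )
}

#' @method print grid_spec
#' @export
print.grid_spec <- function(x, ...) {
  m <- x$membership
  cat(sprintf("grid_spec: %d x %d cells, years %d-%d\n", x$n_rows, x$n_cols,
              min(x$years), max(x$years)))
  cat(sprintf("  %d regions / %d countries / %d admin1 / %d admin2\n",
              length(unique(m$region_id)), length(unique(m$country_id)),
              length(unique(m$admin1_id)), length(unique(m$admin2_id))))
  invisible(x)
}

# internal: validate that the admin hierarchy nests (admin2 in admin1 in
# country in region) and every cell appears exactly once
validate_membership <- function(membership, n_cells) {
  if (!setequal(membership$cell_id, 0:(n_cells - 1L)) ||
      anyDuplicated(membership$cell_id))
    stop("membership must cover every cell exactly once", call. = FALSE)
  for (pair in list(c("admin2_id", "admin1_id"), c("admin1_id", "country_id"),
                    c("country_id", "region_id"))) {
    parents <- tapply(membership[[pair[2L]]], membership[[pair[1L]]],
                      function(v) length(unique(v)))
    if (any(parents > 1L))
      stop(sprintf("%s does not nest within %s", pair[1L], pair[2L]),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a raster cube (cell x year x layer array)
#'
#' The package's gridded container: covariates, population, coverage truth
#' surfaces, diarrhoea episodes and mortality all live in cubes aligned to a
#' [grid_spec()].
#'
#' @param values Numeric array `n_cells x n_years x n_layers`, or a matrix
#'   (`n_cells x n_years`) for a single layer.
#' @param grid A [grid_spec()].
#' @param layers Character vector of layer names.
#' @return An object of class `raster_cube`.
#' @export
raster_cube <- function(values, grid, layers = NULL) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (dim(values)[1L] != grid$n_cells || dim(values)[2L] != length(grid$years))
    stop("cube dimensions do not match grid", call. = FALSE)
  if (is.null(layers)) layers <- sprintf("layer_%02d", seq_len(dim(values)[3L]))
  if (length(layers) != dim(values)[3L])
    stop("one name per layer required", call. = FALSE)
  dimnames(values) <- list(NULL, as.character(grid$years), layers)
  structure(list(values = values, grid = grid, layers = layers),
            class = "raster_cube")
}

#' Extract one layer of a raster cube as a cell x year matrix
#' @param cube A [raster_cube()].
#' @param layer Layer name or index.
#' @return Numeric matrix `n_cells x n_years`.
#' @export
cube_layer <- function(cube, layer = 1L) {
  stopifnot(inherits(cube, "raster_cube"))
  m <- cube$values[, , layer, drop = FALSE]
  dn <- dimnames(m)[1:2]
  dim(m) <- dim(m)[1:2]  # always cells x years, even for one year
  dimnames(m) <- dn
  m
}

#' @method print raster_cube
#' @export
print.raster_cube <- function(x, ...) {
  cat(sprintf("raster_cube: %d cells x %d years x %d layer(s)\n",
              dim(x$values)[1L], dim(x$values)[2L], dim(x$values)[3L]))
  cat("  layers:", paste(x$layers, collapse = ", "), "\n")
  invisible(x)
}
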