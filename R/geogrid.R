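#' Geo-referenced raster grid
#'
#' `geo_grid` is the raster carrier used throughout the package: a numeric
#' matrix of cell values (row 1 is the northernmost row, column 1 the
#' westernmost column) together with the geographic location of the grid's
#' upper-left corner, a square cell size in decimal degrees, and a nodata
#' sentinel used when the grid is written to GeoTIFF. Land cover, elevation,
#' slope, walking speed, crossing cost and travel time are all carried as
#' `geo_grid` objects sharing one geometry.
#'
#' Coordinates are WGS84 geographic (longitude/latitude). A point maps to the
#' cell containing it under half-open cell intervals `[edge, edge + cell_size)`
#' so facility snapping is deterministic.
#'
#' @param values Numeric matrix of cell values. `NA` marks nodata/impassable
#'   cells. Non-finite values other than `NA` are rejected.
#' @param origin_lon,origin_lat Longitude/latitude of the grid's upper-left
#'   corner, decimal degrees.
#' @param cell_size Cell edge length in decimal degrees; cells are square.
#' @param nodata Sentinel value used to encode `NA` on disk.
#'
#' @return An object of class `geo_grid`.
#' @examples
#' g <- geo_grid(matrix(1:12, 3, 4), origin_lon = 30, origin_lat = 0.5)
#' dim(g)
#' @export
geo_grid <- function(values, origin_lon = 0, origin_lat = 0,
                     cell_size = 20 / 111120, nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  g <- structure(
    list(
      values = values,
      origin_lon = as.numeric(origin_lon),
      origin_lat = as.numeric(origin_lat),
      cell_size = as.numeric(cell_size),
      nodata = as.numeric(nodata)
    ),
    class = "geo_grid"
  )
  validate_geo_grid(g)
}

validate_geo_grid <- function(g) {
  stopifnot(inherits(g, "geo_grid"))
  if (length(g$cell_size) != 1 || !is.finite(g$cell_size) || g$cell_size <= 0) {
    stop("cell_size must be a single positive number (square cells)", call. = FALSE)
  }
  if (!is.finite(g$origin_lon) || !is.finite(g$origin_lat)) {
    stop("grid origin must be finite", call. = FALSE)
  }
  bad <- !is.na(g$values) & !is.finite(g$values)
  if (any(bad)) {
    stop("grid values must be finite or NA (", sum(bad),
         " non-finite entries found)", call. = FALSE)
  }
  g
}

#' @export
dim.geo_grid <- function(x) dim(x$values)

#' @export
print.geo_grid <- function(x, ...) {
  d <- dim(x$values)
  n_na <- sum(is.na(x$values))
  cat(sprintf("<geo_grid> %d x %d cells, %.6g deg (~%.1f m) resolution\n",
              d[1], d[2], x$cell_size, degrees_to_metres(x$cell_size)))
  cat(sprintf("  origin (upper-left): %.6f, %.6f; NA cells: %d (%.1f%%)\n",
              x$origin_lon, x$origin_lat, n_na, 100 * n_na / length(x$values)))
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  if (all(is.finite(rng))) cat(sprintf("  value range: [%.6g, %.6g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
as.matrix.geo_grid <- function(x, ...) x$values

#' Bounding box in decimal degrees
#'
#' A rectangle used to clip facility sets to the study area; a lightweight
#' stand-in for an administrative boundary polygon.
#'
#' @param min_lon,min_lat,max_lon,max_lat Corner coordinates, decimal degrees.
#' @return An object of class `bounding_box`.
#' @export
bounding_box <- function(min_lon, min_lat, max_lon, max_lat) {
  if (!(min_lon < max_lon && min_lat < max_lat)) {
    stop("bounding box requires min < max on both axes", call. = FALSE)
  }
  structure(list(min_lon = min_lon, min_lat = min_lat,
                 max_lon = max_lon, max_lat = max_lat),
            class = "bounding_box")
}

#' Extent of a grid as a bounding box
#' @param grid A [geo_grid()].
#' @return A [bounding_box()] covering the grid.
#' @export
grid_extent <- function(grid) {
  d <- dim(grid$values)
  bounding_box(
    min_lon = grid$origin_lon,
    min_lat = grid$origin_lat - d[1] * grid$cell_size,
    max_lon = grid$origin_lon + d[2] * grid$cell_size,
    max_lat = grid$origin_lat
  )
}

#' Convert decimal degrees to metres
#'
#' Applies the single conversion factor 111120 m per degree on both axes.
#' This uniform equirectangular approximation is only accurate near the
#' equator, which is where the method is intended to be applied; no
#' latitude-dependent correction is made.
#'
#' @param delta Angular distance in decimal degrees.
#' @return Distance in metres.
#' @examples
#' degrees_to_metres(1)          # 111120
#' metres_to_degrees(20)         # a 20 m cell in degrees
#' @export
degrees_to_metres <- function(delta) delta * 111120

#' @rdname degrees_to_metres
#' @param metres Distance in metres.
#' @export
metres_to_degrees <- function(metres) metres / 111120

# Cell centre coordinates; rows top-down.
cell_centre_lon <- function(grid, col) grid$origin_lon + (col - 0.5) * grid$cell_size
cell_centre_lat <- function(grid, row) grid$origin_lat - (row - 0.5) * grid$cell_size

#' Locate points on a grid
#'
#' Maps longitude/latitude points to the (row, col) of the containing cell
#' under half-open cell intervals. Points outside the grid get `NA` indices.
#'
#' @param grid A [geo_grid()].
#' @param lon,lat Point coordinates, decimal degrees.
#' @return A tibble with columns `row`, `col` (NA outside the grid).
#' @export
point_to_cell <- function(grid, lon, lat) {
  d <- dim(grid$values)
  col <- floor((lon - grid$origin_lon) / grid$cell_size) + 1
  row <- floor((grid$origin_lat - lat) / grid$cell_size) + 1
  outside <- row < 1 | row > d[1] | col < 1 | col > d[2]
  row[outside] <- NA_integer_
  col[outside] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Bilinear resampling to a new cell size
#'
#' Resamples a grid to a target resolution over the same extent, interpolating
#' bilinearly between input cell centres (values beyond the outermost centres
#' are edge-replicated). Any interpolation touching an `NA` source cell yields
#' `NA`: elevations are never fabricated across voids.
#'
#' @param grid A [geo_grid()] of continuous values (e.g. a DEM).
#' @param target_cell_size New cell size in decimal degrees.
#' @return A [geo_grid()] covering the same extent at the new resolution.
#' @examples
#' dem <- geo_grid(matrix(100, 6, 6), cell_size = 30 / 111120)
#' fine <- resample_bilinear(dem, 20 / 111120)
#' dim(fine)  # 9 x 9
#' @export
resample_bilinear <- function(grid, target_cell_size) {
  stopifnot(target_cell_size > 0)
  d <- dim(grid$values)
  if (d[1] < 2 || d[2] < 2) {
    stop("bilinear resampling needs at least a 2 x 2 grid", call. = FALSE)
  }
  n_rows <- as.integer(round(d[1] * grid$cell_size / target_cell_size))
  n_cols <- as.integer(round(d[2] * grid$cell_size / target_cell_size))
  if (n_rows < 1 || n_cols < 1) stop("target cell size exceeds grid extent", call. = FALSE)

  # fractional source positions (in source cell-centre units) of output centres
  src_r <- ((seq_len(n_rows) - 0.5) * target_cell_size / grid$cell_size) + 0.5
  src_c <- ((seq_len(n_cols) - 0.5) * target_cell_size / grid$cell_size) + 0.5
  out <- bilinear_sample(grid$values, src_r, src_c)

  geo_grid(out, grid$origin_lon, grid$origin_lat, target_cell_size, grid$nodata)
}

# Sample matrix v at fractional (row, col) grids with edge clamping;
# NA in any contributing source cell -> NA.
bilinear_sample <- function(v, src_r, src_c) {
  d <- dim(v)
  r0 <- pmin(pmax(floor(src_r), 1), d[1] - 1)
  c0 <- pmin(pmax(floor(src_c), 1), d[2] - 1)
  fr <- pmin(pmax(src_r - r0, 0), 1)
  fc <- pmin(pmax(src_c - c0, 0), 1)

  R0 <- matrix(r0, length(src_r), length(src_c))
  C0 <- matrix(c0, length(src_r), length(src_c), byrow = TRUE)
  FR <- matrix(fr, length(src_r), length(src_c))
  FC <- matrix(fc, length(src_r), length(src_c), byrow = TRUE)

  idx <- function(r, c) v[cbind(as.vector(r), as.vector(c))]
  v00 <- idx(R0, C0); v01 <- idx(R0, C0 + 1)
  v10 <- idx(R0 + 1, C0); v11 <- idx(R0 + 1, C0 + 1)
  # incremental form: exact on constant fields
  top <- v00 + as.vector(FC) * (v01 - v00)
  bottom <- v10 + as.vector(FC) * (v11 - v10)
  out <- top + as.vector(FR) * (bottom - top)
  matrix(out, length(src_r), length(src_c))
}

#' Align a grid to a reference geometry
#'
#' Re-grids `grid` onto the shape, origin and cell size of `reference`.
#' Categorical layers (land cover) use nearest-neighbour assignment;
#' continuous layers (elevation) use bilinear interpolation. Reference cells
#' whose centres fall outside `grid` become `NA`.
#'
#' @param grid A [geo_grid()] to re-grid.
#' @param reference A [geo_grid()] supplying the target geometry.
#' @param method `"nearest"` for categorical grids, `"bilinear"` for
#'   continuous grids.
#' @return A [geo_grid()] with `reference`'s geometry.
#' @export
align_to <- function(grid, reference, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  ge <- grid_extent(grid); re <- grid_extent(reference)
  if (ge$max_lon <= re$min_lon || re$max_lon <= ge$min_lon ||
      ge$max_lat <= re$min_lat || re$max_lat <= ge$min_lat) {
    stop("grids do not overlap spatially", call. = FALSE)
  }
  d_ref <- dim(reference$values)
  lon <- cell_centre_lon(reference, seq_len(d_ref[2]))
  lat <- cell_centre_lat(reference, seq_len(d_ref[1]))
  # positions in source cell-centre units
  src_c <- (lon - grid$origin_lon) / grid$cell_size + 0.5
  src_r <- (grid$origin_lat - lat) / grid$cell_size + 0.5

  d <- dim(grid$values)
  out <- if (method == "nearest") {
    rr <- round(src_r); cc <- round(src_c)
    rr[rr < 1 | rr > d[1]] <- NA; cc[cc < 1 | cc > d[2]] <- NA
    R <- matrix(rr, d_ref[1], d_ref[2])
    C <- matrix(cc, d_ref[1], d_ref[2], byrow = TRUE)
    vals <- rep(NA_real_, length(R))
    ok <- !is.na(R) & !is.na(C)
    vals[ok] <- grid$values[cbind(as.vector(R)[ok], as.vector(C)[ok])]
    matrix(vals, d_ref[1], d_ref[2])
  } else {
    inside_r <- src_r >= 0.5 & src_r <= d[1] + 0.5
    inside_c <- src_c >= 0.5 & src_c <= d[2] + 0.5
    m <- bilinear_sample(grid$values, src_r, src_c)
    m[!inside_r, ] <- NA
    m[, !inside_c] <- NA
    m
  }
  geo_grid(out, reference$origin_lon, reference$origin_lat,
           reference$cell_size, reference$nodata)
}

#' Long-form view of a grid
#'
#' @param x A [geo_grid()].
#' @param ... Unused.
#' @return A tibble with one row per cell: `row`, `col`, `lon`, `lat`
#'   (cell centres) and `value`.
#' @export
tidy.geo_grid <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    lon = cell_centre_lon(x, rep(seq_len(d[2]), each = d[1])),
    lat = cell_centre_lat(x, rep(seq_len(d[1]), times = d[2])),
    value = as.vector(x$values)
  )
}

#' @export
as_tibble.geo_grid <- function(x, ...) tidy.geo_grid(x, ...)
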