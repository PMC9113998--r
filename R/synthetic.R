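#' Synthetic scenes
#'
#' Deterministic generators of small toy scenes — DEM, land cover, roads and
#' facilities on a shared 20 m grid near the equator (where the uniform
#' degree-to-metre factor is valid) — exercising every branch of the
#' pipeline without any data downloads: uniform plains, lake/island
#' water-barrier scenes, and random landscapes with relief, blocky land
#' cover and an L-shaped two-category road.
#'
#' @param n Grid side length in cells.
#' @param speed_class Land-cover class code for the uniform scene.
#' @param seed Integer seed; the same seed always yields a byte-identical
#'   scene.
#' @param relief Total elevation range in metres for the random DEM
#'   (0 = flat).
#' @param n_facilities Number of random facilities in the random scene.
#' @return A `scene`: list with `dem`, `landcover` ([geo_grid()]s sharing
#'   one geometry), `roads` ([road_layer()]), `facilities` (tibble) and
#'   `description`.
#' @name synthetic_scenes
NULL

scene_grid <- function(n, values) {
  geo_grid(values, origin_lon = 30, origin_lat = 0.5,
           cell_size = metres_to_degrees(20))
}

new_scene <- function(dem, landcover, roads, facilities, description) {
  structure(list(dem = dem, landcover = landcover, roads = roads,
                 facilities = facilities, description = description),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat("<scene>", x$description, "\n")
  cat(sprintf("  %d x %d cells, %d road feature(s), %d facility(ies)\n",
              nrow(x$landcover$values), ncol(x$landcover$values),
              nrow(x$roads), nrow(x$facilities)))
  invisible(x)
}

# facility point at the centre of cell (row, col)
facility_at_cell <- function(grid, row, col, id, type = "clinic") {
  tibble::tibble(id = id,
                 lon = cell_centre_lon(grid, col),
                 lat = cell_centre_lat(grid, row),
                 type = type)
}

#' @rdname synthetic_scenes
#' @export
make_uniform_scene <- function(n = 9, speed_class = 3) {
  if (n < 3) stop("uniform scene needs n >= 3", call. = FALSE)
  lc <- scene_grid(n, matrix(as.numeric(speed_class), n, n))
  dem <- scene_grid(n, matrix(0, n, n))
  centre <- (n + 1) %/% 2
  fac <- facility_at_cell(lc, centre, centre, "F1")
  new_scene(dem, lc, road_layer(), fac,
            sprintf("uniform class-%s plain, flat, one central facility",
                    speed_class))
}

#' @rdname synthetic_scenes
#' @export
make_island_scene <- function(n = 15) {
  if (n < 9) stop("island scene needs n >= 9", call. = FALSE)
  lc <- matrix(3, n, n)                    # grassland mainland
  # island block in the upper-left, enclosed by a water ring (class 10)
  isl <- 2:floor(n / 3 + 1)
  ring <- c(min(isl) - 1, max(isl) + 1)
  lc[min(ring):max(ring), min(ring):max(ring)] <- 10
  lc[isl, isl] <- 3
  lc[1, 1:max(ring)] <- 10                 # extend water to the grid edge
  lc[1:max(ring), 1] <- 10
  grid <- scene_grid(n, lc)
  dem <- scene_grid(n, matrix(0, n, n))
  fac <- facility_at_cell(grid, n - 1, n - 1, "F1")
  new_scene(dem, grid, road_layer(), fac,
            "island separated from the mainland facility by a water ring")
}

#' @rdname synthetic_scenes
#' @export
make_random_scene <- function(n = 16, seed = 1L, relief = 50,
                              n_facilities = 3) {
  if (n < 8) stop("random scene needs n >= 8", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    # smooth random DEM: white noise, 3x3 mean filter, scaled to the relief
    noise <- matrix(stats::runif(n * n), n, n)
    sm <- smooth3(noise)
    if (relief > 0 && diff(range(sm)) > 0) {
      dem_vals <- (sm - min(sm)) / diff(range(sm)) * relief
    } else {
      dem_vals <- matrix(0, n, n)
    }
    # blocky land cover: coarse 4x4-cell blocks of passable classes
    block <- 4
    nb <- ceiling(n / block)
    classes <- c(1, 2, 3, 4, 6, 7, 8)
    coarse <- matrix(sample(classes, nb * nb, replace = TRUE), nb, nb)
    lc_vals <- coarse[ceiling(seq_len(n) / block), ceiling(seq_len(n) / block)]

    grid <- scene_grid(n, lc_vals)
    dem <- scene_grid(n, dem_vals)

    # L-shaped road of two categories along mid row / mid column
    mid <- n %/% 2
    lon_mid <- cell_centre_lon(grid, mid)
    lat_mid <- cell_centre_lat(grid, mid)
    roads <- road_layer(
      list(
        cbind(c(cell_centre_lon(grid, 1), lon_mid), c(lat_mid, lat_mid)),
        cbind(c(lon_mid, lon_mid), c(lat_mid, cell_centre_lat(grid, n)))
      ),
      c("primary", "path")
    )

    rows <- sample.int(n, n_facilities, replace = TRUE)
    cols <- sample.int(n, n_facilities, replace = TRUE)
    fac <- dplyr::bind_rows(lapply(seq_len(n_facilities), function(i) {
      facility_at_cell(grid, rows[i], cols[i], paste0("F", i),
                       type = sample(c("clinic", "hospital"), 1))
    }))
  })
  new_scene(dem, grid, roads, fac,
            sprintf("random landscape, %g m relief, seed %d", relief, seed))
}

# 3x3 mean filter with edge replication
smooth3 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  pad <- m[c(1, 1:n1, n1), c(1, 1:n2, n2)]
  out <- matrix(0, n1, n2)
  for (dr in 0:2) for (dc in 0:2) {
    out <- out + pad[dr + 1:n1, dc + 1:n2]
  }
  out / 9
}

#' Write a scene to disk
#'
#' Dumps a scene as files the command-line interface can consume: land
#' cover and DEM as GeoTIFF, roads as GeoJSON, facilities as CSV.
#'
#' @param scene A scene from one of the generators.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    landcover = file.path(dir, "landcover.tif"),
    dem = file.path(dir, "dem.tif"),
    roads = file.path(dir, "roads.geojson"),
    facilities = file.path(dir, "facilities.csv")
  )
  write_geotiff(scene$landcover, paths$landcover)
  write_geotiff(scene$dem, paths$dem)
  write_roads_geojson(scene$roads, paths$roads)
  write_facilities(scene$facilities, paths$facilities)
  invisible(paths)
}
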