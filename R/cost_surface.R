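#' Land-cover class speeds
#'
#' Maps a categorical land-cover grid to walking speeds. Open water
#' (class 10) is the special case that drives the two-pass travel-time rule:
#' in `"blocked"` mode it becomes `NA` (a hard barrier, so island
#' populations register as unreachable in the first pass), in `"passable"`
#' mode it carries `water_speed` so crossings are possible where they are the
#' only option. The nodata class (200) and any class whose table speed is
#' `NA` (e.g. often-flooded ground) are barriers in both modes.
#'
#' @param lc A [geo_grid()] of land-cover class codes.
#' @param table A land-cover [speed_table()] keyed by class code.
#' @param water_mode `"blocked"` or `"passable"`.
#' @param water_speed Speed over open water in passable mode, km/h.
#' @param water_class Class code for open water.
#' @return A [geo_grid()] of km/h, `NA` where impassable.
#' @export
speeds_from_landcover <- function(lc, table = default_landcover_speeds(),
                                  water_mode = c("blocked", "passable"),
                                  water_speed = 1.0, water_class = 10) {
  water_mode <- match.arg(water_mode)
  codes <- lc$values
  seen <- sort(unique(codes[!is.na(codes)]))
  known <- as.numeric(table$category)
  unknown <- setdiff(seen, known)
  if (length(unknown) > 0) {
    stop("land-cover codes missing from the speed table: ",
         toString(unknown), call. = FALSE)
  }
  sp <- table$speed[match(codes, known)]
  water <- !is.na(codes) & codes == water_class
  sp[water] <- if (water_mode == "passable") water_speed else NA_real_
  out <- matrix(sp, nrow(codes), ncol(codes))
  geo_grid(out, lc$origin_lon, lc$origin_lat, lc$cell_size, lc$nodata)
}

#' Overlay road speeds on land-cover speeds
#'
#' Road walking speeds take precedence; cells without a road fall back to
#' the land-cover speed. Because roads are laid down first, a road crossing
#' open water stays passable even in the water-blocked surface (a bridge).
#'
#' @param road_speeds A [geo_grid()] of km/h from [rasterize_roads()]
#'   (`NA` off-road).
#' @param landcover_speeds A [geo_grid()] of km/h from
#'   [speeds_from_landcover()].
#' @return A [geo_grid()] of km/h.
#' @export
overlay_speeds <- function(road_speeds, landcover_speeds) {
  check_aligned(road_speeds, landcover_speeds)
  v <- road_speeds$values
  fill <- is.na(v)
  v[fill] <- landcover_speeds$values[fill]
  geo_grid(v, landcover_speeds$origin_lon, landcover_speeds$origin_lat,
           landcover_speeds$cell_size, landcover_speeds$nodata)
}

check_aligned <- function(a, b) {
  if (!all(dim(a$values) == dim(b$values)) ||
      abs(a$origin_lon - b$origin_lon) > 1e-12 ||
      abs(a$origin_lat - b$origin_lat) > 1e-12 ||
      abs(a$cell_size - b$cell_size) > 1e-15) {
    stop("grids are not aligned (shape/origin/cell size differ)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Assemble a cost allocation surface
#'
#' Converts a walking-speed grid into the seconds needed to cross each cell:
#'
#' `seconds = cell_size_m / (speed_m_per_s * slope_impact * child_factor)`
#'
#' where speeds in km/h are converted to m/s (x 1000/3600) at this step, the
#' slope impact is the return-trip multiplier from [impact_grid()], and the
#' child factor uniformly reduces all speeds (default 0.78). `NA` in either
#' input — open water in blocked mode, slopes over 100%, nodata — makes the
#' cell impassable; an impassable slope dominates even on a road.
#'
#' @param speeds A [geo_grid()] of km/h from [overlay_speeds()].
#' @param impact A [geo_grid()] of slope-impact multipliers; pass `NULL` for
#'   flat terrain (impact 1 everywhere).
#' @param config A [run_config()] supplying `child_factor`, `water_speed`
#'   and `cell_size_m`.
#' @param water_mode `"blocked"` or `"passable"`; recorded as provenance.
#' @return A `cost_surface`: the seconds [geo_grid()] plus the water mode,
#'   child factor, water speed and cell size that produced it.
#' @examples
#' sp <- geo_grid(matrix(5, 3, 3))
#' s <- assemble_cost_surface(sp, NULL, run_config(child_factor = 1))
#' as.matrix(s$grid)[1, 1]   # 14.4 s to cross a 20 m cell at 5 km/h
#' @export
assemble_cost_surface <- function(speeds, impact = NULL,
                                  config = run_config(),
                                  water_mode = c("blocked", "passable")) {
  water_mode <- match.arg(water_mode)
  if (is.null(impact)) {
    impact <- geo_grid(matrix(1, nrow(speeds$values), ncol(speeds$values)),
                       speeds$origin_lon, speeds$origin_lat,
                       speeds$cell_size, speeds$nodata)
  }
  check_aligned(speeds, impact)
  sp <- speeds$values
  im <- impact$values
  bad <- (!is.na(sp) & sp <= 0) | (!is.na(im) & im <= 0)
  if (any(bad)) stop("speeds and impacts must be positive", call. = FALSE)

  speed_ms <- sp * 1000 / 3600
  seconds <- config$cell_size_m / (speed_ms * im * config$child_factor)
  grid <- geo_grid(seconds, speeds$origin_lon, speeds$origin_lat,
                   speeds$cell_size, speeds$nodata)
  structure(list(
    grid = grid,
    water_mode = water_mode,
    child_factor = config$child_factor,
    water_speed = config$water_speed,
    cell_size_m = config$cell_size_m
  ), class = "cost_surface")
}

#' @export
print.cost_surface <- function(x, ...) {
  cat(sprintf("<cost_surface> water %s; child factor %.2f; water speed %.2f km/h; %g m cells\n",
              x$water_mode, x$child_factor, x$water_speed, x$cell_size_m))
  print(x$grid)
  invisible(x)
}

#' Build both cost allocation surfaces for a scene
#'
#' Convenience wrapper running the full surface construction: land-cover
#' speeds in both water modes, road rasterization and overlay, slope and
#' slope impact from the DEM, and assembly of the water-blocked and
#' water-passable surfaces.
#'
#' @param landcover A [geo_grid()] of land-cover class codes (the reference
#'   geometry).
#' @param dem A [geo_grid()] of elevations in metres, aligned to
#'   `landcover`; `NULL` for flat terrain.
#' @param roads A [road_layer()]; `NULL` or empty for a roadless scene.
#' @param config A [run_config()].
#' @param landcover_table,road_table Speed tables; defaults are the built-in
#'   tables.
#' @return A list with elements `blocked` and `passable` (both
#'   [assemble_cost_surface()] results), `slope`, `impact` and `speeds`
#'   grids.
#' @export
build_cost_surfaces <- function(landcover, dem = NULL, roads = NULL,
                                config = run_config(),
                                landcover_table = default_landcover_speeds(),
                                road_table = default_road_speeds()) {
  impact <- NULL
  slope <- NULL
  if (!is.null(dem)) {
    slope <- slope_percent(dem)
    impact <- impact_grid(slope)
  }
  road_grid <- NULL
  if (!is.null(roads) && nrow(roads) > 0) {
    tag_speeds <- resolve_tag_speeds(roads$tag, road_table)
    road_grid <- rasterize_roads(roads, tag_speeds, landcover)
  } else {
    road_grid <- geo_grid(matrix(NA_real_, nrow(landcover$values),
                                 ncol(landcover$values)),
                          landcover$origin_lon, landcover$origin_lat,
                          landcover$cell_size, landcover$nodata)
  }
  surfaces <- lapply(c(blocked = "blocked", passable = "passable"), function(mode) {
    lc_speeds <- speeds_from_landcover(landcover, landcover_table,
                                       water_mode = mode,
                                       water_speed = config$water_speed)
    sp <- overlay_speeds(road_grid, lc_speeds)
    assemble_cost_surface(sp, impact, config, water_mode = mode)
  })
  list(blocked = surfaces$blocked, passable = surfaces$passable,
       slope = slope, impact = impact, road_speeds = road_grid)
}
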