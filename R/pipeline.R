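#' Configuration-driven pipeline commands
#'
#' The pipeline runs in two steps, each driven by the same INI-style
#' configuration file: `cmd_cost_surface()` builds the water-blocked and
#' water-passable cost allocation surfaces from land cover, DEM and roads;
#' `cmd_travel_time()` runs the two-pass least-cost analysis from those
#' surfaces and the facility table. `cmd_run_all()` composes the two. Each
#' command writes its outputs plus a JSON run manifest recording every input
#' path, parameter value and the seed, sufficient to reproduce the run.
#'
#' Recognised `[inputs]` keys: `landcover`, `dem` (optional), `roads`
#' (optional GeoJSON), `facilities`. `[outputs]` keys: `blocked`,
#' `passable`, `travel_time`, `facility_report`, `manifest_dir` (defaults
#' derived from `dir`). `[parameters]`: `child_factor`, `water_speed`,
#' `cell_size_m`, `max_speed`, `rng_seed`, `facility_types`
#' (comma-separated filter, empty = any type).
#'
#' @param config_path Path to the configuration file.
#' @return Invisibly, a named list of written output paths.
#' @name pipeline
NULL

config_output <- function(config, key, default) {
  config$outputs[[key]] %||% default
}

config_input <- function(config, key, required = TRUE) {
  p <- config$inputs[[key]]
  if (is.null(p)) {
    if (required) stop("config is missing required input '", key, "'", call. = FALSE)
    return(NULL)
  }
  if (!file.exists(p)) stop("input '", key, "' not found: ", p, call. = FALSE)
  p
}

write_manifest <- function(path, config, inputs, outputs, extra = list()) {
  manifest <- c(list(
    inputs = inputs,
    outputs = outputs,
    parameters = list(
      child_factor = config$child_factor,
      water_speed = config$water_speed,
      cell_size_m = config$cell_size_m,
      max_speed = config$max_speed,
      rng_seed = config$rng_seed
    ),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline
#' @export
cmd_cost_surface <- function(config_path) {
  config <- load_run_config(config_path)
  lc_path <- config_input(config, "landcover")
  dem_path <- config_input(config, "dem", required = FALSE)
  roads_path <- config_input(config, "roads", required = FALSE)
  out_dir <- config_output(config, "dir", dirname(config_path))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  landcover <- read_geotiff(lc_path)
  dem <- NULL
  if (!is.null(dem_path)) {
    dem <- read_geotiff(dem_path)
    if (abs(dem$cell_size - landcover$cell_size) > 1e-15 ||
        !all(dim(dem$values) == dim(landcover$values))) {
      dem <- align_to(resample_bilinear(dem, landcover$cell_size),
                      landcover, method = "bilinear")
    }
  }
  roads <- if (!is.null(roads_path)) read_roads_geojson(roads_path) else NULL

  lc_table <- if (!is.null(config$inputs$landcovercosts)) {
    load_speed_table(config$inputs$landcovercosts, "landcover")
  } else default_landcover_speeds()
  rd_table <- if (!is.null(config$inputs$roadcosts)) {
    load_speed_table(config$inputs$roadcosts, "road")
  } else default_road_speeds()

  surfaces <- build_cost_surfaces(landcover, dem, roads, config,
                                  lc_table, rd_table)

  paths <- list(
    blocked = config_output(config, "blocked", file.path(out_dir, "cost_blocked.tif")),
    passable = config_output(config, "passable", file.path(out_dir, "cost_passable.tif")),
    manifest = file.path(out_dir, "cost_surface_manifest.json")
  )
  write_geotiff(surfaces$blocked$grid, paths$blocked)
  write_geotiff(surfaces$passable$grid, paths$passable)
  write_manifest(paths$manifest, config,
                 inputs = list(landcover = lc_path, dem = dem_path,
                               roads = roads_path),
                 outputs = paths[c("blocked", "passable")],
                 extra = list(step = "cost_surface"))
  message("cost surfaces written: ", paths$blocked, ", ", paths$passable)
  invisible(paths)
}

#' @rdname pipeline
#' @export
cmd_travel_time <- function(config_path) {
  config <- load_run_config(config_path)
  out_dir <- config_output(config, "dir", dirname(config_path))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  blocked_path <- config_output(config, "blocked",
                                file.path(out_dir, "cost_blocked.tif"))
  passable_path <- config_output(config, "passable",
                                 file.path(out_dir, "cost_passable.tif"))
  for (p in c(blocked_path, passable_path)) {
    if (!file.exists(p)) stop("cost surface not found (run the cost-surface ",
                              "step first): ", p, call. = FALSE)
  }
  fac_path <- config_input(config, "facilities")

  as_surface <- function(path, mode) {
    structure(list(grid = read_geotiff(path), water_mode = mode,
                   child_factor = config$child_factor,
                   water_speed = config$water_speed,
                   cell_size_m = config$cell_size_m),
              class = "cost_surface")
  }
  blocked <- as_surface(blocked_path, "blocked")
  passable <- as_surface(passable_path, "passable")
  facilities <- load_facilities(fac_path)
  wanted <- config$facility_types

  result <- travel_time_map(blocked, passable, facilities,
                            wanted_types = wanted,
                            rng_seed = config$rng_seed)

  paths <- list(
    travel_time = config_output(config, "travel_time",
                                file.path(out_dir, "travel_time_minutes.tif")),
    facility_report = config_output(config, "facility_report",
                                    file.path(out_dir, "facility_report.csv")),
    manifest = file.path(out_dir, "travel_time_manifest.json")
  )
  write_geotiff(result$minutes, paths$travel_time)
  write_facility_report(result$report, paths$facility_report)
  write_manifest(paths$manifest, config,
                 inputs = list(blocked = blocked_path, passable = passable_path,
                               facilities = fac_path),
                 outputs = paths[c("travel_time", "facility_report")],
                 extra = list(step = "travel_time",
                              facility_types = as.list(wanted)))
  message("travel-time map written: ", paths$travel_time)
  invisible(paths)
}

#' @rdname pipeline
#' @export
cmd_run_all <- function(config_path) {
  p1 <- cmd_cost_surface(config_path)
  p2 <- cmd_travel_time(config_path)
  invisible(c(p1, p2))
}

#' @rdname pipeline
#' @param dir Output directory for the generated fixture scene.
#' @param scene Scene name: `"uniform"`, `"island"` or `"random"`.
#' @param n Grid side length.
#' @param seed Seed for the random scene.
#' @export
cmd_make_fixture <- function(dir, scene = c("random", "uniform", "island"),
                             n = 16, seed = 1L) {
  scene <- match.arg(scene)
  sc <- switch(scene,
    uniform = make_uniform_scene(n),
    island = make_island_scene(max(n, 9)),
    random = make_random_scene(n, seed = seed)
  )
  paths <- write_scene(sc, dir)
  cfg <- file.path(dir, "run.cfg")
  writeLines(c(
    "[inputs]",
    paste0("landcover = ", paths$landcover),
    paste0("dem = ", paths$dem),
    paste0("roads = ", paths$roads),
    paste0("facilities = ", paths$facilities),
    "[outputs]",
    paste0("dir = ", dir),
    "[parameters]",
    "child_factor = 0.78",
    "water_speed = 1.0",
    "cell_size_m = 20",
    paste0("rng_seed = ", as.integer(seed))
  ), cfg)
  message("fixture scene '", scene, "' written under ", dir)
  invisible(c(paths, list(config = cfg)))
}
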