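#' Walking-speed lookup tables
#'
#' A speed table maps a category — an OpenStreetMap-style road class such as
#' `"trunk"` or a numeric land-cover class code — to a pedestrian walking
#' speed in km/h. `NA` speeds mark categories that are barriers to travel
#' (open water in the blocked surface, permanently flooded ground, missing
#' data). Speeds must be positive and no faster than `max_speed`, the 5 km/h
#' ceiling commonly used for adult walking.
#'
#' `default_landcover_speeds()` and `default_road_speeds()` return the
#' built-in tables: nine 20 m land-cover classes (plus the nodata code 200)
#' and the merged OSM road taxonomy, with the fastest speeds on trunk-grade
#' roads where pedestrians preferentially walk.
#'
#' @param entries A data frame with columns `category` and `speed` (km/h,
#'   `NA` allowed).
#' @param kind `"road"` or `"landcover"`.
#' @param max_speed Maximum admissible walking speed, km/h.
#' @return A `speed_table`: a tibble with columns `category` and `speed` and
#'   attributes `kind` and `max_speed`.
#' @examples
#' default_landcover_speeds()
#' speed_table(data.frame(category = "trunk", speed = 5), kind = "road")
#' @export
speed_table <- function(entries, kind = c("road", "landcover"), max_speed = 5) {
  kind <- match.arg(kind)
  entries <- tibble::as_tibble(entries)
  if (!all(c("category", "speed") %in% names(entries))) {
    stop("speed table needs columns 'category' and 'speed'", call. = FALSE)
  }
  entries$category <- as.character(entries$category)
  entries$speed <- as.numeric(entries$speed)
  dup <- unique(entries$category[duplicated(entries$category)])
  if (length(dup) > 0) {
    stop("duplicate categories in speed table: ", toString(dup), call. = FALSE)
  }
  bad <- !is.na(entries$speed) & entries$speed <= 0
  if (any(bad)) {
    stop("non-positive speeds for: ", toString(entries$category[bad]), call. = FALSE)
  }
  fast <- !is.na(entries$speed) & entries$speed > max_speed
  if (any(fast)) {
    stop("speeds above the ", max_speed, " km/h maximum for: ",
         toString(entries$category[fast]), call. = FALSE)
  }
  structure(entries[, c("category", "speed")],
            kind = kind, max_speed = max_speed,
            class = c("speed_table", class(entries)))
}

#' @rdname speed_table
#' @export
default_landcover_speeds <- function() {
  speed_table(tibble::tibble(
    category = c("1", "2", "3", "4", "5", "6", "7", "8", "10", "200"),
    speed    = c(1.5, 1.5, 3.0, 3.0, NA, 3.0, 1.15, 1.5, 1.0, NA)
  ), kind = "landcover")
}

#' @rdname speed_table
#' @export
default_road_speeds <- function() {
  speed_table(tibble::tibble(
    category = c("motorway", "motorway_link", "trunk", "trunk_link",
                 "primary", "primary_link", "secondary", "secondary_link",
                 "tertiary", "tertiary_link", "residential", "unclassified",
                 "track", "track_grade1-5", "service", "bridleway",
                 "cycleway", "living_street", "pedestrian", "path",
                 "footway", "steps", "unknown"),
    speed    = c(5.0, 5.0, 5.0, 5.0,
                 5.0, 5.0, 4.5, 4.5,
                 4.5, 4.5, 4.0, 3.5,
                 3.5, 3.5, 3.5, 3.5,
                 3.5, 4.0, 4.0, 3.5,
                 3.5, 3.5, 3.5)
  ), kind = "road")
}

#' Load a speed table from CSV
#'
#' Reads a two-column CSV (`category`, `speed`) such as the road-cost and
#' land-cover-cost files that configure a run. Empty speed fields and the
#' literal strings `NA`/`N/A` load as barriers.
#'
#' @param path CSV file path.
#' @inheritParams speed_table
#' @return A [speed_table()].
#' @export
load_speed_table <- function(path, kind = c("road", "landcover"), max_speed = 5) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("speed table not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = c("", "NA", "N/A"))
  names(df) <- tolower(names(df))
  if (!all(c("category", "speed") %in% names(df))) {
    stop("speed table CSV needs columns 'category' and 'speed': ", path, call. = FALSE)
  }
  sp <- suppressWarnings(as.numeric(df$speed))
  unparseable <- !is.na(df$speed) & is.na(sp)
  if (any(unparseable)) {
    stop("unparseable speeds in ", path, " for: ",
         toString(df$category[unparseable]), call. = FALSE)
  }
  speed_table(tibble::tibble(category = df$category, speed = sp),
              kind = kind, max_speed = max_speed)
}

#' Write a speed table to CSV
#' @param table A [speed_table()].
#' @param path Output CSV path.
#' @export
write_speed_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table)[, c("category", "speed")], path)
  invisible(path)
}

#' Apply the child walking-speed reduction
#'
#' Walking speeds are reduced multiplicatively to represent adults travelling
#' with children: observed speeds drop by roughly 22% when an adult carries
#' or is accompanied by a child, giving the default factor 0.78. Barriers
#' (`NA`) stay barriers.
#'
#' @param speed Speed(s) in km/h, `NA` allowed.
#' @param child_factor Multiplier in (0, 1]; 1 reproduces adult speeds.
#' @return Weighted speed(s) in km/h.
#' @examples
#' child_weight(3.0)        # grassland: 2.34 km/h
#' child_weight(1.5)        # trees: 1.17 km/h
#' child_weight(5, child_factor = 1)
#' @export
child_weight <- function(speed, child_factor = 0.78) {
  if (!(length(child_factor) == 1 && is.finite(child_factor) &&
        child_factor > 0 && child_factor <= 1)) {
    stop("child_factor must be a single value in (0, 1]", call. = FALSE)
  }
  speed * child_factor
}

#' Fuzzy-match layer categories against a speed table
#'
#' Road layers assembled from multiple sources rarely spell their categories
#' exactly as the speed table does. Categories are first normalised
#' (lower-cased, trimmed, internal whitespace and hyphen/underscore variants
#' collapsed); each layer category then maps to the most similar table
#' category, scored 0-100 by normalised Levenshtein similarity. Categories
#' scoring below `threshold` are reported as unmatched (and downstream get
#' the `"unknown"` road speed).
#'
#' @param table_categories Character vector of table categories.
#' @param layer_categories Character vector of categories found in the layer.
#' @param threshold Minimum similarity in \[0, 100\] for a match; at 100 only
#'   (normalised) exact matches survive.
#' @return A list with `mapping` (tibble: `layer`, `table`, `similarity`) and
#'   `unmatched` (character vector).
#' @examples
#' fuzzy_match_categories(c("trunk", "path"), c("Trunk ", "zzz_road"))
#' @export
fuzzy_match_categories <- function(table_categories, layer_categories,
                                   threshold = 80) {
  stopifnot(length(table_categories) > 0, length(layer_categories) > 0)
  norm <- function(x) {
    x <- stringr::str_to_lower(stringr::str_trim(x))
    x <- stringr::str_replace_all(x, "[\\s]+", " ")
    stringr::str_replace_all(x, "[-_]", "_")
  }
  tn <- norm(table_categories)
  layer_categories <- unique(layer_categories)
  ln <- norm(layer_categories)
  d <- utils::adist(ln, tn)
  maxlen <- outer(nchar(ln), nchar(tn), pmax)
  sim <- 100 * (1 - d / pmax(maxlen, 1))
  best <- apply(sim, 1, which.max)
  best_sim <- sim[cbind(seq_along(ln), best)]
  hit <- best_sim >= threshold
  list(
    mapping = tibble::tibble(
      layer = layer_categories[hit],
      table = table_categories[best[hit]],
      similarity = best_sim[hit]
    ),
    unmatched = layer_categories[!hit]
  )
}

#' Resolve road-layer tags to speeds
#'
#' Combines [fuzzy_match_categories()] with the `"unknown"` fallback: every
#' tag present in the layer receives a speed, either from its matched table
#' row or from the table's `"unknown"` entry.
#'
#' @param tags Character vector of tags appearing in a road layer.
#' @param table A road [speed_table()].
#' @param threshold Fuzzy-match threshold, see [fuzzy_match_categories()].
#' @return A named numeric vector of speeds (km/h), one per unique tag.
#' @export
resolve_tag_speeds <- function(tags, table, threshold = 80) {
  tags <- unique(tags)
  m <- fuzzy_match_categories(table$category, tags, threshold)
  speeds <- stats::setNames(rep(NA_real_, length(tags)), tags)
  if (nrow(m$mapping) > 0) {
    speeds[m$mapping$layer] <-
      table$speed[match(m$mapping$table, table$category)]
  }
  if (length(m$unmatched) > 0) {
    fallback <- table$speed[table$category == "unknown"]
    if (length(fallback) != 1) {
      stop("unmatched road categories (", toString(m$unmatched),
           ") and no 'unknown' fallback row in the speed table", call. = FALSE)
    }
    speeds[m$unmatched] <- fallback
    message("road categories matched to 'unknown' fallback: ",
            toString(m$unmatched))
  }
  speeds
}

#' Run configuration
#'
#' Bundles the tunable parameters of a run: the child walking-speed factor
#' (default 0.78, i.e. a 22% reduction; set 1.0 for adult surfaces), the
#' speed assigned to open water in the water-passable surface (default
#' 1 km/h), the cell size in metres (default 20), the maximum walking speed
#' (5 km/h), input/output paths, and the random seed used when facilities on
#' impassable cells are snapped to a random passable neighbour.
#'
#' @param child_factor Multiplier in (0, 1] applied to all walking speeds.
#' @param water_speed Speed over open water in the passable surface, km/h.
#' @param cell_size_m Cell edge length in metres.
#' @param max_speed Maximum walking speed, km/h.
#' @param rng_seed Integer seed for facility snapping.
#' @param facility_types Character vector of facility types to map travel
#'   time to; empty = closest facility of any type.
#' @param inputs,outputs Named lists of file paths.
#' @return A `run_config` object (a list).
#' @export
run_config <- function(child_factor = 0.78, water_speed = 1.0,
                       cell_size_m = 20, max_speed = 5, rng_seed = 1L,
                       facility_types = character(),
                       inputs = list(), outputs = list()) {
  if (!(child_factor > 0 && child_factor <= 1)) {
    stop("child_factor must lie in (0, 1]", call. = FALSE)
  }
  if (!(water_speed > 0)) stop("water_speed must be > 0", call. = FALSE)
  if (!(cell_size_m > 0)) stop("cell_size_m must be > 0", call. = FALSE)
  structure(list(
    child_factor = child_factor, water_speed = water_speed,
    cell_size_m = cell_size_m, max_speed = max_speed,
    rng_seed = as.integer(rng_seed), facility_types = facility_types,
    inputs = inputs, outputs = outputs
  ), class = "run_config")
}

#' Load a run configuration from an INI-style file
#'
#' The run is controlled by a plain-text configuration with `[inputs]`,
#' `[outputs]` and `[parameters]` sections of `key = value` lines (`#` or `;`
#' comments). Unspecified parameters take the defaults of [run_config()].
#'
#' @param path Configuration file path.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  sections <- parse_ini(path)
  pars <- sections$parameters %||% list()
  num <- function(key, default) {
    v <- pars[[key]]
    if (is.null(v)) return(default)
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) stop("parameter '", key, "' is not numeric: ", v, call. = FALSE)
    x
  }
  types_raw <- pars[["facility_types"]]
  facility_types <- if (is.null(types_raw) || types_raw == "") character() else
    stringr::str_trim(stringr::str_split_1(types_raw, ","))
  run_config(
    child_factor = num("child_factor", 0.78),
    water_speed = num("water_speed", 1.0),
    cell_size_m = num("cell_size_m", 20),
    max_speed = num("max_speed", 5),
    rng_seed = as.integer(num("rng_seed", 1)),
    facility_types = facility_types,
    inputs = sections$inputs %||% list(),
    outputs = sections$outputs %||% list()
  )
}

parse_ini <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- stringr::str_trim(lines)
  lines <- lines[lines != "" & !stringr::str_starts(lines, "[#;]")]
  sections <- list()
  current <- "parameters"
  for (ln in lines) {
    if (stringr::str_starts(ln, stringr::fixed("["))) {
      current <- tolower(stringr::str_remove_all(ln, "[\\[\\]]"))
      next
    }
    kv <- stringr::str_split_fixed(ln, "=", 2)
    if (kv[2] == "") stop("malformed config line: ", ln, call. = FALSE)
    key <- tolower(stringr::str_trim(kv[1]))
    sections[[current]][[key]] <- stringr::str_trim(kv[2])
  }
  sections
}
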