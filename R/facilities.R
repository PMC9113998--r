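#' Load health facility points
#'
#' Reads a facility table (CSV with columns `id`, `lon`/`longitude`,
#' `lat`/`latitude`, `type`) into a tibble. Rows with non-numeric
#' coordinates are dropped with a per-row warning; duplicate ids are an
#' error.
#'
#' @param path CSV file path.
#' @return A tibble with columns `id`, `lon`, `lat`, `type`.
#' @export
load_facilities <- function(path) {
  if (!file.exists(path)) stop("facility file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  names(df) <- tolower(names(df))
  names(df)[names(df) == "longitude"] <- "lon"
  names(df)[names(df) == "latitude"] <- "lat"
  missing_cols <- setdiff(c("id", "lon", "lat", "type"), names(df))
  if (length(missing_cols) > 0) {
    stop("facility table is missing columns: ", toString(missing_cols),
         call. = FALSE)
  }
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  bad <- is.na(lon) | is.na(lat)
  if (any(bad)) {
    warning("dropping ", sum(bad), " facility row(s) with malformed coordinates: ",
            toString(df$id[bad]), call. = FALSE)
  }
  out <- tibble::tibble(id = df$id, lon = lon, lat = lat, type = df$type)[!bad, ]
  dup <- unique(out$id[duplicated(out$id)])
  if (length(dup) > 0) {
    stop("duplicate facility ids: ", toString(dup), call. = FALSE)
  }
  out
}

#' Filter facilities by type
#'
#' Travel-time maps are produced per facility type (e.g. only hospitals) as
#' well as to the closest facility of any type. An empty `wanted_types`
#' means "any type".
#'
#' @param facilities A facility tibble (see [load_facilities()]).
#' @param wanted_types Character vector of types to keep; `character()`
#'   keeps everything.
#' @return The filtered tibble.
#' @export
filter_by_type <- function(facilities, wanted_types = character()) {
  if (length(wanted_types) == 0) return(facilities)
  out <- dplyr::filter(facilities, .data$type %in% wanted_types)
  absent <- setdiff(wanted_types, facilities$type)
  if (length(absent) > 0) {
    warning("no facilities of type(s): ", toString(absent), call. = FALSE)
  }
  out
}

#' Validate facility locations and snap onto passable cells
#'
#' Facilities outside the boundary or grid are removed. A facility whose
#' containing cell is impassable (open water in the blocked surface, slope
#' over 100%, nodata) is moved to one of its passable 8-neighbours, chosen
#' uniformly at random under `rng_seed`; if no neighbour is passable it is
#' removed. Every input facility appears exactly once in the audit report.
#' Passability is judged against the water-blocked surface, so facilities
#' sitting on water are relocated to the shore or dropped.
#'
#' @param facilities A facility tibble.
#' @param surface The water-blocked [assemble_cost_surface()] result.
#' @param boundary A [bounding_box()]; defaults to the surface extent.
#' @param rng_seed Integer seed making the snapping reproducible.
#' @return A list with `source_cells` (tibble of unique `row`, `col` handed
#'   to the solver) and `report` (tibble: `id`, `action` in
#'   kept/moved/removed, `reason`, original and final cell indices).
#' @export
validate_and_snap <- function(facilities, surface, boundary = NULL,
                              rng_seed = 1L) {
  grid <- surface$grid
  if (is.null(boundary)) boundary <- grid_extent(grid)
  d <- dim(grid$values)

  in_box <- facilities$lon >= boundary$min_lon & facilities$lon <= boundary$max_lon &
    facilities$lat >= boundary$min_lat & facilities$lat <= boundary$max_lat
  cells <- point_to_cell(grid, facilities$lon, facilities$lat)

  n <- nrow(facilities)
  action <- character(n)
  reason <- character(n)
  final_row <- rep(NA_integer_, n)
  final_col <- rep(NA_integer_, n)

  withr::with_seed(rng_seed, {
    for (i in seq_len(n)) {
      if (!in_box[i]) {
        action[i] <- "removed"; reason[i] <- "outside boundary"
        next
      }
      r <- cells$row[i]; c <- cells$col[i]
      if (is.na(r)) {
        action[i] <- "removed"; reason[i] <- "outside grid"
        next
      }
      if (!is.na(grid$values[r, c])) {
        action[i] <- "kept"; reason[i] <- "on passable cell"
        final_row[i] <- r; final_col[i] <- c
        next
      }
      nb <- neighbours8(r, c, d)
      passable <- nb[!is.na(grid$values[nb]), , drop = FALSE]
      if (nrow(passable) == 0) {
        action[i] <- "removed"
        reason[i] <- "impassable cell, no passable neighbour"
      } else {
        pick <- if (nrow(passable) == 1) 1L else sample.int(nrow(passable), 1)
        action[i] <- "moved"
        reason[i] <- "impassable cell, snapped to passable neighbour"
        final_row[i] <- passable[pick, 1]
        final_col[i] <- passable[pick, 2]
      }
    }
  })

  report <- tibble::tibble(
    id = facilities$id,
    action = action,
    reason = reason,
    orig_row = cells$row, orig_col = cells$col,
    final_row = final_row, final_col = final_col
  )
  sources <- dplyr::distinct(
    tibble::tibble(row = final_row[!is.na(final_row)],
                   col = final_col[!is.na(final_col)])
  )
  if (nrow(sources) == 0) {
    stop("no valid facility locations survive validation (no destinations)",
         call. = FALSE)
  }
  list(source_cells = sources, report = report)
}

# 8-neighbourhood as a (row, col) matrix, clipped to the grid
neighbours8 <- function(r, c, d) {
  off <- cbind(
    r = r + c(-1, -1, -1, 0, 0, 1, 1, 1),
    c = c + c(-1, 0, 1, -1, 1, -1, 0, 1)
  )
  off[off[, 1] >= 1 & off[, 1] <= d[1] & off[, 2] >= 1 & off[, 2] <= d[2], ,
      drop = FALSE]
}

#' Write a facility audit report
#' @param report The `report` tibble from [validate_and_snap()].
#' @param path Output CSV path.
#' @export
write_facility_report <- function(report, path) {
  readr::write_csv(report, path)
  invisible(path)
}

#' Write facilities to CSV
#' @param facilities A facility tibble.
#' @param path Output CSV path.
#' @export
write_facilities <- function(facilities, path) {
  readr::write_csv(facilities, path)
  invisible(path)
}
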