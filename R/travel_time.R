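#' Multi-source least-cost travel time
#'
#' Runs Dijkstra's algorithm simultaneously from every facility cell over
#' the cost surface, yielding each cell's minimum accumulated travel time
#' (seconds) to its nearest facility. Moves connect 8-neighbouring cells;
#' the cost of stepping between adjacent cells i and j is
#' `0.5 * (c_i + c_j) * d`, where `c` is each cell's seconds-to-cross and
#' `d` is 1 for orthogonal and `sqrt(2)` for diagonal moves, so traversing
#' k uniform cells in a straight orthogonal line costs exactly `k * c`.
#' `NA` cells are untraversable; passable cells with no route to any source
#' come back as `+Inf`.
#'
#' @param surface An [assemble_cost_surface()] result.
#' @param sources A tibble/data frame of source cells with columns `row`,
#'   `col` (1-based), e.g. `source_cells` from [validate_and_snap()].
#' @return A [geo_grid()] of seconds: 0 at sources, `+Inf` where
#'   unreachable, `NA` where impassable.
#' @export
cost_distance <- function(surface, sources) {
  stopifnot(inherits(surface, "cost_surface"))
  if (nrow(sources) == 0) stop("at least one source cell is required", call. = FALSE)
  g <- surface$grid
  secs <- grid_dijkstra(g$values, as.integer(sources$row), as.integer(sources$col))
  geo_grid_allow_inf(secs, g)
}

# internal: geo_grid carrying +Inf sentinels (skips the finite-or-NA check)
geo_grid_allow_inf <- function(values, template) {
  structure(list(values = values,
                 origin_lon = template$origin_lon,
                 origin_lat = template$origin_lat,
                 cell_size = template$cell_size,
                 nodata = template$nodata),
            class = "geo_grid")
}

#' Two-pass travel time with the water-barrier rule
#'
#' Travel over open water is prevented unless it is the only way to reach a
#' facility. Pass 1 runs on the water-blocked surface; any cell whose pass-1
#' time is finite keeps it. Cells that are unreachable in pass 1 — island
#' cells and the water itself — take their time from pass 2, run on the
#' water-passable surface where open water carries a slow crossing speed.
#' Cells unreachable in both passes become `NA`.
#'
#' @param blocked,passable The two [assemble_cost_surface()] results for the
#'   same scene.
#' @param sources Source cells as for [cost_distance()].
#' @return A [geo_grid()] of seconds (`NA` where unreachable in both passes).
#' @export
two_pass_travel_time <- function(blocked, passable, sources) {
  check_aligned(blocked$grid, passable$grid)
  pass1 <- cost_distance(blocked, sources)
  v <- pass1$values
  needs_water <- !is.finite(v)   # NA cells and +Inf cells alike
  if (any(needs_water)) {
    pass2 <- cost_distance(passable, sources)
    v[needs_water] <- pass2$values[needs_water]
  }
  v[!is.finite(v)] <- NA
  geo_grid(v, pass1$origin_lon, pass1$origin_lat, pass1$cell_size, pass1$nodata)
}

#' Convert a seconds grid to minutes
#'
#' @param seconds_grid A [geo_grid()] of seconds (e.g. from
#'   [two_pass_travel_time()]); `+Inf` becomes `NA`.
#' @return A [geo_grid()] of minutes.
#' @export
to_minutes <- function(seconds_grid) {
  v <- seconds_grid$values / 60
  v[!is.finite(v)] <- NA
  geo_grid(v, seconds_grid$origin_lon, seconds_grid$origin_lat,
           seconds_grid$cell_size, seconds_grid$nodata)
}

#' Extract grid values at points
#'
#' Point-samples a travel-time (or any) grid at longitude/latitude
#' locations, e.g. survey cluster coordinates; each point takes the value of
#' its containing cell. Points outside the extent get `NA` with a warning.
#'
#' @param grid A [geo_grid()].
#' @param points A data frame with columns `lon` and `lat`.
#' @return A numeric vector, one value per point.
#' @export
extract_at_points <- function(grid, points) {
  cells <- point_to_cell(grid, points$lon, points$lat)
  outside <- is.na(cells$row)
  if (any(outside)) {
    warning(sum(outside), " point(s) outside the grid extent", call. = FALSE)
  }
  out <- rep(NA_real_, nrow(cells))
  ok <- !outside
  out[ok] <- grid$values[cbind(cells$row[ok], cells$col[ok])]
  out
}

#' Six-number summary of travel times
#'
#' @param values Numeric vector (minutes); `NA` values are dropped.
#' @return A one-row tibble: `min`, `q1`, `median`, `mean`, `q3`, `max`.
#' @export
summary_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no non-NA values to summarise", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  tibble::tibble(min = min(values), q1 = q[1], median = q[2],
                 mean = mean(values), q3 = q[3], max = max(values))
}

#' Count values within travel-time thresholds
#'
#' Buckets values as: exactly 0, then half-open intervals `(0, b1]`,
#' `(b1, b2]`, ..., and an overflow bucket beyond the last bound — the usual
#' "how many clusters lie within 15/30/60 minutes of care" tabulation.
#'
#' @param values Numeric vector (minutes); `NA` values are dropped.
#' @param bounds Strictly increasing positive thresholds (minutes).
#' @return A tibble with columns `interval` and `count`.
#' @export
threshold_counts <- function(values, bounds) {
  if (is.unsorted(bounds, strictly = TRUE)) {
    stop("bounds must be strictly increasing", call. = FALSE)
  }
  values <- values[!is.na(values)]
  edges <- c(0, bounds, Inf)
  counts <- c(
    sum(values == 0),
    vapply(seq_len(length(edges) - 1), function(i) {
      sum(values > edges[i] & values <= edges[i + 1])
    }, integer(1))
  )
  labels <- c("0", sprintf("(%g,%g]", edges[-length(edges)], edges[-1]))
  tibble::tibble(interval = labels, count = counts)
}

#' Spearman rank correlation
#'
#' Compares two travel-time estimates over the same locations by rank, the
#' standard check that two accessibility surfaces order locations the same
#' way even when their absolute minutes differ.
#'
#' @param a,b Numeric vectors of equal length (>= 3), pairwise non-NA.
#' @return Spearman's rho in \[-1, 1\].
#' @export
rank_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("inputs differ in length", call. = FALSE)
  if (length(a) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("inputs must be pairwise non-NA", call. = FALSE)
  stats::cor(a, b, method = "spearman")
}

#' Travel-time map: the full least-cost-path stage
#'
#' Validates and snaps facilities against the water-blocked surface, runs
#' the two-pass least-cost analysis, and returns the minutes grid together
#' with the facility audit report.
#'
#' @param blocked,passable The two [assemble_cost_surface()] results.
#' @param facilities A facility tibble (see [load_facilities()]).
#' @param wanted_types Facility-type filter; empty = any type.
#' @param boundary Optional [bounding_box()].
#' @param rng_seed Seed for facility snapping.
#' @return A `travel_time_result`: list with `minutes` ([geo_grid()]),
#'   `seconds`, `report`, `source_cells`.
#' @export
travel_time_map <- function(blocked, passable, facilities,
                            wanted_types = character(), boundary = NULL,
                            rng_seed = 1L) {
  kept <- filter_by_type(facilities, wanted_types)
  if (nrow(kept) == 0) stop("no facilities left after type filtering", call. = FALSE)
  snap <- validate_and_snap(kept, blocked, boundary, rng_seed)
  seconds <- two_pass_travel_time(blocked, passable, snap$source_cells)
  structure(list(
    minutes = to_minutes(seconds),
    seconds = seconds,
    report = snap$report,
    source_cells = snap$source_cells
  ), class = "travel_time_result")
}

#' @export
print.travel_time_result <- function(x, ...) {
  cat("<travel_time_result>\n")
  print(x$minutes)
  acts <- table(x$report$action)
  cat("  facilities:", paste(names(acts), acts, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname travel_time_map
#' @param x A `travel_time_result`.
#' @param ... Unused.
#' @export
tidy.travel_time_result <- function(x, ...) tidy.geo_grid(x$minutes)

#' @rdname travel_time_map
#' @export
glance.travel_time_result <- function(x, ...) {
  v <- as.vector(x$minutes$values)
  acts <- x$report$action
  dplyr::bind_cols(
    summary_stats(v[!is.na(v)]),
    tibble::tibble(
      n_cells = length(v),
      n_unreachable = sum(is.na(v)),
      n_kept = sum(acts == "kept"),
      n_moved = sum(acts == "moved"),
      n_removed = sum(acts == "removed")
    )
  )
}
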