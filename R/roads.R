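#' Road polyline layer
#'
#' A road layer is a tibble with one row per polyline feature: a `tag` column
#' giving the road category (the only attribute the pipeline needs) and a
#' `geometry` list-column of n x 2 matrices of longitude/latitude vertices.
#'
#' @param geometries List of numeric matrices, each n x 2 (lon, lat) with at
#'   least two vertices.
#' @param tags Character vector of road categories, one per feature.
#' @return A `road_layer` tibble.
#' @examples
#' road_layer(list(cbind(c(0, 0.001), c(0, 0))), "path")
#' @export
road_layer <- function(geometries = list(), tags = character()) {
  if (length(geometries) != length(tags)) {
    stop("one tag per geometry required", call. = FALSE)
  }
  tags <- as.character(tags)
  if (length(tags) > 0 && any(is.na(tags) | tags == "")) {
    stop("every road feature needs a non-empty tag", call. = FALSE)
  }
  geometries <- lapply(geometries, function(gm) {
    gm <- as.matrix(gm)
    if (nrow(gm) < 2 || ncol(gm) != 2 || !all(is.finite(gm))) {
      stop("road geometries must be n x 2 matrices with >= 2 finite vertices",
           call. = FALSE)
    }
    gm
  })
  structure(tibble::tibble(tag = tags, geometry = geometries),
            class = c("road_layer", class(tibble::tibble())))
}

#' Rasterize roads onto a reference grid
#'
#' Burns road walking speeds into the reference grid geometry with
#' all-touched semantics: a cell is marked if and only if at least one road
#' segment geometrically intersects its closed square, which keeps rasterized
#' lines 8-connected so the network's connectivity survives conversion.
#' Features are grouped by speed and each group rasterized separately; by
#' default overlapping groups merge by taking the maximum speed per cell
#' (the fastest road wins), which can be disabled so that later features
#' simply overwrite earlier ones.
#'
#' @param roads A [road_layer()].
#' @param speeds Named numeric vector mapping every tag in `roads` to a
#'   walking speed in km/h (see [resolve_tag_speeds()]).
#' @param reference A [geo_grid()] supplying the output geometry.
#' @param priority If `TRUE` (default) overlapping roads keep the fastest
#'   speed; if `FALSE`, the last feature written wins.
#' @return A [geo_grid()] of km/h, `NA` in every cell no road touches.
#' @export
rasterize_roads <- function(roads, speeds, reference, priority = TRUE) {
  d <- dim(reference$values)
  if (length(reference$values) == 0) stop("empty reference grid", call. = FALSE)
  out <- matrix(NA_real_, d[1], d[2])
  if (nrow(roads) > 0) {
    missing_tags <- setdiff(unique(roads$tag), names(speeds))
    if (length(missing_tags) > 0) {
      stop("no speed for road tags: ", toString(missing_tags), call. = FALSE)
    }
    feat_speed <- unname(speeds[roads$tag])
    if (anyNA(feat_speed)) {
      stop("NA speed for road tags: ",
           toString(unique(roads$tag[is.na(feat_speed)])), call. = FALSE)
    }
    if (priority) {
      for (sp in sort(unique(feat_speed))) {   # ascending: max-merge by overwrite
        mask <- group_mask(roads$geometry[feat_speed == sp], reference)
        out[mask] <- sp
      }
    } else {
      for (i in seq_len(nrow(roads))) {
        mask <- group_mask(roads$geometry[i], reference)
        out[mask] <- feat_speed[i]
      }
    }
  }
  geo_grid(out, reference$origin_lon, reference$origin_lat,
           reference$cell_size, reference$nodata)
}

# logical matrix of cells touched by any segment of any geometry in the list
group_mask <- function(geoms, reference) {
  d <- dim(reference$values)
  mask <- matrix(FALSE, d[1], d[2])
  for (gm in geoms) {
    # continuous grid coordinates: cell (r, c) spans x in [c-1, c], y in [r-1, r]
    x <- (gm[, 1] - reference$origin_lon) / reference$cell_size
    y <- (reference$origin_lat - gm[, 2]) / reference$cell_size
    for (s in seq_len(nrow(gm) - 1)) {
      mask <- mark_segment(mask, x[s], y[s], x[s + 1], y[s + 1])
    }
  }
  mask
}

# all-touched marking of one segment in continuous grid coordinates:
# every cell whose closed unit square the segment intersects is marked
mark_segment <- function(mask, x0, y0, x1, y1) {
  d <- dim(mask)
  c_lo <- max(1L, floor(min(x0, x1)) + 1L)
  c_hi <- min(d[2], floor(max(x0, x1)) + 1L)
  r_lo <- max(1L, floor(min(y0, y1)) + 1L)
  r_hi <- min(d[1], floor(max(y0, y1)) + 1L)
  # touching the boundary line between cells marks both closed squares
  if (min(x0, x1) == floor(min(x0, x1)) && c_lo > 1L) c_lo <- c_lo - 1L
  if (min(y0, y1) == floor(min(y0, y1)) && r_lo > 1L) r_lo <- r_lo - 1L
  if (c_lo > c_hi || r_lo > r_hi) return(mask)
  cols <- c_lo:c_hi
  rows <- r_lo:r_hi
  for (cc in cols) {
    for (rr in rows) {
      if (!mask[rr, cc] &&
          segment_hits_cell(x0, y0, x1, y1, cc - 1, cc, rr - 1, rr)) {
        mask[rr, cc] <- TRUE
      }
    }
  }
  mask
}

# closed-rectangle / segment intersection (Liang-Barsky clipping)
segment_hits_cell <- function(x0, y0, x1, y1, xmin, xmax, ymin, ymax) {
  dx <- x1 - x0
  dy <- y1 - y0
  p <- c(-dx, dx, -dy, dy)
  q <- c(x0 - xmin, xmax - x0, y0 - ymin, ymax - y0)
  t0 <- 0; t1 <- 1
  for (i in 1:4) {
    if (p[i] == 0) {
      if (q[i] < 0) return(FALSE)
    } else {
      t <- q[i] / p[i]
      if (p[i] < 0) {
        if (t > t1) return(FALSE)
        if (t > t0) t0 <- t
      } else {
        if (t < t0) return(FALSE)
        if (t < t1) t1 <- t
      }
    }
  }
  t0 <= t1
}

#' Read and write road layers as GeoJSON
#'
#' Roads travel on disk as a GeoJSON FeatureCollection of LineString /
#' MultiLineString features whose properties carry the road category in a
#' `tag` field.
#'
#' @param path GeoJSON file path.
#' @param roads A [road_layer()].
#' @return `read_roads_geojson()` returns a [road_layer()].
#' @export
read_roads_geojson <- function(path) {
  if (!file.exists(path)) stop("roads file not found: ", path, call. = FALSE)
  gj <- jsonlite::read_json(path)
  feats <- gj$features %||% list()
  geoms <- list()
  tags <- character()
  for (f in feats) {
    tag <- f$properties$tag
    if (is.null(tag)) stop("road feature without a 'tag' property", call. = FALSE)
    geom <- f$geometry
    coords_list <- switch(geom$type,
      LineString = list(geom$coordinates),
      MultiLineString = geom$coordinates,
      stop("unsupported geometry type: ", geom$type, call. = FALSE)
    )
    for (cl in coords_list) {
      m <- do.call(rbind, lapply(cl, function(p) c(p[[1]], p[[2]])))
      geoms[[length(geoms) + 1]] <- m
      tags <- c(tags, tag)
    }
  }
  road_layer(geoms, tags)
}

#' @rdname read_roads_geojson
#' @export
write_roads_geojson <- function(roads, path) {
  feats <- purrr::map2(roads$geometry, roads$tag, function(gm, tag) {
    list(
      type = "Feature",
      properties = list(tag = tag),
      geometry = list(
        type = "LineString",
        coordinates = lapply(seq_len(nrow(gm)), function(i) c(gm[i, 1], gm[i, 2]))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
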