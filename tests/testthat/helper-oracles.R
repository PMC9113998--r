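# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the graph oracle builds an explicit igraph
# edge-by-edge, the line oracle marks cells by dense point sampling.

# Explicit-graph multi-source Dijkstra over an 8-connected cost matrix.
# cost: matrix of seconds-per-cell (NA untraversable); sources: tibble(row, col).
# Returns a matrix of seconds (Inf unreachable, NA where cost is NA).
oracle_cost_distance <- function(cost, sources) {
  d <- dim(cost)
  id <- function(r, c) (c - 1L) * d[1] + r
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      if (is.na(cost[r, c])) next
      for (k in seq_len(8)) {
        dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)[k]
        dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)[k]
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > d[1] || cc < 1 || cc > d[2]) next
        if (is.na(cost[rr, cc])) next
        from <- c(from, id(r, c)); to <- c(to, id(rr, cc))
        w <- c(w, 0.5 * (cost[r, c] + cost[rr, cc]) *
                 ifelse(dr != 0 & dc != 0, sqrt(2), 1))
      }
    }
  }
  g <- igraph::make_empty_graph(n = d[1] * d[2], directed = TRUE)
  if (length(from) > 0) {
    g <- igraph::add_edges(g, rbind(from, to), weight = w)
  }
  src_ids <- id(sources$row, sources$col)
  dm <- igraph::distances(g, v = src_ids, mode = "out")
  best <- apply(dm, 2, min)
  out <- matrix(best, d[1], d[2])
  out[is.na(cost)] <- NA
  out
}

# Supercover line oracle: which cells does the segment touch? Marks every
# cell whose closed unit square comes within eps of a densely sampled point.
oracle_line_cells <- function(x0, y0, x1, y1, n_rows, n_cols, n_sample = 20000) {
  eps <- 1e-9
  t <- seq(0, 1, length.out = n_sample)
  # include the exact gridline crossings so corner touches are seen
  # (a segment through a cell corner touches all four closed squares)
  for (d in list(c(x0, x1), c(y0, y1))) {
    if (d[1] != d[2]) {
      ks <- seq(ceiling(min(d)), floor(max(d)))
      t <- c(t, (ks - d[1]) / (d[2] - d[1]))
    }
  }
  t <- sort(unique(pmin(pmax(t, 0), 1)))
  xs <- x0 + t * (x1 - x0)
  ys <- y0 + t * (y1 - y0)
  mask <- matrix(FALSE, n_rows, n_cols)
  for (i in seq_along(t)) {
    cols <- unique(pmax(1, pmin(n_cols, floor(c(xs[i] - eps, xs[i] + eps)) + 1)))
    rows <- unique(pmax(1, pmin(n_rows, floor(c(ys[i] - eps, ys[i] + eps)) + 1)))
    mask[rows, cols] <- TRUE
  }
  mask
}

# Random cost surface with NA patches, for oracle-equivalence sweeps.
random_cost_surface <- function(n_rows, n_cols, na_frac = 0.2) {
  vals <- matrix(runif(n_rows * n_cols, 10, 100), n_rows, n_cols)
  vals[runif(n_rows * n_cols) < na_frac] <- NA
  grid <- geo_grid(vals, origin_lon = 30, origin_lat = 0.5,
                   cell_size = metres_to_degrees(20))
  structure(list(grid = grid, water_mode = "blocked", child_factor = 1,
                 water_speed = 1, cell_size_m = 20),
            class = "cost_surface")
}

# First passable cell of a surface, as a one-row source tibble.
first_passable_cell <- function(cost) {
  idx <- which(!is.na(cost), arr.ind = TRUE)
  tibble::tibble(row = idx[1, 1], col = idx[1, 2])
}
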