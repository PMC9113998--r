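# reference geometry shared by the road tests: 10 x 10 cells of 20 m at 0.5N
ref_grid <- function(n = 10) {
  geo_grid(matrix(0, n, n), origin_lon = 30, origin_lat = 0.5,
           cell_size = metres_to_degrees(20))
}

# polyline through the centres of the given (row, col) cells
line_through_cells <- function(g, rows, cols) {
  cbind(30 + (cols - 0.5) * g$cell_size, 0.5 - (rows - 0.5) * g$cell_size)
}

test_that("a horizontal segment marks exactly the cells it spans", {
  g <- ref_grid()
  geom <- line_through_cells(g, c(4, 4), c(2, 4))
  r <- rasterize_roads(road_layer(list(geom), "path"), c(path = 3.5), g)
  marked <- which(!is.na(r$values), arr.ind = TRUE)
  expect_equal(nrow(marked), 3)
  expect_true(all(marked[, "row"] == 4))
  expect_setequal(marked[, "col"], 2:4)
  expect_true(all(r$values[4, 2:4] == 3.5))
})

test_that("crossing roads keep the fastest speed at the intersection", {
  g <- ref_grid()
  motorway <- line_through_cells(g, c(5, 5), c(1, 9))   # horizontal
  path <- line_through_cells(g, c(1, 9), c(5, 5))       # vertical
  r <- rasterize_roads(road_layer(list(motorway, path), c("motorway", "path")),
                       c(motorway = 5.0, path = 3.5), g)
  expect_equal(r$values[5, 5], 5.0)
  expect_equal(r$values[2, 5], 3.5)
  expect_equal(r$values[5, 2], 5.0)
})

test_that("an empty road layer rasterizes to all-NA", {
  r <- rasterize_roads(road_layer(), numeric(), ref_grid())
  expect_true(all(is.na(r$values)))
})

test_that("diagonal lines rasterize 8-connected with no gaps, matching a supercover oracle", {
  g <- ref_grid(12)
  # slopes chosen so no segment grazes a cell corner exactly: corner touches
  # are a measure-zero configuration whose marking is rounding-dependent
  cases <- list(c(2, 2, 10, 9), c(1, 3, 11, 12), c(10, 2, 4, 11))
  for (cs in cases) {
    geom <- line_through_cells(g, c(cs[1], cs[3]), c(cs[2], cs[4]))
    r <- rasterize_roads(road_layer(list(geom), "track"), c(track = 3.5), g)
    got <- !is.na(r$values)
    # oracle works in continuous grid coordinates (cell centres at k - 0.5)
    want <- oracle_line_cells(cs[2] - 0.5, cs[1] - 0.5, cs[4] - 0.5, cs[3] - 0.5,
                              12, 12)
    expect_identical(got, want)
    # connectivity: each marked cell has a marked 8-neighbour (if >1 marked)
    marked <- which(got, arr.ind = TRUE)
    for (i in seq_len(nrow(marked))) {
      dists <- pmax(abs(marked[, 1] - marked[i, 1]),
                    abs(marked[, 2] - marked[i, 2]))
      expect_true(any(dists == 1), label = "marked cell with no 8-neighbour")
    }
  }
})

test_that("rasterization is order-invariant and monotone in features", {
  g <- ref_grid()
  geoms <- list(
    line_through_cells(g, c(2, 2), c(1, 8)),
    line_through_cells(g, c(1, 8), c(4, 4)),
    line_through_cells(g, c(7, 3), c(2, 9))
  )
  tags <- c("primary", "path", "residential")
  speeds <- c(primary = 5.0, path = 3.5, residential = 4.0)
  base <- rasterize_roads(road_layer(geoms, tags), speeds, g)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    r <- rasterize_roads(road_layer(geoms[perm], tags[perm]), speeds, g)
    expect_identical(r$values, base$values)
  }
  # monotonicity: adding a feature never unmarks or lowers a cell
  fewer <- rasterize_roads(road_layer(geoms[1:2], tags[1:2]), speeds, g)
  was_marked <- !is.na(fewer$values)
  expect_true(all(!is.na(base$values[was_marked])))
  expect_true(all(base$values[was_marked] >= fewer$values[was_marked]))
})

test_that("joint rasterization equals the max-merge of per-speed-group rasters", {
  g <- ref_grid()
  geoms <- list(
    line_through_cells(g, c(3, 3), c(1, 9)),
    line_through_cells(g, c(1, 9), c(6, 6)),
    line_through_cells(g, c(8, 2), c(2, 9))
  )
  tags <- c("trunk", "footway", "secondary")
  speeds <- c(trunk = 5.0, footway = 3.5, secondary = 4.5)
  joint <- rasterize_roads(road_layer(geoms, tags), speeds, g)
  per_group <- lapply(seq_along(tags), function(i) {
    rasterize_roads(road_layer(geoms[i], tags[i]), speeds, g)$values
  })
  merged <- Reduce(function(a, b) {
    out <- pmax(a, b, na.rm = TRUE)
    out[is.na(a) & is.na(b)] <- NA
    out
  }, per_group)
  expect_equal(joint$values, merged)
})

test_that("disabling speed priority lets the last-written feature win", {
  g <- ref_grid()
  geoms <- list(line_through_cells(g, c(5, 5), c(2, 8)),
                line_through_cells(g, c(2, 8), c(5, 5)))
  r <- rasterize_roads(road_layer(geoms, c("trunk", "path")),
                       c(trunk = 5.0, path = 3.5), g, priority = FALSE)
  expect_equal(r$values[5, 5], 3.5)   # path written last
})

test_that("road layers round-trip through GeoJSON", {
  g <- ref_grid()
  rl <- road_layer(list(line_through_cells(g, c(2, 6), c(2, 7)),
                        line_through_cells(g, c(1, 9), c(5, 5))),
                   c("primary", "path"))
  f <- withr::local_tempfile(fileext = ".geojson")
  write_roads_geojson(rl, f)
  rl2 <- read_roads_geojson(f)
  expect_equal(rl2$tag, rl$tag)
  expect_equal(rl2$geometry, rl$geometry)
})

test_that("road layer validation rejects bad features", {
  expect_error(road_layer(list(cbind(1, 2)), "path"), ">= 2")
  expect_error(road_layer(list(cbind(c(0, 1), c(0, 1))), ""), "non-empty tag")
  expect_error(rasterize_roads(road_layer(list(cbind(c(30, 30.001), c(0, 0))),
                                          "mystery"),
                               c(path = 3.5), ref_grid()), "no speed")
})
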