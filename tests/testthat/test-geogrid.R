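test_that("geo_grid validates its invariants", {
  g <- geo_grid(matrix(1:12, 3, 4), origin_lon = 30, origin_lat = 0.5)
  expect_equal(dim(g), c(3L, 4L))
  expect_error(geo_grid(matrix(1, 2, 2), cell_size = 0), "cell_size")
  expect_error(geo_grid(matrix(c(1, Inf, 3, 4), 2, 2)), "finite or NA")
  expect_silent(geo_grid(matrix(c(1, NA, 3, 4), 2, 2)))
})

test_that("GeoTIFF round-trips grids cell-for-cell, including NA patterns", {
  cases <- list(
    uniform = matrix(7.5, 4, 4),
    mixed = matrix(c(1.25, NA, -3, 0, NA, 6, 7, 8, 9, 10, NA, 12), 3, 4),
    all_na = matrix(NA_real_, 3, 3)
  )
  for (nm in names(cases)) {
    g <- geo_grid(cases[[nm]], origin_lon = 32.1, origin_lat = 0.25,
                  cell_size = 20 / 111120)
    f <- withr::local_tempfile(fileext = ".tif")
    write_geotiff(g, f)
    g2 <- read_geotiff(f)
    expect_identical(as.matrix(g2), as.matrix(g), label = nm)
    expect_equal(g2$origin_lon, g$origin_lon)
    expect_equal(g2$origin_lat, g$origin_lat)
    expect_equal(g2$cell_size, g$cell_size)
  }
})

test_that("a 3 x 4 raster reads back with the right shape", {
  g <- geo_grid(matrix(seq_len(12), 3, 4))
  f <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(g, f)
  expect_equal(dim(read_geotiff(f)), c(3L, 4L))
})

test_that("read_geotiff rejects missing and malformed files", {
  expect_error(read_geotiff(tempfile()), "not found")
  bad <- withr::local_tempfile(fileext = ".tif")
  writeBin(charToRaw("not a tiff at all"), bad)
  expect_error(read_geotiff(bad), "TIFF")
})

test_that("files written here are readable by an independent TIFF reader", {
  g <- geo_grid(matrix(c(1.5, NA, 3, 4, 5, 6), 2, 3),
                origin_lon = 30, origin_lat = 0.5, cell_size = 20 / 111120,
                nodata = -9999)
  f <- withr::local_tempfile(fileext = ".tif")
  write_geotiff(g, f)
  script <- paste(
    "import tifffile, json, sys",
    "with tifffile.TiffFile(sys.argv[1]) as t:",
    "    page = t.pages[0]",
    "    a = page.asarray()",
    "    scale = page.tags[33550].value",
    "    tie = page.tags[33922].value",
    "print(json.dumps({'vals': a.flatten().tolist(),",
    "                  'scale': list(scale), 'tie': list(tie)}))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(f)), stdout = TRUE)
  parsed <- jsonlite::fromJSON(paste(out, collapse = ""))
  expected <- as.vector(t(as.matrix(g)))
  expected[is.na(expected)] <- -9999
  expect_equal(parsed$vals, expected)
  expect_equal(parsed$scale[1:2], rep(20 / 111120, 2))
  expect_equal(parsed$tie[4:5], c(30, 0.5))
})

test_that("bilinear resampling is exact on affine surfaces", {
  cs <- 30 / 111120
  nr <- 12; nc <- 10
  f <- function(x, y) 4 + 2 * x + 3 * y
  vals <- outer(seq_len(nr), seq_len(nc), function(r, c) f(c, r))
  g <- geo_grid(vals, cell_size = cs)
  out <- resample_bilinear(g, 20 / 111120)
  # expected: evaluate the same affine field at output cell-centre positions
  ratio <- (20 / 111120) / cs
  exp_vals <- outer(seq_len(nrow(out$values)), seq_len(ncol(out$values)),
                    function(r, c) f((c - 0.5) * ratio + 0.5, (r - 0.5) * ratio + 0.5))
  interior_r <- 3:(nrow(out$values) - 2)
  interior_c <- 3:(ncol(out$values) - 2)
  expect_lt(max(abs(out$values[interior_r, interior_c] -
                    exp_vals[interior_r, interior_c])), 1e-9)
})

test_that("resampling 90 cells at 30 m to 20 m gives 135 cells", {
  g <- geo_grid(matrix(5, 90, 90), cell_size = 30 / 111120)
  out <- resample_bilinear(g, 20 / 111120)
  expect_equal(dim(out), c(135L, 135L))
  expect_true(all(out$values == 5))   # constant grid stays constant
})

test_that("NA neighbourhoods propagate through resampling", {
  vals <- matrix(1, 6, 6); vals[3, 3] <- NA
  g <- geo_grid(vals, cell_size = 30 / 111120)
  out <- resample_bilinear(g, 20 / 111120)
  expect_true(anyNA(out$values))
  expect_false(all(is.na(out$values)))
  expect_error(resample_bilinear(geo_grid(matrix(1, 1, 1)), 1e-4), "2 x 2")
})

test_that("align_to is the identity on matching geometry", {
  g <- geo_grid(matrix(runif(20), 4, 5), origin_lon = 30, origin_lat = 0.5,
                cell_size = 20 / 111120)
  expect_equal(as.matrix(align_to(g, g, "nearest")), as.matrix(g))
  expect_equal(as.matrix(align_to(g, g, "bilinear")), as.matrix(g),
               tolerance = 1e-9)
  shifted <- geo_grid(matrix(0, 4, 5), g$origin_lon + g$cell_size / 4,
                      g$origin_lat, g$cell_size)
  const <- geo_grid(matrix(3.3, 4, 5), g$origin_lon, g$origin_lat, g$cell_size)
  aligned <- align_to(const, shifted, "bilinear")
  expect_true(all(na.omit(as.vector(aligned$values)) == 3.3))
  far <- geo_grid(matrix(1, 3, 3), origin_lon = 90, origin_lat = 50,
                  cell_size = g$cell_size)
  expect_error(align_to(g, far), "overlap")
})

test_that("degree-to-metre conversion uses the uniform 111120 factor", {
  expect_equal(degrees_to_metres(1), 111120)
  expect_equal(degrees_to_metres(0), 0)
  expect_equal(metres_to_degrees(20), 20 / 111120)
  expect_equal(degrees_to_metres(metres_to_degrees(20)), 20)
  # linearity
  a <- 0.37; b <- 1.21
  expect_equal(degrees_to_metres(a + b),
               degrees_to_metres(a) + degrees_to_metres(b))
})

test_that("points map to containing cells under half-open intervals", {
  g <- geo_grid(matrix(0, 4, 4), origin_lon = 30, origin_lat = 0.5,
                cell_size = 0.1)
  # exactly on the upper-left corner -> cell (1, 1)
  expect_equal(point_to_cell(g, 30, 0.5), tibble::tibble(row = 1L, col = 1L))
  # on an interior edge -> the cell whose half-open interval starts there
  expect_equal(point_to_cell(g, 30.1, 0.45)$col, 2L)
  expect_true(is.na(point_to_cell(g, 29.9, 0.45)$row))
})
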