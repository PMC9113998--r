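#' Read and write single-band GeoTIFF rasters
#'
#' All rasters move in and out of the pipeline as single-band GeoTIFF files
#' in WGS84 geographic coordinates. `write_geotiff()` produces an
#' uncompressed little-endian baseline TIFF with 64-bit IEEE float samples
#' plus the GeoTIFF georeferencing tags (ModelPixelScale, ModelTiepoint, a
#' minimal GeoKeyDirectory declaring EPSG:4326) and the GDAL nodata tag, so
#' files open directly in QGIS/GDAL/rasterio. `read_geotiff()` reads
#' uncompressed single-band rasters (8/16/32-bit integer or 32/64-bit float,
#' either byte order, any strip layout) written by this package or by
#' standard GIS tools.
#'
#' @param path File path.
#' @param grid A [geo_grid()].
#' @return `read_geotiff()` returns a [geo_grid()]; `write_geotiff()`
#'   invisibly returns `path`.
#' @examples
#' g <- geo_grid(matrix(runif(12), 3, 4))
#' f <- tempfile(fileext = ".tif")
#' write_geotiff(g, f)
#' identical(as.matrix(read_geotiff(f)), as.matrix(g))
#' @name geotiff
NULL

TIFF_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                     `11` = 4L, `12` = 8L)

#' @rdname geotiff
#' @export
write_geotiff <- function(grid, path) {
  validate_geo_grid(grid)
  d <- dim(grid$values)
  vals <- grid$values
  vals[is.na(vals)] <- grid$nodata
  # TIFF strips are row-major, top row first
  pix <- as.vector(t(vals))
  nbytes <- length(pix) * 8L

  nodata_str <- charToRaw(format(grid$nodata, scientific = FALSE))
  nodata_str <- c(nodata_str, as.raw(0L))

  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  dbl <- function(x) writeBin(as.numeric(x), raw(), size = 8, endian = "little")

  data_off <- 8L
  ifd_off <- data_off + nbytes
  entry <- function(tag, type, count, value_raw) {
    v <- value_raw
    if (length(v) < 4) v <- c(v, raw(4 - length(v)))
    c(u16(tag), u16(type), u32(count), v)
  }

  # out-of-line values live directly after the IFD
  n_entries <- 15L
  after_ifd <- ifd_off + 2L + n_entries * 12L + 4L
  scale_off <- after_ifd
  tie_off <- scale_off + 3L * 8L
  geokey_off <- tie_off + 6L * 8L
  geokeys <- c(1L, 1L, 0L, 3L,      # version, revision, minor, key count
               1024L, 0L, 1L, 2L,   # GTModelType = geographic
               1025L, 0L, 1L, 1L,   # GTRasterType = PixelIsArea
               2048L, 0L, 1L, 4326L)
  nodata_off <- geokey_off + length(geokeys) * 2L

  entries <- c(
    entry(256L, 4L, 1L, u32(d[2])),                    # ImageWidth
    entry(257L, 4L, 1L, u32(d[1])),                    # ImageLength
    entry(258L, 3L, 1L, u16(64L)),                     # BitsPerSample
    entry(259L, 3L, 1L, u16(1L)),                      # no compression
    entry(262L, 3L, 1L, u16(1L)),                      # BlackIsZero
    entry(273L, 4L, 1L, u32(data_off)),                # StripOffsets
    entry(277L, 3L, 1L, u16(1L)),                      # SamplesPerPixel
    entry(278L, 4L, 1L, u32(d[1])),                    # RowsPerStrip
    entry(279L, 4L, 1L, u32(nbytes)),                  # StripByteCounts
    entry(284L, 3L, 1L, u16(1L)),                      # PlanarConfiguration
    entry(339L, 3L, 1L, u16(3L)),                      # SampleFormat = float
    entry(33550L, 12L, 3L, u32(scale_off)),            # ModelPixelScale
    entry(33922L, 12L, 6L, u32(tie_off)),              # ModelTiepoint
    entry(34735L, 3L, length(geokeys), u32(geokey_off)),
    entry(42113L, 2L, length(nodata_str), u32(nodata_off))
  )

  out <- c(
    charToRaw("II"), u16(42L), u32(ifd_off),
    writeBin(pix, raw(), size = 8, endian = "little"),
    u16(n_entries), entries, u32(0L),
    dbl(c(grid$cell_size, grid$cell_size, 0)),
    dbl(c(0, 0, 0, grid$origin_lon, grid$origin_lat, 0)),
    writeBin(geokeys, raw(), size = 2, endian = "little"),
    nodata_str
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

#' @rdname geotiff
#' @export
read_geotiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 8) stop("not a TIFF file: ", path, call. = FALSE)
  order_mark <- rawToChar(buf[1:2])
  endian <- switch(order_mark, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path, call. = FALSE))
  rd <- function(off, n, size, what = "integer", signed = TRUE) {
    readBin(buf[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  if (rd(2, 1, 2, signed = FALSE) != 42) stop("not a TIFF file: ", path, call. = FALSE)
  ifd_off <- rd(4, 1, 4)
  n_entries <- rd(ifd_off, 1, 2, signed = FALSE)

  tags <- list()
  for (i in seq_len(n_entries)) {
    e_off <- ifd_off + 2 + (i - 1) * 12
    tag <- rd(e_off, 1, 2, signed = FALSE)
    type <- rd(e_off + 2, 1, 2, signed = FALSE)
    count <- rd(e_off + 4, 1, 4)
    size <- TIFF_TYPE_SIZES[as.character(type)]
    if (is.na(size)) next
    total <- size * count
    v_off <- if (total <= 4) e_off + 8 else rd(e_off + 8, 1, 4)
    value <- switch(as.character(type),
      `2` = {
        chars <- rd(v_off, count, 1, "raw")
        rawToChar(chars[chars != as.raw(0)])
      },
      `3` = rd(v_off, count, 2, signed = FALSE),
      `4` = rd(v_off, count, 4),
      `11` = rd(v_off, count, 4, "double"),
      `12` = rd(v_off, count, 8, "double"),
      `1` = as.integer(rd(v_off, count, 1, "raw")),
      NULL
    )
    if (!is.null(value)) tags[[as.character(tag)]] <- value
  }

  need <- function(tag, what) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) stop("TIFF is missing required ", what, ": ", path, call. = FALSE)
    v
  }
  width <- need(256, "ImageWidth")
  height <- need(257, "ImageLength")
  spp <- tags[["277"]] %||% 1L
  if (spp != 1) stop("multi-band rasters are not supported (", spp, " bands): ",
                     path, call. = FALSE)
  compression <- tags[["259"]] %||% 1L
  if (compression != 1) stop("compressed TIFF not supported: ", path, call. = FALSE)
  bits <- (tags[["258"]] %||% 1L)[1]
  fmt <- (tags[["339"]] %||% 1L)[1]

  scale <- need(33550, "geotransform (ModelPixelScale)")
  tie <- need(33922, "geotransform (ModelTiepoint)")
  if (abs(scale[1] - scale[2]) > 1e-12 * max(scale[1], scale[2])) {
    stop("non-square cells are not supported (x/y scale ",
         scale[1], "/", scale[2], ")", call. = FALSE)
  }
  # tie point (i, j) -> (lon, lat): shift to the upper-left corner of cell (0,0)
  origin_lon <- tie[4] - tie[1] * scale[1]
  origin_lat <- tie[5] + tie[2] * scale[2]

  strip_offsets <- need(273, "strip offsets")
  strip_bytes <- need(279, "strip byte counts")
  sample_size <- bits / 8
  pix <- unlist(lapply(seq_along(strip_offsets), function(i) {
    n <- strip_bytes[i] / sample_size
    if (fmt == 3) {
      rd(strip_offsets[i], n, sample_size, "double")
    } else {
      rd(strip_offsets[i], n, sample_size, "integer",
         signed = (fmt == 2 || sample_size == 4))
    }
  }))
  if (length(pix) != width * height) {
    stop("pixel count does not match declared dimensions: ", path, call. = FALSE)
  }
  vals <- matrix(as.numeric(pix), nrow = height, ncol = width, byrow = TRUE)

  nodata <- suppressWarnings(as.numeric(tags[["42113"]] %||% NA))
  if (!is.na(nodata)) vals[vals == nodata] <- NA
  vals[is.nan(vals)] <- NA
  geo_grid(vals, origin_lon, origin_lat, scale[1],
           nodata = if (is.na(nodata)) -9999 else nodata)
}
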